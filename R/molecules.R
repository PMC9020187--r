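# Coarse-grain molecule templates for Bis-GMA and TEGDMA, and formulation
# arithmetic.
#
# Mapping labels 1-7 name the bead roles:
#   1 methacrylate (SC4, reactive), 2 ester (N4a), 3 hydroxyl/ether linker
#   (TP1), 4 phenyl ether (TN2a), 5 aromatic ring bead (TC5), 6 isopropylidene
#   bridge (SC2), 7 glycol ether (SN3a).
# TEGDMA is the linear 6-bead chain 1-2-7-7-2-1; Bis-GMA is two 1-2-3-4 arms,
# two 3-bead aromatic rings of label-5 beads, and one bridge bead (label 6).

.MW_DEFAULT <- c(BISGMA = 512.59, TEGDMA = 286.32)

.bead_row <- function(label, type_code) {
  sp <- bead_spec(type_code)
  data.frame(label = label, type_code = type_code, size_class = sp$size_class,
             mass = sp$mass, heavy_atoms = sp$heavy_atoms,
             stringsAsFactors = FALSE)
}

.bond_df <- function(ai, aj, r0, k, constrained = FALSE) {
  data.frame(ai = as.integer(ai), aj = as.integer(aj), r0 = r0, k = k,
             constrained = constrained, dynamic = FALSE)
}

.angle_df <- function(ai, aj, ak, theta0, k, constrained = FALSE) {
  data.frame(ai = as.integer(ai), aj = as.integer(aj), ak = as.integer(ak),
             theta0 = theta0, k = k, constrained = constrained, dynamic = FALSE)
}

.dihedral_df <- function(ai, aj, ak, al, phi0, k, n, improper = FALSE) {
  data.frame(ai = as.integer(ai), aj = as.integer(aj), ak = as.integer(ak),
             al = as.integer(al), phi0 = phi0, k = k, n = as.integer(n),
             improper = improper)
}

#' TEGDMA coarse-grain molecule template
#'
#' Six beads in the mapping-label sequence 1-2-7-7-2-1 (types SC4, N4a,
#' SN3a, SN3a, N4a, SC4; 20 heavy atoms in total), with the tabulated
#' harmonic bonds (1-2: 0.355 nm / 35000; 2-7: 0.345 / 6000; 7-7:
#' 0.37 / 9000), angles (1-2-7: 115 deg / 100; 2-7-7: 124 deg / 100) and
#' periodic dihedrals (1-2-7-7 and 2-7-7-2, each k = 2 kJ/mol, n = 3).
#' Both terminal label-1 beads are reactive methacrylate groups.
#'
#' @return A list of class `cg_template` with fields `species`, `beads`,
#'   `bonds`, `angles`, `dihedrals`, `reactive_locals`, `mw` (g/mol) and
#'   `coords` (reference geometry, nm).
#' @export
tegdma_template <- function() {
  beads <- do.call(rbind, Map(.bead_row,
                              label = c(1L, 2L, 7L, 7L, 2L, 1L),
                              type_code = c("SC4", "N4a", "SN3a",
                                            "SN3a", "N4a", "SC4")))
  bonds <- rbind(
    .bond_df(1, 2, 0.355, 35000),
    .bond_df(2, 3, 0.345, 6000),
    .bond_df(3, 4, 0.370, 9000),
    .bond_df(4, 5, 0.345, 6000),
    .bond_df(5, 6, 0.355, 35000))
  angles <- rbind(
    .angle_df(1, 2, 3, 115, 100),
    .angle_df(2, 3, 4, 124, 100),
    .angle_df(3, 4, 5, 124, 100),
    .angle_df(4, 5, 6, 115, 100))
  dihedrals <- rbind(
    .dihedral_df(1, 2, 3, 4, 0, 2, 3),
    .dihedral_df(2, 3, 4, 5, 0, 2, 3),
    .dihedral_df(3, 4, 5, 6, 0, 2, 3))
  tpl <- structure(list(species = "TEGDMA", beads = beads, bonds = bonds,
                        angles = angles, dihedrals = dihedrals,
                        reactive_locals = c(1L, 6L),
                        mw = unname(.MW_DEFAULT["TEGDMA"])),
                   class = "cg_template")
  tpl$coords <- .template_coords(tpl)
  tpl
}

#' Bis-GMA coarse-grain molecule template
#'
#' Fifteen beads in the canonical order arm A (1-2-3-4), ring A (three
#' label-5 beads), bridge (label 6), ring B, arm B (4-3-2-1). Each aromatic
#' ring is a rigid triangle: two constrained bonds (0.229 nm on the edge
#' adjacent to the arm bead 4, 0.197 nm on the bridge-side edge) plus one
#' constrained angle, and two improper dihedrals (4-5-5-5 at 0 deg /
#' 65 kJ/mol and 5-5-5-6 at 180 deg / 100 kJ/mol) keep it planar with its
#' substituents. Ring rotation is governed by two periodic dihedrals per
#' ring (3-4-5-5 quadruples, k = 8.46 kJ/mol, n = 2, phi0 = 313 deg), and
#' the bridge angle 5-6-5 is stiff (70 deg, 700 kJ/mol/rad^2). All bonded
#' term lists are symmetric under the arm-swapping permutation.
#'
#' @return A `cg_template` (see [tegdma_template()]).
#' @export
bisgma_template <- function() {
  # bead indices: 1-4 arm A; 5-7 ring A (5 bonded to arm bead 4, 7 bonded
  # to the bridge); 8 bridge; 9-11 ring B (9 bonded to arm bead 12, 11 to
  # the bridge); 12-15 arm B (reversed order: 4,3,2,1)
  beads <- do.call(rbind, Map(.bead_row,
    label = c(1L, 2L, 3L, 4L, 5L, 5L, 5L, 6L, 5L, 5L, 5L, 4L, 3L, 2L, 1L),
    type_code = c("SC4", "N4a", "TP1", "TN2a", "TC5", "TC5", "TC5", "SC2",
                  "TC5", "TC5", "TC5", "TN2a", "TP1", "N4a", "SC4")))
  bonds <- rbind(
    # arm A
    .bond_df(1, 2, 0.355, 35000),
    .bond_df(2, 3, 0.230, 5000),
    .bond_df(3, 4, 0.240, 28000),
    .bond_df(4, 5, 0.300, 15000),
    # ring A constraints: longer edge adjacent to the bead bonded to type 4
    .bond_df(5, 6, 0.229, NA_real_, constrained = TRUE),
    .bond_df(6, 7, 0.197, NA_real_, constrained = TRUE),
    .bond_df(7, 8, 0.271, 35000),
    # ring B (mirror image)
    .bond_df(11, 8, 0.271, 35000),
    .bond_df(10, 11, 0.197, NA_real_, constrained = TRUE),
    .bond_df(9, 10, 0.229, NA_real_, constrained = TRUE),
    .bond_df(12, 9, 0.300, 15000),
    # arm B
    .bond_df(13, 12, 0.240, 28000),
    .bond_df(14, 13, 0.230, 5000),
    .bond_df(15, 14, 0.355, 35000))
  # constrained ring angle: between the two constrained edges; with the
  # third triangle side implied by the law of cosines (see vignette)
  ring_angle <- 60
  angles <- rbind(
    .angle_df(1, 2, 3, 108, 110),
    .angle_df(2, 3, 4, 76, 120),
    .angle_df(3, 4, 5, 130, 40),
    .angle_df(4, 5, 6, 120, 80),
    .angle_df(5, 6, 7, ring_angle, NA_real_, constrained = TRUE),
    .angle_df(6, 7, 8, 140, 130),
    .angle_df(7, 8, 11, 70, 700),
    .angle_df(10, 11, 8, 140, 130),
    .angle_df(9, 10, 11, ring_angle, NA_real_, constrained = TRUE),
    .angle_df(12, 9, 10, 120, 80),
    .angle_df(13, 12, 9, 130, 40),
    .angle_df(14, 13, 12, 76, 120),
    .angle_df(15, 14, 13, 108, 110))
  dihedrals <- rbind(
    .dihedral_df(1, 2, 3, 4, 0, 35, 1),
    # ring-rotation dihedrals: two per ring on the ring edges at the
    # arm-attached bead (the second edge is the rigid-triangle side)
    .dihedral_df(3, 4, 5, 6, 313, 8.46, 2),
    .dihedral_df(3, 4, 5, 7, 313, 8.46, 2),
    .dihedral_df(13, 12, 9, 10, 313, 8.46, 2),
    .dihedral_df(13, 12, 9, 11, 313, 8.46, 2),
    .dihedral_df(15, 14, 13, 12, 0, 35, 1),
    # impropers keeping rings planar with their substituents
    .dihedral_df(4, 5, 6, 7, 0, 65, 1, improper = TRUE),
    .dihedral_df(5, 6, 7, 8, 180, 100, 1, improper = TRUE),
    .dihedral_df(12, 9, 10, 11, 0, 65, 1, improper = TRUE),
    .dihedral_df(9, 10, 11, 8, 180, 100, 1, improper = TRUE))
  tpl <- structure(list(species = "BISGMA", beads = beads, bonds = bonds,
                        angles = angles, dihedrals = dihedrals,
                        reactive_locals = c(1L, 15L),
                        mw = unname(.MW_DEFAULT["BISGMA"])),
                   class = "cg_template")
  tpl$coords <- .template_coords(tpl)
  tpl
}

# Deterministic reference geometry: grow the molecule along its bond tree
# from a fixed direction sequence, then relax the bonded energy (with
# constraints as stiff springs and a soft intramolecular repulsion) by
# steepest descent. No RNG involved.
.template_coords <- function(tpl) {
  n <- nrow(tpl$beads)
  pos <- matrix(0, n, 3)
  placed <- rep(FALSE, n); placed[1] <- TRUE
  # fixed quasi-uniform direction sequence (spherical Fibonacci points)
  dirs <- t(vapply(seq_len(4 * n), function(i) {
    z <- 1 - 2 * (i - 0.5) / (4 * n)
    th <- i * pi * (3 - sqrt(5))
    r <- sqrt(max(0, 1 - z^2))
    c(r * cos(th), r * sin(th), z)
  }, numeric(3)))
  di <- 1L
  edge <- tpl$bonds[, c("ai", "aj", "r0")]
  repeat {
    progressed <- FALSE
    for (b in seq_len(nrow(edge))) {
      i <- edge$ai[b]; j <- edge$aj[b]
      if (placed[i] && !placed[j]) {
        pos[j, ] <- pos[i, ] + edge$r0[b] * dirs[di, ]; di <- di + 1L
        placed[j] <- TRUE; progressed <- TRUE
      } else if (placed[j] && !placed[i]) {
        pos[i, ] <- pos[j, ] + edge$r0[b] * dirs[di, ]; di <- di + 1L
        placed[i] <- TRUE; progressed <- TRUE
      }
    }
    if (all(placed) || !progressed) break
  }
  if (!all(placed)) stop("template bond graph is disconnected")
  .relax_bonded(pos, tpl$bonds, tpl$angles, tpl$dihedrals)
}

# steepest descent on bonded energy; constrained terms become stiff
# harmonic restraints for the purpose of generating a reference geometry
.relax_bonded <- function(pos, bonds, angles, dihedrals,
                          n_steps = 2000, gamma = 1e-5) {
  b <- bonds
  b$k[b$constrained] <- 50000
  a <- angles
  a$k[a$constrained] <- 1500
  soft_sigma <- 0.30
  e_of <- function(p) {
    r <- .bonded_eval(p, b, a, dihedrals, box = NULL)
    rep_e <- .soft_repulsion(p, b, soft_sigma)
    list(e = r$energy_total + rep_e$energy, f = r$forces + rep_e$forces)
  }
  cur <- e_of(pos)
  for (s in seq_len(n_steps)) {
    fmax <- max(abs(cur$f))
    if (fmax < 1) break
    step <- min(gamma * fmax, 0.02) / max(fmax, 1e-12)
    trial <- pos + step * cur$f
    tr <- e_of(trial)
    if (tr$e <= cur$e) {
      pos <- trial; cur <- tr; gamma <- gamma * 1.2
    } else {
      gamma <- gamma * 0.5
    }
  }
  sweep(pos, 2, colMeans(pos))
}

# soft intramolecular repulsion between beads not directly bonded;
# keeps the generated reference geometry from collapsing onto itself
.soft_repulsion <- function(pos, bonds, sigma, eps = 2) {
  n <- nrow(pos)
  pr <- t(combn(n, 2))
  bonded <- paste(pmin(bonds$ai, bonds$aj), pmax(bonds$ai, bonds$aj))
  keep <- !(paste(pr[, 1], pr[, 2]) %in% bonded)
  pr <- pr[keep, , drop = FALSE]
  d <- pos[pr[, 1], , drop = FALSE] - pos[pr[, 2], , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  within <- r < sigma
  F <- matrix(0, n, 3); e <- 0
  if (any(within)) {
    pr <- pr[within, , drop = FALSE]; d <- d[within, , drop = FALSE]
    r <- r[within]
    e <- sum(eps * (sigma / r - 1)^2)
    fmag <- 2 * eps * (sigma / r - 1) * sigma / r^2
    fv <- d * (fmag / r)
    F <- .acc_force(F, pr[, 1], fv)
    F <- .acc_force(F, pr[, 2], -fv)
  }
  list(energy = e, forces = F)
}

#' Formulation molecule counts from a Bis-GMA weight fraction
#'
#' Converts a requested Bis-GMA weight fraction into integer molecule
#' counts. The total target mass is `mass_basis` TEGDMA-equivalents
#' (`M = mass_basis * mw_tegdma`); each species count is the nearest
#' integer to its mass share divided by its molar mass. With the default
#' molar masses (512.59 and 286.32 g/mol) and `mass_basis = 1000` this
#' reproduces the nine study formulations, e.g. 50 wt% Bis-GMA gives 500
#' TEGDMA and 279 Bis-GMA molecules.
#'
#' @param w_bisgma Bis-GMA weight fraction in `[0, 1]`.
#' @param mass_basis Target mass in TEGDMA molecule equivalents
#'   (default 1000).
#' @param mw Named numeric vector with elements `BISGMA` and `TEGDMA`
#'   (g/mol).
#' @return A list of class `cg_formulation` with `n_tegdma`, `n_bisgma`,
#'   `w_bisgma` (requested), `w_realized`, and `mw`.
#' @export
#' @examples
#' formulation_counts(0.5)  # 500 TEGDMA, 279 Bis-GMA
formulation_counts <- function(w_bisgma, mass_basis = 1000, mw = .MW_DEFAULT) {
  if (!is.finite(w_bisgma) || w_bisgma < 0 || w_bisgma > 1) {
    stop("weight fraction must lie in [0, 1]")
  }
  if (mass_basis <= 0) stop("mass_basis must be positive")
  M <- mass_basis * mw[["TEGDMA"]]
  n_teg <- as.integer(round((1 - w_bisgma) * M / mw[["TEGDMA"]]))
  n_bis <- as.integer(round(w_bisgma * M / mw[["BISGMA"]]))
  m_bis <- n_bis * mw[["BISGMA"]]
  m_teg <- n_teg * mw[["TEGDMA"]]
  w_real <- if (m_bis + m_teg > 0) m_bis / (m_bis + m_teg) else 0
  structure(list(n_tegdma = n_teg, n_bisgma = n_bis,
                 w_bisgma = w_bisgma, w_realized = w_real, mw = mw),
            class = "cg_formulation")
}

#' @export
print.cg_formulation <- function(x, ...) {
  cat(sprintf("Formulation: %d TEGDMA + %d Bis-GMA (requested %.0f wt%%, realized %.1f wt%% Bis-GMA)\n",
              x$n_tegdma, x$n_bisgma, 100 * x$w_bisgma, 100 * x$w_realized))
  invisible(x)
}

#' Serialize a molecule template to an itp-like text block
#'
#' Writes the bead list and bonded-term sections of a template in a
#' GROMACS-itp-like layout (`[atoms]`, `[bonds]`, `[constraints]`,
#' `[angles]`, `[dihedrals]`) for interoperability checks.
#'
#' @param tpl A `cg_template`.
#' @return Character vector of lines.
#' @export
template_itp_text <- function(tpl) {
  out <- c(sprintf("; %s coarse-grain template", tpl$species), "[atoms]")
  out <- c(out, sprintf("%4d %-5s %2d %8.3f", seq_len(nrow(tpl$beads)),
                        tpl$beads$type_code, tpl$beads$label, tpl$beads$mass))
  hb <- tpl$bonds[!tpl$bonds$constrained, ]
  cb <- tpl$bonds[tpl$bonds$constrained, ]
  out <- c(out, "[bonds]",
           sprintf("%4d %4d %8.3f %10.1f", hb$ai, hb$aj, hb$r0, hb$k))
  if (nrow(cb)) {
    out <- c(out, "[constraints]", sprintf("%4d %4d %8.3f", cb$ai, cb$aj, cb$r0))
  }
  ha <- tpl$angles[!tpl$angles$constrained, ]
  out <- c(out, "[angles]",
           sprintf("%4d %4d %4d %8.1f %8.1f", ha$ai, ha$aj, ha$ak, ha$theta0, ha$k))
  out <- c(out, "[dihedrals]",
           sprintf("%4d %4d %4d %4d %8.1f %8.2f %2d %s",
                   tpl$dihedrals$ai, tpl$dihedrals$aj, tpl$dihedrals$ak,
                   tpl$dihedrals$al, tpl$dihedrals$phi0, tpl$dihedrals$k,
                   tpl$dihedrals$n,
                   ifelse(tpl$dihedrals$improper, "; improper", "")))
  out
}
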