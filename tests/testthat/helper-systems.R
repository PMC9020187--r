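# Shared builders for miniature test systems and the bonded-parameter
# transcriptions used by the table-driven template tests.

default_ff <- function(...) {
  ff <- load_forcefield()
  mods <- list(...)
  for (n in names(mods)) ff[[n]] <- mods[[n]]
  ff
}

# a bare topology of n identical unbonded beads (LJ fluid); one bead per
# "molecule" so density bookkeeping stays meaningful
lj_fluid_topology <- function(n, type_code = "N4a") {
  sp <- bead_spec(type_code)
  beads <- data.frame(id = seq_len(n), molecule = seq_len(n),
                      species = "TEGDMA", label = 2L, type_code = type_code,
                      size_class = sp$size_class, mass = sp$mass,
                      heavy_atoms = sp$heavy_atoms)
  structure(list(
    beads = beads,
    bonds = data.frame(ai = integer(0), aj = integer(0), r0 = numeric(0),
                       k = numeric(0), constrained = logical(0),
                       dynamic = logical(0)),
    angles = data.frame(ai = integer(0), aj = integer(0), ak = integer(0),
                        theta0 = numeric(0), k = numeric(0),
                        constrained = logical(0), dynamic = logical(0)),
    dihedrals = data.frame(ai = integer(0), aj = integer(0), ak = integer(0),
                           al = integer(0), phi0 = numeric(0), k = numeric(0),
                           n = integer(0), improper = logical(0)),
    reactive = rep(FALSE, n), active = rep(FALSE, n),
    consumed = rep(FALSE, n), initial_active = integer(0),
    mw = c(BISGMA = 512.59, TEGDMA = 286.32), n_static_bonds = 0L,
    bond_log = data.frame(attempt = integer(0), bead_i = integer(0),
                          bead_j = integer(0), distance_nm = numeric(0))),
    class = "cg_topology")
}

lj_fluid_state <- function(n_side, spacing, jitter = 0, seed = 1) {
  set.seed(seed)
  g <- seq_len(n_side) * spacing - spacing / 2
  pos <- as.matrix(expand.grid(g, g, g))
  colnames(pos) <- NULL
  pos <- pos + matrix(runif(length(pos), -jitter, jitter), ncol = 3)
  cg_state(pos, rep(n_side * spacing, 3))
}

# small equilibrated TEGDMA box reused across engine tests
tegdma_box <- function(n_mol = 30, density = 0.6, seed = 3) {
  f <- formulation_counts(0)
  f$n_tegdma <- as.integer(n_mol); f$n_bisgma <- 0L
  pack_box(f, n_active = 0, target_density = density, seed = seed)
}

bisgma_box <- function(n_mol = 8, density = 0.3, seed = 8) {
  f <- formulation_counts(1)
  f$n_bisgma <- as.integer(n_mol); f$n_tegdma <- 0L
  pack_box(f, n_active = 0, target_density = density, seed = seed)
}

# transcription of the published bonded-parameter tables, by mapping label
# sequences, with the expected per-template term counts
bond_table <- function() {
  rbind(
    data.frame(li = 1, lj = 2, r0 = 0.355, k = 35000, constrained = FALSE, n_bis = 2, n_teg = 2),
    data.frame(li = 2, lj = 3, r0 = 0.230, k = 5000,  constrained = FALSE, n_bis = 2, n_teg = 0),
    data.frame(li = 3, lj = 4, r0 = 0.240, k = 28000, constrained = FALSE, n_bis = 2, n_teg = 0),
    data.frame(li = 4, lj = 5, r0 = 0.300, k = 15000, constrained = FALSE, n_bis = 2, n_teg = 0),
    data.frame(li = 5, lj = 5, r0 = 0.229, k = NA,    constrained = TRUE,  n_bis = 2, n_teg = 0),
    data.frame(li = 5, lj = 5, r0 = 0.197, k = NA,    constrained = TRUE,  n_bis = 2, n_teg = 0),
    data.frame(li = 5, lj = 6, r0 = 0.271, k = 35000, constrained = FALSE, n_bis = 2, n_teg = 0),
    data.frame(li = 2, lj = 7, r0 = 0.345, k = 6000,  constrained = FALSE, n_bis = 0, n_teg = 2),
    data.frame(li = 7, lj = 7, r0 = 0.370, k = 9000,  constrained = FALSE, n_bis = 0, n_teg = 1))
}

angle_table <- function() {
  rbind(
    data.frame(li = 1, lj = 2, lk = 3, theta0 = 108, k = 110, n_bis = 2, n_teg = 0),
    data.frame(li = 2, lj = 3, lk = 4, theta0 = 76,  k = 120, n_bis = 2, n_teg = 0),
    data.frame(li = 3, lj = 4, lk = 5, theta0 = 130, k = 40,  n_bis = 2, n_teg = 0),
    data.frame(li = 4, lj = 5, lk = 5, theta0 = 120, k = 80,  n_bis = 2, n_teg = 0),
    data.frame(li = 5, lj = 5, lk = 6, theta0 = 140, k = 130, n_bis = 2, n_teg = 0),
    data.frame(li = 5, lj = 6, lk = 5, theta0 = 70,  k = 700, n_bis = 1, n_teg = 0),
    data.frame(li = 1, lj = 2, lk = 7, theta0 = 115, k = 100, n_bis = 0, n_teg = 2),
    data.frame(li = 2, lj = 7, lk = 7, theta0 = 124, k = 100, n_bis = 0, n_teg = 2))
}

dihedral_table <- function() {
  rbind(
    data.frame(phi0 = 0,   k = 35,   n = 1, improper = FALSE, n_bis = 2, n_teg = 0),
    data.frame(phi0 = 313, k = 8.46, n = 2, improper = FALSE, n_bis = 4, n_teg = 0),
    data.frame(phi0 = 0,   k = 2,    n = 3, improper = FALSE, n_bis = 0, n_teg = 3),
    data.frame(phi0 = 0,   k = 65,   n = 1, improper = TRUE,  n_bis = 2, n_teg = 0),
    data.frame(phi0 = 180, k = 100,  n = 1, improper = TRUE,  n_bis = 2, n_teg = 0))
}

# random 4-bead configurations with non-degenerate internal geometry
# (flanking angles away from collinearity), for gradient checks
random_quad <- function() {
  repeat {
    p <- matrix(rnorm(12, sd = 0.35), 4, 3)
    ok <- TRUE
    for (trip in list(1:3, 2:4)) {
      a <- p[trip[1], ] - p[trip[2], ]; b <- p[trip[3], ] - p[trip[2], ]
      cth <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      if (abs(cth) > 0.9) ok <- FALSE
    }
    if (min(dist(p)) < 0.1) ok <- FALSE
    if (ok) return(p)
  }
}

empty_bonds <- function() data.frame(ai = integer(0), aj = integer(0),
                                     r0 = numeric(0), k = numeric(0),
                                     constrained = logical(0), dynamic = logical(0))
empty_angles <- function() data.frame(ai = integer(0), aj = integer(0),
                                      ak = integer(0), theta0 = numeric(0),
                                      k = numeric(0), constrained = logical(0),
                                      dynamic = logical(0))
empty_dihedrals <- function() data.frame(ai = integer(0), aj = integer(0),
                                         ak = integer(0), al = integer(0),
                                         phi0 = numeric(0), k = numeric(0),
                                         n = integer(0), improper = logical(0))

# numeric gradient of the total bonded + LJ energy for a configuration
numeric_forces <- function(state, topology, ff, pairs = NULL, h = 1e-6) {
  if (is.null(pairs)) {
    np <- neighbor_pairs(state, topology, ff$cutoff, 0)
    pairs <- cgresin:::.pair_table(np, topology, ff)
  }
  Fn <- matrix(0, nrow(state$pos), 3)
  for (i in seq_len(nrow(state$pos))) for (c in 1:3) {
    sp <- state; sp$pos[i, c] <- sp$pos[i, c] + h
    sm <- state; sm$pos[i, c] <- sm$pos[i, c] - h
    ep <- compute_forces(sp, topology, ff, pairs)$energy$total
    em <- compute_forces(sm, topology, ff, pairs)$energy$total
    Fn[i, c] <- -(ep - em) / (2 * h)
  }
  Fn
}
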