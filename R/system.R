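# System building: topology instantiation from templates, random packing in
# the curing study's insertion order (initiators, then Bis-GMA, then the
# remaining TEGDMA), periodic-boundary bookkeeping and neighbor lists.

#' Instantiate a system topology from an ordered list of molecules
#'
#' Lower-level constructor used by [pack_box()] and the fixtures: takes a
#' character vector of species (`"TEGDMA"`/`"BISGMA"`) in insertion order
#' and builds the global bead table and bonded-term tables.
#'
#' @param species Character vector, one entry per molecule, in order.
#' @param mw Named molar masses (g/mol) used for real-mass densities.
#' @return A list of class `cg_topology` with fields `beads` (data frame:
#'   `id`, `molecule`, `species`, `label`, `type_code`, `mass`,
#'   `heavy_atoms`), `bonds`, `angles`, `dihedrals` (term tables with
#'   `dynamic` flags), per-bead state vectors `reactive`, `active`,
#'   `consumed`, `initial_active`, and the event log `bond_log`.
#' @export
build_topology <- function(species, mw = .MW_DEFAULT) {
  tpls <- list(TEGDMA = tegdma_template(), BISGMA = bisgma_template())
  beads <- list(); bonds <- list(); angles <- list(); dihedrals <- list()
  offset <- 0L
  for (m in seq_along(species)) {
    tpl <- tpls[[species[m]]]
    nb <- nrow(tpl$beads)
    b <- tpl$beads
    b$id <- offset + seq_len(nb)
    b$molecule <- m
    b$species <- species[m]
    beads[[m]] <- b[, c("id", "molecule", "species", "label", "type_code",
                        "size_class", "mass", "heavy_atoms")]
    bd <- tpl$bonds; bd$ai <- bd$ai + offset; bd$aj <- bd$aj + offset
    an <- tpl$angles; an$ai <- an$ai + offset; an$aj <- an$aj + offset
    an$ak <- an$ak + offset
    dh <- tpl$dihedrals
    dh$ai <- dh$ai + offset; dh$aj <- dh$aj + offset
    dh$ak <- dh$ak + offset; dh$al <- dh$al + offset
    bonds[[m]] <- bd; angles[[m]] <- an; dihedrals[[m]] <- dh
    offset <- offset + nb
  }
  beads <- do.call(rbind, beads)
  rownames(beads) <- NULL
  n <- nrow(beads)
  structure(list(
    beads = beads,
    bonds = do.call(rbind, bonds),
    angles = do.call(rbind, angles),
    dihedrals = do.call(rbind, dihedrals),
    reactive = beads$label == 1L,
    active = rep(FALSE, n),
    consumed = rep(FALSE, n),
    initial_active = integer(0),
    mw = mw,
    n_static_bonds = sum(vapply(bonds, nrow, 1L)),
    bond_log = data.frame(attempt = integer(0), bead_i = integer(0),
                          bead_j = integer(0), distance_nm = numeric(0))
  ), class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  dyn <- sum(x$bonds$dynamic)
  cat(sprintf("cg_topology: %d beads, %d molecules (%d TEGDMA, %d Bis-GMA)\n",
              nrow(x$beads), max(x$beads$molecule),
              sum(x$beads$species == "TEGDMA") / 6,
              sum(x$beads$species == "BISGMA") / 15))
  cat(sprintf("  bonds: %d static + %d polymer; active labels: %d; conversion: %.3f\n",
              x$n_static_bonds, dyn, sum(x$active), conversion(x)))
  invisible(x)
}

# 1-2 and 1-3 exclusion pairs from the bond graph (constraint bonds and the
# implied third ring edges count as connections), as a canonical i<j matrix
.exclusion_pairs <- function(topology) {
  bonds <- rbind(cbind(topology$bonds$ai, topology$bonds$aj),
                 cbind(topology$angles$ai[topology$angles$constrained],
                       topology$angles$ak[topology$angles$constrained]))
  n <- nrow(topology$beads)
  adj <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
  one_three <- lapply(adj, function(nb) {
    nb <- unique(nb)
    if (length(nb) < 2) return(NULL)
    t(combn(nb, 2))
  })
  one_three <- do.call(rbind, one_three)
  all_pairs <- rbind(bonds, one_three)
  ii <- pmin(all_pairs[, 1], all_pairs[, 2])
  jj <- pmax(all_pairs[, 1], all_pairs[, 2])
  keys <- unique((ii - 1) * n + jj)
  cbind(((keys - 1) %/% n) + 1, ((keys - 1) %% n) + 1)
}

#' Nonbonded neighbor pairs within a cutoff
#'
#' Returns exactly the unordered bead pairs whose minimum-image distance is
#' at most `cutoff + skin`, excluding first (bonded) and second (sharing an
#' angle / two bonds) bonded neighbors.
#'
#' @param state A `cg_state` (positions and box).
#' @param topology The `cg_topology` providing the exclusions.
#' @param cutoff Interaction cutoff, nm.
#' @param skin Extra neighbor-list margin, nm (default 0).
#' @return Two-column integer matrix of pairs with `i < j`.
#' @export
neighbor_pairs <- function(state, topology, cutoff, skin = 0) {
  if (any(state$box < 2 * (cutoff + skin))) {
    stop("box smaller than twice the interaction range")
  }
  pr <- .pair_search(state$pos, state$box, cutoff + skin)
  if (nrow(pr) == 0) return(pr)
  n <- nrow(topology$beads)
  excl <- .exclusion_pairs(topology)
  keys <- (pr[, 1] - 1) * n + pr[, 2]
  ekeys <- (excl[, 1] - 1) * n + excl[, 2]
  pr[!(keys %in% ekeys), , drop = FALSE]
}

# pair table with per-pair LJ coefficients looked up from the force field
.pair_table <- function(pairs, topology, forcefield) {
  if (nrow(pairs) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      sigma = numeric(0), epsilon = numeric(0)))
  }
  ti <- topology$beads$type_code[pairs[, 1]]
  tj <- topology$beads$type_code[pairs[, 2]]
  data.frame(i = pairs[, 1], j = pairs[, 2],
             sigma = forcefield$sigma[cbind(ti, tj)],
             epsilon = forcefield$epsilon[cbind(ti, tj)])
}

#' Simulation state constructor
#'
#' @param pos n-by-3 matrix of positions, nm (stored unwrapped).
#' @param box Length-3 orthorhombic box, nm.
#' @param vel n-by-3 matrix of velocities, nm/ps (defaults to zero).
#' @return A list of class `cg_state`.
#' @export
cg_state <- function(pos, box, vel = NULL) {
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  structure(list(pos = pos, vel = vel, box = box, step = 0L),
            class = "cg_state")
}

#' Wrap positions into the primary periodic cell
#'
#' Positions are kept unwrapped internally (so shrinkage and diffusion are
#' well defined); file writers wrap on output through this helper.
#'
#' @param state A `cg_state`.
#' @return The state with positions folded into `[0, box)`.
#' @export
wrap_positions <- function(state) {
  for (c in 1:3) {
    state$pos[, c] <- state$pos[, c] - state$box[c] * floor(state$pos[, c] / state$box[c])
  }
  state
}

#' Pack a formulation into a periodic box
#'
#' Random-insertion packing in the curing study's order: first the
#' initiator monomers carrying the active (radical) labels, then all
#' Bis-GMA, then the remaining TEGDMA. Each molecule is inserted with a
#' random rigid rotation and translation; an insertion is rejected when
#' any inter-molecular bead distance falls below `min_dist`. Initiators
#' are drawn from TEGDMA when the formulation contains any, otherwise
#' from Bis-GMA; each initiator gets the active flag on one randomly
#' chosen methacrylate bead.
#'
#' @param formulation A `cg_formulation` from [formulation_counts()].
#' @param n_active Number of initiator radicals (active labels).
#' @param target_density Initial packing density guess, g/cm^3 (default
#'   0.9); the box edge follows from the total real mass.
#' @param seed Integer seed; equal seeds give identical coordinates.
#' @param min_dist Inter-molecular rejection distance, nm (default 0.25).
#' @param max_tries Insertion attempts per molecule before failing.
#' @return List with `topology` (a `cg_topology`) and `state` (a
#'   `cg_state`, velocities zero).
#' @export
pack_box <- function(formulation, n_active = 10, target_density = 0.9,
                     seed = NULL, min_dist = 0.25, max_tries = 2000) {
  n_teg <- formulation$n_tegdma
  n_bis <- formulation$n_bisgma
  if (n_active > n_teg + n_bis) stop("more initiators than molecules")
  if (!is.null(seed)) set.seed(seed)

  init_species <- if (n_teg > 0) "TEGDMA" else "BISGMA"
  n_init <- min(n_active, if (init_species == "TEGDMA") n_teg else n_bis)
  if (n_init < n_active) stop("more initiators than molecules of the initiator species")
  rest_teg <- n_teg - if (init_species == "TEGDMA") n_init else 0L
  rest_bis <- n_bis - if (init_species == "BISGMA") n_init else 0L
  species <- c(rep(init_species, n_init), rep("BISGMA", rest_bis),
               rep("TEGDMA", rest_teg))

  topo <- build_topology(species, mw = formulation$mw)
  # molar mass [g/mol] / N_A gives grams per molecule
  mass_g <- (n_bis * formulation$mw[["BISGMA"]] +
             n_teg * formulation$mw[["TEGDMA"]]) / 6.02214076e23
  vol_nm3 <- mass_g / target_density / .NM3_CM3
  L <- vol_nm3^(1 / 3)
  box <- c(L, L, L)

  tpls <- list(TEGDMA = tegdma_template(), BISGMA = bisgma_template())
  pos <- matrix(NA_real_, nrow(topo$beads), 3)
  filled <- 0L
  for (m in seq_along(species)) {
    tpl <- tpls[[species[m]]]
    nb <- nrow(tpl$coords)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      R <- .quat_rot(q)
      cand <- tpl$coords %*% t(R)
      cand <- sweep(cand, 2, stats::runif(3) * box, "+")
      if (filled > 0) {
        dmin <- .min_cross_dist(cand, pos[seq_len(filled), , drop = FALSE], box)
        if (dmin < min_dist) next
      }
      ok <- TRUE
      pos[filled + seq_len(nb), ] <- cand
      filled <- filled + nb
      break
    }
    if (!ok) {
      stop("packing failed for molecule ", m,
           ": no insertion found in ", max_tries,
           " tries; use a larger box (lower target_density)")
    }
  }

  # active labels: one of the two methacrylate beads of each initiator
  for (m in seq_len(n_init)) {
    cand <- topo$beads$id[topo$beads$molecule == m & topo$beads$label == 1L]
    pick <- cand[sample.int(2L, 1L)]
    topo$active[pick] <- TRUE
    topo$reactive[pick] <- FALSE
  }
  topo$initial_active <- which(topo$active)

  list(topology = topo, state = cg_state(pos, box))
}

.quat_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# minimum over all cross distances between two coordinate sets (min image)
.min_cross_dist <- function(a, b, box) {
  dmin <- Inf
  for (k in seq_len(nrow(a))) {
    d <- .mic(sweep(b, 2, a[k, ]), box)
    dmin <- min(dmin, min(rowSums(d^2)))
  }
  sqrt(dmin)
}
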