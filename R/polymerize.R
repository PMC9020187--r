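# Simulated chain-growth polymerization: cutoff-criterion bond formation
# between active (radical-bearing) and reactive (unreacted methacrylate)
# beads, with the active label passed to the reaction partner, followed by
# the bond/relax/retry schedule. Only propagation is modelled; there are no
# termination reactions -- the run ends when no bond forms for a set number
# of consecutive attempts.

#' Polymerization schedule
#'
#' @param bonding_cutoff Bond-formation cutoff, nm (default 0.55, i.e. the
#'   5.5 Angstrom criterion).
#' @param bonds_per_relaxation Successful bonds accumulated before a
#'   relaxation cycle (default 10).
#' @param relax_steps MD steps of the relaxation run after a successful
#'   cycle (default 40000).
#' @param retry_steps MD steps after an attempt that formed no bond
#'   (default 20000).
#' @param max_failed_attempts Consecutive empty attempts before the run
#'   terminates (default 40).
#' @param seed Optional integer seed for the whole run.
#' @return A list of class `polymerization_schedule`.
#' @export
polymerization_schedule <- function(bonding_cutoff = 0.55,
                                    bonds_per_relaxation = 10L,
                                    relax_steps = 40000L,
                                    retry_steps = 20000L,
                                    max_failed_attempts = 40L,
                                    seed = NULL) {
  stopifnot(bonding_cutoff > 0, bonds_per_relaxation >= 1,
            relax_steps >= 0, retry_steps >= 0, max_failed_attempts >= 1)
  structure(list(bonding_cutoff = bonding_cutoff,
                 bonds_per_relaxation = as.integer(bonds_per_relaxation),
                 relax_steps = as.integer(relax_steps),
                 retry_steps = as.integer(retry_steps),
                 max_failed_attempts = as.integer(max_failed_attempts),
                 seed = seed),
            class = "polymerization_schedule")
}

# parameters of the bonded terms added for the polymer backbone; no
# backbone dihedrals are set (numerical stability of the reacted network)
.POLYMER_BOND <- list(r0 = 0.31, k = 35000)
.POLYMER_BACKBONE_ANGLE <- list(theta0 = 125, k = 350)
.POLYMER_SIDECHAIN_ANGLE <- list(theta0 = 80, k = 50)

#' Find bonding candidates within the cutoff
#'
#' All (active bead, reactive bead) pairs whose minimum-image distance is
#' at most the cutoff (boundary included), sorted by ascending distance.
#' Pairs already bonded, self-pairs, and -- by default -- the two
#' methacrylate beads of one and the same monomer are excluded.
#'
#' @param state A `cg_state`.
#' @param topology A `cg_topology` with consistent labels.
#' @param cutoff Bonding cutoff, nm.
#' @param exclude_same_molecule If `TRUE` (default) a monomer's second
#'   methacrylate bead cannot react with its own partner bead directly
#'   (avoids degenerate short loops); network-mediated cyclization remains
#'   possible.
#' @return Data frame with columns `active`, `reactive`, `distance`,
#'   ordered by distance (ties by lowest bead index).
#' @export
find_candidates <- function(state, topology, cutoff,
                            exclude_same_molecule = TRUE) {
  act <- which(topology$active)
  rea <- which(topology$reactive & !topology$consumed & !topology$active)
  empty <- data.frame(active = integer(0), reactive = integer(0),
                      distance = numeric(0))
  if (length(act) == 0 || length(rea) == 0) return(empty)
  grid <- expand.grid(active = act, reactive = rea)
  d <- .mic(state$pos[grid$active, , drop = FALSE] -
            state$pos[grid$reactive, , drop = FALSE], state$box)
  d2 <- rowSums(d^2)
  grid$distance <- sqrt(d2)
  # boundary rule: a pair exactly at the cutoff reacts (<=, compared on
  # squared distances with a relative epsilon against roundoff)
  grid <- grid[d2 <= cutoff^2 * (1 + 1e-12), , drop = FALSE]
  if (nrow(grid) == 0) return(empty)
  if (exclude_same_molecule) {
    mol <- topology$beads$molecule
    grid <- grid[mol[grid$active] != mol[grid$reactive], , drop = FALSE]
  }
  # already-bonded pairs can arise only through prior dynamic bonds
  dyn <- topology$bonds[topology$bonds$dynamic, , drop = FALSE]
  if (nrow(dyn) && nrow(grid)) {
    bk <- paste(pmin(dyn$ai, dyn$aj), pmax(dyn$ai, dyn$aj))
    gk <- paste(pmin(grid$active, grid$reactive),
                pmax(grid$active, grid$reactive))
    grid <- grid[!(gk %in% bk), , drop = FALSE]
  }
  grid[order(grid$distance, pmin(grid$active, grid$reactive)), , drop = FALSE]
}

# neighbors of a bead through non-constrained static bonds (ester side)
.static_neighbors <- function(topology, bead) {
  b <- topology$bonds[!topology$bonds$dynamic, , drop = FALSE]
  c(b$aj[b$ai == bead], b$ai[b$aj == bead])
}

.polymer_neighbors <- function(topology, bead) {
  b <- topology$bonds[topology$bonds$dynamic, , drop = FALSE]
  c(b$aj[b$ai == bead], b$ai[b$aj == bead])
}

#' Apply bond formation to a candidate list
#'
#' Greedy nearest-first matching: each active bead forms at most one bond
#' per call and each reactive bead is consumed at most once. For every
#' formed bond the topology gains the polymer backbone bond
#' (k = 35000 kJ/mol/nm^2, r0 = 0.31 nm); a backbone angle (125 deg,
#' 350 kJ/mol/rad^2) across any bead that now has two polymer bonds; and
#' backbone-sidechain angles (80 deg, 50 kJ/mol/rad^2) between the new
#' bond and each endpoint's ester-side static bond. The active label moves
#' from the initiating bead to the partner.
#'
#' @param topology A `cg_topology`.
#' @param candidates Output of [find_candidates()].
#' @param attempt Attempt index recorded in the bond log.
#' @return List with `topology` and `n_bonds_formed`.
#' @export
apply_bonding <- function(topology, candidates, attempt = NA_integer_) {
  n_formed <- 0L
  used_active <- integer(0)
  for (r in seq_len(nrow(candidates))) {
    a <- candidates$active[r]; p <- candidates$reactive[r]
    if (a %in% used_active) next
    if (!topology$active[a]) {
      stop("candidate references bead ", a, " which is no longer active")
    }
    if (topology$consumed[p] || topology$active[p]) next  # taken this call
    # form the bond
    topology$bonds <- rbind(topology$bonds, data.frame(
      ai = a, aj = p, r0 = .POLYMER_BOND$r0, k = .POLYMER_BOND$k,
      constrained = FALSE, dynamic = TRUE))
    # backbone angle on any bead now holding two polymer bonds
    for (bead in c(a, p)) {
      pn <- .polymer_neighbors(topology, bead)
      if (length(pn) == 2) {
        topology$angles <- rbind(topology$angles, data.frame(
          ai = pn[1], aj = bead, ak = pn[2],
          theta0 = .POLYMER_BACKBONE_ANGLE$theta0,
          k = .POLYMER_BACKBONE_ANGLE$k,
          constrained = FALSE, dynamic = TRUE))
      }
    }
    # backbone-sidechain angles: new bond against each endpoint's static bond
    for (pair in list(c(a, p), c(p, a))) {
      for (nb in .static_neighbors(topology, pair[1])) {
        topology$angles <- rbind(topology$angles, data.frame(
          ai = pair[2], aj = pair[1], ak = nb,
          theta0 = .POLYMER_SIDECHAIN_ANGLE$theta0,
          k = .POLYMER_SIDECHAIN_ANGLE$k,
          constrained = FALSE, dynamic = TRUE))
      }
    }
    # label transfer
    topology$active[a] <- FALSE
    topology$consumed[a] <- TRUE
    topology$active[p] <- TRUE
    topology$reactive[p] <- FALSE
    used_active <- c(used_active, a)
    topology$bond_log <- rbind(topology$bond_log, data.frame(
      attempt = attempt, bead_i = a, bead_j = p,
      distance_nm = candidates$distance[r]))
    n_formed <- n_formed + 1L
  }
  list(topology = topology, n_bonds_formed = n_formed)
}

#' Run the simulated polymerization schedule
#'
#' Repeats bonding attempts against the cutoff criterion. Every successful
#' attempt is followed by an energy minimization (relaxing the freshly
#' formed backbone bonds); after `bonds_per_relaxation` accumulated
#' successes the system is additionally relaxed by `relax_steps` MD steps.
#' An attempt that forms no bond triggers a `retry_steps` MD run and
#' increments the consecutive-failure counter (reset by any success). The
#' run terminates when the counter reaches `max_failed_attempts`.
#'
#' @param state Equilibrated `cg_state`.
#' @param topology A `cg_topology` with at least one active label (a run
#'   without actives terminates with zero conversion).
#' @param forcefield A `cg_forcefield`.
#' @param schedule A `polymerization_schedule`.
#' @param ensemble An `ensemble_spec` for the relaxation/retry MD runs
#'   (default 298 K, 1 bar NPT).
#' @param minimize_steps Step cap for the post-bonding minimizations
#'   (default 300).
#' @param minimize_tol Force tolerance (kJ/mol/nm) for those
#'   minimizations (default 200).
#' @param verbose Print per-attempt progress.
#' @return List with `state`, `topology`, and `trace` (data frame:
#'   attempt, bonds_formed, bonds_total, conversion, volume_nm3).
#' @export
polymerization_run <- function(state, topology, forcefield, schedule,
                               ensemble = ensemble_spec(),
                               minimize_steps = 300L, minimize_tol = 200,
                               verbose = FALSE) {
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  failures <- 0L
  since_relax <- 0L
  attempt <- 0L
  trace <- data.frame(attempt = integer(0), bonds_formed = integer(0),
                      bonds_total = integer(0), conversion = numeric(0),
                      volume_nm3 = numeric(0))
  repeat {
    attempt <- attempt + 1L
    cand <- find_candidates(state, topology, schedule$bonding_cutoff)
    res <- apply_bonding(topology, cand, attempt = attempt)
    topology <- res$topology
    n_formed <- res$n_bonds_formed
    trace <- rbind(trace, data.frame(
      attempt = attempt, bonds_formed = n_formed,
      bonds_total = sum(topology$bonds$dynamic),
      conversion = conversion(topology),
      volume_nm3 = prod(state$box)))
    if (verbose) {
      message(sprintf("attempt %d: %d bond(s), conversion %.3f",
                      attempt, n_formed, conversion(topology)))
    }
    if (n_formed == 0L) {
      failures <- failures + 1L
      if (failures >= schedule$max_failed_attempts) break
      if (schedule$retry_steps > 0) {
        out <- run_md(state, topology, forcefield, ensemble,
                      schedule$retry_steps)
        state <- out$state
      }
    } else {
      failures <- 0L
      since_relax <- since_relax + n_formed
      # every topology update is followed by a minimization, relaxing the
      # freshly formed (possibly stretched) backbone bonds before any MD
      state <- minimize(state, topology, forcefield,
                        force_tol = minimize_tol,
                        max_steps = minimize_steps)
      # fresh thermal velocities after each minimization, as in staged
      # minimization/MD curing workflows, so bond-formation work does not
      # accumulate as heat
      state <- init_velocities(state, topology, ensemble$temperature)
      if (since_relax >= schedule$bonds_per_relaxation) {
        if (schedule$relax_steps > 0) {
          out <- run_md(state, topology, forcefield, ensemble,
                        schedule$relax_steps)
          state <- out$state
        }
        since_relax <- 0L
      }
    }
  }
  list(state = state, topology = topology, trace = trace)
}

#' Write the polymerization event log as TSV
#'
#' @param topology A `cg_topology` after a polymerization run.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_bond_log <- function(topology, path) {
  utils::write.table(topology$bond_log, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
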