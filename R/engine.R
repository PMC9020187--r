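# Molecular-dynamics engine: velocity-Verlet propagation at a 20 fs default
# timestep with a stochastic velocity-rescaling thermostat, an isotropic
# weak-coupling barostat, and SHAKE constraints for the rigid aromatic-ring
# triangles (two constrained bonds plus one constrained angle per ring,
# the angle enforced as the equivalent third distance).

#' Ensemble specification
#'
#' @param temperature Thermostat set point, K (default 298).
#' @param pressure Barostat set point, bar (default 1); `NA` disables
#'   pressure coupling (NVT), as does `barostat = "none"`.
#' @param tau_t Thermostat coupling time, ps (default 1.0).
#' @param tau_p Barostat coupling time, ps (default 12.0).
#' @param timestep_fs Integration timestep, fs (default 20).
#' @param thermostat `"vrescale"` (stochastic velocity rescaling) or
#'   `"none"` (NVE).
#' @param barostat `"berendsen"` (isotropic weak coupling) or `"none"`.
#' @param compressibility Isothermal compressibility used by the weak
#'   coupling barostat, bar^-1.
#' @param constraint_tol Relative SHAKE tolerance (default 1e-4).
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(temperature = 298, pressure = 1,
                          tau_t = 1.0, tau_p = 12.0, timestep_fs = 20,
                          thermostat = c("vrescale", "none"),
                          barostat = c("berendsen", "none"),
                          compressibility = 4.5e-5,
                          constraint_tol = 1e-4) {
  thermostat <- match.arg(thermostat)
  barostat <- match.arg(barostat)
  if (temperature <= 0) stop("temperature must be positive")
  if (timestep_fs <= 0) stop("timestep must be positive")
  if (is.na(pressure)) barostat <- "none"
  structure(list(temperature = temperature, pressure = pressure,
                 tau_t = tau_t, tau_p = tau_p, timestep_fs = timestep_fs,
                 thermostat = thermostat, barostat = barostat,
                 compressibility = compressibility,
                 constraint_tol = constraint_tol),
            class = "ensemble_spec")
}

#' Compute forces and the energy breakdown for a system
#'
#' Assembles all bonded terms (harmonic bonds and angles, periodic
#' dihedrals, impropers) and shifted Lennard-Jones nonbonded interactions.
#' The total force over all beads sums to the zero vector.
#'
#' @param state A `cg_state`.
#' @param topology A `cg_topology`.
#' @param forcefield A `cg_forcefield`.
#' @param pairs Optional precomputed pair table (from the internal
#'   neighbor list); when `NULL` the current neighbor pairs at the
#'   force-field cutoff are used.
#' @return List with `forces` (n-by-3, kJ mol^-1 nm^-1), `energy` (named
#'   list: bond, angle, dihedral, improper, lj, total) and `virial`.
#' @export
compute_forces <- function(state, topology, forcefield, pairs = NULL) {
  if (is.null(pairs)) {
    np <- neighbor_pairs(state, topology, forcefield$cutoff, 0)
    pairs <- .pair_table(np, topology, forcefield)
  }
  bd <- .bonded_eval(state$pos, topology$bonds, topology$angles,
                     topology$dihedrals, state$box,
                     prefactor = forcefield$harmonic_prefactor,
                     dihedral_force_cap = forcefield$dihedral_force_cap %||% 1000)
  nb <- .nonbonded_eval(state$pos, pairs, state$box, forcefield$cutoff,
                        shift = identical(forcefield$shift_mode, "potential-shift"))
  en <- list(bond = bd$e_bond, angle = bd$e_angle, dihedral = bd$e_dihedral,
             improper = bd$e_improper, lj = nb$e_lj,
             total = bd$energy_total + nb$e_lj)
  list(forces = bd$forces + nb$forces, energy = en,
       virial = bd$virial + nb$virial)
}

# Distance-constraint list: constrained bonds plus, for each constrained
# angle, the equivalent outer-bead distance by the law of cosines.
.constraint_list <- function(topology) {
  cb <- topology$bonds[topology$bonds$constrained, , drop = FALSE]
  ca <- topology$angles[topology$angles$constrained, , drop = FALSE]
  out <- data.frame(i = cb$ai, j = cb$aj, d0 = cb$r0)
  if (nrow(ca)) {
    d_ik <- vapply(seq_len(nrow(ca)), function(r) {
      a <- ca[r, ]
      len <- function(x, y) {
        hit <- (cb$ai == x & cb$aj == y) | (cb$ai == y & cb$aj == x)
        if (!any(hit)) stop("constrained angle without constrained bonds")
        cb$r0[which(hit)[1]]
      }
      l1 <- len(a$ai, a$aj); l2 <- len(a$aj, a$ak)
      sqrt(l1^2 + l2^2 - 2 * l1 * l2 * cos(a$theta0 * pi / 180))
    }, numeric(1))
    out <- rbind(out, data.frame(i = ca$ai, j = ca$ak, d0 = d_ik))
  }
  out
}

#' Project positions onto the constraint manifold (SHAKE)
#'
#' Iteratively restores all constrained distances (constrained bonds, and
#' constrained angles converted to the equivalent outer-bead distance) to
#' within a relative tolerance, moving beads inversely to their masses.
#'
#' @param positions n-by-3 position matrix, nm.
#' @param constraints Data frame with columns `i`, `j`, `d0` (nm), e.g.
#'   from a topology's constrained terms.
#' @param masses Per-bead masses, amu.
#' @param tol Relative tolerance on each constrained distance.
#' @param box Periodic box (or `NULL`).
#' @param maxit Iteration cap; non-convergence is an error.
#' @param ref_positions Positions supplying the correction directions.
#'   During MD these are the pre-step positions (the classic SHAKE choice,
#'   which keeps the integrator time-reversible and free of first-order
#'   energy drift); the default uses the input positions themselves, which
#'   is appropriate for static projection (minimization, setup).
#' @return List with `positions` and `iterations`.
#' @export
shake_project <- function(positions, constraints, masses, tol = 1e-4,
                          box = NULL, maxit = 2000L,
                          ref_positions = positions) {
  if (is.null(constraints) || nrow(constraints) == 0) {
    return(list(positions = positions, iterations = 0L))
  }
  invm <- 1 / masses
  wi <- invm[constraints$i]; wj <- invm[constraints$j]
  dref <- .mic(ref_positions[constraints$i, , drop = FALSE] -
               ref_positions[constraints$j, , drop = FALSE], box)
  it <- 0L
  repeat {
    d <- .mic(positions[constraints$i, , drop = FALSE] -
              positions[constraints$j, , drop = FALSE], box)
    r2 <- rowSums(d^2)
    err <- sqrt(r2) / constraints$d0 - 1
    if (max(abs(err)) < tol) break
    it <- it + 1L
    if (it > maxit) stop("SHAKE failed to converge in ", maxit, " iterations")
    # mild damping once the plain Jacobi update is slow to settle
    omega <- if (it > maxit / 2) 0.7 else 1.0
    dd <- rowSums(d * dref)
    # fall back to current directions if the reference has turned degenerate
    bad <- dd <= 0.1 * r2
    if (any(bad)) { dref[bad, ] <- d[bad, ]; dd[bad] <- r2[bad] }
    g <- omega * (r2 - constraints$d0^2) / (2 * dd * (wi + wj))
    corr <- dref * g
    positions <- .acc_force(positions, constraints$i, -corr * wi)
    positions <- .acc_force(positions, constraints$j, corr * wj)
  }
  list(positions = positions, iterations = it)
}

# remove relative velocity components along constrained directions (RATTLE)
.rattle_velocities <- function(pos, vel, constraints, masses, tol, box,
                               maxit = 200L) {
  if (is.null(constraints) || nrow(constraints) == 0) return(vel)
  invm <- 1 / masses
  wi <- invm[constraints$i]; wj <- invm[constraints$j]
  d <- .mic(pos[constraints$i, , drop = FALSE] -
            pos[constraints$j, , drop = FALSE], box)
  r2 <- rowSums(d^2)
  for (it in seq_len(maxit)) {
    dv <- vel[constraints$i, , drop = FALSE] - vel[constraints$j, , drop = FALSE]
    rv <- rowSums(d * dv)
    if (max(abs(rv) / sqrt(r2)) < tol) break
    g <- rv / (r2 * (wi + wj))
    corr <- d * g
    vel <- .acc_force(vel, constraints$i, -corr * wi)
    vel <- .acc_force(vel, constraints$j, corr * wj)
  }
  vel
}

#' Steepest-descent energy minimization
#'
#' Adaptive-step steepest descent with SHAKE projection after every
#' accepted move, so constrained ring geometries are preserved. The energy
#' is non-increasing across accepted steps.
#'
#' @param state A `cg_state`.
#' @param topology A `cg_topology`.
#' @param forcefield A `cg_forcefield`.
#' @param force_tol Convergence threshold on the maximum per-bead force
#'   component, kJ mol^-1 nm^-1 (default 10).
#' @param max_steps Step cap (default 500).
#' @return The minimized `cg_state` (velocities untouched), with
#'   attributes `converged` and `n_steps`.
#' @export
minimize <- function(state, topology, forcefield, force_tol = 10,
                     max_steps = 500L) {
  cons <- .constraint_list(topology)
  masses <- topology$beads$mass
  skin <- 0.2
  np <- neighbor_pairs(state, topology, forcefield$cutoff, skin)
  pairs <- .pair_table(np, topology, forcefield)
  ref_pos <- state$pos
  state$pos <- shake_project(state$pos, cons, masses, 1e-6,
                             box = state$box)$positions
  cur <- compute_forces(state, topology, forcefield, pairs)
  if (!is.finite(cur$energy$total)) stop("minimization diverged (energy not finite)")
  gamma <- 1e-6
  steps <- 0L
  while (max(abs(cur$forces)) > force_tol && steps < max_steps) {
    steps <- steps + 1L
    fmax <- max(abs(cur$forces))
    # cap the largest per-bead displacement at 0.02 nm
    scale <- min(gamma, 0.02 / fmax)
    trial <- state
    trial$pos <- state$pos + scale * cur$forces
    trial$pos <- shake_project(trial$pos, cons, masses, 1e-6,
                               box = state$box)$positions
    if (max(abs(trial$pos - ref_pos)) > skin / 2) {
      np <- neighbor_pairs(trial, topology, forcefield$cutoff, skin)
      pairs <- .pair_table(np, topology, forcefield)
      ref_pos <- trial$pos
    }
    tr <- compute_forces(trial, topology, forcefield, pairs)
    if (!is.finite(tr$energy$total)) stop("minimization diverged (energy not finite)")
    if (tr$energy$total <= cur$energy$total) {
      state <- trial; cur <- tr; gamma <- gamma * 1.2
    } else {
      gamma <- gamma * 0.5
      if (gamma < 1e-14) break
    }
  }
  attr(state, "converged") <- max(abs(cur$forces)) <= force_tol
  attr(state, "n_steps") <- steps
  state
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param state A `cg_state`.
#' @param topology A `cg_topology` (for the bead masses).
#' @param temperature Target temperature, K.
#' @param seed Optional integer seed.
#' @return The state with sampled velocities; the centre-of-mass drift is
#'   removed.
#' @export
init_velocities <- function(state, topology, temperature, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- topology$beads$mass
  n <- length(m)
  sd <- sqrt(.kB * temperature / m)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  mom <- colSums(v * m) / sum(m)
  state$vel <- sweep(v, 2, mom)
  state
}

.kinetic <- function(vel, m) 0.5 * sum(m * rowSums(vel^2))

#' Run molecular dynamics
#'
#' Velocity-Verlet propagation with optional stochastic velocity-rescaling
#' thermostat and isotropic weak-coupling barostat; SHAKE is applied to all
#' constrained distances every step. Trajectories are bitwise reproducible
#' for a fixed seed.
#'
#' @param state A `cg_state` (velocities are drawn from the thermostat
#'   temperature when all-zero and a thermostat is active).
#' @param topology A `cg_topology`.
#' @param forcefield A `cg_forcefield`.
#' @param ensemble An `ensemble_spec`.
#' @param n_steps Number of integration steps (0 returns the input state).
#' @param seed Optional integer seed (thermostat noise, velocity init).
#' @param stride Observable sampling stride in steps (default 100).
#' @param skin Neighbor-list skin, nm (default 0.2), with
#'   displacement-triggered rebuilds.
#' @param record_traj If `TRUE`, store position snapshots at each sample.
#' @return List with `state`, `observables` (data frame: step, time_ps,
#'   T_K, P_bar, V_nm3, density_gcm3, energy terms) and optionally `traj`.
#' @export
run_md <- function(state, topology, forcefield, ensemble, n_steps,
                   seed = NULL, stride = 100L, skin = 0.2,
                   record_traj = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (n_steps == 0) {
    return(list(state = state,
                observables = .obs_frame(0), traj = list()))
  }
  dt <- ensemble$timestep_fs / 1000  # ps
  m <- topology$beads$mass
  n <- length(m)
  cons <- .constraint_list(topology)
  n_cons <- nrow(cons)
  ndf <- 3 * n - 3 - n_cons
  tol <- ensemble$constraint_tol

  if (ensemble$thermostat != "none" && all(state$vel == 0)) {
    state <- init_velocities(state, topology, ensemble$temperature)
  }

  np <- neighbor_pairs(state, topology, forcefield$cutoff, skin)
  pairs <- .pair_table(np, topology, forcefield)
  ref_pos <- state$pos
  fr <- compute_forces(state, topology, forcefield, pairs)

  nsamp <- floor(n_steps / stride)
  obs <- .obs_frame(nsamp)
  traj <- if (record_traj) vector("list", nsamp) else NULL
  isamp <- 0L

  for (step in seq_len(n_steps)) {
    # half kick + drift
    state$vel <- state$vel + fr$forces * (dt / 2 / m)
    old_pos <- state$pos
    state$pos <- state$pos + state$vel * dt
    if (n_cons > 0) {
      state$pos <- shake_project(state$pos, cons, m, tol / 2, state$box,
                                 ref_positions = old_pos)$positions
      state$vel <- state$vel + (state$pos - old_pos - state$vel * dt) / dt
    }
    # forces at new positions
    if (max(abs(state$pos - ref_pos)) > skin / 2) {
      np <- neighbor_pairs(state, topology, forcefield$cutoff, skin)
      pairs <- .pair_table(np, topology, forcefield)
      ref_pos <- state$pos
    }
    fr <- compute_forces(state, topology, forcefield, pairs)
    # second half kick
    state$vel <- state$vel + fr$forces * (dt / 2 / m)
    if (n_cons > 0) {
      state$vel <- .rattle_velocities(state$pos, state$vel, cons, m, tol,
                                      state$box)
    }

    K <- .kinetic(state$vel, m)
    Tinst <- 2 * K / (ndf * .kB)
    vol <- prod(state$box)
    Pinst <- (2 * K + fr$virial) / (3 * vol) * .PRESS_UNIT

    if (ensemble$thermostat == "vrescale") {
      state$vel <- state$vel * .vrescale_factor(K, ndf, ensemble$temperature,
                                                dt, ensemble$tau_t)
    }
    if (ensemble$barostat == "berendsen") {
      mu <- (1 - dt / ensemble$tau_p * ensemble$compressibility *
               (ensemble$pressure - Pinst))^(1 / 3)
      mu <- min(max(mu, 0.98), 1.02)
      state$box <- state$box * mu
      state$pos <- state$pos * mu
      ref_pos <- ref_pos * mu
      if (n_cons > 0) {
        # isotropic scaling stretches constrained distances by mu; project
        # back so every frame satisfies the constraint tolerance
        state$pos <- shake_project(state$pos, cons, m, tol / 2,
                                   state$box)$positions
      }
    }

    state$step <- state$step + 1L
    if (step %% stride == 0L) {
      isamp <- isamp + 1L
      obs[isamp, ] <- list(state$step, state$step * dt, Tinst, Pinst,
                           vol, .density_from(topology, vol, "real_mw"),
                           fr$energy$bond, fr$energy$angle,
                           fr$energy$dihedral, fr$energy$improper,
                           fr$energy$lj, K, fr$energy$total + K)
      if (record_traj) traj[[isamp]] <- state$pos
    }
  }
  list(state = state, observables = obs, traj = traj)
}

.obs_frame <- function(n) {
  data.frame(step = integer(n), time_ps = numeric(n), T_K = numeric(n),
             P_bar = numeric(n), V_nm3 = numeric(n),
             density_gcm3 = numeric(n), E_bond = numeric(n),
             E_angle = numeric(n), E_dihedral = numeric(n),
             E_improper = numeric(n), E_lj = numeric(n),
             E_kinetic = numeric(n), E_total = numeric(n))
}

# stochastic velocity rescaling (canonical sampling through velocity
# rescaling); reduces to exact rescaling as tau -> 0 and to NVE as tau -> Inf
.vrescale_factor <- function(K, ndf, T0, dt, tau) {
  if (K <= 0) return(1)
  c1 <- exp(-dt / tau)
  Kbar <- 0.5 * ndf * .kB * T0
  r1 <- stats::rnorm(1)
  rsum <- if (ndf > 1) stats::rchisq(1, ndf - 1) else 0
  a2 <- c1 + (Kbar / (ndf * K)) * (1 - c1) * (r1^2 + rsum) +
    2 * r1 * sqrt(c1 * (1 - c1) * Kbar / (ndf * K))
  sqrt(max(a2, 1e-12))
}

#' Heating sweep: density versus temperature
#'
#' Ramps the thermostat set point linearly from `T_start` to `T_end` over
#' `n_steps` NPT steps, divided into `n_windows` equal windows. The density
#' recorded for a window is the mean over its second half, attributed to
#' the window's midpoint set temperature.
#'
#' @param state Equilibrated `cg_state`.
#' @param topology A `cg_topology`.
#' @param forcefield A `cg_forcefield`.
#' @param T_start,T_end Sweep bounds, K (defaults 150 and 500; heating).
#' @param n_steps Total MD steps across the sweep (default 1e6 matches the
#'   study protocol; scale down for desk-size runs).
#' @param pressure Barostat set point, bar.
#' @param n_windows Number of temperature windows (default 25).
#' @param seed Optional integer seed.
#' @param ... Further arguments to [ensemble_spec()].
#' @return A data frame of class `cg_sweep` with columns `temperature`,
#'   `density`, `n` plus attribute `final_state`.
#' @export
temperature_sweep <- function(state, topology, forcefield,
                              T_start = 150, T_end = 500, n_steps = 1e6,
                              pressure = 1, n_windows = 25, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  steps_per <- max(2L, floor(n_steps / n_windows))
  mids <- T_start + (seq_len(n_windows) - 0.5) / n_windows * (T_end - T_start)
  dens <- numeric(n_windows)
  nsamp <- integer(n_windows)
  stride <- max(1L, floor(steps_per / 20))
  for (w in seq_len(n_windows)) {
    ens <- ensemble_spec(temperature = mids[w], pressure = pressure, ...)
    out <- run_md(state, topology, forcefield, ens, steps_per,
                  stride = stride)
    state <- out$state
    ob <- out$observables
    half <- ob[ob$step > max(ob$step) - steps_per / 2, ]
    dens[w] <- mean(half$density_gcm3)
    nsamp[w] <- nrow(half)
  }
  res <- data.frame(temperature = mids, density = dens, n = nsamp)
  class(res) <- c("cg_sweep", "data.frame")
  attr(res, "final_state") <- state
  res
}
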