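# Force assembly, minimization, SHAKE, and the MD integrator.

test_that("a TEGDMA chain at exact equilibrium geometry has zero bond/angle energy", {
  tpl <- tegdma_template()
  # build the chain with exact bond lengths and angles (planar turtle walk)
  r0 <- tpl$bonds$r0
  th <- tpl$angles$theta0
  pos <- matrix(0, 6, 3)
  dir <- c(1, 0, 0)
  pos[2, ] <- pos[1, ] + r0[1] * dir
  for (k in 3:6) {
    turn <- (180 - th[k - 2]) * pi / 180 * (-1)^k
    R <- matrix(c(cos(turn), -sin(turn), 0, sin(turn), cos(turn), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    dir <- as.vector(R %*% dir)
    pos[k, ] <- pos[k - 1, ] + r0[k - 1] * dir
  }
  topo <- build_topology("TEGDMA")
  st <- cg_state(sweep(pos, 2, c(-2, -3, -3)), c(6, 6, 6))
  fr <- compute_forces(st, topo, load_forcefield())
  expect_lt(fr$energy$bond, 1e-10)
  expect_lt(fr$energy$angle, 1e-10)
})

test_that("two-bead LJ forces match the analytic derivative and forces sum to zero", {
  topo <- lj_fluid_topology(2, "N4a")
  ff <- load_forcefield()
  sg <- ff$sigma["N4a", "N4a"]; ep <- ff$epsilon["N4a", "N4a"]
  for (r in c(0.42, 0.52, 0.8)) {
    st <- cg_state(rbind(c(2, 2, 2), c(2 + r, 2, 2)), c(6, 6, 6))
    fr <- compute_forces(st, topo, ff)
    ana <- lj_energy(r, sg, ep, cutoff = ff$cutoff)
    expect_equal(fr$energy$lj, ana$energy, tolerance = 1e-12)
    expect_equal(fr$forces[2, 1], ana$force, tolerance = 1e-10)
    expect_equal(colSums(fr$forces), c(0, 0, 0), tolerance = 1e-12)
  }
})

test_that("system forces equal the numeric gradient on a packed random box", {
  sys <- tegdma_box(20, density = 0.4, seed = 17)
  ff <- load_forcefield()
  np <- neighbor_pairs(sys$state, sys$topology, ff$cutoff, 0)
  pairs <- cgresin:::.pair_table(np, sys$topology, ff)
  fr <- compute_forces(sys$state, sys$topology, ff, pairs)
  Fn <- numeric_forces(sys$state, sys$topology, ff, pairs)
  rel <- abs(fr$forces - Fn) / pmax(abs(Fn), 1)
  expect_lt(max(rel), 1e-5)
  expect_lt(max(abs(colSums(fr$forces))), 1e-9)
})

test_that("overlapping beads raise a singularity error", {
  topo <- lj_fluid_topology(2)
  st <- cg_state(rbind(c(1, 1, 1), c(1, 1, 1 + 1e-8)), c(4, 4, 4))
  expect_error(compute_forces(st, topo, load_forcefield()), "overlapping")
})

test_that("minimization drives a stretched dimer to its equilibrium length", {
  topo <- lj_fluid_topology(2)
  topo$bonds <- data.frame(ai = 1L, aj = 2L, r0 = 0.4, k = 5000,
                           constrained = FALSE, dynamic = FALSE)
  ff <- make_forcefield(0.4, 1e-6, cutoff = 1.1)  # negligible LJ
  st <- cg_state(rbind(c(2, 2, 2), c(2.65, 2, 2)), c(6, 6, 6))
  out <- minimize(st, topo, ff, force_tol = 0.5, max_steps = 2000)
  expect_true(attr(out, "converged"))
  expect_equal(sqrt(sum((out$pos[1, ] - out$pos[2, ])^2)), 0.4, tolerance = 1e-3)
  # an already-minimal dimer converges without moving
  out2 <- minimize(out, topo, ff, force_tol = 0.5, max_steps = 100)
  expect_equal(out2$pos, out$pos, tolerance = 1e-6)
})

test_that("minimization restores perturbed ring constraints", {
  fx <- make_fixture("bisgma1")
  set.seed(9)
  fx$state$pos <- fx$state$pos + matrix(rnorm(45, sd = 0.02), 15, 3)
  out <- minimize(fx$state, fx$topology, load_forcefield(),
                  force_tol = 50, max_steps = 400)
  cb <- fx$topology$bonds[fx$topology$bonds$constrained, ]
  d <- sqrt(rowSums((out$pos[cb$ai, ] - out$pos[cb$aj, ])^2))
  expect_equal(d, cb$r0, tolerance = 1e-4)
  expect_true(all(sort(unique(round(cb$r0, 3))) == c(0.197, 0.229)))
})

test_that("SHAKE projection is the identity on satisfied constraints and restores stretched ones", {
  fx <- make_fixture("bisgma1")
  topo <- fx$topology
  cons <- cgresin:::.constraint_list(topo)
  m <- topo$beads$mass
  st <- minimize(fx$state, topo, load_forcefield(), force_tol = 50, max_steps = 300)
  out <- shake_project(st$pos, cons, m, tol = 1e-6)
  expect_equal(out$iterations, 0L)
  expect_identical(out$positions, st$pos)
  # stretch one ring edge by 5%
  pp <- st$pos
  edge <- c(cons$i[1], cons$j[1])
  mid <- colMeans(pp[edge, ])
  pp[edge[1], ] <- mid + (pp[edge[1], ] - mid) * 1.05
  pp[edge[2], ] <- mid + (pp[edge[2], ] - mid) * 1.05
  out2 <- shake_project(pp, cons, m, tol = 1e-6)
  d <- sqrt(rowSums((out2$positions[cons$i, ] - out2$positions[cons$j, ])^2))
  expect_equal(d / cons$d0, rep(1, nrow(cons)), tolerance = 1e-5)
})

test_that("constrained angles map to the law-of-cosines distance", {
  topo <- make_fixture("bisgma1")$topology
  cons <- cgresin:::.constraint_list(topo)
  # 6 ring-bond constraints plus 2 angle-derived ones
  expect_equal(nrow(cons), 6)
  d_angle <- sqrt(0.229^2 + 0.197^2 - 2 * 0.229 * 0.197 * cos(60 * pi / 180))
  expect_equal(sort(cons$d0)[3:4], rep(d_angle, 2), tolerance = 1e-12)
})

test_that("zero steps returns the state unchanged and equal seeds give equal trajectories", {
  sys <- tegdma_box(20, density = 0.4, seed = 23)
  ff <- load_forcefield()
  ens <- ensemble_spec(timestep_fs = 10)
  out0 <- run_md(sys$state, sys$topology, ff, ens, 0)
  expect_identical(out0$state$pos, sys$state$pos)
  o1 <- run_md(sys$state, sys$topology, ff, ens, 200, seed = 77, stride = 50)
  o2 <- run_md(sys$state, sys$topology, ff, ens, 200, seed = 77, stride = 50)
  expect_identical(o1$state$pos, o2$state$pos)
  expect_identical(o1$observables, o2$observables)
})

test_that("momentum is conserved with the thermostat off", {
  sys <- tegdma_box(20, density = 0.4, seed = 23)
  st <- minimize(sys$state, sys$topology, load_forcefield(),
                 force_tol = 50, max_steps = 400)
  st <- init_velocities(st, sys$topology, 200, seed = 3)
  out <- run_md(st, sys$topology, load_forcefield(),
                ensemble_spec(timestep_fs = 10, thermostat = "none",
                              barostat = "none"), 300, stride = 100)
  p <- colSums(out$state$vel * sys$topology$beads$mass)
  expect_lt(max(abs(p)), 1e-9)
})

test_that("weak-coupling barostat holds the set pressure on an LJ fluid", {
  topo <- lj_fluid_topology(125)
  ff <- make_forcefield(0.47, 2.5, cutoff = 1.1)
  st <- lj_fluid_state(5, 0.62, jitter = 0.03, seed = 5)
  ens <- ensemble_spec(temperature = 298, pressure = 1, timestep_fs = 20,
                       tau_p = 4)
  out <- run_md(st, topo, ff, ens, 4000, seed = 41, stride = 50)
  ob <- out$observables
  keep <- ob$step > 2000  # discard relaxation
  pbar <- mean(ob$P_bar[keep])
  se <- stats::sd(ob$P_bar[keep]) / sqrt(sum(keep))
  expect_lt(abs(pbar - 1), 4 * se + 20)
  # density settles to something physical for this fluid
  expect_gt(tail(ob$density_gcm3, 1), 0.05)
})

test_that("temperature sweep ramps set points monotonically and reproducibly", {
  sys <- tegdma_box(20, density = 0.4, seed = 23)
  ff <- load_forcefield()
  stm <- minimize(sys$state, sys$topology, ff, force_tol = 50, max_steps = 400)
  sw1 <- temperature_sweep(stm, sys$topology, ff, T_start = 150,
                           T_end = 500, n_steps = 600, n_windows = 6,
                           seed = 9, timestep_fs = 10)
  expect_equal(nrow(sw1), 6)
  expect_true(all(diff(sw1$temperature) > 0))
  expect_equal(sw1$temperature[1], 150 + 350 / 12)
  expect_true(all(sw1$density > 0))
  sw2 <- temperature_sweep(stm, sys$topology, ff, T_start = 150,
                           T_end = 500, n_steps = 600, n_windows = 6,
                           seed = 9, timestep_fs = 10)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
})
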