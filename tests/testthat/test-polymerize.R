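# Cutoff-criterion bonding, label transfer, and the curing schedule.

test_that("candidate search applies the distance criterion inclusively", {
  fx <- make_fixture("mixed14", seed = 3)
  topo <- fx$topology
  act <- which(topo$active)[1]
  rea <- which(topo$reactive & !topo$active)
  rea <- rea[topo$beads$molecule[rea] != topo$beads$molecule[act]][1]
  st <- fx$state
  # place the pair at exactly 0.54, everything else far
  st$pos[rea, ] <- st$pos[act, ] + c(0.54, 0, 0)
  cand <- find_candidates(st, topo, 0.55)
  expect_true(any(cand$active == act & cand$reactive == rea))
  hit <- cand[cand$active == act & cand$reactive == rea, ]
  expect_equal(hit$distance, 0.54, tolerance = 1e-12)
  # boundary inclusion: exactly at the cutoff
  st$pos[rea, ] <- st$pos[act, ] + c(0.55, 0, 0)
  cand2 <- find_candidates(st, topo, 0.55)
  expect_true(any(cand2$active == act & cand2$reactive == rea))
  # sorted ascending by distance
  expect_true(!is.unsorted(cand2$distance))
})

test_that("no candidates exist without reactive partners", {
  fx <- make_fixture("mixed14", seed = 3)
  topo <- fx$topology
  topo$reactive[] <- FALSE
  expect_equal(nrow(find_candidates(fx$state, topo, 5)), 0)
})

test_that("bond formation transfers the active label and keeps the count", {
  fx <- make_fixture("mixed14", seed = 3)
  topo <- fx$topology
  n_act <- sum(topo$active)
  cand <- find_candidates(fx$state, topo, 1.5)
  res <- apply_bonding(topo, cand, attempt = 1L)
  expect_gt(res$n_bonds_formed, 0)
  expect_equal(sum(res$topology$active), n_act)
  # initiating beads are consumed, partners active
  log <- res$topology$bond_log
  expect_true(all(res$topology$consumed[log$bead_i]))
  expect_true(all(res$topology$active[log$bead_j]))
  # static structure untouched
  expect_equal(sum(!res$topology$bonds$dynamic), topo$n_static_bonds)
  expect_equal(nrow(res$topology$beads), nrow(topo$beads))
})

test_that("two actives competing for one reactive bead form exactly one bond", {
  fx <- make_fixture("mixed14", seed = 3)
  topo <- fx$topology
  acts <- which(topo$active)
  rea <- which(topo$reactive & !topo$active)
  mol <- topo$beads$molecule
  rea <- rea[!(mol[rea] %in% mol[acts])][1]
  cand <- data.frame(active = acts, reactive = rea,
                     distance = c(0.30, 0.40))
  res <- apply_bonding(topo, cand, 1L)
  expect_equal(res$n_bonds_formed, 1L)
  # the nearest active wins
  expect_equal(res$topology$bond_log$bead_i, acts[1])
  expect_false(res$topology$active[acts[1]])
  expect_true(res$topology$active[acts[2]])
})

test_that("chain growth involves n+1 beads with the terminal bead active", {
  fx <- make_fixture("chain5", seed = 2)
  topo <- fx$topology
  dyn <- topo$bonds[topo$bonds$dynamic, ]
  expect_equal(nrow(dyn), 5)
  members <- unique(c(dyn$ai, dyn$aj))
  expect_equal(length(members), 6)          # n + 1 label-1 beads
  expect_equal(sum(topo$active[members]), 1) # exactly the chain end
  # interior beads have degree 2 and exactly one backbone angle each
  deg <- table(c(dyn$ai, dyn$aj))
  expect_equal(sort(unname(as.vector(deg))), c(1, 1, 2, 2, 2, 2))
  backbone <- topo$angles[topo$angles$dynamic &
                            topo$angles$theta0 == 125, ]
  expect_equal(nrow(backbone), 4)  # one per degree-2 bead
  expect_true(all(names(deg)[deg == 2] %in% as.character(backbone$aj)))
})

test_that("bonds never join two actives or two reactives, and duplicates are impossible", {
  fx <- make_fixture("mixed14", seed = 5)
  ff <- default_ff()
  sch <- polymerization_schedule(bonding_cutoff = 0.8, bonds_per_relaxation = 4,
                                 relax_steps = 100, retry_steps = 50,
                                 max_failed_attempts = 4, seed = 7)
  st <- minimize(fx$state, fx$topology, ff, force_tol = 100, max_steps = 300)
  ens <- ensemble_spec(timestep_fs = 10, tau_t = 0.2)
  res <- polymerization_run(st, fx$topology, ff, sch, ens, minimize_steps = 150)
  dyn <- res$topology$bonds[res$topology$bonds$dynamic, ]
  # every polymer bond joins two label-1 beads of different molecules
  lab <- res$topology$beads$label
  mol <- res$topology$beads$molecule
  expect_true(all(lab[dyn$ai] == 1 & lab[dyn$aj] == 1))
  expect_true(all(mol[dyn$ai] != mol[dyn$aj]))
  keys <- paste(pmin(dyn$ai, dyn$aj), pmax(dyn$ai, dyn$aj))
  expect_equal(anyDuplicated(keys), 0)
  # label-1 polymer degree never exceeds 2
  expect_true(all(table(c(dyn$ai, dyn$aj)) <= 2))
})

test_that("the schedule terminates after exactly the failure budget when bonding is disabled", {
  fx <- make_fixture("mixed14", seed = 3)
  ff <- default_ff()
  sch <- polymerization_schedule(bonding_cutoff = 1e-6,
                                 bonds_per_relaxation = 10,
                                 relax_steps = 0, retry_steps = 0,
                                 max_failed_attempts = 7, seed = 1)
  res <- polymerization_run(fx$state, fx$topology, ff, sch)
  expect_equal(nrow(res$trace), 7)
  expect_true(all(res$trace$bonds_formed == 0))
  expect_equal(tail(res$trace$conversion, 1),
               conversion(fx$topology))  # only the initiator flags count
})

test_that("a full tiny curing run satisfies the audit invariants", {
  fx <- make_fixture("mixed14", seed = 4)
  ff <- default_ff()
  st <- minimize(fx$state, fx$topology, ff, force_tol = 50, max_steps = 600)
  ens <- ensemble_spec(timestep_fs = 10, tau_t = 0.2)
  out0 <- run_md(st, fx$topology, ff, ens, 400, seed = 9)
  sch <- polymerization_schedule(bonding_cutoff = 0.8, bonds_per_relaxation = 4,
                                 relax_steps = 200, retry_steps = 100,
                                 max_failed_attempts = 5, seed = 13)
  res <- polymerization_run(out0$state, fx$topology, ff, sch, ens)
  expect_gt(conversion(res$topology), 0)
  # replay audit: every logged formation distance within the cutoff
  expect_true(all(res$topology$bond_log$distance_nm <= 0.8))
  # conversion trace is non-decreasing
  expect_true(!is.unsorted(res$trace$conversion))
  # active-label count conserved from packing to termination
  expect_equal(sum(res$topology$active), 2)
  # bead/molecule/static-term counts unchanged
  expect_equal(nrow(res$topology$beads), nrow(fx$topology$beads))
  expect_equal(sum(!res$topology$bonds$dynamic), fx$topology$n_static_bonds)
  expect_equal(nrow(res$topology$dihedrals), nrow(fx$topology$dihedrals))
})
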