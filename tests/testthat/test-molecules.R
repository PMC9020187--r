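# Molecule templates and formulation arithmetic.

test_that("TEGDMA template has the printed bead and term inventory", {
  t <- tegdma_template()
  expect_equal(nrow(t$beads), 6)
  expect_equal(t$beads$label, c(1, 2, 7, 7, 2, 1))
  expect_equal(sum(t$beads$heavy_atoms), 20)
  expect_equal(nrow(t$bonds), 5)
  expect_equal(nrow(t$angles), 4)
  expect_equal(nrow(t$dihedrals), 3)
  expect_equal(t$reactive_locals, c(1L, 6L))
  expect_equal(t$beads$type_code[t$reactive_locals], c("SC4", "SC4"))
})

test_that("Bis-GMA template has the printed bead and term inventory", {
  b <- bisgma_template()
  expect_equal(nrow(b$beads), 15)
  expect_equal(sum(b$beads$heavy_atoms), 37)
  expect_equal(sum(b$beads$label == 5), 6)   # two 3-bead aromatic rings
  expect_equal(sum(b$beads$label == 6), 1)   # one bridge bead
  expect_equal(sum(b$bonds$constrained), 4)  # two constrained bonds per ring
  expect_equal(sum(b$angles$constrained), 2) # one constrained angle per ring
  expect_equal(sum(b$dihedrals$improper), 4) # two impropers per ring
  expect_equal(length(b$reactive_locals), 2)
  expect_equal(b$beads$type_code[b$reactive_locals], c("SC4", "SC4"))
  # the longer constrained edge is adjacent to the arm bead (type 4)
  cb <- b$bonds[b$bonds$constrained, ]
  arm_beads <- which(b$beads$label == 4)
  ring_neighbors_of_arm <- b$bonds$aj[b$bonds$ai %in% arm_beads &
                                        b$beads$label[b$bonds$aj] == 5]
  ring_neighbors_of_arm <- c(ring_neighbors_of_arm,
                             b$bonds$ai[b$bonds$aj %in% arm_beads &
                                          b$beads$label[b$bonds$ai] == 5])
  long_edges <- cb[cb$r0 == 0.229, ]
  expect_true(all(long_edges$ai %in% ring_neighbors_of_arm |
                    long_edges$aj %in% ring_neighbors_of_arm))
})

test_that("template bonded terms match the parameter tables row for row", {
  tb <- bond_table(); ta <- angle_table(); td <- dihedral_table()
  for (tpl in list(bisgma_template(), tegdma_template())) {
    lab <- tpl$beads$label
    col <- if (tpl$species == "BISGMA") "n_bis" else "n_teg"
    for (r in seq_len(nrow(tb))) {
      row <- tb[r, ]
      hit <- ((lab[tpl$bonds$ai] == row$li & lab[tpl$bonds$aj] == row$lj) |
              (lab[tpl$bonds$ai] == row$lj & lab[tpl$bonds$aj] == row$li)) &
        tpl$bonds$r0 == row$r0 &
        (row$constrained | tpl$bonds$k == row$k) &
        tpl$bonds$constrained == row$constrained
      expect_equal(sum(hit), row[[col]],
                   info = sprintf("%s bond %d-%d r0=%g", tpl$species,
                                  row$li, row$lj, row$r0))
    }
    expect_equal(nrow(tpl$bonds), sum(tb[[col]]))
    for (r in seq_len(nrow(ta))) {
      row <- ta[r, ]
      seq_match <- (lab[tpl$angles$ai] == row$li & lab[tpl$angles$aj] == row$lj &
                      lab[tpl$angles$ak] == row$lk) |
        (lab[tpl$angles$ai] == row$lk & lab[tpl$angles$aj] == row$lj &
           lab[tpl$angles$ak] == row$li)
      hit <- seq_match & tpl$angles$theta0 == row$theta0 &
        !tpl$angles$constrained & tpl$angles$k == row$k
      expect_equal(sum(hit), row[[col]],
                   info = sprintf("%s angle %d-%d-%d", tpl$species,
                                  row$li, row$lj, row$lk))
    }
    expect_equal(sum(!tpl$angles$constrained), sum(ta[[col]]))
    for (r in seq_len(nrow(td))) {
      row <- td[r, ]
      hit <- tpl$dihedrals$phi0 == row$phi0 & tpl$dihedrals$k == row$k &
        tpl$dihedrals$n == row$n & tpl$dihedrals$improper == row$improper
      expect_equal(sum(hit), row[[col]],
                   info = sprintf("%s dihedral phi0=%g k=%g", tpl$species,
                                  row$phi0, row$k))
    }
    expect_equal(nrow(tpl$dihedrals), sum(td[[col]]))
  }
})

test_that("templates pass the connectivity check", {
  for (tpl in list(tegdma_template(), bisgma_template())) {
    n <- nrow(tpl$beads)
    # adjacency: bonds plus the rigid-triangle edge implied by each
    # constrained angle
    edges <- rbind(cbind(tpl$bonds$ai, tpl$bonds$aj),
                   cbind(tpl$angles$ai[tpl$angles$constrained],
                         tpl$angles$ak[tpl$angles$constrained]))
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE; adj[edges[, 2:1]] <- TRUE
    # connectedness (BFS)
    seen <- rep(FALSE, n); seen[1] <- TRUE; front <- 1L
    while (length(front)) {
      nxt <- which(apply(adj[front, , drop = FALSE], 2, any) & !seen)
      seen[nxt] <- TRUE; front <- nxt
    }
    expect_true(all(seen))
    # every angle's middle bead is bonded to both outer beads
    for (r in seq_len(nrow(tpl$angles))) {
      a <- tpl$angles[r, ]
      expect_true(adj[a$ai, a$aj] && adj[a$aj, a$ak])
    }
    # every dihedral's consecutive beads are connected
    for (r in seq_len(nrow(tpl$dihedrals))) {
      d <- tpl$dihedrals[r, ]
      expect_true(adj[d$ai, d$aj] && adj[d$aj, d$ak] && adj[d$ak, d$al])
    }
  }
})

test_that("Bis-GMA bonded terms are invariant under the arm swap", {
  b <- bisgma_template()
  perm <- c(15L, 14L, 13L, 12L, 9L, 10L, 11L, 8L, 5L, 6L, 7L, 4L, 3L, 2L, 1L)
  # beads map onto equal specifications
  expect_equal(b$beads$label[perm], b$beads$label)
  expect_equal(b$beads$type_code[perm], b$beads$type_code)
  key_bond <- function(ai, aj, r0, k, cns) {
    paste(pmin(ai, aj), pmax(ai, aj), r0, ifelse(is.na(k), -1, k), cns)
  }
  k1 <- sort(key_bond(b$bonds$ai, b$bonds$aj, b$bonds$r0, b$bonds$k, b$bonds$constrained))
  k2 <- sort(key_bond(perm[b$bonds$ai], perm[b$bonds$aj], b$bonds$r0,
                      b$bonds$k, b$bonds$constrained))
  expect_identical(k1, k2)
  key_ang <- function(ai, aj, ak, t0) {
    paste(pmin(ai, ak), aj, pmax(ai, ak), t0)
  }
  a1 <- sort(key_ang(b$angles$ai, b$angles$aj, b$angles$ak, b$angles$theta0))
  a2 <- sort(key_ang(perm[b$angles$ai], perm[b$angles$aj], perm[b$angles$ak],
                     b$angles$theta0))
  expect_identical(a1, a2)
})

test_that("formulation arithmetic reproduces the nine study tuples", {
  printed <- list(c(1.0, 0, 559), c(0.8, 200, 447), c(0.7, 300, 391),
                  c(0.6, 400, 335), c(0.5, 500, 279), c(0.4, 600, 223),
                  c(0.3, 700, 168), c(0.2, 800, 112), c(0.0, 1000, 0))
  for (p in printed) {
    f <- formulation_counts(p[1])
    expect_equal(f$n_tegdma, p[2], info = sprintf("w = %.1f", p[1]))
    expect_equal(f$n_bisgma, p[3], info = sprintf("w = %.1f", p[1]))
  }
  expect_error(formulation_counts(1.2), "\\[0, 1\\]")
})

test_that("realized weight fraction honors the one-molecule rounding bound", {
  for (w in seq(0.05, 0.95, by = 0.06)) {
    f <- formulation_counts(w)
    M <- 1000 * f$mw[["TEGDMA"]]
    expect_lte(abs(f$w_realized - w), f$mw[["BISGMA"]] / M + 1e-12)
  }
})

test_that("itp-like serialization covers all term sections", {
  txt <- template_itp_text(bisgma_template())
  for (sec in c("[atoms]", "[bonds]", "[constraints]", "[angles]", "[dihedrals]")) {
    expect_true(any(txt == sec))
  }
})
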