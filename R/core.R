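# Internal geometry and force kernels. Positions are stored unwrapped; all
# inter-bead vectors go through the minimum-image convention for an
# orthorhombic box. The virial W = sum(r_ij . F_ij) is accumulated from
# term-local coordinates so it is well defined under periodic boundaries.

#' Minimum-image displacement between two points
#'
#' Returns the displacement `a - b` wrapped into the primary image of an
#' orthorhombic periodic box: every component of the result has magnitude
#' at most half the box length.
#'
#' @param a,b Numeric length-3 vectors or n-by-3 matrices (nm).
#' @param box Length-3 box vector (nm), or `NULL` for no wrapping.
#' @return Displacement(s) with the same shape as the inputs.
#' @export
#' @examples
#' minimum_image(c(0.1, 0, 0), c(9.9, 0, 0), c(10, 10, 10))  # +0.2, 0, 0
minimum_image <- function(a, b, box = NULL) {
  d <- a - b
  .mic(d, box)
}

.mic <- function(d, box) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    for (c in 1:3) d[, c] <- d[, c] - box[c] * round(d[, c] / box[c])
  } else {
    d <- d - box * round(d / box)
  }
  d
}

# accumulate per-term force contributions onto a force matrix, summing
# duplicates (rowsum is the fast path for repeated indices)
.acc_force <- function(F, idx, contrib) {
  if (length(idx) == 0) return(F)
  s <- rowsum(contrib, idx)
  ui <- as.integer(rownames(s))
  F[ui, ] <- F[ui, ] + s
  F
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rownorm <- function(m) sqrt(rowSums(m^2))

# Evaluate all bonded terms (skipping constrained ones). Returns forces,
# per-class energies, and the bonded virial.
.bonded_eval <- function(pos, bonds, angles, dihedrals, box,
                         prefactor = "half", dihedral_force_cap = 1000) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  pf <- if (identical(prefactor, "full")) 1.0 else 0.5
  e_bond <- e_angle <- e_dih <- e_imp <- 0
  W <- 0

  bb <- bonds[!bonds$constrained, , drop = FALSE]
  if (nrow(bb)) {
    d <- .mic(pos[bb$ai, , drop = FALSE] - pos[bb$aj, , drop = FALSE], box)
    r <- .rownorm(d)
    dr <- r - bb$r0
    e_bond <- sum(pf * bb$k * dr^2)
    fmag <- -2 * pf * bb$k * dr
    fv <- d * (fmag / r)
    F <- .acc_force(F, bb$ai, fv)
    F <- .acc_force(F, bb$aj, -fv)
    W <- W + sum(fmag * r)
  }

  aa <- angles[!angles$constrained, , drop = FALSE]
  if (nrow(aa)) {
    rij <- .mic(pos[aa$ai, , drop = FALSE] - pos[aa$aj, , drop = FALSE], box)
    rkj <- .mic(pos[aa$ak, , drop = FALSE] - pos[aa$aj, , drop = FALSE], box)
    nij <- .rownorm(rij); nkj <- .rownorm(rkj)
    cth <- pmin(1, pmax(-1, rowSums(rij * rkj) / (nij * nkj)))
    th <- acos(cth)
    sth <- pmax(sqrt(1 - cth^2), 1e-8)
    dth <- th - aa$theta0 * pi / 180
    e_angle <- sum(pf * aa$k * dth^2)
    dEdth <- 2 * pf * aa$k * dth
    # dtheta/dri = -(1/sin) dcos/dri ; Fi = -dEdth * dtheta/dri
    common <- dEdth / sth
    Fi <- (rkj / (nij * nkj) - rij * (cth / nij^2)) * common
    Fk <- (rij / (nij * nkj) - rkj * (cth / nkj^2)) * common
    F <- .acc_force(F, aa$ai, Fi)
    F <- .acc_force(F, aa$ak, Fk)
    F <- .acc_force(F, aa$aj, -(Fi + Fk))
    W <- W + sum(rij * Fi) + sum(rkj * Fk)
  }

  if (nrow(dihedrals)) {
    dd <- dihedrals
    b1 <- .mic(pos[dd$aj, , drop = FALSE] - pos[dd$ai, , drop = FALSE], box)
    b2 <- .mic(pos[dd$ak, , drop = FALSE] - pos[dd$aj, , drop = FALSE], box)
    b3 <- .mic(pos[dd$al, , drop = FALSE] - pos[dd$ak, , drop = FALSE], box)
    n1 <- .cross3(b1, b2)
    n2 <- .cross3(b2, b3)
    nb2 <- .rownorm(b2)
    phi <- atan2(rowSums(.cross3(n1, n2) * (b2 / nb2)), rowSums(n1 * n2))
    arg <- dd$n * phi - dd$phi0 * pi / 180
    e <- dd$k * (1 + cos(arg))
    e_dih <- sum(e[!dd$improper])
    e_imp <- sum(e[dd$improper])
    dEdphi <- -dd$k * dd$n * sin(arg)
    n1sq <- pmax(rowSums(n1^2), 1e-12)
    n2sq <- pmax(rowSums(n2^2), 1e-12)
    Fi <- n1 * (dEdphi * nb2 / n1sq)
    Fl <- n2 * (-dEdphi * nb2 / n2sq)
    tt <- rowSums(b1 * b2) / nb2^2
    uu <- rowSums(b3 * b2) / nb2^2
    Fj <- -Fi * (1 + tt) + Fl * uu
    Fk <- Fi * tt - Fl * (1 + uu)
    # The analytic dihedral force diverges as 1/sin^2 of the flanking bond
    # angles when a quadruple approaches collinearity -- the well-known
    # instability of dihedrals across soft CG angles. A joint per-term cap
    # rescales the four force contributions of a near-degenerate quadruple
    # as a unit (net force and torque stay zero), bounding the single-step
    # impulse it can deliver. Away from degeneracy the forces are the
    # exact negative energy gradient.
    fmax <- sqrt(pmax(rowSums(Fi^2), rowSums(Fj^2),
                      rowSums(Fk^2), rowSums(Fl^2)))
    capsc <- pmin(1, dihedral_force_cap / pmax(fmax, 1e-12))
    if (any(capsc < 1)) {
      Fi <- Fi * capsc; Fj <- Fj * capsc; Fk <- Fk * capsc; Fl <- Fl * capsc
    }
    F <- .acc_force(F, dd$ai, Fi)
    F <- .acc_force(F, dd$aj, Fj)
    F <- .acc_force(F, dd$ak, Fk)
    F <- .acc_force(F, dd$al, Fl)
    # virial from term-local coordinates p_i = 0, p_j = b1, ...
    W <- W + sum(b1 * Fj) + sum((b1 + b2) * Fk) + sum((b1 + b2 + b3) * Fl)
  }

  list(forces = F, e_bond = e_bond, e_angle = e_angle,
       e_dihedral = e_dih, e_improper = e_imp,
       energy_total = e_bond + e_angle + e_dih + e_imp, virial = W)
}

# LJ evaluation over a precomputed pair table (i, j, sigma, epsilon).
.nonbonded_eval <- function(pos, pairs, box, cutoff, shift) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(list(forces = F, e_lj = 0, virial = 0))
  }
  d <- .mic(pos[pairs$i, , drop = FALSE] - pos[pairs$j, , drop = FALSE], box)
  r <- .rownorm(d)
  if (any(r < 1e-6)) stop("overlapping beads (r < 1e-6 nm)")
  within <- r <= cutoff
  e <- numeric(length(r)); fmag <- numeric(length(r))
  if (any(within)) {
    sr6 <- (pairs$sigma[within] / r[within])^6
    epsw <- pairs$epsilon[within]
    e[within] <- 4 * epsw * (sr6^2 - sr6)
    if (shift) {
      sc6 <- (pairs$sigma[within] / cutoff)^6
      e[within] <- e[within] - 4 * epsw * (sc6^2 - sc6)
    }
    fmag[within] <- 24 * epsw * (2 * sr6^2 - sr6) / r[within]
  }
  fv <- d * (fmag / r)
  F <- .acc_force(F, pairs$i, fv)
  F <- .acc_force(F, pairs$j, -fv)
  list(forces = F, e_lj = sum(e), virial = sum(fmag * r))
}

# All unordered pairs with minimum-image distance <= rmax, found by a
# blocked O(N^2) scan (vectorized; memory bounded by the block size).
.pair_search <- function(pos, box, rmax, block = 512L) {
  n <- nrow(pos)
  if (n < 2) return(matrix(integer(0), 0, 2))
  r2max <- rmax^2
  out_i <- list(); out_j <- list(); nb <- 0L
  jidx <- seq_len(n)
  for (start in seq(1L, n - 1L, by = block)) {
    I <- start:min(start + block - 1L, n - 1L)
    dx <- outer(pos[I, 1], pos[, 1], "-")
    dy <- outer(pos[I, 2], pos[, 2], "-")
    dz <- outer(pos[I, 3], pos[, 3], "-")
    if (!is.null(box)) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
    }
    r2 <- dx * dx + dy * dy + dz * dz
    sel <- r2 <= r2max & outer(I, jidx, "<")
    w <- which(sel, arr.ind = TRUE)
    if (nrow(w)) {
      nb <- nb + 1L
      out_i[[nb]] <- I[w[, 1]]
      out_j[[nb]] <- w[, 2]
    }
  }
  if (nb == 0L) return(matrix(integer(0), 0, 2))
  cbind(unlist(out_i), unlist(out_j))
}
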