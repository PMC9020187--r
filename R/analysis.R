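# Observables: density (real molecular weights or Martini masses),
# volumetric curing shrinkage, double-bond conversion, glass-transition
# estimation from density-temperature sweeps, bonded-distribution
# histograms, and centre-of-geometry mapping of all-atom trajectories.

.density_from <- function(topology, volume_nm3, mass_mode) {
  if (volume_nm3 <= 0) stop("box volume must be positive")
  if (mass_mode == "real_mw") {
    mols <- topology$beads[!duplicated(topology$beads$molecule), ]
    mass_amu <- sum(topology$mw[mols$species])
  } else {
    mass_amu <- sum(topology$beads$mass)
  }
  mass_amu * .AMU_G / (volume_nm3 * .NM3_CM3)
}

#' System density
#'
#' Total mass over box volume in g/cm^3. For reporting model densities the
#' actual molecular weights of the monomers are used (`"real_mw"`, the
#' default); the Martini bead masses that drive the dynamics are available
#' as `"martini"`.
#'
#' @param state A `cg_state` (for the box volume).
#' @param topology A `cg_topology`.
#' @param mass_mode `"real_mw"` or `"martini"`.
#' @return Density in g/cm^3.
#' @export
#' @examples
#' # 100 TEGDMA molecules in a 5 nm cube: 0.3804 g/cm^3
density_gcm3 <- function(state, topology, mass_mode = c("real_mw", "martini")) {
  mass_mode <- match.arg(mass_mode)
  .density_from(topology, prod(state$box), mass_mode)
}

#' Double-bond conversion
#'
#' Fraction of methacrylate (label-1) beads whose double bond has been
#' consumed: beads holding at least one polymer bond, plus -- following the
#' radical mechanism, where initiation consumes the initiator's double
#' bond -- the initially activated beads when
#' `count_initiators_as_reacted` is on (the default).
#'
#' @param topology A `cg_topology`.
#' @param count_initiators_as_reacted Count the initiator beads as reacted
#'   even before their first propagation step.
#' @return Fraction in `[0, 1]`.
#' @export
conversion <- function(topology, count_initiators_as_reacted = TRUE) {
  lab1 <- which(topology$beads$label == 1L)
  if (length(lab1) == 0) return(0)
  dyn <- topology$bonds[topology$bonds$dynamic, , drop = FALSE]
  reacted <- unique(c(dyn$ai, dyn$aj))
  reacted <- reacted[reacted %in% lab1]
  if (count_initiators_as_reacted) {
    reacted <- unique(c(reacted, topology$initial_active))
  }
  length(reacted) / length(lab1)
}

#' Volumetric polymerization shrinkage
#'
#' Percent decrease of the simulation box volume upon curing:
#' `100 (V_before - V_after) / V_before`. A negative value (expansion) is
#' reported as such.
#'
#' @param volume_before Reference (uncured, equilibrated) volume.
#' @param volume_after Volume after curing at matched conversion.
#' @return Shrinkage in percent.
#' @export
shrinkage <- function(volume_before, volume_after) {
  if (volume_before <= 0) stop("reference volume must be positive")
  100 * (volume_before - volume_after) / volume_before
}

#' Sweep series constructor
#'
#' @param temperature Strictly monotone temperatures, K.
#' @param density Positive densities, g/cm^3.
#' @param n Optional per-point sample counts.
#' @return A data frame of class `cg_sweep`.
#' @export
sweep_series <- function(temperature, density, n = rep(1L, length(temperature))) {
  if (any(diff(temperature) <= 0) && any(diff(temperature) >= 0)) {
    if (!all(diff(temperature) > 0) && !all(diff(temperature) < 0)) {
      stop("temperatures must be strictly monotone")
    }
  }
  if (any(density <= 0)) stop("densities must be positive")
  res <- data.frame(temperature = temperature, density = density, n = n)
  class(res) <- c("cg_sweep", "data.frame")
  res
}

#' Glass-transition estimate from a density-temperature sweep
#'
#' Fits two free straight lines to the low- and high-temperature regimes,
#' scanning every interior split point and minimizing the total squared
#' residual, and reports the temperature at which the two fitted lines
#' intersect. On noiseless piecewise-linear input the breakpoint is
#' recovered exactly. If no split improves on a single straight line
#' beyond `tol` (relative), a degenerate-fit warning is raised and the
#' single-line result (with `tg = NA`) returned.
#'
#' @param series A `cg_sweep` (or data frame with `temperature` and
#'   `density`), at least 6 points spanning both regimes.
#' @param min_points Minimum points per segment (default 3).
#' @param tol Relative improvement threshold for the degenerate-fit check.
#' @return List of class `cg_tgfit`: `tg` (K), `slope_low`, `slope_high`
#'   (g cm^-3 K^-1), `intercept_low`, `intercept_high`, `split_index`,
#'   `sse`, `sse_single`, `degenerate`.
#' @export
fit_tg <- function(series, min_points = 3L, tol = 1e-3) {
  x <- series$temperature; y <- series$density
  n <- length(x)
  if (n < 2 * min_points) stop("need at least ", 2 * min_points, " points")
  fit1 <- stats::lm.fit(cbind(1, x), y)
  sse_single <- sum(fit1$residuals^2)
  best <- NULL
  for (k in min_points:(n - min_points)) {
    fl <- stats::lm.fit(cbind(1, x[1:k]), y[1:k])
    fh <- stats::lm.fit(cbind(1, x[(k + 1):n]), y[(k + 1):n])
    sse <- sum(fl$residuals^2) + sum(fh$residuals^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(k = k, sse = sse, cl = fl$coefficients,
                   ch = fh$coefficients)
    }
  }
  # a single line already fits to numerical precision, or no split helps
  scale <- sum((y - mean(y))^2)
  perfect_line <- sse_single <= 1e-12 * max(scale, .Machine$double.eps)
  improve <- if (sse_single > 0) (sse_single - best$sse) / sse_single else 0
  slopes_equal <- abs(best$cl[2] - best$ch[2]) <
    1e-9 * max(abs(best$cl[2]), abs(best$ch[2]), 1e-12)
  degenerate <- perfect_line || slopes_equal ||
    (sse_single > 0 && improve < tol)
  if (degenerate) {
    warning("degenerate fit: no breakpoint improves on a single line")
    return(structure(list(tg = NA_real_,
                          slope_low = unname(fit1$coefficients[2]),
                          slope_high = unname(fit1$coefficients[2]),
                          intercept_low = unname(fit1$coefficients[1]),
                          intercept_high = unname(fit1$coefficients[1]),
                          split_index = NA_integer_, sse = sse_single,
                          sse_single = sse_single, degenerate = TRUE),
                     class = "cg_tgfit"))
  }
  tg <- (best$ch[1] - best$cl[1]) / (best$cl[2] - best$ch[2])
  structure(list(tg = unname(tg), slope_low = unname(best$cl[2]),
                 slope_high = unname(best$ch[2]),
                 intercept_low = unname(best$cl[1]),
                 intercept_high = unname(best$ch[1]),
                 split_index = best$k, sse = best$sse,
                 sse_single = sse_single, degenerate = FALSE),
            class = "cg_tgfit")
}

#' @export
print.cg_tgfit <- function(x, ...) {
  if (x$degenerate) {
    cat("Tg fit: degenerate (single line), slope",
        format(x$slope_low, digits = 4), "\n")
  } else {
    cat(sprintf("Tg = %.1f K (slopes %.2e / %.2e g cm^-3 K^-1, split at point %d)\n",
                x$tg, x$slope_low, x$slope_high, x$split_index))
  }
  invisible(x)
}

#' Bonded-term distributions over a trajectory
#'
#' Normalized histograms of bond lengths, angles, and (proper or improper)
#' dihedral angles over trajectory frames, for validating the
#' parametrization against reference distributions. Dihedral histograms
#' include a mode count above a prominence threshold (bimodality check).
#'
#' @param traj List of n-by-3 position matrices (frames).
#' @param topology A `cg_topology`.
#' @param box Periodic box, or `NULL`.
#' @param terms Any of `"bonds"`, `"angles"`, `"dihedrals"`.
#' @param bins Number of histogram bins.
#' @param term_rows Optional integer rows selecting specific terms of each
#'   table; `NULL` pools all terms of a class.
#' @param prominence Fraction of the maximum density a local maximum must
#'   reach (against its flanking minima) to count as a mode.
#' @return Named list of class `cg_distributions`; each element has
#'   `mids`, `density`, `values` and, for dihedrals, `n_modes`.
#' @export
bonded_distributions <- function(traj, topology, box = NULL,
                                 terms = c("bonds", "angles", "dihedrals"),
                                 bins = 72, term_rows = NULL,
                                 prominence = 0.2) {
  if (length(traj) < 1) stop("need at least one frame")
  terms <- match.arg(terms, several.ok = TRUE)
  out <- list()
  if ("bonds" %in% terms) {
    tab <- topology$bonds[!topology$bonds$constrained, , drop = FALSE]
    if (!is.null(term_rows)) tab <- tab[term_rows, , drop = FALSE]
    if (nrow(tab) == 0) stop("empty bond selection")
    v <- unlist(lapply(traj, function(p) {
      .rownorm(.mic(p[tab$ai, , drop = FALSE] - p[tab$aj, , drop = FALSE], box))
    }))
    out$bonds <- .hist_norm(v, bins)
  }
  if ("angles" %in% terms) {
    tab <- topology$angles[!topology$angles$constrained, , drop = FALSE]
    if (!is.null(term_rows)) tab <- tab[term_rows, , drop = FALSE]
    if (nrow(tab) == 0) stop("empty angle selection")
    v <- unlist(lapply(traj, function(p) {
      rij <- .mic(p[tab$ai, , drop = FALSE] - p[tab$aj, , drop = FALSE], box)
      rkj <- .mic(p[tab$ak, , drop = FALSE] - p[tab$aj, , drop = FALSE], box)
      acos(pmin(1, pmax(-1, rowSums(rij * rkj) /
                          (.rownorm(rij) * .rownorm(rkj))))) * 180 / pi
    }))
    out$angles <- .hist_norm(v, bins)
  }
  if ("dihedrals" %in% terms) {
    tab <- topology$dihedrals
    if (!is.null(term_rows)) tab <- tab[term_rows, , drop = FALSE]
    if (nrow(tab) == 0) stop("empty dihedral selection")
    v <- unlist(lapply(traj, function(p) .dihedral_values(p, tab, box)))
    h <- .hist_norm(v, bins, limits = c(-180, 180))
    h$n_modes <- .count_modes(h$density, prominence, circular = TRUE)
    out$dihedrals <- h
  }
  structure(out, class = "cg_distributions")
}

.dihedral_values <- function(p, tab, box) {
  b1 <- .mic(p[tab$aj, , drop = FALSE] - p[tab$ai, , drop = FALSE], box)
  b2 <- .mic(p[tab$ak, , drop = FALSE] - p[tab$aj, , drop = FALSE], box)
  b3 <- .mic(p[tab$al, , drop = FALSE] - p[tab$ak, , drop = FALSE], box)
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nb2 <- .rownorm(b2)
  atan2(rowSums(.cross3(n1, n2) * (b2 / nb2)), rowSums(n1 * n2)) * 180 / pi
}

.hist_norm <- function(v, bins, limits = range(v)) {
  if (diff(limits) == 0) limits <- limits + c(-0.5, 0.5)
  br <- seq(limits[1], limits[2], length.out = bins + 1)
  h <- graphics::hist(pmin(pmax(v, limits[1]), limits[2]), breaks = br,
                      plot = FALSE)
  list(mids = h$mids, density = h$density, values = v)
}

# count local maxima whose height exceeds `prominence` of the global
# maximum relative to the lower flanking minimum
.count_modes <- function(dens, prominence, circular = FALSE) {
  n <- length(dens)
  if (circular) {
    ext <- c(dens, dens, dens)
    idx <- (n + 1):(2 * n)
  } else {
    ext <- dens; idx <- seq_len(n)
  }
  peak <- 0L
  thr <- prominence * max(dens)
  for (i in idx) {
    if (i == 1 || i == length(ext)) next
    if (ext[i] >= ext[i - 1] && ext[i] > ext[i + 1]) {
      # walk to flanking minima
      l <- i; while (l > 1 && ext[l - 1] <= ext[l]) l <- l - 1
      r <- i; while (r < length(ext) && ext[r + 1] <= ext[r]) r <- r + 1
      if (ext[i] - max(ext[l], ext[r]) >= thr) peak <- peak + 1L
    }
  }
  peak
}

#' Map an all-atom trajectory to coarse-grain beads (centre of geometry)
#'
#' Each bead position is the unweighted mean of its assigned atoms, per
#' frame (centre-of-geometry mapping).
#'
#' @param aa_traj A single m-by-3 matrix or a list of frames.
#' @param mapping Named list: bead name -> integer vector of atom indices.
#' @param n_atoms Optional total heavy-atom count of the mapped residue;
#'   when given, every atom must be assigned exactly once.
#' @return A matrix (or list of matrices) of bead positions, rows named by
#'   bead.
#' @export
cg_map <- function(aa_traj, mapping, n_atoms = NULL) {
  idx <- unlist(mapping)
  if (anyDuplicated(idx)) {
    stop("mapping validation error: atom(s) assigned to more than one bead: ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "))
  }
  if (!is.null(n_atoms)) {
    missing <- setdiff(seq_len(n_atoms), idx)
    if (length(missing)) {
      stop("mapping validation error: unassigned heavy atom(s): ",
           paste(missing, collapse = ", "))
    }
  }
  map_one <- function(fr) {
    out <- t(vapply(mapping, function(a) colMeans(fr[a, , drop = FALSE]),
                    numeric(3)))
    rownames(out) <- names(mapping)
    out
  }
  if (is.list(aa_traj)) lapply(aa_traj, map_one) else map_one(aa_traj)
}

#' Read a mapping definition from an index-group text file
#'
#' Format in the spirit of GROMACS index files: `[ bead_name ]` headers
#' followed by whitespace-separated atom indices; `#` or `;` comments.
#'
#' @param path File path.
#' @return Named list of integer vectors, usable with [cg_map()].
#' @export
read_mapping <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  mapping <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      current <- trimws(gsub("\\[|\\]", "", ln))
      mapping[[current]] <- integer(0)
    } else {
      if (is.null(current)) stop("indices before any [ group ] header")
      mapping[[current]] <- c(mapping[[current]],
                              as.integer(strsplit(ln, "\\s+")[[1]]))
    }
  }
  mapping
}
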