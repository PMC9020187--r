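# Interaction functional forms and parameter tables.
#
# The bonded functional forms are:
#   bond:     V(r)     = 1/2 k (r - r0)^2            [k in kJ mol^-1 nm^-2]
#   angle:    V(theta) = 1/2 k (theta - theta0)^2    [theta in rad internally,
#                                                     k in kJ mol^-1 rad^-2]
#   dihedral: V(phi)   = k (1 + cos(n phi - phi0))   [proper and improper]
#   LJ 12-6:  V(r)     = 4 eps ((sig/r)^12 - (sig/r)^6), potential-shifted
#             to zero at the cutoff.
# The 1/2 prefactor convention for the harmonic terms is the default; the
# k (x - x0)^2 convention is available through `prefactor = "full"`.

.BEAD_TYPES <- c("SC4", "N4a", "TP1", "TN2a", "TC5", "SC2", "SN3a")

.size_class_of <- function(type_code) {
  first <- substr(type_code, 1L, 1L)
  ifelse(first == "T", "tiny", ifelse(first == "S", "small", "regular"))
}

.DEFAULT_MASSES <- c(regular = 72, small = 54, tiny = 36)
.HEAVY_ATOMS <- c(regular = 4L, small = 3L, tiny = 2L)

#' Bead specification for a Martini-3-style bead type
#'
#' Builds the specification record for one of the seven bead types used by
#' the Bis-GMA/TEGDMA model. The size class follows the type-code prefix
#' (`T` = tiny, `S` = small, otherwise regular); tiny, small and regular
#' beads carry two, three and four heavy atoms respectively, and the
#' standard Martini masses are 36, 54 and 72 amu.
#'
#' @param type_code One of `"SC4"`, `"N4a"`, `"TP1"`, `"TN2a"`, `"TC5"`,
#'   `"SC2"`, `"SN3a"`.
#' @param masses Named numeric vector of masses (amu) per size class;
#'   defaults to the standard Martini masses.
#' @return A list of class `bead_spec` with fields `type_code`,
#'   `size_class`, `mass` (amu) and `heavy_atoms`.
#' @export
#' @examples
#' bead_spec("TC5")$heavy_atoms  # 2
bead_spec <- function(type_code, masses = .DEFAULT_MASSES) {
  if (!type_code %in% .BEAD_TYPES) {
    stop("unknown bead type code: ", type_code)
  }
  sc <- .size_class_of(type_code)
  structure(list(type_code = type_code,
                 size_class = sc,
                 mass = unname(masses[[sc]]),
                 heavy_atoms = unname(.HEAVY_ATOMS[[sc]])),
            class = "bead_spec")
}

#' Harmonic bond energy and force
#'
#' Evaluates `V(r) = 1/2 k (r - r0)^2` (or `k (r - r0)^2` under the
#' `"full"` convention) together with the radial force `-dV/dr`.
#'
#' @param r Distance(s) between the bonded beads, nm. Must be positive.
#' @param r0 Equilibrium distance, nm.
#' @param k Force constant, kJ mol^-1 nm^-2.
#' @param prefactor `"half"` (default) or `"full"` harmonic convention.
#' @return List with `energy` (kJ mol^-1) and `force` (kJ mol^-1 nm^-1,
#'   the negative gradient; positive when the bond is compressed).
#' @export
#' @examples
#' harmonic_bond_energy(0.365, r0 = 0.355, k = 35000)$energy  # 1.75
harmonic_bond_energy <- function(r, r0, k, prefactor = c("half", "full")) {
  prefactor <- match.arg(prefactor)
  if (any(r <= 0)) stop("bond distance must be positive")
  pf <- if (prefactor == "half") 0.5 else 1.0
  dr <- r - r0
  list(energy = pf * k * dr^2, force = -2 * pf * k * dr)
}

#' Harmonic angle energy
#'
#' Evaluates `V(theta) = 1/2 k (theta - theta0)^2` with the angle deviation
#' taken in radians, as the printed units (kJ mol^-1 rad^-2) require.
#'
#' @param theta Angle(s), degrees, in `[0, 180]`.
#' @param theta0 Equilibrium angle, degrees.
#' @param k Force constant, kJ mol^-1 rad^-2.
#' @param prefactor `"half"` (default) or `"full"` harmonic convention.
#' @return List with `energy` (kJ mol^-1) and `dE_dtheta`
#'   (kJ mol^-1 rad^-1, derivative with respect to the angle in radians).
#' @export
harmonic_angle_energy <- function(theta, theta0, k,
                                  prefactor = c("half", "full")) {
  prefactor <- match.arg(prefactor)
  if (any(theta < 0 | theta > 180)) stop("angle must lie in [0, 180] degrees")
  pf <- if (prefactor == "half") 0.5 else 1.0
  dth <- (theta - theta0) * pi / 180
  list(energy = pf * k * dth^2, dE_dtheta = 2 * pf * k * dth)
}

#' Periodic (proper or improper) dihedral energy
#'
#' Evaluates `V(phi) = k (1 + cos(n phi - phi0))`. The same functional form
#' is used for proper dihedrals and for the improper dihedrals that keep
#' the aromatic rings planar.
#'
#' @param phi Dihedral angle(s), degrees.
#' @param phi0 Phase angle, degrees.
#' @param k Energy constant, kJ mol^-1.
#' @param n Integer multiplicity, `n >= 1`.
#' @return List with `energy` (kJ mol^-1, in `[0, 2k]`) and `dE_dphi`
#'   (kJ mol^-1 rad^-1).
#' @export
#' @examples
#' periodic_dihedral_energy(0, phi0 = 0, k = 35, n = 1)$energy  # 70
periodic_dihedral_energy <- function(phi, phi0, k, n) {
  if (any(n < 1)) stop("multiplicity must be >= 1")
  arg <- (n * phi - phi0) * pi / 180
  list(energy = k * (1 + cos(arg)), dE_dphi = -k * n * sin(arg))
}

#' Lennard-Jones 12-6 pair energy
#'
#' Evaluates `V(r) = 4 eps ((sig/r)^12 - (sig/r)^6)`, optionally
#' potential-shifted so the energy is exactly zero at the cutoff, and zero
#' beyond it.
#'
#' @param r Distance(s), nm. Must be positive.
#' @param sigma LJ size parameter, nm.
#' @param epsilon LJ well depth, kJ mol^-1.
#' @param cutoff Cutoff distance, nm, or `NULL` for no cutoff.
#' @param shift If `TRUE` (default when a cutoff is given), subtract the
#'   cutoff energy so V(cutoff) = 0.
#' @return List with `energy` (kJ mol^-1) and `force` (kJ mol^-1 nm^-1,
#'   the negative gradient).
#' @export
lj_energy <- function(r, sigma, epsilon, cutoff = NULL, shift = !is.null(cutoff)) {
  if (any(r <= 0)) stop("pair distance must be positive")
  sr6 <- (sigma / r)^6
  e <- 4 * epsilon * (sr6^2 - sr6)
  f <- 24 * epsilon * (2 * sr6^2 - sr6) / r
  if (!is.null(cutoff)) {
    if (shift) {
      sc6 <- (sigma / cutoff)^6
      e <- e - 4 * epsilon * (sc6^2 - sc6)
    }
    beyond <- r > cutoff
    e[beyond] <- 0
    f[beyond] <- 0
  }
  list(energy = e, force = f)
}

#' Load a force-field parameter file
#'
#' Reads a plain-text parameter file with `[masses]` and `[pairs]`
#' sections. Masses are listed as `size_class mass_amu`; pair coefficients
#' as `TYPE1 TYPE2 sigma_nm epsilon_kJmol`. `#` starts a comment. All 28
#' unordered pairs of the seven used bead types must be present; a missing
#' pair, an unknown type code or a nonpositive coefficient is an error,
#' never silently defaulted.
#'
#' @param path Path to the parameter file. The default is the nonbonded
#'   table bundled with the package (synthetic Martini-3-style values; see
#'   the package vignette).
#' @param cutoff Nonbonded cutoff, nm (default 1.1, potential-shifted).
#' @param shift_mode `"potential-shift"` (default) or `"none"`.
#' @return A list of class `cg_forcefield` with `sigma` and `epsilon`
#'   (7 x 7 symmetric matrices with type-code dimnames), `masses` (named
#'   per size class), `cutoff`, `shift_mode` and `harmonic_prefactor`.
#' @export
load_forcefield <- function(path = system.file("extdata",
                                               "nonbonded_synthetic_martini3_style.ff",
                                               package = "cgresin"),
                            cutoff = 1.1,
                            shift_mode = c("potential-shift", "none")) {
  shift_mode <- match.arg(shift_mode)
  if (!file.exists(path)) stop("force-field file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  section <- NA_character_
  masses <- .DEFAULT_MASSES
  nt <- length(.BEAD_TYPES)
  sig <- matrix(NA_real_, nt, nt, dimnames = list(.BEAD_TYPES, .BEAD_TYPES))
  eps <- sig

  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      if (!section %in% c("masses", "pairs")) {
        stop("unknown section in force-field file: [", section, "]")
      }
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (identical(section, "masses")) {
      if (length(tok) != 2 || !tok[1] %in% names(masses)) {
        stop("bad [masses] entry: '", ln, "'")
      }
      m <- as.numeric(tok[2])
      if (!is.finite(m) || m <= 0) stop("nonpositive mass in entry: '", ln, "'")
      masses[tok[1]] <- m
    } else if (identical(section, "pairs")) {
      if (length(tok) != 4) stop("bad [pairs] entry: '", ln, "'")
      a <- tok[1]; b <- tok[2]
      if (!a %in% .BEAD_TYPES) stop("unknown type code '", a, "' in entry: '", ln, "'")
      if (!b %in% .BEAD_TYPES) stop("unknown type code '", b, "' in entry: '", ln, "'")
      s <- as.numeric(tok[3]); e <- as.numeric(tok[4])
      if (!is.finite(s) || s <= 0) stop("nonpositive sigma in entry: '", ln, "'")
      if (!is.finite(e) || e <= 0) stop("nonpositive epsilon in entry: '", ln, "'")
      sig[a, b] <- s; sig[b, a] <- s
      eps[a, b] <- e; eps[b, a] <- e
    } else {
      stop("entry outside a section: '", ln, "'")
    }
  }

  if (anyNA(sig)) {
    miss <- which(is.na(sig) & upper.tri(sig, diag = TRUE), arr.ind = TRUE)
    pair <- paste0("(", .BEAD_TYPES[miss[1, 1]], ",", .BEAD_TYPES[miss[1, 2]], ")")
    stop("missing nonbonded pair ", pair, " in force-field file")
  }

  structure(list(sigma = sig, epsilon = eps, masses = masses,
                 cutoff = cutoff, shift_mode = shift_mode,
                 harmonic_prefactor = "half"),
            class = "cg_forcefield")
}

#' Build a force-field object from explicit tables
#'
#' Programmatic constructor used mainly by tests to run the engine with
#' synthetic nonbonded tables (for example a single-sigma LJ fluid).
#'
#' @param sigma,epsilon 7 x 7 symmetric matrices with type-code dimnames,
#'   or single numbers (expanded to uniform matrices).
#' @param masses Named masses per size class, amu.
#' @param cutoff Nonbonded cutoff, nm.
#' @param shift_mode `"potential-shift"` or `"none"`.
#' @param harmonic_prefactor `"half"` or `"full"`.
#' @return A `cg_forcefield` object (see [load_forcefield()]).
#' @export
make_forcefield <- function(sigma, epsilon, masses = .DEFAULT_MASSES,
                            cutoff = 1.1,
                            shift_mode = c("potential-shift", "none"),
                            harmonic_prefactor = c("half", "full")) {
  shift_mode <- match.arg(shift_mode)
  harmonic_prefactor <- match.arg(harmonic_prefactor)
  nt <- length(.BEAD_TYPES)
  expand <- function(x) {
    if (is.matrix(x)) {
      stopifnot(all(dim(x) == c(nt, nt)))
      if (max(abs(x - t(x))) > 1e-12) stop("pair matrix must be symmetric")
      dimnames(x) <- list(.BEAD_TYPES, .BEAD_TYPES)
      x
    } else {
      matrix(x, nt, nt, dimnames = list(.BEAD_TYPES, .BEAD_TYPES))
    }
  }
  sig <- expand(sigma); eps <- expand(epsilon)
  if (any(sig <= 0) || any(eps <= 0)) stop("sigma and epsilon must be positive")
  structure(list(sigma = sig, epsilon = eps, masses = masses,
                 cutoff = cutoff, shift_mode = shift_mode,
                 harmonic_prefactor = harmonic_prefactor),
            class = "cg_forcefield")
}
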