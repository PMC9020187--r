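# Coordinate and topology file formats: GRO (fixed width, nm), XYZ
# (Angstrom), LAMMPS data (full style) export, and TSV observable tables.
# Writers wrap coordinates into the primary cell on output; the
# GRO and XYZ writers round-trip through their readers at the stated
# format precision.

#' Write a GRO coordinate file
#'
#' @param state A `cg_state`.
#' @param topology A `cg_topology` (residue names and bead naming).
#' @param path Output path.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(state, topology, path, title = "cgresin system") {
  st <- wrap_positions(state)
  n <- nrow(st$pos)
  b <- topology$beads
  resname <- substr(b$species, 1, 5)
  atomname <- paste0("B", b$label)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     b$molecule %% 100000, resname, atomname, b$id %% 100000,
                     st$pos[, 1], st$pos[, 2], st$pos[, 3]),
             sprintf("%10.5f%10.5f%10.5f", st$box[1], st$box[2], st$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' @param path Input path.
#' @return List with `pos` (nm), `box`, `resid`, `resname`, `atomname`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[2]))
  at <- lines[3:(2 + n)]
  pos <- cbind(as.numeric(substr(at, 21, 28)),
               as.numeric(substr(at, 29, 36)),
               as.numeric(substr(at, 37, 44)))
  boxline <- strsplit(trimws(lines[3 + n]), "\\s+")[[1]]
  list(pos = pos,
       box = as.numeric(boxline[1:3]),
       resid = as.integer(substr(at, 1, 5)),
       resname = trimws(substr(at, 6, 10)),
       atomname = trimws(substr(at, 11, 15)))
}

#' Write an XYZ coordinate file (Angstrom)
#'
#' @param state A `cg_state`.
#' @param topology A `cg_topology`.
#' @param path Output path.
#' @param comment Comment line (the box, nm, is appended).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(state, topology, path, comment = "cgresin") {
  st <- wrap_positions(state)
  ang <- st$pos * 10
  lines <- c(sprintf("%d", nrow(ang)),
             sprintf("%s box_nm %.5f %.5f %.5f", comment,
                     st$box[1], st$box[2], st$box[3]),
             sprintf("%-5s %12.5f %12.5f %12.5f",
                     topology$beads$type_code, ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ coordinate file
#'
#' @param path Input path.
#' @return List with `pos` (nm), `types`, and `box` when present in the
#'   comment line.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  box <- NULL
  cm <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  bi <- which(cm == "box_nm")
  if (length(bi) == 1 && length(cm) >= bi + 3) {
    box <- as.numeric(cm[(bi + 1):(bi + 3)])
  }
  tok <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  types <- vapply(tok, `[`, "", 1)
  pos <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3))) / 10
  list(pos = pos, types = types, box = box)
}

#' Export topology and coordinates as a LAMMPS data file (full style)
#'
#' Bonded types are deduplicated by their coefficients; Pair/Bond/Angle
#' coefficient sections are included as comments for interoperability
#' checks (the package does not execute LAMMPS).
#'
#' @param state A `cg_state`.
#' @param topology A `cg_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(state, topology, path) {
  st <- wrap_positions(state)
  b <- topology$beads
  types <- sort(unique(b$type_code))
  tmap <- stats::setNames(seq_along(types), types)
  bonds <- topology$bonds
  bkey <- sprintf("%.4f_%.1f_%d", bonds$r0,
                  ifelse(is.na(bonds$k), -1, bonds$k), bonds$constrained)
  btype <- as.integer(factor(bkey, levels = unique(bkey)))
  ang <- topology$angles
  akey <- sprintf("%.2f_%.1f_%d", ang$theta0,
                  ifelse(is.na(ang$k), -1, ang$k), ang$constrained)
  atype <- as.integer(factor(akey, levels = unique(akey)))
  dih <- topology$dihedrals[!topology$dihedrals$improper, , drop = FALSE]
  imp <- topology$dihedrals[topology$dihedrals$improper, , drop = FALSE]
  dkey <- sprintf("%.1f_%.3f_%d", dih$phi0, dih$k, dih$n)
  dtype <- as.integer(factor(dkey, levels = unique(dkey)))
  ikey <- sprintf("%.1f_%.3f_%d", imp$phi0, imp$k, imp$n)
  itype <- as.integer(factor(ikey, levels = unique(ikey)))

  lines <- c("LAMMPS data file generated by cgresin", "",
             sprintf("%d atoms", nrow(b)),
             sprintf("%d bonds", nrow(bonds)),
             sprintf("%d angles", nrow(ang)),
             sprintf("%d dihedrals", nrow(dih)),
             sprintf("%d impropers", nrow(imp)), "",
             sprintf("%d atom types", length(types)),
             sprintf("%d bond types", max(btype, 0)),
             sprintf("%d angle types", max(atype, 0)),
             sprintf("%d dihedral types", max(dtype, 0)),
             sprintf("%d improper types", max(itype, 0)), "",
             sprintf("0.0 %.6f xlo xhi", st$box[1]),
             sprintf("0.0 %.6f ylo yhi", st$box[2]),
             sprintf("0.0 %.6f zlo zhi", st$box[3]), "",
             "Masses", "",
             sprintf("%d %.3f  # %s", tmap[types],
                     vapply(types, function(t) bead_spec(t)$mass, 1), types),
             "", "Atoms  # full", "",
             sprintf("%d %d %d 0.0 %.6f %.6f %.6f",
                     b$id, b$molecule, tmap[b$type_code],
                     st$pos[, 1], st$pos[, 2], st$pos[, 3]))
  if (nrow(bonds)) {
    lines <- c(lines, "", "Bonds", "",
               sprintf("%d %d %d %d", seq_len(nrow(bonds)), btype,
                       bonds$ai, bonds$aj))
  }
  if (nrow(ang)) {
    lines <- c(lines, "", "Angles", "",
               sprintf("%d %d %d %d %d", seq_len(nrow(ang)), atype,
                       ang$ai, ang$aj, ang$ak))
  }
  if (nrow(dih)) {
    lines <- c(lines, "", "Dihedrals", "",
               sprintf("%d %d %d %d %d %d", seq_len(nrow(dih)), dtype,
                       dih$ai, dih$aj, dih$ak, dih$al))
  }
  if (nrow(imp)) {
    lines <- c(lines, "", "Impropers", "",
               sprintf("%d %d %d %d %d %d", seq_len(nrow(imp)), itype,
                       imp$ai, imp$aj, imp$ak, imp$al))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an observable series as TSV
#'
#' @param observables Data frame (e.g. from [run_md()] or a `cg_sweep`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observables <- function(observables, path) {
  utils::write.table(observables, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
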