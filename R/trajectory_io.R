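# Multi-frame XYZ trajectory I/O with per-frame energies.
#
# The internal canonical energy unit is kcal/mol: all trimming thresholds are
# stated in kcal/mol, so input energies (hartree, eV or kcal/mol) are
# converted on read.

HARTREE_TO_KCALMOL <- 627.5094740631
EV_TO_KCALMOL <- 23.060548

#' Convert energies to kcal/mol
#'
#' @param x Numeric vector of energies.
#' @param from Unit of `x`: `"kcalmol"`, `"hartree"` or `"ev"`.
#' @return Energies in kcal/mol.
#' @export
to_kcalmol <- function(x, from = c("kcalmol", "hartree", "ev")) {
  from <- match.arg(from)
  switch(from,
    kcalmol = x,
    hartree = x * HARTREE_TO_KCALMOL,
    ev = x * EV_TO_KCALMOL
  )
}

#' Convert energies from kcal/mol
#'
#' Inverse of [to_kcalmol()].
#' @inheritParams to_kcalmol
#' @param to Target unit.
#' @return Energies in the target unit.
#' @export
from_kcalmol <- function(x, to = c("kcalmol", "hartree", "ev")) {
  to <- match.arg(to)
  switch(to,
    kcalmol = x,
    hartree = x / HARTREE_TO_KCALMOL,
    ev = x / EV_TO_KCALMOL
  )
}

#' Construct a single trajectory snapshot
#'
#' A snapshot is one trajectory frame: element symbols, Cartesian coordinates
#' and (optionally) an energy in kcal/mol.
#'
#' @param index Zero-or-positive integer frame ordinal.
#' @param elements Character vector of element symbols, one per atom.
#' @param coords Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param energy Scalar energy in kcal/mol, or `NA` if unknown.
#' @param source_tag Free-text provenance (file and frame).
#' @return An object of class `"snapshot"`.
#' @export
snapshot <- function(index, elements, coords, energy = NA_real_,
                     source_tag = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) != nrow(coords)) {
    stop("snapshot: ", length(elements), " elements but ",
         nrow(coords), " coordinate rows")
  }
  if (ncol(coords) != 3) stop("snapshot: coords must have 3 columns")
  if (!is.na(energy) && !is.finite(energy)) stop("snapshot: non-finite energy")
  structure(
    list(index = as.integer(index), elements = as.character(elements),
         coords = coords, energy = as.numeric(energy),
         source_tag = source_tag),
    class = "snapshot"
  )
}

#' @export
print.snapshot <- function(x, ...) {
  cat(sprintf("<snapshot %d: %d atoms (%s), E = %s kcal/mol>\n",
              x$index, length(x$elements),
              paste(unique(x$elements), collapse = ","),
              if (is.na(x$energy)) "NA" else format(x$energy)))
  invisible(x)
}

.new_ensemble <- function(snapshots, energy_unit) {
  if (length(snapshots) == 0) stop("ensemble must contain at least one frame")
  n <- length(snapshots[[1]]$elements)
  for (s in snapshots) {
    if (!identical(s$elements, snapshots[[1]]$elements)) {
      stop("inconsistent element lists across frames (frame ", s$index, ")")
    }
  }
  structure(
    list(snapshots = snapshots, atom_count = n, energy_unit_input = energy_unit),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  e <- vapply(x$snapshots, function(s) s$energy, numeric(1))
  cat(sprintf("<trajectory ensemble: %d frames x %d atoms, E in [%s, %s] kcal/mol>\n",
              length(x$snapshots), x$atom_count,
              format(suppressWarnings(min(e, na.rm = TRUE))),
              format(suppressWarnings(max(e, na.rm = TRUE)))))
  invisible(x)
}

#' @export
length.trajectory_ensemble <- function(x) length(x$snapshots)

# Energy parsing dialect for XYZ comment lines: split the line on whitespace
# and '=' (so "E=-76.26" yields a "-76.26" token), scan tokens left to right,
# and take the first token that parses as a float but is not a pure integer.
# Tolerates comments like "step 5 E=-1.0 Eh" from common MD writers.
.parse_comment_energy <- function(comment) {
  tokens <- strsplit(trimws(comment), "[[:space:]=]+")[[1]]
  float_re <- "^[+-]?([0-9]+\\.[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$|^[+-]?[0-9]+[eE][+-]?[0-9]+$"
  int_re <- "^[+-]?[0-9]+$"
  for (tok in tokens) {
    if (grepl(int_re, tok)) next
    if (grepl(float_re, tok)) return(as.numeric(tok))
  }
  NA_real_
}

#' Read a multi-frame XYZ trajectory
#'
#' Reads a standard multi-frame XYZ file (per frame: atom-count line, comment
#' line, then one `"El x y z"` line per atom). The per-frame energy is taken
#' from the first floating-point token on the comment line (integer tokens are
#' skipped; `key=value` pairs are understood), or from a sidecar energy file,
#' and converted to kcal/mol.
#'
#' @param path Path to the XYZ file.
#' @param energy_unit Unit of the input energies: `"hartree"`, `"kcalmol"` or
#'   `"ev"`.
#' @param energies Optional path to a sidecar energy file (one value per line,
#'   same unit), which overrides comment-line energies.
#' @return A `trajectory_ensemble`: ordered snapshots with energies in
#'   kcal/mol. Frames whose comment line has no parsable energy get `NA`
#'   energy with a warning; they take part in speciation but are excluded from
#'   energy-dependent steps (trimming, styling).
#' @export
read_xyz_trajectory <- function(path,
                                energy_unit = c("kcalmol", "hartree", "ev"),
                                energies = NULL) {
  energy_unit <- match.arg(energy_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) > 0 && grepl("^[[:space:]]*$", lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) stop("empty XYZ file: ", path)

  side <- NULL
  if (!is.null(energies)) {
    side <- as.numeric(readLines(energies, warn = FALSE))
  }

  snapshots <- list()
  pos <- 1L
  frame <- 0L
  missing_energy <- integer(0)
  while (pos <= length(lines)) {
    natoms <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(natoms) || natoms <= 0) {
      stop("malformed atom count line at frame ", frame + 1L,
           " (line ", pos, "): '", lines[pos], "'")
    }
    if (pos + 1L + natoms > length(lines)) {
      stop("truncated frame ", frame + 1L, ": expected ", natoms, " atom lines")
    }
    comment <- lines[pos + 1L]
    atom_lines <- lines[(pos + 2L):(pos + 1L + natoms)]
    fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
    nf <- lengths(fields)
    if (any(nf < 4)) {
      stop("malformed atom line in frame ", frame + 1L, ": '",
           atom_lines[which(nf < 4)[1]], "'")
    }
    elements <- vapply(fields, `[[`, character(1), 1L)
    coords <- matrix(NA_real_, natoms, 3)
    for (k in seq_len(natoms)) {
      coords[k, ] <- as.numeric(fields[[k]][2:4])
    }
    if (anyNA(coords)) stop("non-numeric coordinates in frame ", frame + 1L)
    frame <- frame + 1L
    e_raw <- if (!is.null(side)) {
      if (frame > length(side)) NA_real_ else side[frame]
    } else {
      .parse_comment_energy(comment)
    }
    if (is.na(e_raw)) missing_energy <- c(missing_energy, frame)
    snapshots[[frame]] <- snapshot(
      index = frame, elements = elements, coords = coords,
      energy = if (is.na(e_raw)) NA_real_ else to_kcalmol(e_raw, energy_unit),
      source_tag = sprintf("%s#%d", path, frame)
    )
    pos <- pos + 2L + natoms
  }
  if (length(missing_energy) > 0) {
    warning("no parsable energy for frame(s) ",
            paste(missing_energy, collapse = ", "),
            " of ", path, "; retained with NA energy")
  }
  .new_ensemble(snapshots, energy_unit)
}

#' Write a trajectory ensemble to a multi-frame XYZ file
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param path Output path.
#' @param comments Optional character vector of comment lines (defaults to the
#'   frame energies in kcal/mol).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(ensemble, path, comments = NULL) {
  out <- character(0)
  for (k in seq_along(ensemble$snapshots)) {
    s <- ensemble$snapshots[[k]]
    cmt <- if (!is.null(comments)) comments[k]
           else if (is.na(s$energy)) "" else sprintf("%.10f", s$energy)
    out <- c(out, as.character(length(s$elements)), cmt,
             sprintf("%-3s %18.10f %18.10f %18.10f",
                     s$elements, s$coords[, 1], s$coords[, 2], s$coords[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Export the conformers of a species as a multi-frame XYZ file
#'
#' Writes every recorded conformer of one species, lowest energy first (ties
#' broken by first-seen snapshot index). The comment line carries the energy
#' in kcal/mol and the species fingerprint hash, so exported geometries can be
#' fed to electronic-structure refinement.
#'
#' @param record A `species_record` (see [analyze_trajectory()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_xyz <- function(record, path) {
  stopifnot(inherits(record, "species_record"))
  n <- nrow(record$conformers)
  if (n == 0) stop("species record has no conformers")
  ord <- order(record$conformers$energy, record$conformers$snapshot_index)
  out <- character(0)
  for (k in ord) {
    e <- record$conformers$energy[k]
    cmt <- sprintf("%s fingerprint=%s frame=%d",
                   if (is.na(e)) "NA" else sprintf("%.10f", e),
                   fingerprint_hash(record$fingerprint),
                   record$conformers$snapshot_index[k])
    xyz <- record$geometries[[k]]
    out <- c(out, as.character(length(record$elements)), cmt,
             sprintf("%-3s %18.10f %18.10f %18.10f",
                     record$elements, xyz[, 1], xyz[, 2], xyz[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}
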