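# YAML serialization of event schedules (for the command-line `synth`
# subcommand). Schema:
#
#   base:
#     metal: Mn
#     ligands: [N, O, F, P, S, Cl]
#     bonded: [true, true, true, true, false, false]
#   events:
#     - {frame: 4, type: break_bond, i: 1, j: 6}
#     - {frame: 9, type: swap_ligand, i: 1, j: 2, k: 7}
#   n_frames: 20
#   jitter_sigma: 0.02
#   energy_base_sd: 10
#   energy_conformer_sd: 1
#   seed: 7
#
# Atom indices are 1-based positions in the generated structure (atom 1 is
# the metal, atoms 2.. are the ligands in order).

#' Read an event schedule from a YAML file
#'
#' @param path Path to a schedule YAML file (see the package vignette for the
#'   schema).
#' @param criteria [bond_criteria()] used to place the base structure.
#' @return A list with `schedule` (an `event_schedule`) and `n_frames`.
#' @export
read_schedule_yaml <- function(path, criteria = bond_criteria()) {
  # keep YAML-1.1 boolean-ish scalars ("N", "no", ...) as strings so element
  # symbols like N survive; booleans are re-parsed with as.logical below
  y <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
  if (is.null(y$base)) stop("schedule YAML must contain a 'base' section")
  ligands <- as.character(y$base$ligands)
  bonded <- if (is.null(y$base$bonded)) rep(TRUE, length(ligands))
            else as.logical(y$base$bonded)
  base <- toy_complex(metal = y$base$metal %||% "Mn", ligands = ligands,
                      bonded = bonded, criteria = criteria)
  events <- lapply(y$events %||% list(), function(e) {
    e$frame <- as.integer(e$frame)
    for (f in c("i", "j", "k", "unit")) {
      if (!is.null(e[[f]])) e[[f]] <- as.integer(e[[f]])
    }
    if (!is.null(e$offset)) e$offset <- as.numeric(e$offset)
    e
  })
  schedule <- event_schedule(
    base, events,
    jitter_sigma = y$jitter_sigma %||% 0.02,
    energy_base_sd = y$energy_base_sd %||% 10,
    energy_conformer_sd = y$energy_conformer_sd %||% 1,
    seed = as.integer(y$seed %||% 1L))
  list(schedule = schedule, n_frames = as.integer(y$n_frames %||% 20L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the ground truth of a generated trajectory as JSON
#'
#' @param truth The `truth` component returned by [generate_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
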