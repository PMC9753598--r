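# Snapshot-by-snapshot reaction event identification.
#
# Walking the trajectory: the first frame initializes the species database;
# each later frame is compared with its predecessor and, on a change of
# bonding pattern, looked up in (or added to) the database, recording a
# directed transition. A frame whose pattern matches an earlier species is a
# revisit: it closes a directed edge back to the existing node rather than
# creating a duplicate, so trajectories A -> B -> A yield two species and two
# transitions.

.new_species_record <- function(fp, graph, elements) {
  structure(
    list(fingerprint = fp,
         elements = elements,
         conformers = data.frame(snapshot_index = integer(0), energy = numeric(0)),
         geometries = list(),
         node_energy = NA_real_,
         representative_graph = graph,
         representative_index = NA_integer_),
    class = "species_record"
  )
}

.add_conformer <- function(record, snap, graph) {
  record$conformers <- rbind(
    record$conformers,
    data.frame(snapshot_index = snap$index, energy = snap$energy))
  record$geometries <- c(record$geometries, list(snap$coords))
  e <- record$conformers$energy
  if (any(!is.na(e))) {
    new_min <- min(e, na.rm = TRUE)
    # representative: lowest energy, ties broken by lowest snapshot index
    best <- which(!is.na(e) & e == new_min)[1]
    if (is.na(record$node_energy) || new_min < record$node_energy ||
        (new_min == record$node_energy &&
         record$conformers$snapshot_index[best] < record$representative_index)) {
      record$node_energy <- new_min
      record$representative_index <- record$conformers$snapshot_index[best]
      record$representative_graph <- graph
    }
  }
  record
}

#' @export
print.species_record <- function(x, ...) {
  cat(sprintf("<species %s: %d conformer(s), E_min = %s kcal/mol>\n",
              fingerprint_hash(x$fingerprint), nrow(x$conformers),
              if (is.na(x$node_energy)) "NA" else format(x$node_energy)))
  invisible(x)
}

#' Test isomorphism of two molecular graphs
#'
#' Decides whether an element- and interaction-type-preserving bijection
#' exists between two molecular graphs, using the VF2 algorithm with vertex
#' colors (elements) and edge colors (interaction types). This is an
#' implementation route independent of the canonical [fingerprint()]; the two
#' must always agree, which the test suite certifies.
#'
#' @param g1,g2 `molecular_graph` objects built with the same active
#'   interaction types.
#' @return `TRUE` or `FALSE`.
#' @export
is_isomorphic <- function(g1, g2) {
  stopifnot(inherits(g1, "molecular_graph"), inherits(g2, "molecular_graph"))
  if (!setequal(g1$active_types, g2$active_types)) {
    stop("graphs were built with different active interaction types")
  }
  if (length(g1$elements) != length(g2$elements)) return(FALSE)
  if (!identical(sort(g1$elements), sort(g2$elements))) return(FALSE)
  if (nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  all_el <- sort(unique(c(g1$elements, g2$elements)))
  vc1 <- match(g1$elements, all_el)
  vc2 <- match(g2$elements, all_el)
  ec1 <- match(g1$edges$type, INTERACTION_TYPES)
  ec2 <- match(g2$edges$type, INTERACTION_TYPES)
  igraph::isomorphic(as_igraph(g1), as_igraph(g2), method = "vf2",
                     vertex.color1 = vc1, vertex.color2 = vc2,
                     edge.color1 = ec1, edge.color2 = ec2)
}

.new_eventlog <- function(species_db, transitions, frame_species) {
  structure(
    list(species_db = species_db,
         transitions = transitions,
         frame_species = frame_species),
    class = "event_log"
  )
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event log: %d species, %d transition(s)>\n",
              length(x$species_db), nrow(x$transitions)))
  invisible(x)
}

.empty_transitions <- function() {
  data.frame(from_fingerprint = character(0), to_fingerprint = character(0),
             from_snapshot = integer(0), to_snapshot = integer(0),
             stringsAsFactors = FALSE)
}

#' Identify species and reaction events along a trajectory
#'
#' Runs the event-identification walk: the first snapshot initializes the
#' species database; every subsequent snapshot is bond-perceived,
#' fingerprinted, and either appended as a conformer of the current species
#' (no change in bonding pattern) or matched against the database. A pattern
#' seen before is re-identified (the database is updated, no duplicate node);
#' a new pattern creates a new species record. Every change of pattern between
#' consecutive frames is logged as a directed transition.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param criteria A [bond_criteria()] object.
#' @return An `event_log`: `species_db` (named list of `species_record`, keyed
#'   by canonical fingerprint), `transitions` (data frame with columns
#'   `from_fingerprint`, `to_fingerprint`, `from_snapshot`, `to_snapshot`) and
#'   `frame_species` (fingerprint key per frame).
#' @export
analyze_trajectory <- function(ensemble, criteria = bond_criteria()) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (length(ensemble$snapshots) == 0) stop("empty ensemble")
  db <- list()
  transitions <- .empty_transitions()
  frame_species <- character(length(ensemble$snapshots))
  prev_key <- NULL
  prev_index <- NA_integer_
  for (k in seq_along(ensemble$snapshots)) {
    snap <- ensemble$snapshots[[k]]
    g <- perceive_bonds(snap, criteria)
    key <- as.character(fingerprint(g))
    if (is.null(db[[key]])) {
      db[[key]] <- .new_species_record(structure(key, class = "fingerprint"),
                                       g, snap$elements)
    }
    db[[key]] <- .add_conformer(db[[key]], snap, g)
    if (!is.null(prev_key) && !identical(key, prev_key)) {
      transitions <- rbind(transitions, data.frame(
        from_fingerprint = prev_key, to_fingerprint = key,
        from_snapshot = prev_index, to_snapshot = snap$index,
        stringsAsFactors = FALSE))
    }
    frame_species[k] <- key
    prev_key <- key
    prev_index <- snap$index
  }
  .new_eventlog(db, transitions, frame_species)
}

#' Merge event logs from parallel trajectories
#'
#' Parallel exploration runs of the same system are analyzed independently and
#' merged on fingerprint keys: conformer lists are concatenated, node energies
#' re-minimized, and transition lists appended. No cross-trajectory
#' transitions are created.
#'
#' @param logs A list of `event_log` objects.
#' @return A merged `event_log` (its `frame_species` concatenates the runs).
#' @export
merge_event_logs <- function(logs) {
  stopifnot(length(logs) >= 1, all(vapply(logs, inherits, logical(1), "event_log")))
  db <- list()
  transitions <- .empty_transitions()
  frame_species <- character(0)
  for (log in logs) {
    for (key in names(log$species_db)) {
      rec <- log$species_db[[key]]
      if (is.null(db[[key]])) {
        db[[key]] <- rec
      } else {
        merged <- db[[key]]
        merged$conformers <- rbind(merged$conformers, rec$conformers)
        merged$geometries <- c(merged$geometries, rec$geometries)
        if (!is.na(rec$node_energy) &&
            (is.na(merged$node_energy) || rec$node_energy < merged$node_energy)) {
          merged$node_energy <- rec$node_energy
          merged$representative_graph <- rec$representative_graph
          merged$representative_index <- rec$representative_index
        }
        db[[key]] <- merged
      }
    }
    transitions <- rbind(transitions, log$transitions)
    frame_species <- c(frame_species, log$frame_species)
  }
  .new_eventlog(db, transitions, frame_species)
}

#' Summarize the species database as a table
#'
#' @param log An `event_log`.
#' @return A data frame with one row per species: fingerprint hash, conformer
#'   count, node energy (most stable conformer) and the min/median/max of the
#'   conformer energies, all in kcal/mol.
#' @export
species_table <- function(log) {
  stopifnot(inherits(log, "event_log"))
  rows <- lapply(log$species_db, function(rec) {
    e <- rec$conformers$energy
    data.frame(
      fingerprint = fingerprint_hash(rec$fingerprint),
      n_conformers = nrow(rec$conformers),
      node_energy = rec$node_energy,
      e_min = if (all(is.na(e))) NA_real_ else min(e, na.rm = TRUE),
      e_median = if (all(is.na(e))) NA_real_ else stats::median(e, na.rm = TRUE),
      e_max = if (all(is.na(e))) NA_real_ else max(e, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
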