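# Fragment analysis: connected components of snapshot graphs by breadth-first
# search, and trajectory-wide inventories of unique fragments anchored on a
# transition-metal (pivot) atom. Restricting the interaction types traversed
# (e.g. covalent+organometallic only, or additionally hydrogen bonds) selects
# what counts as "one fragment": with hydrogen bonds active, hydrogen-bonded
# aggregates become single fragments.

#' Decompose a molecular graph into connected fragments
#'
#' Breadth-first search over the edges whose interaction type is in
#' `active_types` partitions the atoms into connected components; each
#' component is one fragment. Fragments are returned in deterministic order of
#' their smallest atom index.
#'
#' @param graph A `molecular_graph` built with a superset of `active_types`.
#' @param active_types Interaction types to traverse (default: the graph's own
#'   active types).
#' @param pivot_element Optional element symbol used to set each fragment's
#'   `contains_pivot` flag and `n_pivot` count.
#' @return A list of `fragment` objects: `atom_indices` (increasing),
#'   `subgraph` (induced `molecular_graph` restricted to `active_types`),
#'   `contains_pivot`, `n_pivot`, and the subgraph `fingerprint`.
#' @export
find_fragments <- function(graph, active_types = graph$active_types,
                           pivot_element = NULL) {
  stopifnot(inherits(graph, "molecular_graph"))
  if (!all(active_types %in% graph$active_types)) {
    stop("graph was not built with interaction type(s): ",
         paste(setdiff(active_types, graph$active_types), collapse = ", "))
  }
  n <- length(graph$elements)
  ed <- graph$edges[graph$edges$type %in% active_types, , drop = FALSE]
  nbr <- vector("list", n)
  for (k in seq_len(nrow(ed))) {
    nbr[[ed$i[k]]] <- c(nbr[[ed$i[k]]], ed$j[k])
    nbr[[ed$j[k]]] <- c(nbr[[ed$j[k]]], ed$i[k])
  }
  visited <- logical(n)
  fragments <- list()
  for (root in seq_len(n)) {
    if (visited[root]) next
    # BFS from the root: explore all neighbors at the current depth before
    # descending
    comp <- integer(0)
    queue <- root
    visited[root] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in nbr[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comp <- sort(comp)
    sub <- .induced_subgraph(graph, comp, active_types)
    n_pivot <- if (is.null(pivot_element)) 0L
               else sum(graph$elements[comp] == pivot_element)
    fragments[[length(fragments) + 1L]] <- structure(
      list(atom_indices = comp, subgraph = sub,
           contains_pivot = n_pivot > 0L, n_pivot = as.integer(n_pivot),
           fingerprint = fingerprint(sub)),
      class = "fragment")
  }
  fragments
}

.induced_subgraph <- function(graph, atoms, active_types) {
  remap <- match(seq_along(graph$elements), atoms)
  ed <- graph$edges[graph$edges$type %in% active_types &
                    graph$edges$i %in% atoms & graph$edges$j %in% atoms, ,
                    drop = FALSE]
  ed$i <- remap[ed$i]
  ed$j <- remap[ed$j]
  .new_molgraph(graph$elements[atoms], ed, graph$snapshot_index, active_types)
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment: %d atoms (%s)%s>\n",
              length(x$atom_indices),
              paste(unique(x$subgraph$elements), collapse = ","),
              if (x$contains_pivot) sprintf(", %d pivot atom(s)", x$n_pivot) else ""))
  invisible(x)
}

#' Enumerate unique pivot-containing fragments across a trajectory
#'
#' For every snapshot, extracts all fragments containing at least one pivot
#' atom (e.g. the Mn centers of a multinuclear catalytic system), fingerprints
#' their subgraphs and deduplicates both within snapshots (two identical
#' separate metal fragments count twice toward occurrences but appear once in
#' the inventory) and across snapshots. A fragment with two or more pivot
#' atoms is one (multinuclear) entry; its nuclearity is the `n_pivot` column.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param criteria A [bond_criteria()] object; its `active_types` define
#'   fragment connectivity.
#' @param pivot_element Element symbol of the pivot atom; must occur in the
#'   system.
#' @return A data frame with one row per unique fragment: `fingerprint`
#'   (hash), `n_atoms`, `n_pivot`, `occurrences` (total count over all
#'   snapshots), `first_frame` (snapshot index of first appearance) and
#'   `min_energy` (lowest total energy, kcal/mol, among hosting snapshots —
#'   a whole-snapshot energy, not a per-fragment estimate). The full
#'   `fragment` objects of first occurrence are attached as attribute
#'   `"fragments"`.
#' @export
unique_pivot_fragments <- function(ensemble, criteria = bond_criteria(),
                                   pivot_element = "Mn") {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (!pivot_element %in% ensemble$snapshots[[1]]$elements) {
    stop("pivot element '", pivot_element, "' does not occur in the system")
  }
  inventory <- list()
  for (snap in ensemble$snapshots) {
    g <- perceive_bonds(snap, criteria)
    frs <- find_fragments(g, pivot_element = pivot_element)
    for (fr in frs) {
      if (!fr$contains_pivot) next
      key <- as.character(fr$fingerprint)
      if (is.null(inventory[[key]])) {
        inventory[[key]] <- list(fragment = fr, occurrences = 0L,
                                 first_frame = snap$index,
                                 min_energy = NA_real_)
      }
      rec <- inventory[[key]]
      rec$occurrences <- rec$occurrences + 1L
      if (!is.na(snap$energy) &&
          (is.na(rec$min_energy) || snap$energy < rec$min_energy)) {
        rec$min_energy <- snap$energy
      }
      inventory[[key]] <- rec
    }
  }
  rows <- lapply(inventory, function(rec) data.frame(
    fingerprint = fingerprint_hash(rec$fragment$fingerprint),
    n_atoms = length(rec$fragment$atom_indices),
    n_pivot = rec$fragment$n_pivot,
    occurrences = rec$occurrences,
    first_frame = rec$first_frame,
    min_energy = rec$min_energy,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fragments") <- lapply(inventory, function(rec) rec$fragment)
  out
}
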