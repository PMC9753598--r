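# Reaction network assembly, energy-threshold trimming, and visual style
# mappings.
#
# Nodes are species (their energy is the most stable conformer's); a directed
# edge source -> target carries the transformation energy
# delta_e = E(target) - E(source) and the number of times the transformation
# was observed. Trimming removes thermodynamically inaccessible species and
# uphill transformations above user thresholds, then prunes nodes left
# disconnected.

#' Assemble a reaction network from an event log
#'
#' One node per species; one directed edge per distinct (source, target) pair
#' of the logged transitions, with `multiplicity` the number of occurrences
#' and `delta_e` the node-energy difference E(target) - E(source) in kcal/mol
#' (`NA` when either node has no energy).
#'
#' @param log An `event_log` from [analyze_trajectory()].
#' @return A `reaction_network`: `nodes` (named list of `species_record`),
#'   `edges` (data frame `source`, `target`, `delta_e`, `multiplicity`),
#'   `min_energy`/`max_energy` over node energies, and `reference` (set by
#'   [trim_network()], `NULL` here).
#' @export
build_network <- function(log) {
  stopifnot(inherits(log, "event_log"))
  if (length(log$species_db) == 0) stop("empty event log")
  tr <- log$transitions
  if (nrow(tr) > 0) {
    pair_key <- paste(tr$from_fingerprint, tr$to_fingerprint, sep = "\r")
    counts <- table(pair_key)
    first <- tr[!duplicated(pair_key), , drop = FALSE]
    first_key <- paste(first$from_fingerprint, first$to_fingerprint, sep = "\r")
    edges <- data.frame(
      source = first$from_fingerprint,
      target = first$to_fingerprint,
      multiplicity = as.integer(counts[first_key]),
      stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = character(0), target = character(0),
                        multiplicity = integer(0), stringsAsFactors = FALSE)
  }
  energy <- vapply(log$species_db, function(r) r$node_energy, numeric(1))
  edges$delta_e <- unname(energy[edges$target] - energy[edges$source])
  edges <- edges[, c("source", "target", "delta_e", "multiplicity")]
  rownames(edges) <- NULL
  .new_network(log$species_db, edges)
}

.new_network <- function(nodes, edges, reference = NULL) {
  energy <- vapply(nodes, function(r) r$node_energy, numeric(1))
  has_e <- !is.na(energy)
  structure(
    list(nodes = nodes, edges = edges,
         min_energy = if (any(has_e)) min(energy[has_e]) else NA_real_,
         max_energy = if (any(has_e)) max(energy[has_e]) else NA_real_,
         reference = reference),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction network: %d node(s), %d edge(s), E in [%s, %s] kcal/mol>\n",
              length(x$nodes), nrow(x$edges),
              format(x$min_energy), format(x$max_energy)))
  invisible(x)
}

#' Trimming thresholds for a reaction network
#'
#' @param node_threshold Maximum allowed node energy in kcal/mol relative to
#'   the reference node.
#' @param edge_threshold Maximum allowed (signed, uphill) transformation
#'   energy in kcal/mol. Downhill transformations are never removed.
#' @param reference Fingerprint key of the zero-energy state, typically the
#'   species of intact, noninteracting starting components. `NULL` selects the
#'   lowest-energy node of the untrimmed network.
#' @param prune_unreachable If `TRUE`, the final pruning pass also removes
#'   nodes with no directed path from the reference; by default only nodes
#'   left without any incident edge are removed.
#' @return An object of class `"trim_config"`.
#' @export
trim_config <- function(node_threshold = 25, edge_threshold = 25,
                        reference = NULL, prune_unreachable = FALSE) {
  stopifnot(is.finite(node_threshold), is.finite(edge_threshold))
  structure(
    list(node_threshold = node_threshold, edge_threshold = edge_threshold,
         reference = if (is.null(reference)) NULL else as.character(reference),
         prune_unreachable = isTRUE(prune_unreachable)),
    class = "trim_config"
  )
}

.relative_energies <- function(net, reference) {
  energy <- vapply(net$nodes, function(r) r$node_energy, numeric(1))
  energy - energy[reference]
}

#' Trim a reaction network by energy thresholds
#'
#' Three passes: (1) every node whose energy relative to the reference exceeds
#' `node_threshold` is removed together with all its incoming and outgoing
#' edges; (2) every remaining edge with (signed) `delta_e` above
#' `edge_threshold` is removed; (3) nodes left inaccessible are removed —
#' by default those with no incident edge at all, or additionally those
#' without a directed path from the reference when `prune_unreachable` is set.
#' The reference node is always retained. The input network is not modified.
#'
#' Nodes without an energy cannot be assessed against the threshold and are
#' removed in pass 1 with a warning.
#'
#' @param net A `reaction_network`.
#' @param cfg A [trim_config()].
#' @return A new, trimmed `reaction_network` whose node energies are those of
#'   the input and whose `reference` field records the reference key.
#' @export
trim_network <- function(net, cfg = trim_config()) {
  stopifnot(inherits(net, "reaction_network"), inherits(cfg, "trim_config"))
  energy <- vapply(net$nodes, function(r) r$node_energy, numeric(1))
  reference <- cfg$reference
  if (is.null(reference)) {
    if (all(is.na(energy))) stop("no node has an energy; cannot pick a reference")
    reference <- names(net$nodes)[which.min(energy)]
  }
  if (!reference %in% names(net$nodes)) {
    stop("reference fingerprint is not a node of the network")
  }
  rel <- .relative_energies(net, reference)
  # a reference sitting more than node_threshold above the network minimum
  # would trim away every lower-lying state: configuration error
  if (!is.na(energy[reference]) && any(!is.na(energy)) &&
      energy[reference] - min(energy, na.rm = TRUE) > cfg$node_threshold) {
    stop("reference node exceeds the node threshold above the network minimum")
  }
  if (anyNA(rel)) {
    warning("removing ", sum(is.na(rel)), " node(s) with missing energies")
  }
  # pass 1: node threshold
  keep <- !is.na(rel) & rel <= cfg$node_threshold
  keep[reference] <- TRUE
  kept_keys <- names(net$nodes)[keep]
  edges <- net$edges[net$edges$source %in% kept_keys &
                     net$edges$target %in% kept_keys, , drop = FALSE]
  # pass 2: edge threshold on signed (uphill) transformation energy
  edges <- edges[!is.na(edges$delta_e) & edges$delta_e <= cfg$edge_threshold, ,
                 drop = FALSE]
  # pass 3: prune inaccessible nodes (never the reference)
  if (cfg$prune_unreachable) {
    reach <- .reachable_from(kept_keys, edges, reference)
    kept_keys <- kept_keys[kept_keys %in% reach | kept_keys == reference]
  } else {
    incident <- kept_keys %in% c(edges$source, edges$target)
    kept_keys <- kept_keys[incident | kept_keys == reference]
  }
  edges <- edges[edges$source %in% kept_keys & edges$target %in% kept_keys, ,
                 drop = FALSE]
  rownames(edges) <- NULL
  .new_network(net$nodes[kept_keys], edges, reference = reference)
}

# directed reachability by BFS over the edge list
.reachable_from <- function(keys, edges, start) {
  seen <- start
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- setdiff(edges$target[edges$source == v], seen)
    seen <- c(seen, nxt)
    queue <- c(queue, nxt)
  }
  seen
}

#' Visual style mapping for a reaction network
#'
#' Node colors map energies linearly onto `[0, 1]` between the lowest (MIN,
#' color 0) and highest (MAX, color 1) node energies. Edge widths use the
#' inverse mapping of transformation energies, so the lowest-`delta_e` (most
#' probable) transformation gets width 1 (thickest) and the highest gets 0.
#' When all node energies (or all `delta_e`) coincide, the degenerate
#' convention maps everything to 0.5. Nodes or edges without energies get
#' `NA`.
#'
#' @param net A `reaction_network`.
#' @return A list with `node_color` (named numeric vector in `[0,1]`) and
#'   `edge_width` (numeric vector along the network's edge rows).
#' @export
style_network <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  energy <- vapply(net$nodes, function(r) r$node_energy, numeric(1))
  if (all(is.na(energy))) stop("no node has an energy")
  rng <- range(energy, na.rm = TRUE)
  node_color <- if (rng[1] == rng[2]) {
    ifelse(is.na(energy), NA_real_, 0.5)
  } else {
    (energy - rng[1]) / (rng[2] - rng[1])
  }
  de <- net$edges$delta_e
  edge_width <- rep(NA_real_, length(de))
  if (any(!is.na(de))) {
    dr <- range(de, na.rm = TRUE)
    edge_width <- if (dr[1] == dr[2]) {
      ifelse(is.na(de), NA_real_, 0.5)
    } else {
      1 - (de - dr[1]) / (dr[2] - dr[1])
    }
  }
  list(node_color = node_color, edge_width = edge_width)
}

#' Five-number summary of a species' conformer energies
#'
#' Summarizes the energy spread of the conformers (isomers) of one species as
#' (min, Q1, median, Q3, max) in kcal/mol, the statistics drawn as boxplots
#' next to network nodes. Quartiles use linear interpolation between order
#' statistics.
#'
#' @param record A `species_record`.
#' @return Named numeric vector `c(min, q1, median, q3, max)`.
#' @export
isomer_stats <- function(record) {
  stopifnot(inherits(record, "species_record"))
  e <- record$conformers$energy
  e <- e[!is.na(e)]
  if (length(e) == 0) stop("species record has no conformer energies")
  q <- stats::quantile(e, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

# ---- exports ---------------------------------------------------------------

.network_igraph <- function(net) {
  style <- style_network(net)
  keys <- names(net$nodes)
  g <- igraph::make_empty_graph(n = length(keys), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = fingerprint_hash_vec(keys))
  g <- igraph::set_vertex_attr(g, "fingerprint", value = keys)
  g <- igraph::set_vertex_attr(
    g, "energy", value = vapply(net$nodes, function(r) r$node_energy, numeric(1)))
  g <- igraph::set_vertex_attr(g, "color_value", value = unname(style$node_color))
  if (nrow(net$edges) > 0) {
    idx <- rbind(match(net$edges$source, keys), match(net$edges$target, keys))
    g <- igraph::add_edges(g, idx)
    g <- igraph::set_edge_attr(g, "delta_e", value = net$edges$delta_e)
    g <- igraph::set_edge_attr(g, "multiplicity", value = net$edges$multiplicity)
    g <- igraph::set_edge_attr(g, "width_value", value = style$edge_width)
  }
  g
}

fingerprint_hash_vec <- function(keys) {
  vapply(keys, fingerprint_hash, character(1), USE.NAMES = FALSE)
}

#' Export a reaction network
#'
#' Writes the network with node energies, color values, edge transformation
#' energies, multiplicities and width values. Formats: GraphML (round-trips
#' through [read_network_graphml()]), DOT for Graphviz rendering, JSON
#' node-link, or a CSV edge list.
#'
#' @param net A `reaction_network`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"dot"`, `"json"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "dot", "json", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    .write_graphml(net, path)
  } else if (format == "dot") {
    igraph::write_graph(.network_igraph(net), path, format = "dot")
  } else if (format == "json") {
    style <- style_network(net)
    keys <- names(net$nodes)
    obj <- list(
      nodes = data.frame(
        id = fingerprint_hash_vec(keys),
        fingerprint = keys,
        energy = vapply(net$nodes, function(r) r$node_energy, numeric(1)),
        color_value = unname(style$node_color),
        stringsAsFactors = FALSE),
      links = cbind(
        data.frame(source = fingerprint_hash_vec(net$edges$source),
                   target = fingerprint_hash_vec(net$edges$target),
                   stringsAsFactors = FALSE),
        net$edges[, c("delta_e", "multiplicity")],
        width_value = style$edge_width)
    )
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    out <- cbind(
      data.frame(source = fingerprint_hash_vec(net$edges$source),
                 target = fingerprint_hash_vec(net$edges$target),
                 stringsAsFactors = FALSE),
      net$edges[, c("delta_e", "multiplicity")])
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

# GraphML writer with full double precision ("%.17g"), so that node energies
# and edge delta_e round-trip exactly through read_network_graphml().
.write_graphml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) ifelse(is.na(x), "NaN", sprintf("%.17g", x))
  style <- style_network(net)
  keys <- names(net$nodes)
  energy <- vapply(net$nodes, function(r) r$node_energy, numeric(1))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="v_name" for="node" attr.name="name" attr.type="string"/>',
    '  <key id="v_fp" for="node" attr.name="fingerprint" attr.type="string"/>',
    '  <key id="v_e" for="node" attr.name="energy" attr.type="double"/>',
    '  <key id="v_c" for="node" attr.name="color_value" attr.type="double"/>',
    '  <key id="e_de" for="edge" attr.name="delta_e" attr.type="double"/>',
    '  <key id="e_m" for="edge" attr.name="multiplicity" attr.type="double"/>',
    '  <key id="e_w" for="edge" attr.name="width_value" attr.type="double"/>',
    '  <graph id="G" edgedefault="directed">')
  for (k in seq_along(keys)) {
    lines <- c(lines, sprintf(
      '    <node id="n%d"><data key="v_name">%s</data><data key="v_fp">%s</data><data key="v_e">%s</data><data key="v_c">%s</data></node>',
      k - 1L, esc(fingerprint_hash(keys[k])), esc(keys[k]),
      num(energy[k]), num(unname(style$node_color[k]))))
  }
  if (nrow(net$edges) > 0) {
    si <- match(net$edges$source, keys) - 1L
    ti <- match(net$edges$target, keys) - 1L
    lines <- c(lines, sprintf(
      '    <edge source="n%d" target="n%d"><data key="e_de">%s</data><data key="e_m">%s</data><data key="e_w">%s</data></edge>',
      si, ti, num(net$edges$delta_e),
      num(as.numeric(net$edges$multiplicity)), num(style$edge_width)))
  }
  writeLines(c(lines, "  </graph>", "</graphml>"), path)
  invisible(path)
}

#' Read a reaction network from GraphML
#'
#' Reconstructs the topology, node energies, edge transformation energies and
#' multiplicities written by [write_network()] (species records carry only the
#' fingerprint and node energy; conformer ensembles are not serialized to
#' GraphML).
#'
#' @param path Path to a GraphML file written by [write_network()].
#' @return A `reaction_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  keys <- igraph::vertex_attr(g, "fingerprint")
  energy <- igraph::vertex_attr(g, "energy")
  energy[is.nan(energy)] <- NA_real_
  nodes <- stats::setNames(lapply(seq_along(keys), function(k) {
    rec <- .new_species_record(structure(keys[k], class = "fingerprint"),
                               NULL, character(0))
    rec$node_energy <- energy[k]
    rec
  }), keys)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(
    source = keys[el[, 1]], target = keys[el[, 2]],
    delta_e = if (igraph::ecount(g)) igraph::edge_attr(g, "delta_e") else numeric(0),
    multiplicity = if (igraph::ecount(g)) as.integer(igraph::edge_attr(g, "multiplicity")) else integer(0),
    stringsAsFactors = FALSE)
  .new_network(nodes, edges)
}
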