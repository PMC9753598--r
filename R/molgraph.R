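# Bond perception: Snapshot -> labeled molecular graph with typed edges.
#
# Four interaction types are perceived from interatomic distances:
#   covalent        nonmetal-nonmetal, d <= covalent_scale * (r_i + r_j)
#   organometallic  transition metal-nonmetal, d <= organometallic_scale * (r_i + r_j)
#   hydrogen_bond   D-H...A with D,A in {N,O,F}, d(D,A) <= hbond_max_da and
#                   angle(D-H...A) >= hbond_min_angle
#   ionic           alkali/alkaline-earth cation to {O,N,halogen} within
#                   ionic_max_dist
# Species identity downstream is by connectivity and element labels only;
# there are no bond orders or formal charges.

INTERACTION_TYPES <- c("covalent", "organometallic", "hydrogen_bond", "ionic")

#' Bond perception criteria
#'
#' Distance (and, for hydrogen bonds, angle) criteria that turn Cartesian
#' coordinates into a typed molecular graph. Scales multiply the sum of
#' covalent radii of the pair.
#'
#' @param covalent_scale Unitless factor on summed covalent radii for
#'   nonmetal-nonmetal pairs. Must lie in (0.5, 2).
#' @param organometallic_scale Unitless factor for transition-metal-nonmetal
#'   pairs. Must lie in (0.5, 2).
#' @param hbond_max_da Donor-acceptor distance cutoff in Angstrom.
#' @param hbond_min_angle Minimum D-H...A angle in degrees (in (90, 180)).
#' @param ionic_max_dist Cation-anion distance cutoff in Angstrom.
#' @param active_types Subset of
#'   `c("covalent", "organometallic", "hydrogen_bond", "ionic")`: the
#'   interaction types emitted into the graph. The default (covalent +
#'   organometallic) defines species identity; hydrogen-bond and ionic edges
#'   are opt-in, mainly for fragment analysis of aggregates.
#' @return An object of class `"bond_criteria"`.
#' @export
bond_criteria <- function(covalent_scale = 1.15,
                          organometallic_scale = 1.15,
                          hbond_max_da = 3.5,
                          hbond_min_angle = 120,
                          ionic_max_dist = 3.0,
                          active_types = c("covalent", "organometallic")) {
  stopifnot(covalent_scale > 0.5, covalent_scale < 2.0,
            organometallic_scale > 0.5, organometallic_scale < 2.0,
            hbond_max_da > 0, ionic_max_dist > 0,
            hbond_min_angle > 90, hbond_min_angle < 180)
  active_types <- match.arg(active_types, INTERACTION_TYPES, several.ok = TRUE)
  structure(
    list(covalent_scale = covalent_scale,
         organometallic_scale = organometallic_scale,
         hbond_max_da = hbond_max_da,
         hbond_min_angle = hbond_min_angle,
         ionic_max_dist = ionic_max_dist,
         active_types = active_types),
    class = "bond_criteria"
  )
}

.new_molgraph <- function(elements, edges, snapshot_index, active_types) {
  rownames(edges) <- NULL
  structure(
    list(elements = as.character(elements),
         edges = edges,
         snapshot_index = as.integer(snapshot_index),
         active_types = active_types),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular graph: %d atoms, %d edges (%s)>\n",
              length(x$elements), nrow(x$edges),
              paste(x$active_types, collapse = ",")))
  invisible(x)
}

.empty_edges <- function() {
  data.frame(i = integer(0), j = integer(0), type = character(0),
             dist = numeric(0), stringsAsFactors = FALSE)
}

#' Perceive bonds in a snapshot
#'
#' Builds the labeled molecular graph of one snapshot by applying the distance
#' criteria in `criteria` to all atom pairs. Atoms are indexed by their
#' position in the frame (1-based in R); edges carry the interaction type and
#' the Euclidean distance.
#'
#' @param snap A `snapshot`.
#' @param criteria A [bond_criteria()] object.
#' @return A `molecular_graph` with vertices labeled by element and edges
#'   typed by interaction. Only the criteria's `active_types` are emitted.
#' @examples
#' w <- snapshot(1, c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' perceive_bonds(w, bond_criteria())
#' @export
perceive_bonds <- function(snap, criteria = bond_criteria()) {
  stopifnot(inherits(snap, "snapshot"), inherits(criteria, "bond_criteria"))
  if (anyNA(snap$coords) || !all(is.finite(snap$coords))) {
    stop("non-finite coordinates in snapshot ", snap$index)
  }
  el <- snap$elements
  n <- length(el)
  r <- covalent_radius(el) # errors on unknown symbols
  xyz <- snap$coords
  act <- criteria$active_types

  dist_mat <- as.matrix(stats::dist(xyz))
  nonmetal <- .is_nonmetal(el)
  tmetal <- is_transition_metal(el)
  ionic_center <- .is_ionic_center(el)

  edges <- .empty_edges()
  add_edges <- function(i, j, type) {
    if (length(i) == 0) return()
    edges <<- rbind(edges, data.frame(
      i = i, j = j, type = type, dist = dist_mat[cbind(i, j)],
      stringsAsFactors = FALSE))
  }

  pair <- which(upper.tri(dist_mat), arr.ind = TRUE)
  ii <- pair[, 1]; jj <- pair[, 2]
  d <- dist_mat[pair]
  rsum <- r[ii] + r[jj]

  if ("covalent" %in% act || "hydrogen_bond" %in% act) {
    cov_sel <- nonmetal[ii] & nonmetal[jj] & d <= criteria$covalent_scale * rsum
  }
  if ("covalent" %in% act) {
    add_edges(ii[cov_sel], jj[cov_sel], "covalent")
  }
  if ("organometallic" %in% act) {
    om_sel <- xor(tmetal[ii], tmetal[jj]) & !ionic_center[ii] &
      !ionic_center[jj] & d <= criteria$organometallic_scale * rsum
    add_edges(ii[om_sel], jj[om_sel], "organometallic")
  }
  if ("hydrogen_bond" %in% act) {
    hb <- .perceive_hbonds(el, xyz, dist_mat, ii, jj, cov_sel, criteria)
    add_edges(hb$i, hb$j, if (nrow(hb)) "hydrogen_bond" else character(0))
  }
  if ("ionic" %in% act) {
    anion <- el %in% c("O", "N", .HALOGENS)
    ion_sel <- xor(ionic_center[ii], ionic_center[jj]) &
      (anion[ii] | anion[jj]) & d <= criteria$ionic_max_dist
    add_edges(ii[ion_sel], jj[ion_sel], "ionic")
  }

  edges <- edges[order(edges$i, edges$j, match(edges$type, INTERACTION_TYPES)), ]
  .new_molgraph(el, edges, snap$index, act)
}

# Hydrogen bonds: for every H covalently bound to a donor D in {N,O,F}, an
# edge D...A to any acceptor A in {N,O,F} (A != D) with d(D,A) <= hbond_max_da
# and angle D-H...A >= hbond_min_angle. The edge connects donor and acceptor.
.perceive_hbonds <- function(el, xyz, dist_mat, ii, jj, cov_sel, criteria) {
  dono <- el %in% c("N", "O", "F")
  out <- .empty_edges()[, c("i", "j")]
  # covalent D-H pairs
  ci <- ii[cov_sel]; cj <- jj[cov_sel]
  dh <- rbind(
    cbind(D = ci[el[cj] == "H" & dono[ci]], H = cj[el[cj] == "H" & dono[ci]]),
    cbind(D = cj[el[ci] == "H" & dono[cj]], H = ci[el[ci] == "H" & dono[cj]])
  )
  if (is.null(dh) || nrow(dh) == 0) return(out)
  acceptors <- which(dono)
  for (k in seq_len(nrow(dh))) {
    D <- dh[k, "D"]; H <- dh[k, "H"]
    for (A in acceptors) {
      if (A == D) next
      if (dist_mat[D, A] > criteria$hbond_max_da) next
      v1 <- xyz[D, ] - xyz[H, ]
      v2 <- xyz[A, ] - xyz[H, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= criteria$hbond_min_angle) {
        out <- rbind(out, data.frame(i = min(D, A), j = max(D, A)))
      }
    }
  }
  unique(out)
}

#' Convert a molecular graph to an igraph object
#'
#' Vertices carry an `element` attribute, edges carry `type` and `dist`.
#'
#' @param graph A `molecular_graph`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  g <- igraph::make_empty_graph(n = length(graph$elements), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "element", value = graph$elements)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j))
    g <- igraph::set_edge_attr(g, "type", value = graph$edges$type)
    g <- igraph::set_edge_attr(g, "dist", value = graph$edges$dist)
  }
  g
}
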