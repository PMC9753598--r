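# Canonical labeling of element- and edge-type-colored molecular graphs.
#
# The fingerprint of a species is a canonical certificate string: two graphs
# receive equal certificates if and only if they are isomorphic under a
# bijection preserving element labels and interaction types. The algorithm is
# iterative color refinement (Weisfeiler-Lehman style) with
# individualization/backtracking on color ties: when refinement leaves a
# non-discrete coloring, every vertex of the first smallest non-singleton
# color class is individualized in turn and the minimum certificate over all
# branches is taken. Branching over a whole (isomorphism-invariant) target
# cell makes the minimum independent of the input vertex order.
#
# Molecular graphs are small and sparse; the backtracking search is shallow in
# practice (it only activates on symmetric structures).

# Refine a coloring to the coarsest stable refinement. `colors` is an integer
# vector; adjacency is a list of per-vertex data.frames (nbr, type_id).
.refine_colors <- function(colors, adj) {
  n <- length(colors)
  repeat {
    sigs <- vapply(seq_len(n), function(v) {
      nb <- adj[[v]]
      if (nrow(nb) == 0) {
        paste0(colors[v], "|")
      } else {
        s <- paste0(nb$type_id, ":", colors[nb$nbr])
        paste0(colors[v], "|", paste(sort(s), collapse = ","))
      }
    }, character(1))
    new_colors <- match(sigs, sort(unique(sigs)))
    if (length(unique(new_colors)) == length(unique(colors))) {
      return(new_colors)
    }
    colors <- new_colors
  }
}

# Certificate string for a discrete coloring: vertices ordered by color.
.certificate_for <- function(colors, elements, edge_i, edge_j, edge_t) {
  perm <- integer(length(colors))
  perm[order(colors)] <- seq_along(colors) # perm[v] = new position of v
  els <- elements[order(colors)]
  if (length(edge_i) == 0) {
    return(paste0(paste(els, collapse = ","), ";"))
  }
  a <- pmin(perm[edge_i], perm[edge_j])
  b <- pmax(perm[edge_i], perm[edge_j])
  e <- paste0(a, "-", b, "-", edge_t)
  paste0(paste(els, collapse = ","), ";", paste(sort(e), collapse = ","))
}

.canon_search <- function(colors, adj, elements, edge_i, edge_j, edge_t) {
  colors <- .refine_colors(colors, adj)
  tab <- table(colors)
  nonsingleton <- as.integer(names(tab)[tab > 1])
  if (length(nonsingleton) == 0) {
    return(.certificate_for(colors, elements, edge_i, edge_j, edge_t))
  }
  # target cell: smallest non-singleton class; ties by smallest color value
  sizes <- tab[as.character(nonsingleton)]
  target <- nonsingleton[sizes == min(sizes)][1]
  cell <- which(colors == target)
  best <- NULL
  for (v in cell) {
    branch <- colors * 2L
    branch[v] <- branch[v] - 1L # individualize v below its old class
    cert <- .canon_search(branch, adj, elements, edge_i, edge_j, edge_t)
    if (is.null(best) || cert < best) best <- cert
  }
  best
}

#' Canonical fingerprint of a molecular graph
#'
#' Computes a canonical certificate of the labeled graph restricted to its
#' active interaction types: vertices are colored by element, edges by
#' interaction type. Two molecular graphs have equal fingerprints exactly when
#' they are isomorphic under an element- and type-preserving bijection, so the
#' fingerprint is invariant under any permutation of atom order. It is the
#' species identity used throughout speciation, network assembly and fragment
#' deduplication.
#'
#' @param graph A `molecular_graph`.
#' @return A character scalar of class `"fingerprint"` (the canonical key).
#' @examples
#' w <- snapshot(1, c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' fingerprint(perceive_bonds(w))
#' @export
fingerprint <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  n <- length(graph$elements)
  if (n == 0) stop("cannot fingerprint an empty graph")
  ed <- graph$edges
  type_id <- match(ed$type, INTERACTION_TYPES)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- data.frame(nbr = integer(0), type_id = integer(0))
  if (nrow(ed) > 0) {
    both <- data.frame(v = c(ed$i, ed$j), nbr = c(ed$j, ed$i),
                       type_id = c(type_id, type_id))
    sp <- split(both[, c("nbr", "type_id")], both$v)
    for (nm in names(sp)) adj[[as.integer(nm)]] <- sp[[nm]]
  }
  init <- match(graph$elements, sort(unique(graph$elements)))
  key <- .canon_search(init, adj, graph$elements, ed$i, ed$j,
                       type_id)
  structure(key, class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s>\n", fingerprint_hash(x)))
  invisible(x)
}

#' Short display hash of a fingerprint
#'
#' A 16-hex-digit FNV-1a hash of the canonical key, for compact display, CSV
#' export and file naming. Species identity always uses the full key, never
#' the hash.
#'
#' @param fp A fingerprint (or any character scalar).
#' @return A 16-character hexadecimal string.
#' @export
fingerprint_hash <- function(fp) {
  bytes <- utf8ToInt(as.character(fp))
  # FNV-1a, 64-bit arithmetic emulated as two 32-bit halves via doubles
  h <- c(0x84222325, 0xcbf29ce4) # lo, hi of 14695981039346656037
  prime_lo <- 0x1b3 # low word of the 64-bit FNV prime 0x100000001b3
  for (b in bytes) {
    # xor into the low byte only (b < 256); avoids 32-bit integer overflow
    h[1] <- h[1] - h[1] %% 256 + bitwXor(h[1] %% 256, b)
    # multiply (hi,lo) by the prime mod 2^64 (doubles stay exact: < 2^53)
    lo <- h[1] * prime_lo
    hi <- h[2] * prime_lo + h[1] * 256 # 2^40 term: lo * 2^8 into the high word
    h[1] <- lo %% 2^32
    h[2] <- (hi + floor(lo / 2^32)) %% 2^32
  }
  hex8 <- function(x) sprintf("%04x%04x", as.integer(x %/% 65536), as.integer(x %% 65536))
  paste0(hex8(h[2]), hex8(h[1]))
}
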