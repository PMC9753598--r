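# Independent oracles used to certify the production implementations:
# - exhaustive-permutation canonical form (isomorphism ground truth)
# - naive all-pairs bond perception
# - union-find connected components

# all permutations of 1..n as a matrix (one per row)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# type-coded adjacency matrix of a molecular_graph (0 = no edge)
.type_matrix <- function(g) {
  n <- length(g$elements)
  A <- matrix(0L, n, n)
  if (nrow(g$edges) > 0) {
    t_id <- match(g$edges$type, c("covalent", "organometallic",
                                  "hydrogen_bond", "ionic"))
    A[cbind(g$edges$i, g$edges$j)] <- t_id
    A[cbind(g$edges$j, g$edges$i)] <- t_id
  }
  A
}

# Exhaustive-permutation canonical certificate: the lexicographic minimum,
# over every vertex ordering, of (elements, upper-triangle of the type-coded
# adjacency matrix). Two graphs are isomorphic (element- and type-preserving)
# iff their certificates are equal. Brute force by construction; independent
# of the package's refinement-based canonicalization.
oracle_certificate <- function(g) {
  n <- length(g$elements)
  A <- .type_matrix(g)
  el_rank <- match(g$elements, sort(unique(g$elements)))
  perms <- all_permutations(n)
  ut <- upper.tri(A)
  best <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    cert <- paste(c(g$elements[p], A[p, p][ut]), collapse = ",")
    if (is.null(best) || cert < best) best <- cert
  }
  best
}

# Naive all-pairs bond perception, written independently of perceive_bonds:
# returns sorted "i-j-type" keys for covalent + organometallic edges.
oracle_bonds <- function(elements, coords, covalent_scale = 1.15,
                         organometallic_scale = 1.15) {
  tm <- c("Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
          "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
          "La", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg")
  ions <- c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba")
  n <- length(elements)
  out <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      rsum <- covalent_radius(elements[i]) + covalent_radius(elements[j])
      a <- elements[i]; b <- elements[j]
      if (!(a %in% c(tm, ions)) && !(b %in% c(tm, ions)) &&
          d <= covalent_scale * rsum) {
        out <- c(out, paste0(i, "-", j, "-covalent"))
      }
      if (xor(a %in% tm, b %in% tm) && !(a %in% ions) && !(b %in% ions) &&
          d <= organometallic_scale * rsum) {
        out <- c(out, paste0(i, "-", j, "-organometallic"))
      }
    }
  }
  sort(out)
}

# Union-find partition oracle: component id per vertex.
oracle_components <- function(n, edge_i, edge_j) {
  parent <- seq_len(n)
  for (k in seq_along(edge_i)) {
    ra <- edge_i[k]; while (parent[ra] != ra) ra <- parent[ra]
    rb <- edge_j[k]; while (parent[rb] != rb) rb <- parent[rb]
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }, integer(1))
  match(roots, unique(roots))
}
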