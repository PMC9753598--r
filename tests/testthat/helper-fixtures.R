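# Shared fixture builders: small structures, random graphs/networks, and
# fabricated event logs.

water_coords <- function() {
  rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
}

water_snapshot <- function(index = 1, energy = NA_real_) {
  snapshot(index, c("O", "H", "H"), water_coords(), energy)
}

# a water base structure for the synthetic generator
water_base <- function() {
  structure(list(elements = c("O", "H", "H"), coords = water_coords(),
                 units = list(1:3)),
            class = "base_structure")
}

# random labeled molecular graph (not geometry-derived); used for
# canonicalization and component tests
random_molgraph <- function(n, p = 0.35,
                            elements_pool = c("C", "O", "N", "Mn"),
                            types = c("covalent", "organometallic")) {
  el <- sample(elements_pool, n, replace = TRUE)
  if (n >= 2) {
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    sel <- stats::runif(nrow(pairs)) < p
    ed <- data.frame(i = as.integer(pairs[sel, 1]),
                     j = as.integer(pairs[sel, 2]),
                     type = sample(types, sum(sel), replace = TRUE),
                     dist = rep(1.5, sum(sel)), stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(i = integer(0), j = integer(0), type = character(0),
                     dist = numeric(0), stringsAsFactors = FALSE)
  }
  reanet:::.new_molgraph(el, ed, 1L, types)
}

# apply a vertex permutation to a molecular graph: perm[v] = new index of v
permute_molgraph <- function(g, perm) {
  inv <- order(perm)
  ed <- g$edges
  ni <- pmin(perm[ed$i], perm[ed$j])
  nj <- pmax(perm[ed$i], perm[ed$j])
  ed2 <- data.frame(i = ni, j = nj, type = ed$type, dist = ed$dist,
                    stringsAsFactors = FALSE)
  reanet:::.new_molgraph(g$elements[inv], ed2, g$snapshot_index, g$active_types)
}

# fabricate an event log with named species, given energies and a transition
# sequence (character vector pairs)
make_log <- function(energies, transitions = NULL) {
  db <- lapply(names(energies), function(nm) {
    rec <- reanet:::.new_species_record(structure(nm, class = "fingerprint"),
                                        NULL, character(0))
    rec$conformers <- data.frame(snapshot_index = 1L, energy = energies[[nm]])
    rec$node_energy <- energies[[nm]]
    rec
  })
  names(db) <- names(energies)
  tr <- if (is.null(transitions)) reanet:::.empty_transitions() else {
    data.frame(from_fingerprint = transitions[, 1],
               to_fingerprint = transitions[, 2],
               from_snapshot = seq_len(nrow(transitions)),
               to_snapshot = seq_len(nrow(transitions)) + 1L,
               stringsAsFactors = FALSE)
  }
  reanet:::.new_eventlog(db, tr, character(0))
}

# random reaction network: n nodes with random energies, random directed edges
random_network <- function(n_nodes = 8, p_edge = 0.3, energy_sd = 15) {
  keys <- paste0("sp", seq_len(n_nodes))
  energies <- stats::setNames(round(stats::rnorm(n_nodes, 0, energy_sd), 3), keys)
  pairs <- expand.grid(from = keys, to = keys, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
  tr <- as.matrix(pairs[rep(seq_len(nrow(pairs)),
                            sample(1:3, nrow(pairs), replace = TRUE)), ,
                        drop = FALSE])
  build_network(make_log(as.list(energies),
                         if (nrow(tr) > 0) tr else NULL))
}

# the six-node trimming scenario: nodes 1 and 4 exceed the node threshold,
# the edge 5 -> 2 exceeds the edge threshold, everything else is within
# bounds
six_node_scenario <- function() {
  energies <- list(n1 = 30, n2 = 24, n3 = 2, n4 = 28, n5 = 0, n6 = 10)
  transitions <- rbind(
    c("n2", "n6"), c("n6", "n5"), c("n3", "n6"), c("n5", "n3"),
    c("n5", "n2"), # uphill by 24 kcal/mol: exceeds the edge threshold of 20
    c("n3", "n1"), c("n1", "n5"), c("n4", "n6"), c("n2", "n4"))
  list(net = build_network(make_log(energies, transitions)),
       cfg = trim_config(node_threshold = 25, edge_threshold = 20))
}
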