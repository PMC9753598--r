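# Network assembly, trimming passes, style mappings, isomer statistics and
# serialization.

test_that("network assembly counts multiplicities and signs delta_e", {
  log1 <- make_log(list(A = 0))
  net1 <- build_network(log1)
  expect_length(net1$nodes, 1)
  expect_equal(nrow(net1$edges), 0)

  log2 <- make_log(list(A = 0, B = 7),
                   rbind(c("A", "B"), c("A", "B"), c("B", "A")))
  net2 <- build_network(log2)
  expect_length(net2$nodes, 2)
  expect_equal(nrow(net2$edges), 2)
  ab <- net2$edges[net2$edges$source == "A", ]
  ba <- net2$edges[net2$edges$source == "B", ]
  expect_equal(ab$multiplicity, 2L)
  expect_equal(ba$multiplicity, 1L)
  expect_equal(ab$delta_e, 7)
  expect_equal(ba$delta_e, -7)
  expect_equal(net2$min_energy, 0)
  expect_equal(net2$max_energy, 7)
})

test_that("the six-node scenario trims exactly nodes 1, 4 and the 5->2 edge", {
  sc <- six_node_scenario()
  trimmed <- trim_network(sc$net, sc$cfg)
  expect_setequal(names(trimmed$nodes), c("n2", "n3", "n5", "n6"))
  kept_edges <- paste(trimmed$edges$source, trimmed$edges$target)
  expect_setequal(kept_edges, c("n2 n6", "n6 n5", "n3 n6", "n5 n3"))
  # every edge incident to the trimmed nodes is gone with them
  expect_false(any(grepl("n1|n4", kept_edges)))
  # input network is unmodified
  expect_length(sc$net$nodes, 6)
  expect_equal(nrow(sc$net$edges), 9)
})

test_that("trimming below all thresholds is the identity", {
  sc <- six_node_scenario()
  loose <- trim_config(node_threshold = 1000, edge_threshold = 1000)
  trimmed <- trim_network(sc$net, loose)
  expect_setequal(names(trimmed$nodes), names(sc$net$nodes))
  expect_equal(nrow(trimmed$edges), nrow(sc$net$edges))
})

test_that("nodes stranded by earlier passes are pruned, except the reference", {
  log <- make_log(list(A = 0, B = 5, C = 30), rbind(c("B", "C")))
  net <- build_network(log)
  trimmed <- trim_network(net, trim_config(node_threshold = 25,
                                           edge_threshold = 25,
                                           reference = "A"))
  # C is over the node threshold; B then loses its only edge and is pruned;
  # the (isolated) reference A is always retained
  expect_identical(names(trimmed$nodes), "A")
  expect_equal(nrow(trimmed$edges), 0)
})

test_that("unreachable-node pruning is available as an option", {
  # A -> B and a disconnected pair C <-> D, all within thresholds
  log <- make_log(list(A = 0, B = 2, C = 3, D = 4),
                  rbind(c("A", "B"), c("C", "D"), c("D", "C")))
  net <- build_network(log)
  default <- trim_network(net, trim_config(reference = "A"))
  expect_setequal(names(default$nodes), c("A", "B", "C", "D"))
  reach <- trim_network(net, trim_config(reference = "A",
                                         prune_unreachable = TRUE))
  expect_setequal(names(reach$nodes), c("A", "B"))
})

test_that("a reference above the node threshold is a configuration error", {
  log <- make_log(list(A = 0, B = 40), rbind(c("A", "B")))
  net <- build_network(log)
  expect_error(trim_network(net, trim_config(reference = "B")),
               "reference node exceeds")
  expect_error(trim_network(net, trim_config(reference = "nope")),
               "not a node")
})

test_that("trimming is idempotent and yields subsets on random networks", {
  set.seed(17)
  for (k in 1:60) {
    net <- random_network(n_nodes = sample(3:10, 1), p_edge = runif(1, 0.1, 0.5))
    cfg <- trim_config(node_threshold = runif(1, 5, 40),
                       edge_threshold = runif(1, 5, 40))
    t1 <- trim_network(net, cfg)
    t2 <- trim_network(t1, trim_config(cfg$node_threshold, cfg$edge_threshold,
                                       reference = t1$reference))
    expect_setequal(names(t2$nodes), names(t1$nodes))
    expect_identical(t2$edges[order(t2$edges$source, t2$edges$target), ],
                     t1$edges[order(t1$edges$source, t1$edges$target), ])
    # subsets of the input
    expect_true(all(names(t1$nodes) %in% names(net$nodes)))
    key <- function(e) paste(e$source, e$target)
    expect_true(all(key(t1$edges) %in% key(net$edges)))
    # no retained node above the node threshold, no retained edge above the
    # edge threshold
    rel <- vapply(t1$nodes, function(r) r$node_energy, numeric(1)) -
      t1$nodes[[t1$reference]]$node_energy
    expect_true(all(rel <= cfg$node_threshold + 1e-12))
    expect_true(all(t1$edges$delta_e <= cfg$edge_threshold + 1e-12))
  }
})

test_that("style maps energies to [0,1] with the documented conventions", {
  log <- make_log(list(A = 0, B = 5, C = 20),
                  rbind(c("A", "B"), c("B", "C"), c("C", "A")))
  net <- build_network(log)
  st <- style_network(net)
  expect_equal(unname(st$node_color[c("A", "C")]), c(0, 1))
  expect_equal(unname(st$node_color["B"]), 0.25)
  # lowest delta_e edge (C->A, -20) is thickest; highest (B->C, +15) thinnest
  expect_equal(st$edge_width[net$edges$source == "C"], 1)
  expect_equal(st$edge_width[net$edges$source == "B"], 0)
  # degenerate conventions
  flat <- build_network(make_log(list(A = 3, B = 3), rbind(c("A", "B"))))
  st_flat <- style_network(flat)
  expect_equal(unname(st_flat$node_color), c(0.5, 0.5))
  expect_equal(st_flat$edge_width, 0.5)
})

test_that("style mappings are monotone on random networks", {
  set.seed(29)
  for (k in 1:20) {
    net <- random_network(n_nodes = sample(4:10, 1))
    st <- style_network(net)
    e <- vapply(net$nodes, function(r) r$node_energy, numeric(1))
    ord <- order(e)
    expect_true(all(diff(st$node_color[ord]) >= 0))
    expect_true(all(diff(e[ord]) > 0) == all(diff(st$node_color[ord]) > 0))
    if (nrow(net$edges) >= 2) {
      de_ord <- order(net$edges$delta_e)
      expect_true(all(diff(st$edge_width[de_ord]) <= 0))
    }
  }
})

test_that("isomer statistics are the five-number summary with interpolation", {
  rec <- reanet:::.new_species_record(structure("A", class = "fingerprint"),
                                      NULL, "He")
  set_e <- function(e) {
    rec$conformers <- data.frame(snapshot_index = seq_along(e), energy = e)
    rec
  }
  expect_equal(unname(isomer_stats(set_e(3))), c(3, 3, 3, 3, 3))
  expect_equal(unname(isomer_stats(set_e(c(0, 1, 2, 3, 4)))), 0:4)
  expect_equal(isomer_stats(set_e(c(0, 10)))[["median"]], 5)
  expect_error(isomer_stats(set_e(numeric(0))), "no conformer energies")
})

test_that("GraphML round-trips topology, energies, delta_e and multiplicity exactly", {
  set.seed(41)
  net <- random_network(n_nodes = 7, p_edge = 0.35)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, format = "graphml")
  back <- read_network_graphml(path)
  expect_setequal(names(back$nodes), names(net$nodes))
  for (nm in names(net$nodes)) {
    expect_identical(back$nodes[[nm]]$node_energy, net$nodes[[nm]]$node_energy)
  }
  ord <- function(e) e[order(e$source, e$target), c("source", "target",
                                                    "delta_e", "multiplicity")]
  a <- ord(net$edges); b <- ord(back$edges)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(b, a)
})

test_that("DOT, JSON and CSV exports are written", {
  net <- build_network(make_log(list(A = 0, B = 7),
                                rbind(c("A", "B"), c("B", "A"))))
  for (fmt in c("dot", "json", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(net, path, format = fmt)
    expect_gt(file.size(path), 0)
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path, format = "json")
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(parsed$nodes), 2)
  expect_equal(nrow(parsed$links), 2)
  expect_setequal(parsed$links$delta_e, c(7, -7))
})
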