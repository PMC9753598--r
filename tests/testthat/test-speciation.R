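# Canonical fingerprints, isomorphism, and the event-identification walk.

test_that("fingerprints are invariant under atom reordering", {
  g <- perceive_bonds(water_snapshot())
  for (k in 1:5) {
    perm <- sample(3)
    expect_identical(as.character(fingerprint(permute_molgraph(g, perm))),
                     as.character(fingerprint(g)))
  }
  # different structures get different keys
  oh <- reanet:::.new_molgraph(
    c("O", "H"),
    data.frame(i = 1L, j = 2L, type = "covalent", dist = 0.96),
    1L, c("covalent", "organometallic"))
  expect_false(identical(as.character(fingerprint(g)),
                         as.character(fingerprint(oh))))
})

test_that("edge types are part of species identity", {
  ed <- data.frame(i = 1L, j = 2L, type = "covalent", dist = 2.0)
  g1 <- reanet:::.new_molgraph(c("C", "Mn"), ed, 1L, c("covalent", "organometallic"))
  ed$type <- "organometallic"
  g2 <- reanet:::.new_molgraph(c("C", "Mn"), ed, 1L, c("covalent", "organometallic"))
  expect_false(identical(as.character(fingerprint(g1)),
                         as.character(fingerprint(g2))))
})

test_that("fingerprint equality matches the exhaustive-permutation oracle and VF2", {
  set.seed(101)
  graphs <- lapply(1:60, function(k) random_molgraph(sample(2:7, 1)))
  keys <- vapply(graphs, function(g) as.character(fingerprint(g)), character(1))
  oracle <- vapply(graphs, oracle_certificate, character(1))
  for (a in 1:59) {
    for (b in (a + 1):60) {
      expect_identical(keys[a] == keys[b], oracle[a] == oracle[b])
    }
  }
  # VF2 route agrees with the fingerprint route
  for (k in 1:40) {
    a <- sample(60, 1); b <- sample(60, 1)
    expect_identical(is_isomorphic(graphs[[a]], graphs[[b]]),
                     keys[a] == keys[b])
  }
})

test_that("highly symmetric graphs canonicalize correctly", {
  # a 6-ring of C with alternating H substituents exercises the
  # individualization/backtracking path (refinement alone cannot split it)
  ring <- function(perm = 1:12) {
    ed <- data.frame(
      i = c(1:6, 1:6), j = c(2:6, 1, 7:12),
      type = "covalent", dist = 1.4, stringsAsFactors = FALSE)
    g <- reanet:::.new_molgraph(c(rep("C", 6), rep("H", 6)), ed, 1L, "covalent")
    permute_molgraph(g, perm)
  }
  base_key <- as.character(fingerprint(ring()))
  set.seed(5)
  for (k in 1:6) {
    expect_identical(as.character(fingerprint(ring(sample(12)))), base_key)
  }
  # breaking one ring bond changes the key
  broken <- ring()
  broken$edges <- broken$edges[-1, ]
  expect_false(identical(as.character(fingerprint(broken)), base_key))
})

test_that("is_isomorphic agrees with brute force on a one-edge difference", {
  set.seed(61)
  g1 <- random_molgraph(6, p = 0.5, elements_pool = c("C", "O"))
  # drop one edge
  stopifnot(nrow(g1$edges) > 0)
  g2 <- g1
  g2$edges <- g2$edges[-1, ]
  expect_true(is_isomorphic(g1, g1))
  expect_false(is_isomorphic(g1, g2))
  expect_identical(oracle_certificate(g1) == oracle_certificate(g2), FALSE)
  # different element multisets are trivially non-isomorphic
  ch4 <- reanet:::.new_molgraph(
    c("C", rep("H", 4)),
    data.frame(i = 1L, j = 2:5, type = "covalent", dist = 1.1),
    1L, c("covalent", "organometallic"))
  nh3 <- reanet:::.new_molgraph(
    c("N", rep("H", 3)),
    data.frame(i = 1L, j = 2:4, type = "covalent", dist = 1.0),
    1L, c("covalent", "organometallic"))
  expect_false(is_isomorphic(ch4, nh3))
  # mismatched active types are a configuration error
  cov_only <- reanet:::.new_molgraph("He", reanet:::.empty_edges(), 1L, "covalent")
  expect_error(is_isomorphic(cov_only, ch4), "active interaction types")
})

test_that("a vibrating molecule yields one species and no transitions", {
  sched <- event_schedule(water_base(), seed = 9)
  res <- generate_trajectory(sched, 10)
  log <- analyze_trajectory(res$ensemble)
  expect_length(log$species_db, 1)
  expect_equal(nrow(log$transitions), 0)
  expect_equal(nrow(log$species_db[[1]]$conformers), 10)
})

test_that("a programmed dissociation is logged as one transition at the right frames", {
  base <- toy_complex(ligands = c("N", "O", "F"))
  sched <- event_schedule(
    base, events = list(list(frame = 4, type = "break_bond", i = 1L, j = 2L)),
    seed = 2)
  res <- generate_trajectory(sched, 6)
  log <- analyze_trajectory(res$ensemble)
  expect_length(log$species_db, 2)
  expect_equal(nrow(log$transitions), 1)
  expect_equal(log$transitions$from_snapshot, 3L)
  expect_equal(log$transitions$to_snapshot, 4L)
})

test_that("revisited species are re-identified, not duplicated", {
  base <- toy_complex(ligands = c("N", "O", "F"))
  sched <- event_schedule(
    base, events = list(
      list(frame = 3, type = "break_bond", i = 1L, j = 2L),
      list(frame = 6, type = "form_bond", i = 1L, j = 2L)),
    seed = 8)
  res <- generate_trajectory(sched, 8)
  log <- analyze_trajectory(res$ensemble)
  expect_length(log$species_db, 2)
  expect_equal(nrow(log$transitions), 2)
  # frames 1-2 and 6-8 share a fingerprint
  expect_identical(log$frame_species[1], log$frame_species[8])
  # node energy is the most stable conformer's
  for (rec in log$species_db) {
    expect_equal(rec$node_energy, min(rec$conformers$energy))
  }
})

test_that("speciation is deterministic and ensemble-decomposable", {
  sched <- random_schedule(77)
  res <- generate_trajectory(sched$schedule, sched$n_frames)
  log1 <- analyze_trajectory(res$ensemble)
  log2 <- analyze_trajectory(res$ensemble)
  expect_identical(names(log1$species_db), names(log2$species_db))
  expect_identical(log1$transitions, log2$transitions)
  expect_lte(length(log1$species_db), length(res$ensemble))
  expect_lte(nrow(log1$transitions), length(res$ensemble) - 1)
  # splitting the ensemble and merging the logs recovers the same species set
  n <- length(res$ensemble)
  half <- n %/% 2
  e1 <- reanet:::.new_ensemble(res$ensemble$snapshots[1:half], "kcalmol")
  e2 <- reanet:::.new_ensemble(res$ensemble$snapshots[(half + 1):n], "kcalmol")
  merged <- merge_event_logs(list(analyze_trajectory(e1), analyze_trajectory(e2)))
  expect_setequal(names(merged$species_db), names(log1$species_db))
  # no cross-trajectory transitions: merged count is at most the single-run count
  expect_lte(nrow(merged$transitions), nrow(log1$transitions))
})

test_that("the species table summarizes conformer ensembles", {
  sched <- event_schedule(water_base(), energies = c(3, 1, 2, 0), seed = 3)
  res <- generate_trajectory(sched, 4)
  tab <- species_table(analyze_trajectory(res$ensemble))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_conformers, 4)
  expect_equal(tab$node_energy, 0)
  expect_equal(tab$e_min, 0)
  expect_equal(tab$e_median, 1.5)
  expect_equal(tab$e_max, 3)
})
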