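# The synthetic trajectory generator: determinism, ground truth, and
# self-certification.

test_that("a no-event schedule yields one species downstream", {
  sched <- event_schedule(toy_complex(), seed = 20)
  res <- generate_trajectory(sched, 20)
  expect_equal(res$truth$n_species, 1)
  log <- analyze_trajectory(res$ensemble)
  expect_length(log$species_db, 1)
  expect_equal(nrow(log$transitions), 0)
})

test_that("three distinct programmed events give four species and three transitions", {
  base <- toy_complex(ligands = c("N", "O", "F", "P"),
                      bonded = c(TRUE, TRUE, TRUE, FALSE))
  sched <- event_schedule(base, events = list(
    list(frame = 3, type = "break_bond", i = 1L, j = 2L),
    list(frame = 6, type = "form_bond", i = 1L, j = 5L),
    list(frame = 9, type = "swap_ligand", i = 1L, j = 3L, k = 2L)),
    seed = 31)
  res <- generate_trajectory(sched, 12)
  expect_equal(res$truth$n_species, 4)
  expect_equal(nrow(res$truth$transitions), 3)
  log <- analyze_trajectory(res$ensemble)
  expect_length(log$species_db, 4)
  expect_equal(nrow(log$transitions), 3)
  expect_equal(log$transitions$from_snapshot, c(2L, 5L, 8L))
})

test_that("generation is byte-identical for the same seed", {
  sched <- random_schedule(99)
  p1 <- withr::local_tempfile(fileext = ".xyz")
  p2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(generate_trajectory(sched$schedule, sched$n_frames)$ensemble, p1)
  write_xyz_trajectory(generate_trajectory(sched$schedule, sched$n_frames)$ensemble, p2)
  expect_identical(readLines(p1), readLines(p2))
  other <- random_schedule(100)
  p3 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(generate_trajectory(other$schedule, other$n_frames)$ensemble, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("excessive jitter is rejected instead of corrupting the ground truth", {
  sched <- event_schedule(toy_complex(), jitter_sigma = 0.5, seed = 1)
  expect_error(generate_trajectory(sched, 5), "jitter_sigma")
})

test_that("events beyond the trajectory or out of order are rejected", {
  base <- toy_complex()
  expect_error(event_schedule(base, events = list(
    list(frame = 1, type = "break_bond", i = 1L, j = 2L))), ">= 2")
  expect_error(event_schedule(base, events = list(
    list(frame = 5, type = "break_bond", i = 1L, j = 2L),
    list(frame = 5, type = "form_bond", i = 1L, j = 2L))),
    "strictly increasing")
  expect_error(event_schedule(base, events = list(
    list(frame = 3, type = "teleport", i = 1L, j = 2L))), "unknown event type")
  sched <- event_schedule(base, events = list(
    list(frame = 30, type = "break_bond", i = 1L, j = 2L)))
  expect_error(generate_trajectory(sched, 10), "beyond trajectory length")
})

test_that("an edit that does not realize exactly its intended change errors", {
  # breaking an already-detached ligand changes nothing: certification fails
  base <- toy_complex(ligands = c("N", "O"), bonded = c(TRUE, FALSE))
  sched <- event_schedule(base, events = list(
    list(frame = 2, type = "break_bond", i = 1L, j = 3L)), seed = 5)
  expect_error(generate_trajectory(sched, 4), "unrealizable|not exactly")
})

test_that("explicit energies are used verbatim; drawn energies follow the species", {
  sched <- event_schedule(water_base(), energies = c(5, 6, 7), seed = 2)
  res <- generate_trajectory(sched, 3)
  expect_equal(vapply(res$ensemble$snapshots, `[[`, numeric(1), "energy"),
               c(5, 6, 7))
  expect_error(generate_trajectory(
    event_schedule(water_base(), energies = c(1, 2), seed = 2), 3),
    "one value per frame")
  # drawn energies: same species baseline across a revisit
  base <- toy_complex(ligands = c("N", "O", "F"))
  sched2 <- event_schedule(base, events = list(
    list(frame = 3, type = "break_bond", i = 1L, j = 2L),
    list(frame = 5, type = "form_bond", i = 1L, j = 2L)), seed = 7)
  res2 <- generate_trajectory(sched2, 6)
  expect_equal(res2$truth$n_species, 2)
  expect_equal(res2$truth$frame_species, c(1, 1, 2, 2, 1, 1))
  expect_length(res2$truth$species_baseline, 2)
})

test_that("random schedules generate and self-certify across seeds", {
  for (seed in c(1, 2, 3, 4, 5)) {
    sched <- random_schedule(seed)
    res <- generate_trajectory(sched$schedule, sched$n_frames)
    expect_equal(length(res$ensemble), sched$n_frames)
    expect_gte(res$truth$n_species, 2)
    expect_equal(nrow(res$truth$transitions),
                 sum(diff(res$truth$frame_species) != 0))
  }
})

test_that("schedule YAML round-trips through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "base:",
    "  metal: Mn",
    "  ligands: [N, O, F]",
    "  bonded: [true, true, false]",
    "events:",
    "  - {frame: 4, type: break_bond, i: 1, j: 2}",
    "  - {frame: 7, type: form_bond, i: 1, j: 4}",
    "n_frames: 10",
    "seed: 12"), path)
  parsed <- read_schedule_yaml(path)
  expect_equal(parsed$n_frames, 10)
  res <- generate_trajectory(parsed$schedule, parsed$n_frames)
  expect_equal(res$truth$n_species, 3)
  tj <- withr::local_tempfile(fileext = ".json")
  write_truth_json(res$truth, tj)
  parsed_truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(parsed_truth$n_species, 3)
})
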