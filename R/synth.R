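# Synthetic trajectory generator with programmed reaction events.
#
# Emulates a metadynamics-style conformer ensemble at the graph level:
# sequences of snapshots of a toy complex in which the bonding pattern changes
# at programmed frames (dissociation, association, ligand exchange,
# dimerization), with assigned per-frame energies and small coordinate
# jitter. Frames are constructed, not propagated: no force field, no dynamics.
# Energies are assigned from configurable normal distributions (a baseline
# per species plus a per-conformer spread), so trimming and boxplot
# statistics are testable against known values.
#
# The generator self-certifies: every emitted frame's perceived graph (via
# the all-pairs bond oracle) must equal the intended graph, and the jitter
# amplitude must be far smaller than the smallest slack to any perception
# cutoff, otherwise generation errors out rather than silently corrupting the
# ground truth.

# run expr with a private RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.OCT_DIRECTIONS <- rbind(
  c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

#' Build a toy octahedral complex as a base structure
#'
#' One transition-metal center with up to six monoatomic ligands on the
#' octahedral axes. Bonded ligands sit at `bond_factor` times the
#' organometallic perception cutoff; detached ligands at `detach_factor`
#' times, i.e. clearly outside it. Chemical plausibility is out of scope: the
#' contract is graph-level correctness under the given perception criteria.
#'
#' @param metal Element symbol of the center.
#' @param ligands Character vector (length <= 6) of monoatomic ligand
#'   elements.
#' @param bonded Logical vector: which ligands start bonded (default all).
#' @param criteria [bond_criteria()] used to place atoms relative to cutoffs.
#' @param bond_factor,detach_factor Placement distances as fractions of the
#'   perception cutoff.
#' @param origin 3-vector offset of the metal center.
#' @return A `base_structure`: `elements`, `coords`, `metal` (index),
#'   `ligand_of` (metal index per ligand), `units` (list of atom index
#'   vectors, one per molecular unit).
#' @export
toy_complex <- function(metal = "Mn",
                        ligands = c("N", "O", "F", "P", "S", "Cl"),
                        bonded = rep(TRUE, length(ligands)),
                        criteria = bond_criteria(),
                        bond_factor = 0.92, detach_factor = 1.8,
                        origin = c(0, 0, 0)) {
  stopifnot(length(ligands) <= 6, length(bonded) == length(ligands))
  r <- covalent_radius(c(metal, ligands))
  cutoff <- criteria$organometallic_scale * (r[1] + r[-1])
  dists <- ifelse(bonded, bond_factor, detach_factor) * cutoff
  coords <- rbind(origin,
                  .OCT_DIRECTIONS[seq_along(ligands), , drop = FALSE] * dists +
                    rep(origin, each = length(ligands)))
  structure(
    list(elements = c(metal, ligands), coords = unname(coords),
         metal = 1L, ligand_of = rep(1L, length(ligands)),
         units = list(seq_len(1L + length(ligands)))),
    class = "base_structure"
  )
}

#' Combine base structures into one multi-unit system
#'
#' Units keep their own coordinates (supply well-separated origins) and are
#' tracked so that `merge_units` events can translate one unit as a whole.
#'
#' @param ... `base_structure` objects.
#' @return A combined `base_structure`.
#' @export
combine_units <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  elements <- character(0); coords <- NULL; units <- list()
  for (p in parts) {
    offset <- length(elements)
    elements <- c(elements, p$elements)
    coords <- rbind(coords, p$coords)
    units <- c(units, lapply(p$units, function(u) u + offset))
  }
  structure(list(elements = elements, coords = unname(coords),
                 units = units),
            class = "base_structure")
}

#' Programmed event schedule for the synthetic generator
#'
#' Events edit the bonding pattern at given frames:
#' * `break_bond(i, j)` — move atom `j` radially away from `i`, outside the
#'   perception cutoff;
#' * `form_bond(i, j)` — move atom `j` radially toward `i`, inside the cutoff;
#' * `swap_ligand(i, j, k)` — break `i`-`j` and form `i`-`k` in the same
#'   frame (ligand exchange);
#' * `merge_units(unit, offset)` — translate all atoms of unit number `unit`
#'   by the 3-vector `offset` (e.g. dimerization by bringing two complexes
#'   into contact).
#'
#' @param base A `base_structure`.
#' @param events List of events, each a list with `frame` (>= 2, strictly
#'   increasing) and `type` (`"break_bond"`, `"form_bond"`, `"swap_ligand"`,
#'   `"merge_units"`) plus the fields above.
#' @param energies Optional explicit per-frame energies (kcal/mol); by default
#'   energies are drawn per species from normal distributions (see
#'   `energy_base_sd`, `energy_conformer_sd`).
#' @param jitter_sigma Gaussian coordinate noise, Angstrom. Must stay below a
#'   quarter of the smallest slack between any pair distance and its
#'   perception cutoff (enforced).
#' @param energy_base_sd Standard deviation (kcal/mol) of the per-species
#'   baseline energy draw.
#' @param energy_conformer_sd Standard deviation (kcal/mol) of the
#'   per-conformer spread around the species baseline.
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @return An object of class `"event_schedule"`.
#' @export
event_schedule <- function(base, events = list(), energies = NULL,
                           jitter_sigma = 0.02,
                           energy_base_sd = 10, energy_conformer_sd = 1,
                           seed = 1L) {
  stopifnot(inherits(base, "base_structure"))
  frames <- vapply(events, function(e) as.integer(e$frame), integer(1))
  if (length(frames) > 0) {
    if (any(frames < 2)) stop("event frames must be >= 2")
    if (any(diff(frames) <= 0)) stop("event frames must be strictly increasing")
  }
  types <- vapply(events, function(e) e$type, character(1))
  ok <- types %in% c("break_bond", "form_bond", "swap_ligand", "merge_units")
  if (!all(ok)) stop("unknown event type(s): ", paste(types[!ok], collapse = ", "))
  structure(
    list(base = base, events = events, energies = energies,
         jitter_sigma = jitter_sigma, energy_base_sd = energy_base_sd,
         energy_conformer_sd = energy_conformer_sd, seed = as.integer(seed)),
    class = "event_schedule"
  )
}

# edge set of a molecular graph as a sorted character vector "i-j-type"
.edge_key_set <- function(graph) {
  ed <- graph$edges
  if (nrow(ed) == 0) return(character(0))
  sort(paste0(ed$i, "-", ed$j, "-", ed$type))
}

# smallest |distance - applicable cutoff| over all atom pairs (the "slack"
# protecting the intended graph from jitter)
.min_cutoff_slack <- function(elements, coords, criteria) {
  n <- length(elements)
  if (n < 2) return(Inf)
  r <- covalent_radius(elements)
  d <- as.matrix(stats::dist(coords))
  nonmetal <- .is_nonmetal(elements)
  tmetal <- is_transition_metal(elements)
  slack <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cuts <- numeric(0)
      if ("covalent" %in% criteria$active_types && nonmetal[i] && nonmetal[j]) {
        cuts <- c(cuts, criteria$covalent_scale * (r[i] + r[j]))
      }
      if ("organometallic" %in% criteria$active_types && xor(tmetal[i], tmetal[j])) {
        cuts <- c(cuts, criteria$organometallic_scale * (r[i] + r[j]))
      }
      if (length(cuts) > 0) slack <- min(slack, abs(d[i, j] - cuts))
    }
  }
  slack
}

.apply_event <- function(coords, elements, ev, criteria,
                         bond_factor = 0.92, detach_factor = 1.8,
                         units = NULL) {
  move_radial <- function(coords, i, j, factor) {
    cutoff <- .pair_cutoff(elements[i], elements[j], criteria)
    dir <- coords[j, ] - coords[i, ]
    len <- sqrt(sum(dir^2))
    if (len == 0) stop("atoms ", i, " and ", j, " coincide")
    coords[j, ] <- coords[i, ] + dir / len * factor * cutoff
    coords
  }
  switch(ev$type,
    break_bond = move_radial(coords, ev$i, ev$j, detach_factor),
    form_bond = move_radial(coords, ev$i, ev$j, bond_factor),
    swap_ligand = {
      coords <- move_radial(coords, ev$i, ev$j, detach_factor)
      move_radial(coords, ev$i, ev$k, bond_factor)
    },
    merge_units = {
      u <- units[[ev$unit]]
      coords[u, ] <- coords[u, , drop = FALSE] +
        rep(as.numeric(ev$offset), each = length(u))
      coords
    },
    stop("unknown event type: ", ev$type)
  )
}

.pair_cutoff <- function(el_i, el_j, criteria) {
  r <- covalent_radius(c(el_i, el_j))
  scale <- if (xor(is_transition_metal(el_i), is_transition_metal(el_j))) {
    criteria$organometallic_scale
  } else {
    criteria$covalent_scale
  }
  scale * sum(r)
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Emits `n_frames` snapshots of the schedule's base structure. At each event
#' frame the programmed edit (and only it) changes the perceived bonding
#' pattern; between events atoms receive Gaussian jitter small enough that the
#' pattern provably cannot change (enforced as `jitter_sigma` < 0.25 x the
#' minimum slack to any perception cutoff, and additionally certified
#' frame-by-frame against the bond-perception oracle). Per-frame energies are
#' drawn as species baseline + conformer spread unless given explicitly.
#'
#' @param schedule An [event_schedule()].
#' @param n_frames Number of frames (>= 1, and > the last event frame).
#' @param criteria [bond_criteria()] used both to realize edits geometrically
#'   and to certify frames.
#' @return A list with `ensemble` (a `trajectory_ensemble`, energies in
#'   kcal/mol) and `truth`, the ground-truth record: `frame_species` (integer
#'   species id per frame, ids in order of first appearance), `n_species`,
#'   `transitions` (data frame `from_id`, `to_id`, `from_frame`, `to_frame`),
#'   `species_baseline` (assigned baseline energy per species id) and
#'   `edge_sets` (the intended edge set per species).
#' @export
generate_trajectory <- function(schedule, n_frames,
                                criteria = bond_criteria()) {
  stopifnot(inherits(schedule, "event_schedule"), n_frames >= 1)
  events <- schedule$events
  ev_frames <- vapply(events, function(e) as.integer(e$frame), integer(1))
  if (length(ev_frames) > 0 && max(ev_frames) > n_frames) {
    stop("event frame ", max(ev_frames), " beyond trajectory length ", n_frames)
  }
  elements <- schedule$base$elements
  units <- schedule$base$units

  # ideal (noiseless) geometry per frame + intended graph per frame
  ideal <- vector("list", n_frames)
  intended <- vector("list", n_frames)
  coords <- schedule$base$coords
  state_graph <- function(coords) {
    perceive_bonds(snapshot(1L, elements, coords), criteria)
  }
  g <- state_graph(coords)
  for (f in seq_len(n_frames)) {
    k <- match(f, ev_frames)
    if (!is.na(k)) {
      before <- .edge_key_set(g)
      coords <- .apply_event(coords, elements, events[[k]], criteria,
                             units = units)
      g <- state_graph(coords)
      after <- .edge_key_set(g)
      .check_edit(events[[k]], before, after, elements)
    }
    ideal[[f]] <- coords
    intended[[f]] <- .edge_key_set(g)
    slack <- .min_cutoff_slack(elements, coords, criteria)
    if (schedule$jitter_sigma >= 0.25 * slack) {
      stop("jitter_sigma ", schedule$jitter_sigma,
           " too large for cutoff slack ", format(slack), " at frame ", f)
    }
  }

  # ground-truth speciation from intended edge sets
  keys <- vapply(intended, paste, character(1), collapse = ";")
  frame_species <- match(keys, unique(keys))
  tr_at <- which(diff(frame_species) != 0)
  truth_transitions <- data.frame(
    from_id = frame_species[tr_at], to_id = frame_species[tr_at + 1L],
    from_frame = tr_at, to_frame = tr_at + 1L)

  .with_seed(schedule$seed, {
    n_species <- max(frame_species)
    baseline <- stats::rnorm(n_species, 0, schedule$energy_base_sd)
    energies <- if (!is.null(schedule$energies)) {
      if (length(schedule$energies) != n_frames) {
        stop("explicit energies must have one value per frame")
      }
      schedule$energies
    } else {
      baseline[frame_species] +
        stats::rnorm(n_frames, 0, schedule$energy_conformer_sd)
    }
    snaps <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      xyz <- ideal[[f]] + matrix(
        stats::rnorm(3 * length(elements), 0, schedule$jitter_sigma),
        ncol = 3)
      snap <- snapshot(f, elements, xyz, energies[f],
                       source_tag = sprintf("synthetic#%d", f))
      # self-certification: the perceived graph of the emitted frame must be
      # the intended graph
      got <- .edge_key_set(perceive_bonds(snap, criteria))
      if (!identical(got, intended[[f]])) {
        stop("generation failed certification at frame ", f,
             ": jitter crossed a perception cutoff")
      }
      snaps[[f]] <- snap
    }
    list(
      ensemble = .new_ensemble(snaps, "kcalmol"),
      truth = list(
        frame_species = frame_species,
        n_species = n_species,
        transitions = truth_transitions,
        species_baseline = baseline,
        energies = energies,
        edge_sets = lapply(unique(keys), function(k) intended[[match(k, keys)]])
      )
    )
  })
}

.check_edit <- function(ev, before, after, elements) {
  if (ev$type == "merge_units") {
    if (length(setdiff(after, before)) < 1 || length(setdiff(before, after)) != 0) {
      stop("merge_units event did not purely add bonds (frame ", ev$frame, ")")
    }
    return(invisible())
  }
  pair_key <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    paste0("^", a, "-", b, "-")
  }
  lost <- setdiff(before, after)
  gained <- setdiff(after, before)
  expect_lost <- switch(ev$type, break_bond = pair_key(ev$i, ev$j),
                        swap_ligand = pair_key(ev$i, ev$j), form_bond = NULL)
  expect_gain <- switch(ev$type, form_bond = pair_key(ev$i, ev$j),
                        swap_ligand = pair_key(ev$i, ev$k), break_bond = NULL)
  ok <- TRUE
  if (is.null(expect_lost)) ok <- ok && length(lost) == 0
  else ok <- ok && length(lost) == 1 && grepl(expect_lost, lost)
  if (is.null(expect_gain)) ok <- ok && length(gained) == 0
  else ok <- ok && length(gained) == 1 && grepl(expect_gain, gained)
  if (!ok) {
    stop("unrealizable edit at frame ", ev$frame, " (", ev$type,
         "): graph change is not exactly the programmed edit")
  }
  invisible()
}

#' Draw a random event schedule on the default toy complex
#'
#' Used for property-style validation: a six-ligand toy complex (four ligands
#' bonded, two detached at start) with `n_events` random dissociation,
#' association or ligand-exchange events at random distinct frames. Revisits
#' (A -> B -> A) arise naturally when a broken bond is re-formed.
#'
#' @param seed Integer seed (drives both the schedule draw and generation).
#' @param n_events Number of events (default: uniform on 1..5).
#' @param n_frames Trajectory length (default: uniform on
#'   `max(5, 2 * n_events + 1)`..50).
#' @param criteria [bond_criteria()] passed through to generation.
#' @return A list with `schedule` and `n_frames`.
#' @export
random_schedule <- function(seed, n_events = NULL, n_frames = NULL,
                            criteria = bond_criteria()) {
  .with_seed(seed, {
    if (is.null(n_events)) n_events <- sample(1:5, 1)
    if (is.null(n_frames)) n_frames <- sample(max(5, 2 * n_events + 1):50, 1)
    ligands <- c("N", "O", "F", "P", "S", "Cl")
    bonded <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
    base <- toy_complex(ligands = ligands, bonded = bonded,
                        criteria = criteria)
    pick <- function(x) x[sample.int(length(x), 1)] # safe for length-1 x
    frames <- sort(sample(2:n_frames, n_events))
    state <- bonded # which ligands currently bonded
    events <- list()
    for (f in frames) {
      choices <- c(if (any(state)) "break_bond",
                   if (any(!state)) "form_bond",
                   if (any(state) && any(!state)) "swap_ligand")
      type <- pick(choices)
      if (type == "break_bond") {
        lig <- pick(which(state))
        events[[length(events) + 1L]] <- list(frame = f, type = "break_bond",
                                              i = 1L, j = lig + 1L)
        state[lig] <- FALSE
      } else if (type == "form_bond") {
        lig <- pick(which(!state))
        events[[length(events) + 1L]] <- list(frame = f, type = "form_bond",
                                              i = 1L, j = lig + 1L)
        state[lig] <- TRUE
      } else {
        out_l <- pick(which(state))
        in_l <- pick(which(!state))
        events[[length(events) + 1L]] <- list(frame = f, type = "swap_ligand",
                                              i = 1L, j = out_l + 1L,
                                              k = in_l + 1L)
        state[out_l] <- FALSE
        state[in_l] <- TRUE
      }
    }
    list(schedule = event_schedule(base, events, seed = seed),
         n_frames = n_frames)
  })
}

#' A dimerization schedule: two metal complexes merge at a given frame
#'
#' Two Mn complexes start as separate fragments; at `merge_frame` the second
#' unit is translated so its metal center binds the chloride ligand of the
#' first unit, forming a single binuclear (two-pivot) fragment. Mirrors the
#' discovery of dinuclear species in multi-metal trajectories.
#'
#' @param merge_frame Frame of the dimerization event.
#' @param criteria [bond_criteria()].
#' @param seed Integer seed.
#' @return An `event_schedule`.
#' @export
dimerization_schedule <- function(merge_frame = 5L,
                                  criteria = bond_criteria(), seed = 1L) {
  # unit 1: Mn + N,O,F,P on -x,+y,-y,+z and a bridging Cl on +x
  u1 <- toy_complex(metal = "Mn", ligands = c("Cl", "N", "O", "F", "P"),
                    criteria = criteria)
  # ligand order maps to octahedral axes +x,-x,+y,-y,+z: Cl gets +x
  # unit 2: Mn + N,O ligands on +y,-y, far away on the +x axis
  u2 <- toy_complex(metal = "Mn", ligands = c("O", "S"),
                    criteria = criteria, origin = c(14, 0, 0))
  # put unit-2 ligands on the y axes, leaving its -x side free for approach
  u2$coords[2, ] <- u2$coords[1, ] + c(0, 1, 0) * sqrt(sum((u2$coords[2, ] - u2$coords[1, ])^2))
  u2$coords[3, ] <- u2$coords[1, ] + c(0, -1, 0) * sqrt(sum((u2$coords[3, ] - u2$coords[1, ])^2))
  base <- combine_units(u1, u2)
  # translate unit 2 so Mn2 ends up at 0.92 x cutoff beyond the bridging Cl
  cl_pos <- u1$coords[2, ] # Cl on +x of Mn1
  cutoff <- .pair_cutoff("Cl", "Mn", criteria)
  mn2_target <- cl_pos + c(0.92 * cutoff, 0, 0)
  offset <- mn2_target - u2$coords[1, ]
  event_schedule(
    base,
    events = list(list(frame = merge_frame, type = "merge_units",
                       unit = 2L, offset = offset)),
    seed = seed
  )
}
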