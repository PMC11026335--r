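# Experimental design: stimulus set and trial schedules.

#' Create a stimulus set of objects, rooms and object-room pairings
#'
#' The design pairs 4 objects with 16 rooms. Rooms are split into two
#' disjoint halves of 8: one half carries newly learned, semantically
#' unrelated pairings (episodic trials), the other carries pairings with a
#' strong prior-knowledge fit (semantic trials). Within each half every
#' object is paired with exactly two rooms, so each trial type supports a
#' "same object, different room" contrast. The room-to-object assignment and
#' the episodic/semantic room split are randomized by `seed` subject to
#' these constraints, mirroring the counterbalancing of pairings across
#' participants.
#'
#' @param seed integer seed for the randomized assignment, or `NULL` to use
#'   the current RNG state.
#' @param objects,rooms identifier vectors; lengths must be 4 and 16.
#' @return an object of class `stimulus_set`: a list with `objects`,
#'   `rooms`, `episodic_pairs` and `semantic_pairs` (named character
#'   vectors mapping room -> object).
#' @export
#' @examples
#' stim <- make_stimulus_set(seed = 1)
#' table(stim$episodic_pairs)
make_stimulus_set <- function(seed = NULL,
                              objects = paste0("object", 1:4),
                              rooms = sprintf("room%02d", 1:16)) {
  if (length(objects) != 4L || anyDuplicated(objects))
    stop_data("exactly 4 distinct objects required")
  if (length(rooms) != 16L || anyDuplicated(rooms))
    stop_data("exactly 16 distinct rooms required")
  with_seed(seed, {
    room_order <- sample(rooms)
    epi_rooms <- room_order[1:8]
    sem_rooms <- room_order[9:16]
    # each object twice per trial type, order randomized
    epi_obj <- sample(rep(objects, 2L))
    sem_obj <- sample(rep(objects, 2L))
    out <- list(
      objects = objects,
      rooms = rooms,
      episodic_pairs = stats::setNames(epi_obj, epi_rooms),
      semantic_pairs = stats::setNames(sem_obj, sem_rooms)
    )
    class(out) <- "stimulus_set"
    validate_stimulus_set(out)
    out
  })
}

#' Validate the structural invariants of a stimulus set
#'
#' Checks the 4-object/16-room layout, disjointness of the episodic and
#' semantic room halves, and the two-rooms-per-object constraint within each
#' trial type.
#'
#' @param stim a `stimulus_set`.
#' @return `stim`, invisibly; errors otherwise.
#' @export
validate_stimulus_set <- function(stim) {
  if (!inherits(stim, "stimulus_set")) stop_data("not a stimulus_set")
  if (length(stim$objects) != 4L) stop_data("need exactly 4 objects")
  if (length(stim$rooms) != 16L) stop_data("need exactly 16 rooms")
  er <- names(stim$episodic_pairs); sr <- names(stim$semantic_pairs)
  if (length(er) != 8L || length(sr) != 8L)
    stop_data("episodic and semantic pairing maps must have 8 rooms each")
  if (length(intersect(er, sr)) > 0L)
    stop_data("episodic and semantic room sets overlap")
  if (!setequal(c(er, sr), stim$rooms))
    stop_data("pairing maps must cover all 16 rooms")
  for (m in list(stim$episodic_pairs, stim$semantic_pairs)) {
    cnt <- table(factor(m, levels = stim$objects))
    if (any(cnt != 2L))
      stop_data("each object must appear in exactly 2 pairs per trial type")
  }
  invisible(stim)
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Stimulus set: 4 objects x 16 rooms\n")
  cat("  episodic pairs:",
      paste(names(x$episodic_pairs), x$episodic_pairs, sep = "->",
            collapse = ", "), "\n")
  cat("  semantic pairs:",
      paste(names(x$semantic_pairs), x$semantic_pairs, sep = "->",
            collapse = ", "), "\n")
  invisible(x)
}

#' Room-to-object lookup for a stimulus set
#'
#' @param stim a `stimulus_set`.
#' @return a data frame with columns `room`, `object`, `trial_type`.
#' @export
room_object_map <- function(stim) {
  validate_stimulus_set(stim)
  data.frame(
    room = c(names(stim$episodic_pairs), names(stim$semantic_pairs)),
    object = c(unname(stim$episodic_pairs), unname(stim$semantic_pairs)),
    trial_type = rep(c("episodic", "semantic"), each = 8L),
    stringsAsFactors = FALSE
  )
}

new_trial_table <- function(df, stim_dur, iti) {
  rownames(df) <- NULL
  structure(df, class = c("trial_table", "data.frame"),
            stim_dur = stim_dur, iti = iti)
}

#' Generate the occlusion-task trial schedule
#'
#' Each run presents every room `reps` times in a seed-shuffled order, with
#' onsets on a fixed grid of `stim_dur + iti` seconds. The defaults give
#' 4 runs of 96 trials lasting 576 s each (16 rooms x 6 repetitions, 4 s
#' stimulus + 2 s inter-trial interval). Episodic and semantic rooms are
#' shuffled jointly.
#'
#' @param stim a `stimulus_set`.
#' @param n_runs number of runs (>= 1).
#' @param reps repetitions of each room per run (>= 1).
#' @param stim_dur,iti stimulus duration and inter-trial interval, seconds.
#' @param seed integer seed for the trial-order shuffles, or `NULL`.
#' @return a `trial_table` data frame with columns `run`, `trial_index`,
#'   `onset`, `room`, `object`, `trial_type`, `phase`; attributes
#'   `stim_dur` and `iti` carry the timing constants.
#' @export
#' @examples
#' sched <- make_occlusion_schedule(make_stimulus_set(seed = 1), seed = 2)
#' nrow(sched) # 4 x 96
make_occlusion_schedule <- function(stim, n_runs = 4L, reps = 6L,
                                    stim_dur = 4, iti = 2, seed = NULL) {
  validate_stimulus_set(stim)
  if (n_runs < 1L || reps < 1L) stop_data("n_runs and reps must be >= 1")
  if (stim_dur <= 0 || iti < 0) stop_data("non-positive durations rejected")
  map <- room_object_map(stim)
  with_seed(seed, {
    runs <- lapply(seq_len(n_runs), function(r) {
      rooms <- sample(rep(map$room, reps))
      k <- seq_along(rooms)
      data.frame(
        run = r,
        trial_index = k,
        onset = (k - 1) * (stim_dur + iti),
        room = rooms,
        object = map$object[match(rooms, map$room)],
        trial_type = map$trial_type[match(rooms, map$room)],
        phase = "occlusion",
        stringsAsFactors = FALSE
      )
    })
    new_trial_table(do.call(rbind, runs), stim_dur, iti)
  })
}

#' Generate the sensory-template trial schedule
#'
#' A single run showing all 16 correct object-room pairings without
#' occlusion, `reps` times each in seed-shuffled order. The defaults give
#' 192 trials (16 x 12) lasting 480 s (1.5 s stimulus + 1 s inter-trial
#' interval). This run provides the feedforward reference patterns.
#'
#' @inheritParams make_occlusion_schedule
#' @param reps repetitions of each pairing (>= 1), default 12.
#' @return a `trial_table` (phase `"sensory"`, single run).
#' @export
make_sensory_schedule <- function(stim, reps = 12L, stim_dur = 1.5, iti = 1,
                                  seed = NULL) {
  validate_stimulus_set(stim)
  if (reps < 1L) stop_data("reps must be >= 1")
  if (stim_dur <= 0 || iti < 0) stop_data("non-positive durations rejected")
  map <- room_object_map(stim)
  with_seed(seed, {
    rooms <- sample(rep(map$room, reps))
    k <- seq_along(rooms)
    df <- data.frame(
      run = 1L,
      trial_index = k,
      onset = (k - 1) * (stim_dur + iti),
      room = rooms,
      object = map$object[match(rooms, map$room)],
      trial_type = map$trial_type[match(rooms, map$room)],
      phase = "sensory",
      stringsAsFactors = FALSE
    )
    new_trial_table(df, stim_dur, iti)
  })
}

#' Total scheduled duration of one run of a trial table
#'
#' Last trial offset plus the closing inter-trial interval, i.e. the nominal
#' run length implied by the onset grid.
#'
#' @param table a `trial_table`.
#' @param run run number.
#' @return duration in seconds.
#' @export
run_duration <- function(table, run = 1L) {
  tr <- table[table$run == run, , drop = FALSE]
  if (!nrow(tr)) stop_data("no such run: ", run)
  max(tr$onset) + attr(table, "stim_dur") + attr(table, "iti")
}

validate_trial_table <- function(table) {
  need <- c("run", "trial_index", "onset", "room", "object", "trial_type",
            "phase")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop_data("missing column(s): ", paste(miss, collapse = ", "))
  for (r in unique(table$run)) {
    tr <- table[table$run == r, ]
    if (anyDuplicated(tr$trial_index))
      stop_data("duplicated trial_index in run ", r)
    if (is.unsorted(tr$onset, strictly = TRUE))
      stop_data("onsets not strictly increasing within run ", r)
  }
  invisible(table)
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d trials, %d run(s), phase %s\n", nrow(x),
              length(unique(x$run)), paste(unique(x$phase), collapse = "/")))
  cat(sprintf("  stimulus %gs + ITI %gs; run duration %gs\n",
              attr(x, "stim_dur"), attr(x, "iti"), run_duration(x, x$run[1])))
  print(head(as.data.frame(x), 4L))
  invisible(x)
}
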