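# Generative model for subject and cohort voxel patterns.

#' Ground-truth simulation parameters for one group
#'
#' The simulator writes each trial's voxel pattern as an additive mixture of
#' a room-specific (contextual) signature, an object-specific (mnemonic)
#' signature and i.i.d. Gaussian noise. Signatures are unit-norm, so the
#' amplitudes are directly interpretable as per-component SNR against
#' `noise_sd = 1`.
#'
#' @param group group label, e.g. `"younger"` / `"older"`.
#' @param n_voxels voxels per region of interest (>= 2).
#' @param w_ctx contextual (room) amplitude during occlusion trials.
#' @param w_mne_epi,w_mne_sem mnemonic (object) amplitude for the episodic
#'   and semantic retrieval routes.
#' @param w_ff feedforward amplitude applied to both the room and the object
#'   signature on sensory-template trials (both are physically on screen
#'   there).
#' @param noise_sd Gaussian noise standard deviation per voxel.
#' @param signature_seed seed for drawing the signature vectors; `NULL`
#'   defers to the seed given at simulation time.
#' @return an object of class `ground_truth_params`.
#' @export
group_params <- function(group, n_voxels = 50L, w_ctx = 0.9,
                         w_mne_epi = 0.3, w_mne_sem = 0.15, w_ff = 1,
                         noise_sd = 1, signature_seed = NULL) {
  if (n_voxels < 2L) stop_data("n_voxels must be >= 2")
  amps <- c(w_ctx = w_ctx, w_mne_epi = w_mne_epi, w_mne_sem = w_mne_sem,
            w_ff = w_ff, noise_sd = noise_sd)
  if (any(amps < 0)) stop_data("amplitudes and noise_sd must be >= 0")
  structure(list(group = group, n_voxels = as.integer(n_voxels),
                 w_ctx = w_ctx, w_mne_epi = w_mne_epi,
                 w_mne_sem = w_mne_sem, w_ff = w_ff, noise_sd = noise_sd,
                 signature_seed = signature_seed),
            class = "ground_truth_params")
}

#' @export
print.ground_truth_params <- function(x, ...) {
  cat(sprintf(
    "Ground truth [%s]: %d voxels, w_ctx=%g, w_mne_epi=%g, w_mne_sem=%g, w_ff=%g, noise_sd=%g\n",
    x$group, x$n_voxels, x$w_ctx, x$w_mne_epi, x$w_mne_sem, x$w_ff,
    x$noise_sd))
  invisible(x)
}

#' Default per-group parameter presets
#'
#' Reads the shipped preset file (`inst/extdata/group_presets.json`). The
#' "younger" and "older" presets encode the qualitative group differences
#' the package's demo cohort emulates: the older preset has a weaker
#' contextual amplitude, an equal episodic but stronger semantic mnemonic
#' amplitude, a weaker feedforward amplitude and more noise.
#'
#' @param n_voxels voxels per ROI; overrides the preset value if given.
#' @return named list of `ground_truth_params`, one per group.
#' @export
default_group_params <- function(n_voxels = NULL) {
  path <- system.file("extdata", "group_presets.json",
                      package = "feedbackRSA", mustWork = TRUE)
  presets <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(names(presets), function(g) {
    p <- presets[[g]]
    group_params(group = g,
                 n_voxels = n_voxels %||% p$n_voxels,
                 w_ctx = p$w_ctx, w_mne_epi = p$w_mne_epi,
                 w_mne_sem = p$w_mne_sem, w_ff = p$w_ff,
                 noise_sd = p$noise_sd)
  })
  stats::setNames(out, names(presets))
}

#' Draw room and object signature vectors
#'
#' One unit-norm voxel signature per room (16) and per object (4), drawn as
#' Gaussian vectors and, by default, Gram-Schmidt orthogonalized within each
#' type so that recovery tests are not confounded by accidental signature
#' collinearity. With fewer voxels than signatures only the first
#' `n_voxels` vectors of a type can be mutually orthogonal; the remainder
#' are unit-norm only.
#'
#' @param n_voxels number of voxels.
#' @param rooms,objects identifier vectors.
#' @param seed RNG seed.
#' @param orthogonalize logical; set `FALSE` for raw Gaussian directions.
#' @return list with matrices `room` (`n_voxels` x 16) and `object`
#'   (`n_voxels` x 4), columns named by identifier.
#' @export
make_signatures <- function(n_voxels, rooms, objects, seed = NULL,
                            orthogonalize = TRUE) {
  with_seed(seed, {
    draw <- function(ids) {
      V <- matrix(rnorm(n_voxels * length(ids)), n_voxels, length(ids),
                  dimnames = list(NULL, ids))
      if (orthogonalize) gram_schmidt(V)
      else sweep(V, 2L, sqrt(colSums(V^2)), "/")
    }
    list(room = draw(rooms), object = draw(objects))
  })
}

#' Simulate a subject's trial-by-voxel response patterns
#'
#' For occlusion trials the pattern is
#' `w_ctx * s_room + w_mne(type) * s_object + noise`, where `w_mne(type)` is
#' the episodic or semantic mnemonic amplitude; for sensory-template trials
#' the feedforward amplitude `w_ff` replaces both feedback amplitudes and
#' scales room and object signatures alike. Noise is i.i.d. Gaussian per
#' voxel and trial. The rows stand in for single-trial beta estimates.
#'
#' @param truth a `ground_truth_params`.
#' @param schedule a `trial_table` (occlusion or sensory phase).
#' @param seed RNG seed for noise (and signatures when `signatures` is
#'   `NULL` and `truth$signature_seed` is unset).
#' @param signatures optional precomputed result of [make_signatures()];
#'   pass the same object for a subject's occlusion and sensory phases so
#'   both phases share signatures.
#' @param subject,roi labels stored on the result.
#' @param orthogonalize passed to [make_signatures()].
#' @return an object of class `subject_patterns`: list with the pattern
#'   matrix `X` (`n_trials` x `n_voxels`), the `trials` table, and the
#'   provenance fields `subject`, `group`, `roi`, `truth`.
#' @export
simulate_subject_patterns <- function(truth, schedule, seed = NULL,
                                      signatures = NULL, subject = "s01",
                                      roi = "V1", orthogonalize = TRUE) {
  if (!inherits(truth, "ground_truth_params")) stop_data("truth must be ground_truth_params")
  validate_trial_table(schedule)
  if (!nrow(schedule)) stop_data("schedule is empty")
  if (is.null(signatures)) {
    sig_seed <- truth$signature_seed %||% seed
    rooms <- sort(unique(schedule$room))
    objects <- sort(unique(schedule$object))
    signatures <- make_signatures(truth$n_voxels, rooms, objects,
                                  seed = sig_seed,
                                  orthogonalize = orthogonalize)
  }
  if (nrow(signatures$room) != truth$n_voxels)
    stop_data("signature voxel count (", nrow(signatures$room),
              ") does not match n_voxels (", truth$n_voxels, ")")
  miss <- setdiff(unique(schedule$room), colnames(signatures$room))
  if (length(miss)) stop_data("no signature for room(s): ",
                              paste(miss, collapse = ", "))
  P <- truth$n_voxels
  n <- nrow(schedule)
  w_room <- ifelse(schedule$phase == "sensory", truth$w_ff, truth$w_ctx)
  w_obj <- ifelse(schedule$phase == "sensory", truth$w_ff,
                  ifelse(schedule$trial_type == "episodic",
                         truth$w_mne_epi, truth$w_mne_sem))
  S <- t(signatures$room[, schedule$room, drop = FALSE]) * w_room +
       t(signatures$object[, schedule$object, drop = FALSE]) * w_obj
  X <- S + with_seed(seed, matrix(rnorm(n * P, sd = truth$noise_sd), n, P))
  dimnames(X) <- NULL
  if (any(!is.finite(X))) stop_data("non-finite simulated pattern values")
  structure(list(X = X, trials = schedule, subject = subject,
                 group = truth$group, roi = roi, truth = truth,
                 signatures = signatures),
            class = "subject_patterns")
}

#' @export
print.subject_patterns <- function(x, ...) {
  cat(sprintf("Subject patterns: %s [%s, %s] %d trials x %d voxels (%s)\n",
              x$subject, x$group %||% "?", x$roi, nrow(x$X), ncol(x$X),
              paste(unique(x$trials$phase), collapse = "/")))
  invisible(x)
}

#' Simulate a cohort of subjects with occlusion and sensory phases
#'
#' Each subject receives an individually counterbalanced stimulus set, an
#' individual occlusion and sensory schedule, and per-ROI signature draws;
#' all child seeds are derived from `seed` by counter-based splitting, so
#' the cohort is bit-reproducible and adding subjects never alters existing
#' ones.
#'
#' @param params named list of `ground_truth_params`, one per group.
#' @param n_per_group subjects per group (>= 1).
#' @param seed master seed.
#' @param rois ROI labels to simulate (same parameters, independent
#'   signatures and noise).
#' @param n_runs,reps occlusion schedule layout, see
#'   [make_occlusion_schedule()].
#' @param sensory_reps sensory schedule repetitions, see
#'   [make_sensory_schedule()].
#' @param orthogonalize passed to [make_signatures()].
#' @return an object of class `cohort`: list of subjects, each a list with
#'   `subject`, `group`, `stimulus`, and `patterns[[roi]][[phase]]`
#'   (`phase` in `"occlusion"`, `"sensory"`).
#' @export
make_cohort <- function(params, n_per_group, seed = 1L,
                        rois = c("V1", "V2"), n_runs = 4L, reps = 6L,
                        sensory_reps = 12L, orthogonalize = TRUE) {
  if (n_per_group < 1L) stop_data("n_per_group must be >= 1")
  if (is.null(names(params)) || any(!nzchar(names(params))))
    stop_data("params must be a named list of group presets")
  subjects <- list()
  sidx <- 0L
  for (gi in seq_along(params)) {
    truth <- params[[gi]]
    for (si in seq_len(n_per_group)) {
      sidx <- sidx + 1L
      sseed <- derive_seed(seed, gi, si)
      stim <- make_stimulus_set(seed = derive_seed(sseed, 1L))
      occ <- make_occlusion_schedule(stim, n_runs = n_runs, reps = reps,
                                     seed = derive_seed(sseed, 2L))
      sen <- make_sensory_schedule(stim, reps = sensory_reps,
                                   seed = derive_seed(sseed, 3L))
      id <- sprintf("%s_%02d", names(params)[gi], si)
      pats <- lapply(seq_along(rois), function(ri) {
        sig <- make_signatures(truth$n_voxels, sort(stim$rooms),
                               sort(stim$objects),
                               seed = derive_seed(sseed, 10L + ri),
                               orthogonalize = orthogonalize)
        list(
          occlusion = simulate_subject_patterns(
            truth, occ, seed = derive_seed(sseed, 20L + ri),
            signatures = sig, subject = id, roi = rois[ri]),
          sensory = simulate_subject_patterns(
            truth, sen, seed = derive_seed(sseed, 30L + ri),
            signatures = sig, subject = id, roi = rois[ri])
        )
      })
      subjects[[sidx]] <- list(subject = id, group = truth$group,
                               stimulus = stim,
                               patterns = stats::setNames(pats, rois))
    }
  }
  structure(subjects, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, "", "group")
  cat(sprintf("Cohort: %d subjects (%s); ROIs: %s\n", length(x),
              paste(sprintf("%s n=%d", names(table(groups)), table(groups)),
                    collapse = ", "),
              paste(names(x[[1]]$patterns), collapse = ", ")))
  invisible(x)
}
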