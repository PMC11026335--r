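# Single-trial estimation: BOLD simulation and least-squares-separate GLMs.

#' Canonical double-gamma HRF kernel
#'
#' Difference of two gamma densities (peak ~5 s, undershoot ~15 s,
#' SPM-style shape parameters), sampled every `tr` seconds from 0 to
#' `duration` and scaled to unit peak. The value at t = 0 is 0.
#'
#' @param tr sampling interval in seconds (> 0).
#' @param duration kernel support in seconds.
#' @return numeric vector of `ceiling(duration / tr) + 1` amplitudes.
#' @export
hrf_kernel <- function(tr, duration = 32) {
  if (tr <= 0) stop_data("tr must be > 0")
  t <- (0:ceiling(duration / tr)) * tr
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Discrete cosine high-pass drift basis: columns with period > cutoff
# seconds are omitted, so the retained columns model slow drift only.
cosine_drift <- function(n, tr, cutoff = 128) {
  K <- floor(2 * n * tr / cutoff)
  if (K < 1L) return(NULL)
  t <- seq_len(n) - 0.5
  B <- sapply(seq_len(K), function(k) cos(pi * k * t / n))
  B <- matrix(B, nrow = n)
  colnames(B) <- paste0("drift", seq_len(K))
  B
}

#' Bundle nuisance regressors with labels
#'
#' @param mat matrix (timepoints x k) of nuisance regressors.
#' @param labels column labels; defaults to the conventional 6 head-motion
#'   (3 displacement + 3 rotation) and 3 compartment-intensity (global,
#'   white matter, CSF) names when `k = 9`.
#' @return object of class `nuisance_set`.
#' @export
nuisance_set <- function(mat, labels = NULL) {
  mat <- as.matrix(mat)
  if (is.null(labels)) {
    labels <- if (ncol(mat) == 9L)
      c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
        "global", "white_matter", "csf")
    else paste0("nuisance", seq_len(ncol(mat)))
  }
  if (length(labels) != ncol(mat))
    stop_data("label count (", length(labels),
              ") does not match column count (", ncol(mat), ")")
  colnames(mat) <- labels
  structure(list(mat = mat, labels = labels), class = "nuisance_set")
}

#' Simulate a nuisance regressor table
#'
#' Smooth random walks for the six motion parameters and slowly varying
#' autoregressive traces for the three compartment intensities; a stand-in
#' for the precomputed nuisance tables a real-data analysis would load.
#'
#' @param n_timepoints rows to generate.
#' @param seed RNG seed.
#' @return a `nuisance_set` with 9 columns.
#' @export
simulate_nuisance <- function(n_timepoints, seed = NULL) {
  with_seed(seed, {
    motion <- sapply(1:6, function(i) cumsum(rnorm(n_timepoints, sd = 0.01)))
    compart <- sapply(1:3, function(i) {
      x <- numeric(n_timepoints)
      for (t in 2:n_timepoints) x[t] <- 0.98 * x[t - 1] + rnorm(1, sd = 0.05)
      x
    })
    nuisance_set(cbind(motion, compart))
  })
}

# HRF-convolved regressor for each trial of one run, sampled at the TR
# grid. Built on a fine time grid (dt seconds) and linearly interpolated to
# the scan times, so a TR that does not divide the design resolution is
# resampled rather than truncated.
trial_regressors <- function(onsets, stim_dur, n_t, tr, dt = 0.1) {
  dur <- n_t * tr
  fine_t <- seq(0, dur, by = dt)
  h <- hrf_kernel(dt)
  scan_t <- (seq_len(n_t) - 1L) * tr
  R <- matrix(0, n_t, length(onsets))
  for (k in seq_along(onsets)) {
    box <- as.numeric(fine_t >= onsets[k] & fine_t < onsets[k] + stim_dur)
    conv <- stats::convolve(box, rev(h), type = "open")[seq_along(fine_t)]
    R[, k] <- approx(fine_t, conv, xout = scan_t, rule = 2)$y
  }
  R
}

#' Simulate BOLD runs from a schedule and trial response amplitudes
#'
#' Each voxel's time series is the sum over trials of that trial's beta
#' times an HRF-convolved boxcar, plus low-frequency cosine drift with
#' Gaussian random coefficients and white Gaussian noise.
#'
#' @param schedule a `trial_table`.
#' @param patterns a `subject_patterns` aligned row-by-row with `schedule`
#'   (its `X` provides the generating betas).
#' @param tr repetition time in seconds.
#' @param drift_amp standard deviation of the drift-coefficient draws
#'   (0 disables drift).
#' @param noise_sd scanner noise standard deviation.
#' @param seed RNG seed.
#' @param dt design resolution in seconds for the convolution grid.
#' @return list of `bold_run` objects (`Y` timepoints x voxels, `tr`,
#'   `run`), one per run, in run order.
#' @export
simulate_bold <- function(schedule, patterns, tr = 0.8, drift_amp = 0,
                          noise_sd = 0, seed = NULL, dt = 0.1) {
  validate_trial_table(schedule)
  if (nrow(patterns$X) != nrow(schedule))
    stop_data("patterns (", nrow(patterns$X), " rows) not aligned to schedule (",
              nrow(schedule), " trials)")
  if (tr <= 0) stop_data("tr must be > 0")
  stim_dur <- attr(schedule, "stim_dur")
  runs <- sort(unique(schedule$run))
  with_seed(seed, lapply(runs, function(r) {
    sel <- schedule$run == r
    n_t <- ceiling(run_duration(schedule, r) / tr)
    R <- trial_regressors(schedule$onset[sel], stim_dur, n_t, tr, dt)
    Y <- R %*% patterns$X[sel, , drop = FALSE]
    if (drift_amp > 0) {
      B <- cosine_drift(n_t, tr)
      if (!is.null(B))
        Y <- Y + B %*% matrix(rnorm(ncol(B) * ncol(Y), sd = drift_amp),
                              ncol(B), ncol(Y))
    }
    if (noise_sd > 0)
      Y <- Y + matrix(rnorm(length(Y), sd = noise_sd), nrow(Y), ncol(Y))
    structure(list(Y = Y, tr = tr, run = r), class = "bold_run")
  }))
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("BOLD run %s: %d timepoints x %d voxels, TR = %gs\n",
              x$run, nrow(x$Y), ncol(x$Y), x$tr))
  invisible(x)
}

#' Least-squares-separate single-trial beta estimation
#'
#' Fits one GLM per trial. Each design contains the target trial's own
#' HRF-convolved regressor, one regressor per room built from all of that
#' room's onsets with the target trial removed from its room's regressor
#' (otherwise the design would be exactly collinear), the nuisance columns,
#' a cosine high-pass drift basis, and an intercept. The target
#' regressor's coefficient becomes the trial's beta estimate per voxel.
#'
#' @param bold list of `bold_run` objects, as from [simulate_bold()].
#' @param schedule the matching `trial_table`.
#' @param nuisance optional `nuisance_set` (shared across runs) or list of
#'   one per run.
#' @param hp_cutoff high-pass cutoff in seconds for the drift basis;
#'   `NULL` disables drift columns.
#' @param dt design resolution for the convolution grid.
#' @param subject,roi labels stored on the result.
#' @return a `subject_patterns` whose `X` holds the estimated betas
#'   (trials x voxels, schedule order).
#' @export
fit_lss <- function(bold, schedule, nuisance = NULL, hp_cutoff = 128,
                    dt = 0.1, subject = "s01", roi = "V1") {
  validate_trial_table(schedule)
  runs <- sort(unique(schedule$run))
  if (length(bold) != length(runs))
    stop_data("got ", length(bold), " BOLD runs for ", length(runs),
              " scheduled runs")
  stim_dur <- attr(schedule, "stim_dur")
  rooms <- sort(unique(schedule$room))
  B <- matrix(NA_real_, nrow(schedule), ncol(bold[[1]]$Y))
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    sel <- which(schedule$run == r)
    Y <- bold[[ri]]$Y
    n_t <- nrow(Y)
    tr <- bold[[ri]]$tr
    if (max(schedule$onset[sel]) + stim_dur > n_t * tr)
      stop_data("run ", r, ": onsets extend beyond the BOLD run")
    R <- trial_regressors(schedule$onset[sel], stim_dur, n_t, tr, dt)
    room_reg <- sapply(rooms, function(rm)
      rowSums(R[, schedule$room[sel] == rm, drop = FALSE]))
    nmat <- if (is.null(nuisance)) NULL
            else if (inherits(nuisance, "nuisance_set")) nuisance$mat
            else nuisance[[ri]]$mat
    if (!is.null(nmat) && nrow(nmat) != n_t)
      stop_data("nuisance rows (", nrow(nmat), ") do not match run ", r,
                " timepoints (", n_t, ")")
    drift <- if (is.null(hp_cutoff)) NULL else cosine_drift(n_t, tr, hp_cutoff)
    for (k in seq_along(sel)) {
      rm_k <- schedule$room[sel][k]
      others <- room_reg
      others[, rm_k] <- others[, rm_k] - R[, k]
      keep <- colSums(abs(others)) > 1e-10
      X <- cbind(target = R[, k], others[, keep, drop = FALSE], nmat, drift,
                 intercept = 1)
      q <- qr(X)
      if (q$rank < ncol(X)) {
        bad <- colnames(X)[q$pivot[seq(q$rank + 1L, ncol(X))]]
        stop_data("rank-deficient LSS design in run ", r, ", trial ", k,
                  "; collinear column(s): ", paste(bad, collapse = ", "))
      }
      B[sel[k], ] <- qr.coef(q, Y)[1L, ]
    }
  }
  structure(list(X = B, trials = schedule, subject = subject, group = NA,
                 roi = roi, truth = NULL),
            class = "subject_patterns")
}
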