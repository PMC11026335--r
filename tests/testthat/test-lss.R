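test_that("HRF kernel has the canonical double-gamma shape", {
  h <- hrf_kernel(0.8, 32)
  expect_length(h, ceiling(32 / 0.8) + 1)
  t <- (seq_along(h) - 1) * 0.8
  peak_t <- t[which.max(h)]
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 6)
  expect_equal(h[1], 0)
  expect_gt(sum(h), 0)
  h2 <- hrf_kernel(0.5, 32) # grid hits t = 30 exactly
  expect_lt(abs(h2[61]), 0.01 * max(h2))
  expect_error(hrf_kernel(0), "tr")
})

test_that("simulated BOLD has the right length and reduces to a scaled HRF", {
  stim <- make_stimulus_set(seed = 1)
  sched <- make_occlusion_schedule(stim, seed = 2)
  truth <- group_params("g", n_voxels = 2, w_ctx = 1, noise_sd = 0)
  sp <- simulate_subject_patterns(truth, sched, seed = 3)
  bold <- simulate_bold(sched, sp, tr = 0.8)
  expect_length(bold, 4L)
  expect_equal(nrow(bold[[1]]$Y), ceiling(576 / 0.8)) # 720
  # single noiseless trial: the time series is a scaled HRF
  one <- sched[1:1, ]
  attr(one, "stim_dur") <- attr(sched, "stim_dur")
  attr(one, "iti") <- attr(sched, "iti")
  class(one) <- class(sched)
  b1 <- simulate_bold(one,
                      structure(list(X = matrix(1, 1, 1)),
                                class = "subject_patterns"), tr = 0.8)
  b2 <- simulate_bold(one,
                      structure(list(X = matrix(2, 1, 1)),
                                class = "subject_patterns"), tr = 0.8)
  expect_gt(max(b1[[1]]$Y), 0)
  # linear in the generating beta
  expect_equal(b2[[1]]$Y, 2 * b1[[1]]$Y, tolerance = 1e-12)
})

test_that("zero betas give zero BOLD; noise and drift enter additively", {
  stim <- make_stimulus_set(seed = 4)
  sched <- make_occlusion_schedule(stim, n_runs = 1, reps = 1, seed = 5)
  zero <- structure(list(X = matrix(0, 16, 3)), class = "subject_patterns")
  clean <- simulate_bold(sched, zero, tr = 0.8)
  expect_equal(max(abs(clean[[1]]$Y)), 0)
  noisy <- simulate_bold(sched, zero, tr = 0.8, noise_sd = 1,
                         drift_amp = 0.5, seed = 6)
  expect_gt(sd(noisy[[1]]$Y), 0)
})

test_that("LSS recovers noiseless generating betas to 1e-6", {
  stim <- make_stimulus_set(seed = 7)
  sched <- make_occlusion_schedule(stim, n_runs = 2, reps = 2, seed = 8)
  truth <- group_params("g", n_voxels = 3, w_ctx = 1, w_mne_epi = 0.5,
                        w_mne_sem = 0.5, noise_sd = 0)
  sp <- simulate_subject_patterns(truth, sched, seed = 9)
  bold <- simulate_bold(sched, sp, tr = 0.8)
  est <- fit_lss(bold, sched)
  expect_equal(nrow(est$X), nrow(sched)) # one GLM per trial
  expect_lt(max(abs(est$X - sp$X)), 1e-6)
})

test_that("LSS round-trip correlation survives realistic noise", {
  # 10% noise relative to unit signal amplitudes, averaged over seeds
  cors <- numeric(10)
  for (s in 1:10) {
    stim <- make_stimulus_set(seed = 40 + s)
    sched <- make_occlusion_schedule(stim, n_runs = 1, reps = 1,
                                     seed = 50 + s)
    truth <- group_params("g", n_voxels = 4, w_ctx = 1, w_mne_epi = 0.5,
                          w_mne_sem = 0.5, noise_sd = 0)
    sp <- simulate_subject_patterns(truth, sched, seed = 60 + s)
    bold <- simulate_bold(sched, sp, tr = 0.8, noise_sd = 0.1,
                          seed = 70 + s)
    est <- fit_lss(bold, sched)
    cors[s] <- cor(as.vector(est$X), as.vector(sp$X))
  }
  expect_gt(mean(cors), 0.95)
})

test_that("LSS estimates are invariant to nuisance-regressor scaling", {
  stim <- make_stimulus_set(seed = 10)
  sched <- make_occlusion_schedule(stim, n_runs = 1, reps = 1, seed = 11)
  truth <- group_params("g", n_voxels = 2, w_ctx = 1, noise_sd = 0)
  sp <- simulate_subject_patterns(truth, sched, seed = 12)
  bold <- simulate_bold(sched, sp, tr = 0.8, noise_sd = 0.05, seed = 13)
  nui <- simulate_nuisance(nrow(bold[[1]]$Y), seed = 14)
  est1 <- fit_lss(bold, sched, nuisance = nui)
  scaled <- nuisance_set(nui$mat * 10, nui$labels)
  est2 <- fit_lss(bold, sched, nuisance = scaled)
  expect_equal(est1$X, est2$X, tolerance = 1e-8)
})

test_that("rank-deficient designs name the collinear columns", {
  stim <- make_stimulus_set(seed = 15)
  sched <- make_occlusion_schedule(stim, n_runs = 1, reps = 1, seed = 16)
  truth <- group_params("g", n_voxels = 2, w_ctx = 1, noise_sd = 0)
  sp <- simulate_subject_patterns(truth, sched, seed = 17)
  bold <- simulate_bold(sched, sp, tr = 0.8)
  bad <- nuisance_set(matrix(1, nrow(bold[[1]]$Y), 1), "constant_col")
  expect_error(fit_lss(bold, sched, nuisance = bad),
               "collinear column")
})

test_that("nuisance sets validate their shape", {
  expect_error(nuisance_set(matrix(0, 5, 2), c("a", "b", "c")),
               "label count")
  nui <- simulate_nuisance(100, seed = 1)
  expect_equal(ncol(nui$mat), 9L)
  expect_equal(nui$labels[1], "trans_x")
})
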