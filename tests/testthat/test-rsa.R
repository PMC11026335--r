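test_that("crossnobis with identity covariance reduces to cross-validated
           Euclidean on noiseless data", {
  stim <- make_stimulus_set(seed = 1)
  sched <- make_occlusion_schedule(stim, n_runs = 2, reps = 1, seed = 2)
  truth <- group_params("g", n_voxels = 12, w_ctx = 1.3, w_mne_epi = 0.4,
                        w_mne_sem = 0.4, noise_sd = 0)
  sp <- simulate_subject_patterns(truth, sched, seed = 3)
  r <- crossnobis_rdm(sp, noise_cov = "identity", mode = "condition")
  # true per-room patterns (any occurrence; noiseless)
  pat <- sp$X[match(r$labels$room, sched$room), , drop = FALSE]
  expected <- as.matrix(dist(pat))^2 / ncol(sp$X)
  expect_equal(r$D, expected, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(r$D, t(r$D))
  expect_equal(diag(r$D), rep(0, 16))
})

test_that("crossnobis is unbiased under pure noise and admits negatives", {
  meanv <- numeric(200)
  negs <- 0
  for (s in 1:200) {
    fx <- quick_subject(seed = 300 + s, n_voxels = 8, n_runs = 3, reps = 2)
    r <- crossnobis_rdm(fx$patterns, noise_cov = "diag", mode = "condition")
    off <- r$D[upper.tri(r$D)]
    meanv[s] <- mean(off)
    negs <- negs + sum(off < 0)
  }
  se <- sd(meanv) / sqrt(length(meanv))
  expect_lt(abs(mean(meanv)), 3 * se)
  expect_gt(negs, 0)
})

test_that("shrinkage covariance handles more voxels than residual dof", {
  fx <- quick_subject(seed = 13, n_voxels = 60, n_runs = 2, reps = 2)
  r <- crossnobis_rdm(fx$patterns, noise_cov = "shrinkage")
  expect_true(all(is.finite(r$D)))
  lam <- shrinkage_cov(matrix(rnorm(40), 10, 4))
  expect_true(lam$lambda >= 0 && lam$lambda <= 1)
  expect_equal(lam$sigma, t(lam$sigma))
})

test_that("trial-mode crossnobis expands condition distances to 96 trials", {
  fx <- quick_subject(seed = 14, w_ctx = 0.5, n_voxels = 10, reps = 6,
                      n_runs = 4)
  rt <- crossnobis_rdm(fx$patterns, mode = "trial")
  rc <- crossnobis_rdm(fx$patterns, mode = "condition")
  expect_equal(dim(rt$D), c(96L, 96L))
  i <- match(rt$labels$room[5], rc$labels$room)
  j <- match(rt$labels$room[80], rc$labels$room)
  expect_equal(rt$D[5, 80], rc$D[i, j])
})

test_that("pearson RDM matches hand-computed correlation distances", {
  X <- rbind(c(1, 2, 3, 4),
             c(2, 4, 6, 8),
             c(4, 3, 2, 1),
             c(1, 3, 2, 4))
  tt <- data.frame(run = 1L, trial_index = 1:4, onset = 0:3,
                   room = paste0("r", 1:4), object = "o",
                   trial_type = "episodic", phase = "sensory")
  sp <- structure(list(X = X, trials = tt, subject = "s", group = "g",
                       roi = "V1"), class = "subject_patterns")
  r <- pearson_rdm(sp)
  expect_equal(r$D[1, 2], 0)          # perfectly correlated rows
  expect_equal(r$D[1, 3], 2)          # exact negation
  expect_equal(r$D[1, 4], 0.2)        # hand-computed 1 - 0.8
  expect_equal(diag(r$D), rep(0, 4))
  sp$X[2, ] <- 5
  expect_error(pearson_rdm(sp), "trial")
})

test_that("model RDMs encode the ideal dissimilarity patterns", {
  fx <- quick_subject(seed = 15, reps = 6, n_runs = 4, n_voxels = 4)
  r <- crossnobis_rdm(fx$patterns, noise_cov = "identity", mode = "trial")
  expect_equal(nrow(r$D), 96L) # full design span per run
  lab <- r$labels
  ctx <- build_model_rdm(lab, "contextual", "episodic")
  mne <- build_model_rdm(lab, "mnemonic", "episodic")
  same_room <- outer(lab$room, lab$room, "==")
  same_obj <- outer(lab$object, lab$object, "==")
  epi <- lab$trial_type == "episodic"
  both_epi <- outer(epi, epi, "&")
  # contextual: 0 exactly for same-object-same-room cells
  expect_true(all(ctx$M[same_room & same_obj] == 0))
  expect_true(all(ctx$M[!same_room] == 1))
  expect_false(any(ctx$include & !both_epi))
  expect_false(any(diag(ctx$include)))
  # mnemonic: 0 for same-object-different-room, 1 for different object,
  # same-room cells excluded
  expect_true(all(mne$M[same_obj & !same_room] == 0))
  expect_true(all(mne$M[!same_obj] == 1))
  expect_false(any(mne$include[same_room & same_obj]))
})

test_that("mnemonic exclusion count follows the repetition combinatorics", {
  fx <- quick_subject(seed = 16, reps = 2, n_runs = 2, n_voxels = 4)
  r <- crossnobis_rdm(fx$patterns, noise_cov = "identity", mode = "trial")
  mne <- build_model_rdm(r$labels, "mnemonic", "all")
  ctx <- build_model_rdm(r$labels, "contextual", "all")
  # per room with `reps` trials, reps*(reps-1) ordered same-room off-diagonal
  # cells are excluded on top of the diagonal
  reps <- 2L
  expected_excluded <- 16L * reps * (reps - 1L)
  expect_equal(sum(ctx$include) - sum(mne$include), expected_excluded)
})

test_that("fit_model recovers perfect, inverted and tied orderings", {
  lab <- data.frame(room = c("r1", "r1", "r2", "r3"),
                    object = c("a", "a", "a", "b"),
                    trial_type = "episodic")
  m <- build_model_rdm(lab, "contextual", "all")
  neural <- manual_rdm(m$M, lab)
  expect_equal(fit_model(neural, m)$rho, 1)
  expect_true(is.finite(fit_model(neural, m)$z))
  flipped <- manual_rdm(1 - m$M, lab)
  expect_equal(fit_model(flipped, m)$rho, -1)
  # monotone transform invariance (Spearman property)
  fx <- quick_subject(seed = 17, w_ctx = 0.6, n_voxels = 10)
  r <- crossnobis_rdm(fx$patterns, mode = "trial")
  mm <- build_model_rdm(r$labels, "contextual", "episodic")
  cubed <- manual_rdm(r$D^3, r$labels)
  expect_equal(fit_model(r, mm)$rho, fit_model(cubed, mm)$rho)
})

test_that("fit_model's rho matches a hand-ranked oracle under ties", {
  lab <- data.frame(room = paste0("r", 1:4), object = c("a", "a", "b", "b"),
                    trial_type = "episodic")
  D <- matrix(0, 4, 4)
  vals <- c(0.3, 1.0, 1.0, 0.8, 1.2, 0.3) # upper triangle, with ties
  D[upper.tri(D)] <- vals
  D <- D + t(D)
  m <- build_model_rdm(lab, "mnemonic", "all")
  got <- fit_model(manual_rdm(D, lab), m)$rho
  sel <- m$include & upper.tri(D)
  oracle <- cor(rank(D[sel]), rank(m$M[sel]))
  expect_equal(got, oracle)
})

test_that("rdm orderings and dimensions are enforced", {
  fx <- quick_subject(seed = 18, n_voxels = 6)
  r <- crossnobis_rdm(fx$patterns, mode = "condition")
  m <- build_model_rdm(r$labels[16:1, ], "contextual", "all")
  expect_error(fit_model(r, m), "orderings")
  single <- r
  expect_error(crossnobis_rdm(
    structure(list(X = fx$patterns$X[fx$patterns$trials$run == 1, ],
                   trials = fx$patterns$trials[fx$patterns$trials$run == 1, ]),
              class = "subject_patterns")), "2 runs")
})
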