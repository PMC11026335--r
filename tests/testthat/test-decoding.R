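test_that("contextual scheme: 4 problems, shared object, identical cells", {
  stim <- make_stimulus_set(seed = 1)
  for (tt in c("episodic", "semantic")) {
    sch <- build_contextual_scheme(stim, tt)
    expect_length(sch, 4L)
    for (s in sch) {
      expect_identical(s$train_cells, s$test_cells)
      expect_length(unique(s$train_cells$object), 1L)
      expect_length(unique(s$train_cells$room), 2L)
    }
    expect_setequal(vapply(sch, function(s) s$train_cells$object[1], ""),
                    stim$objects)
  }
})

test_that("mnemonic scheme: 12 problems with disjoint rooms, shared objects", {
  stim <- make_stimulus_set(seed = 2)
  sch <- build_mnemonic_scheme(stim, "episodic")
  # C(4,2) object pairs x 2 room assignments
  expect_length(sch, choose(4, 2) * 2)
  for (s in sch) {
    expect_length(intersect(s$train_cells$room, s$test_cells$room), 0L)
    expect_setequal(s$train_cells$object, s$test_cells$object)
    expect_length(unique(s$train_cells$object), 2L)
    # train cells differ in both object and room
    expect_false(any(duplicated(s$train_cells$room)))
  }
})

test_that("scheme builders reject malformed stimulus sets", {
  stim <- make_stimulus_set(seed = 3)
  broken <- stim
  # reassign one episodic room to a different object, breaking the
  # two-rooms-per-object balance
  j <- which(broken$episodic_pairs != broken$episodic_pairs[1])[1]
  broken$episodic_pairs[1] <- broken$episodic_pairs[j]
  expect_error(build_contextual_scheme(broken, "episodic"), "exactly 2")
  expect_error(build_mnemonic_scheme(broken, "episodic"), "exactly 2")
})

test_that("LORO-CV has one fold per run and is perfect when separable", {
  fx <- quick_subject(seed = 5, w_ctx = 3, noise_sd = 0.01)
  sch <- build_contextual_scheme(fx$stim, "episodic")
  res <- run_loro_cv(fx$patterns, sch[[1]])
  expect_length(res$fold_accuracy, 4L)
  expect_equal(res$mean_accuracy, 1)
  expect_equal(mean(res$fold_accuracy), res$mean_accuracy)
  expect_true(all(res$n_test > 0))
})

test_that("LORO-CV accuracy is invariant to run relabeling", {
  fx <- quick_subject(seed = 6, w_ctx = 0.8)
  sch <- build_contextual_scheme(fx$stim, "episodic")[[2]]
  base <- run_loro_cv(fx$patterns, sch)
  relab <- fx$patterns
  relab$trials$run <- c(3L, 1L, 4L, 2L)[relab$trials$run]
  perm <- run_loro_cv(relab, sch)
  expect_equal(sort(perm$fold_accuracy), sort(base$fold_accuracy))
  expect_equal(perm$mean_accuracy, base$mean_accuracy)
})

test_that("compiled solver agrees with libsvm on the same problems", {
  accs <- matrix(0, 6, 2)
  for (s in 1:6) {
    fx <- quick_subject(seed = 20 + s, w_ctx = 0.7, n_voxels = 24)
    sch <- build_contextual_scheme(fx$stim, "episodic")
    accs[s, 1] <- decode_subject(fx$patterns, sch, engine = "dualcd")$accuracy
    accs[s, 2] <- decode_subject(fx$patterns, sch, engine = "libsvm")$accuracy
  }
  expect_lt(mean(abs(accs[, 1] - accs[, 2])), 0.05)
  expect_gt(cor(accs[, 1], accs[, 2]), 0.8)
})

test_that("label permutation brings accuracy to chance", {
  fx <- quick_subject(seed = 7, w_ctx = 1.5, noise_sd = 0.5)
  sch <- build_contextual_scheme(fx$stim, "episodic")
  obs <- decode_subject(fx$patterns, sch)$accuracy
  nulls <- permutation_null(fx$patterns, sch, n_perm = 40, seed = 8)
  expect_length(nulls, 40L)
  expect_gt(obs, max(nulls)) # strong signal beats every permutation
  expect_lt(abs(mean(nulls) - 0.5), 0.05)
  expect_identical(nulls,
                   permutation_null(fx$patterns, sch, n_perm = 40, seed = 8))
})

test_that("permutation fast path matches the generic path's distribution", {
  fx <- quick_subject(seed = 9, w_ctx = 0.5)
  sch <- build_contextual_scheme(fx$stim, "episodic")
  fast <- permutation_null(fx$patterns, sch, n_perm = 12, seed = 10)
  slow <- permutation_null(fx$patterns, sch, n_perm = 12, seed = 10,
                           engine = "libsvm")
  # identical permutations, near-identical classifiers
  expect_lt(mean(abs(fast - slow)), 0.03)
})

test_that("group bootstrap test behaves at its edges", {
  nulls <- replicate(5, runif(20, 0.4, 0.6), simplify = FALSE)
  bt <- group_bootstrap_test(nulls, observed = 0.7, n_boot = 200, seed = 1)
  expect_length(bt$null, 200L)
  expect_equal(bt$p, 0)
  expect_true(bt$significant)
  flat <- replicate(4, rep(0.5, 10), simplify = FALSE)
  bt2 <- group_bootstrap_test(flat, observed = 0.5, n_boot = 100, seed = 2)
  expect_equal(bt2$p, 1)
  expect_false(bt2$significant)
  expect_error(group_bootstrap_test(list(), 0.5), "empty")
  expect_identical(group_bootstrap_test(nulls, 0.55, n_boot = 50, seed = 3),
                   group_bootstrap_test(nulls, 0.55, n_boot = 50, seed = 3))
})

test_that("missing classes in a fold raise a named error", {
  fx <- quick_subject(seed = 11, w_ctx = 0.5)
  sch <- build_contextual_scheme(fx$stim, "episodic")[[1]]
  # remove all run-2 trials of the first training room
  keep <- !(fx$patterns$trials$run == 2 &
              fx$patterns$trials$room == sch$train_cells$room[1])
  crippled <- fx$patterns
  crippled$X <- crippled$X[keep, , drop = FALSE]
  crippled$trials <- crippled$trials[keep, ]
  expect_error(run_loro_cv(crippled, sch), "empty test class")
})
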