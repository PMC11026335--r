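make_di_rdm <- function(vals, objects, rooms,
                        trial_type = rep("episodic", length(objects))) {
  # vals ordered row-wise: (1,2), (1,3), ..., (2,3), ... pairs
  n <- length(objects)
  Dt <- matrix(0, n, n)
  Dt[lower.tri(Dt)] <- vals
  D <- t(Dt) + Dt
  manual_rdm(D, data.frame(room = rooms, object = objects,
                           trial_type = trial_type))
}

test_that("differentiation index reproduces hand arithmetic", {
  # two objects, two rooms each; within = {0.2, 0.4}, between =
  # {1.0, 1.2, 0.8, 1.0} -> di = 1.0 - 0.3 = 0.7
  rdm <- make_di_rdm(c(0.2, 1.0, 1.2, 0.8, 1.0, 0.4),
                     objects = c("a", "a", "b", "b"),
                     rooms = c("r1", "r2", "r3", "r4"))
  expect_equal(differentiation_index(rdm), 0.7)
  # all dissimilarities equal -> di = 0
  flat <- make_di_rdm(rep(0.5, 6), c("a", "a", "b", "b"),
                      c("r1", "r2", "r3", "r4"))
  expect_equal(differentiation_index(flat), 0)
})

test_that("pair policy controls same-room within pairs", {
  # within pairs: (1,2) diff rooms d=0.2, (1,3) same room d=0,
  # (2,3) diff rooms d=0.4; between pairs all 1.0
  rdm <- make_di_rdm(c(0.2, 0, 1.0, 0.4, 1.0, 1.0),
                     objects = c("a", "a", "a", "b"),
                     rooms = c("r1", "r2", "r1", "r3"))
  expect_equal(differentiation_index(rdm, pair_policy = "different_room"),
               1.0 - mean(c(0.2, 0.4)))
  expect_equal(differentiation_index(rdm, pair_policy = "all"),
               1.0 - mean(c(0.2, 0, 0.4)))
  lone <- make_di_rdm(rep(1, 6), c("a", "a", "a", "a"),
                      c("r1", "r2", "r3", "r4"))
  expect_error(differentiation_index(lone), "empty within or between")
})

test_that("di is antisymmetric under swapping within and between sets", {
  rdm <- make_di_rdm(c(0.2, 1.0, 1.2, 0.8, 1.0, 0.4),
                     objects = c("a", "a", "b", "b"),
                     rooms = c("r1", "r2", "r3", "r4"))
  # relabeling objects so that the former within pairs become between pairs
  # and vice versa flips the sign
  swapped <- rdm
  swapped$labels$object <- c("a", "b", "a", "b")
  swapped$labels$room <- c("r1", "r2", "r3", "r4")
  d1 <- differentiation_index(rdm)
  within1 <- c(0.2, 0.4); between1 <- c(1.0, 1.2, 0.8, 1.0)
  expect_equal(d1, mean(between1) - mean(within1))
  expect_equal(mean(within1) - mean(between1), -d1)
  # with labels (a, b, a, b): within = {(1,3) = 1.0, (2,4) = 1.0},
  # between = {(1,2) = 0.2, (1,4) = 1.2, (2,3) = 0.8, (3,4) = 0.4}
  d2 <- differentiation_index(swapped)
  expect_equal(d2, mean(c(0.2, 1.2, 0.8, 0.4)) - mean(c(1.0, 1.0)))
})

test_that("di_records yields per-type feedback and pooled feedforward rows", {
  fx <- quick_subject(seed = 30, w_ctx = 0.5, w_mne = 0.4, n_voxels = 12)
  sen <- quick_subject(seed = 31, w_ff = 0.8, phase = "sensory",
                       n_voxels = 12)
  fb <- crossnobis_rdm(fx$patterns, mode = "trial")
  ff <- pearson_rdm(sen$patterns)
  rec <- di_records(fb, ff, subject = "s1", group = "g", roi = "V1")
  expect_setequal(rec$trial_type[rec$pathway == "feedback"],
                  c("episodic", "semantic"))
  expect_true("all" %in% rec$trial_type[rec$pathway == "feedforward"])
  expect_equal(sum(rec$pathway == "feedforward" & rec$trial_type == "all"),
               1L)
})

test_that("z-scoring flags exactly the planted outlier", {
  set.seed(12)
  rec <- data.frame(subject = sprintf("s%03d", 1:101), group = "g",
                    roi = "V1", pathway = "feedback",
                    trial_type = "episodic", di = c(rnorm(100), 10))
  out <- zscore_and_flag_outliers(rec)
  expect_equal(sum(out$outlier), 1L)
  expect_true(out$outlier[101])
  expect_equal(mean(out$z_di), 0, tolerance = 1e-12)
  # identical values: all z = 0, nothing flagged
  flat <- rec; flat$di <- 1
  outf <- zscore_and_flag_outliers(flat)
  expect_true(all(outf$z_di == 0))
  expect_false(any(outf$outlier))
})

test_that("the 3.29 SD rule marks the most extreme 0.1% of a normal", {
  tail_prob <- 2 * (1 - pnorm(3.29))
  expect_equal(signif(tail_prob, 2), 0.001)
})

test_that("ff-fb correlation recovers monotone coupling and excludes outliers", {
  n <- 12
  set.seed(13)
  ff_di <- sort(rnorm(n))
  mk <- function(pathway, tt, di) data.frame(
    subject = sprintf("s%02d", 1:n), group = "g", roi = "V1",
    pathway = pathway, trial_type = tt, di = di, z_di = scale(di)[, 1],
    outlier = FALSE)
  ff <- mk("feedforward", "all", ff_di)
  fb <- rbind(mk("feedback", "episodic", exp(ff_di)),
              mk("feedback", "semantic", rnorm(n)))
  res <- ff_fb_correlation(ff, fb)
  expect_equal(nrow(res), 2L)
  epi <- res[res$trial_type == "episodic", ]
  expect_equal(epi$rho, 1)
  expect_true(all(res$p_adj >= res$p))
  # flagged subjects drop out of the pairing
  ff2 <- ff; ff2$outlier[1] <- TRUE
  res2 <- ff_fb_correlation(ff2, fb)
  expect_equal(unique(res2$n), n - 1L)
  # independent pathways: rho centred on zero over repetitions
  set.seed(14)
  rhos <- replicate(200, {
    fbr <- mk("feedback", "episodic", rnorm(n))
    ff_fb_correlation(ff, fbr)$rho
  })
  se <- sd(rhos) / sqrt(length(rhos))
  expect_lt(abs(mean(rhos)), 3 * se)
})
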