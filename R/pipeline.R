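# Pipeline orchestration: validated configuration, staged execution,
# tidy result tables and a reproducibility manifest.

#' Build and validate a pipeline configuration
#'
#' All stages of [run_pipeline()] read their settings from this object.
#' Unknown arguments are rejected rather than silently ignored.
#'
#' @param groups named list of `ground_truth_params`
#'   (default [default_group_params()]).
#' @param n_per_group subjects per group.
#' @param rois ROI labels to simulate and analyse.
#' @param n_runs,reps,sensory_reps schedule layout, see
#'   [make_occlusion_schedule()] / [make_sensory_schedule()].
#' @param estimation `"direct"` uses the simulated patterns as single-trial
#'   betas; `"bold_lss"` additionally simulates BOLD runs and re-estimates
#'   betas with [fit_lss()].
#' @param bold_noise_sd,bold_drift_amp,tr BOLD simulation settings (only
#'   used for `estimation = "bold_lss"`).
#' @param n_perm permutations per subject for the decoding null.
#' @param n_boot bootstrap iterations for the group test.
#' @param boot_prob significance quantile of the bootstrap null.
#' @param cost,zscore,engine classifier settings, see [run_loro_cv()].
#' @param noise_cov,rdm_mode crossnobis settings, see [crossnobis_rdm()].
#' @param pair_policy,outlier_threshold differentiation settings, see
#'   [differentiation_index()] and [zscore_and_flag_outliers()].
#' @param seed master seed; every stage and subject derives its own stream
#'   from it.
#' @param output_dir directory for CSV tables and the JSON manifest, or
#'   `NULL` to keep results in memory only.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(groups = default_group_params(),
                            n_per_group = 10L, rois = c("V1", "V2"),
                            n_runs = 4L, reps = 6L, sensory_reps = 12L,
                            estimation = c("direct", "bold_lss"),
                            bold_noise_sd = 0.5, bold_drift_amp = 0,
                            tr = 0.8, n_perm = 100L, n_boot = 1000L,
                            boot_prob = 0.999, cost = 1, zscore = FALSE,
                            engine = c("dualcd", "libsvm"),
                            noise_cov = c("shrinkage", "diag", "identity"),
                            rdm_mode = c("trial", "condition"),
                            pair_policy = c("different_room", "all"),
                            outlier_threshold = 3.29, seed = 1L,
                            output_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop_data("unknown configuration key(s): ",
              paste(names(extra), collapse = ", "))
  estimation <- match.arg(estimation)
  engine <- match.arg(engine)
  noise_cov <- match.arg(noise_cov)
  rdm_mode <- match.arg(rdm_mode)
  pair_policy <- match.arg(pair_policy)
  if (!length(groups) || is.null(names(groups)))
    stop_data("groups must be a named list")
  for (g in groups)
    if (!inherits(g, "ground_truth_params"))
      stop_data("every group entry must be a ground_truth_params")
  if (n_per_group < 1L) stop_data("n_per_group must be >= 1")
  if (n_runs < 2L) stop_data("n_runs must be >= 2 (leave-one-run-out)")
  if (n_perm < 1L) stop_data("n_perm must be >= 1")
  if (n_boot < 1L) stop_data("n_boot must be >= 1")
  if (outlier_threshold <= 0) stop_data("outlier_threshold must be > 0")
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 rois = rois, n_runs = as.integer(n_runs),
                 reps = as.integer(reps),
                 sensory_reps = as.integer(sensory_reps),
                 estimation = estimation, bold_noise_sd = bold_noise_sd,
                 bold_drift_amp = bold_drift_amp, tr = tr,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 boot_prob = boot_prob, cost = cost, zscore = zscore,
                 engine = engine, noise_cov = noise_cov,
                 rdm_mode = rdm_mode, pair_policy = pair_policy,
                 outlier_threshold = outlier_threshold,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

# FNV-1a string hash (hex), used for the manifest's config fingerprint.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

config_fingerprint <- function(config) {
  ser <- jsonlite::toJSON(lapply(unclass(config), function(x)
    if (inherits(x, "ground_truth_params")) unclass(x) else x),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  fnv1a(as.character(ser))
}

#' Run the full feedback-decomposition pipeline
#'
#' Stages, in dependency order: cohort simulation (optionally BOLD + LSS
#' re-estimation), contextual and mnemonic decoding with per-subject
#' permutation nulls and the group bootstrap test, crossnobis RDMs with
#' contextual/mnemonic model fits and group Wilcoxon tests, and
#' differentiation indices with outlier screening and the
#' feedforward-feedback rank correlation. All randomness derives from
#' `config$seed`, making the run bit-reproducible in `"direct"` estimation
#' mode.
#'
#' @param config a `pipeline_config`.
#' @param verbose print stage progress.
#' @return an object of class `feedback_pipeline`: list with `config`,
#'   tidy tables (`decoding`, `decoding_group`, `model_fits`,
#'   `model_fits_group`, `di`, `di_correlations`) and `manifest`. When
#'   `config$output_dir` is set the tables and manifest are also written
#'   there.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  say("stage simulate: %d x %d subjects, rois %s",
      length(config$groups), config$n_per_group,
      paste(config$rois, collapse = ","))
  cohort <- make_cohort(config$groups, config$n_per_group, seed = seed,
                        rois = config$rois, n_runs = config$n_runs,
                        reps = config$reps,
                        sensory_reps = config$sensory_reps)

  if (config$estimation == "bold_lss") {
    say("stage estimate: BOLD + LSS re-estimation")
    for (si in seq_along(cohort)) {
      for (roi in config$rois) {
        for (ph in c("occlusion", "sensory")) {
          sp <- cohort[[si]]$patterns[[roi]][[ph]]
          bseed <- derive_seed(seed, 90L, si, match(roi, config$rois),
                               match(ph, c("occlusion", "sensory")))
          bold <- simulate_bold(sp$trials, sp, tr = config$tr,
                                drift_amp = config$bold_drift_amp,
                                noise_sd = config$bold_noise_sd,
                                seed = bseed)
          est <- fit_lss(bold, sp$trials, subject = sp$subject, roi = roi)
          est$group <- sp$group
          est$truth <- sp$truth
          cohort[[si]]$patterns[[roi]][[ph]] <- est
        }
      }
    }
  }

  say("stage decode")
  dec_rows <- list(); null_store <- list()
  for (si in seq_along(cohort)) {
    sub <- cohort[[si]]
    for (roi in config$rois) {
      occ <- sub$patterns[[roi]]$occlusion
      for (tt in c("episodic", "semantic")) {
        schemes <- list(contextual = build_contextual_scheme(sub$stimulus, tt),
                        mnemonic = build_mnemonic_scheme(sub$stimulus, tt))
        for (sk in names(schemes)) {
          acc <- decode_subject(occ, schemes[[sk]], cost = config$cost,
                                zscore = config$zscore,
                                engine = config$engine)$accuracy
          pseed <- derive_seed(seed, 40L, si, match(roi, config$rois),
                               match(tt, c("episodic", "semantic")),
                               match(sk, names(schemes)))
          nulls <- permutation_null(occ, schemes[[sk]],
                                    n_perm = config$n_perm, seed = pseed,
                                    cost = config$cost,
                                    zscore = config$zscore,
                                    engine = config$engine)
          key <- paste(sub$group, roi, tt, sk, sep = ".")
          null_store[[key]] <- c(null_store[[key]], list(nulls))
          dec_rows[[length(dec_rows) + 1L]] <- data.frame(
            subject = sub$subject, group = sub$group, roi = roi,
            trial_type = tt, scheme = sk, accuracy = acc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  decoding <- do.call(rbind, dec_rows)
  grp_rows <- list()
  for (key in names(null_store)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sel <- decoding$group == parts[1] & decoding$roi == parts[2] &
      decoding$trial_type == parts[3] & decoding$scheme == parts[4]
    obs <- mean(decoding$accuracy[sel])
    bt <- group_bootstrap_test(null_store[[key]], obs,
                               n_boot = config$n_boot,
                               seed = derive_seed(seed, 41L,
                                                  match(key, names(null_store))),
                               prob = config$boot_prob)
    tt_p <- if (sum(sel) >= 2L)
      tryCatch(accuracy_ttest(decoding$accuracy[sel])$p.value,
               error = function(e) NA_real_) # constant accuracies
    else NA_real_
    grp_rows[[length(grp_rows) + 1L]] <- data.frame(
      group = parts[1], roi = parts[2], trial_type = parts[3],
      scheme = parts[4], n = sum(sel), mean_accuracy = obs, p_boot = bt$p,
      significant = bt$significant, p_ttest = tt_p, stringsAsFactors = FALSE)
  }
  decoding_group <- do.call(rbind, grp_rows)

  say("stage rsa")
  fit_rows <- list()
  di_rows <- list()
  for (si in seq_along(cohort)) {
    sub <- cohort[[si]]
    for (roi in config$rois) {
      occ <- sub$patterns[[roi]]$occlusion
      sen <- sub$patterns[[roi]]$sensory
      neural <- crossnobis_rdm(occ, noise_cov = config$noise_cov,
                               mode = config$rdm_mode)
      for (tt in c("episodic", "semantic")) {
        for (mk in c("contextual", "mnemonic")) {
          mf <- fit_model(neural, build_model_rdm(neural$labels, mk, tt))
          fit_rows[[length(fit_rows) + 1L]] <- data.frame(
            subject = sub$subject, group = sub$group, roi = roi,
            trial_type = tt, model = mk, rho = mf$rho, z = mf$z,
            stringsAsFactors = FALSE)
        }
      }
      di_rows[[length(di_rows) + 1L]] <- di_records(
        feedback_rdm = neural, feedforward_rdm = pearson_rdm(sen),
        subject = sub$subject, group = sub$group, roi = roi,
        pair_policy = config$pair_policy)
    }
  }
  model_fits <- do.call(rbind, fit_rows)
  mg_rows <- list()
  combos <- unique(model_fits[c("group", "roi", "trial_type", "model")])
  for (i in seq_len(nrow(combos))) {
    sel <- model_fits$group == combos$group[i] &
      model_fits$roi == combos$roi[i] &
      model_fits$trial_type == combos$trial_type[i] &
      model_fits$model == combos$model[i]
    wt <- wilcoxon_vs_zero(model_fits$z[sel], alternative = "greater")
    mg_rows[[i]] <- cbind(combos[i, ],
                          data.frame(n = sum(sel),
                                     mean_z = mean(model_fits$z[sel]),
                                     p_wilcoxon = wt$p.value))
  }
  model_fits_group <- do.call(rbind, mg_rows)
  rownames(model_fits_group) <- NULL

  say("stage di")
  di <- do.call(rbind, di_rows)
  di <- zscore_and_flag_outliers(di, threshold = config$outlier_threshold)
  ff <- di[di$pathway == "feedforward" & di$trial_type == "all", ]
  fb <- di[di$pathway == "feedback", ]
  di_correlations <- ff_fb_correlation(ff, fb)

  manifest <- list(package = "feedbackRSA",
                   version = as.character(utils::packageVersion("feedbackRSA")),
                   seed = seed, config_hash = config_fingerprint(config),
                   estimation = config$estimation,
                   n_subjects = length(cohort),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  out <- structure(list(config = config, decoding = decoding,
                        decoding_group = decoding_group,
                        model_fits = model_fits,
                        model_fits_group = model_fits_group, di = di,
                        di_correlations = di_correlations,
                        manifest = manifest),
                   class = "feedback_pipeline")
  if (!is.null(config$output_dir)) write_result_bundle(out)
  out
}

write_result_bundle <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("decoding", "decoding_group", "model_fits", "model_fits_group",
            "di", "di_correlations")
  for (tb in tabs)
    write.csv(result[[tb]], file.path(dir, paste0(tb, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.feedback_pipeline <- function(x, ...) {
  cat("Feedback-decomposition pipeline result\n")
  cat(sprintf("  %d subjects, seed %d, estimation %s (config %s)\n",
              x$manifest$n_subjects, x$manifest$seed,
              x$manifest$estimation, x$manifest$config_hash))
  cat(sprintf("  tables: decoding (%d rows), model_fits (%d), di (%d), di_correlations (%d)\n",
              nrow(x$decoding), nrow(x$model_fits), nrow(x$di),
              nrow(x$di_correlations)))
  invisible(x)
}

#' @export
summary.feedback_pipeline <- function(object, ...) {
  cat("Group decoding accuracy (bootstrap p):\n")
  print(object$decoding_group, row.names = FALSE, digits = 3)
  cat("\nGroup model fits (Fisher z, Wilcoxon vs zero):\n")
  print(object$model_fits_group, row.names = FALSE, digits = 3)
  cat("\nMean differentiation index by group/pathway/trial type:\n")
  agg <- stats::aggregate(di ~ group + roi + pathway + trial_type,
                          data = object$di[!object$di$outlier, ], FUN = mean)
  print(agg, row.names = FALSE, digits = 3)
  cat("\nFeedforward-feedback DI correlations:\n")
  print(object$di_correlations, row.names = FALSE, digits = 3)
  invisible(object)
}
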