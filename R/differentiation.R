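# Differentiation indices and their cross-pathway correlation.

#' Differentiation index of an RDM
#'
#' Mean between-object dissimilarity minus mean within-object
#' dissimilarity: higher values mean more distinct object representations
#' (lower within, higher between). `pair_policy` controls whether
#' same-object pairs that also share the room count as "within":
#' `"different_room"` (default) excludes them, mirroring the mnemonic-model
#' exclusion so room similarity cannot inflate within-object similarity;
#' `"all"` keeps every same-object pair. The diagonal is always excluded.
#'
#' @param rdm an `rdm` (labels must carry `object`, `room`, `trial_type`).
#' @param trial_type `"all"` or restrict pairs to `"episodic"` /
#'   `"semantic"` trials.
#' @param pair_policy `"different_room"` or `"all"`.
#' @return the index (units of the source RDM's dissimilarities).
#' @export
differentiation_index <- function(rdm,
                                  trial_type = c("all", "episodic",
                                                 "semantic"),
                                  pair_policy = c("different_room", "all")) {
  trial_type <- match.arg(trial_type)
  pair_policy <- match.arg(pair_policy)
  lab <- rdm$labels
  n <- nrow(lab)
  keep <- if (trial_type == "all") rep(TRUE, n) else lab$trial_type == trial_type
  sel <- upper.tri(rdm$D) & outer(keep, keep, "&")
  same_obj <- outer(lab$object, lab$object, "==")
  same_room <- outer(lab$room, lab$room, "==")
  within <- sel & same_obj
  if (pair_policy == "different_room") within <- within & !same_room
  between <- sel & !same_obj
  if (!sum(within) || !sum(between))
    stop_data("empty within or between pair set after filtering (",
              trial_type, ", ", pair_policy, ")")
  mean(rdm$D[between]) - mean(rdm$D[within])
}

#' Differentiation-index records for one subject
#'
#' Convenience wrapper producing tidy rows: feedback DIs (occlusion-task
#' crossnobis RDM) per trial type, and feedforward DIs (sensory-template
#' Pearson RDM) per trial type plus the single pooled `"all"` record used
#' for the cross-pathway correlation.
#'
#' @param feedback_rdm crossnobis `rdm` of the occlusion task (or `NULL`).
#' @param feedforward_rdm Pearson `rdm` of the sensory run (or `NULL`).
#' @param subject,group,roi labels for the rows.
#' @param pair_policy see [differentiation_index()].
#' @return data frame with columns `subject`, `group`, `roi`, `pathway`,
#'   `trial_type`, `di`.
#' @export
di_records <- function(feedback_rdm = NULL, feedforward_rdm = NULL,
                       subject = "s01", group = NA_character_, roi = "V1",
                       pair_policy = c("different_room", "all")) {
  pair_policy <- match.arg(pair_policy)
  rows <- list()
  add <- function(pathway, rdm, types) {
    for (tt in types) {
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = subject, group = group, roi = roi, pathway = pathway,
        trial_type = tt,
        di = differentiation_index(rdm, tt, pair_policy),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(feedback_rdm))
    add("feedback", feedback_rdm, c("episodic", "semantic"))
  if (!is.null(feedforward_rdm))
    add("feedforward", feedforward_rdm, c("episodic", "semantic", "all"))
  do.call(rbind, rows)
}

#' Standardize differentiation indices and flag outliers
#'
#' z-scores `di` within each stratum (by default group x roi x pathway x
#' trial_type) and flags records whose |z| exceeds `threshold` standard
#' deviations; the default 3.29 marks the most extreme 0.1% of a normal
#' distribution. Flagged records are meant to be excluded from downstream
#' correlations.
#'
#' @param records data frame as returned by [di_records()] (stacked over
#'   subjects).
#' @param threshold outlier threshold in SD units.
#' @param by character vector of stratification columns; set e.g.
#'   `c("roi", "pathway", "trial_type")` for group-pooled standardization.
#' @return `records` with added `z_di` and `outlier` columns.
#' @export
zscore_and_flag_outliers <- function(records, threshold = 3.29,
                                     by = c("group", "roi", "pathway",
                                            "trial_type")) {
  key <- interaction(records[by], drop = TRUE)
  records$z_di <- NA_real_
  for (k in levels(key)) {
    i <- key == k
    if (sum(i) < 2L) stop_data("stratum ", k, " has < 2 records")
    s <- sd(records$di[i])
    # a degenerate stratum of identical values carries no outlier evidence
    records$z_di[i] <- if (s == 0) 0 else
      (records$di[i] - mean(records$di[i])) / s
  }
  records$outlier <- abs(records$z_di) > threshold
  records
}

#' Correlate feedforward with feedback differentiation across subjects
#'
#' One-sided Spearman correlation (alternative `"greater"`: better
#' feedforward differentiation goes with better feedback differentiation)
#' between subjects' feedforward DIs and their episodic/semantic feedback
#' DIs, separately per group x roi x feedback trial type, with
#' Benjamini-Hochberg adjustment across the family. Records flagged as
#' outliers are dropped; a pair enters only if both pathways survive.
#'
#' @param ff feedforward records (rows with `pathway == "feedforward"`,
#'   one per subject x roi, i.e. `trial_type == "all"`), including `z_di`
#'   and `outlier` columns from [zscore_and_flag_outliers()].
#' @param fb feedback records, same format.
#' @param alternative passed to [spearman_test()].
#' @param exact_max passed to [spearman_test()].
#' @return data frame with `group`, `roi`, `trial_type`, `n`, `rho`, `p`,
#'   `p_adj`.
#' @export
ff_fb_correlation <- function(ff, fb, alternative = "greater",
                              exact_max = 8L) {
  ff <- ff[!ff$outlier, ]
  fb <- fb[!fb$outlier, ]
  combos <- unique(fb[c("group", "roi", "trial_type")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    g <- combos$group[i]; r <- combos$roi[i]; tt <- combos$trial_type[i]
    fbi <- fb[fb$group == g & fb$roi == r & fb$trial_type == tt, ]
    ffi <- ff[ff$group == g & ff$roi == r, ]
    m <- match(fbi$subject, ffi$subject)
    ok <- !is.na(m)
    if (sum(ok) < 3L) stop_data("fewer than 3 paired subjects in ",
                                paste(g, r, tt, collapse = " "))
    st <- spearman_test(ffi$di[m[ok]], fbi$di[ok],
                        alternative = alternative, exact_max = exact_max)
    out[[i]] <- data.frame(group = g, roi = r, trial_type = tt,
                           n = st$n, rho = st$rho, p = st$p.value,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p_adj <- bh_adjust(res$p)
  res
}
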