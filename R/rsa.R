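# Representational similarity analysis: crossnobis and Pearson-distance
# RDMs, binary model RDMs with exclusion masks, rank-correlation model fits.

new_rdm <- function(D, labels, metric) {
  dimnames(D) <- NULL
  structure(list(D = D, labels = labels, metric = metric), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM [%s]: %d x %d, range [%.3g, %.3g]\n", x$metric,
              nrow(x$D), ncol(x$D), min(x$D), max(x$D)))
  invisible(x)
}

#' Shrinkage estimate of the noise covariance
#'
#' Sample covariance of the residual rows shrunk toward its diagonal with a
#' Schaefer-Strimmer-style analytic intensity (the intensity minimizing the
#' estimated MSE of the off-diagonal entries), or a user-supplied
#' `lambda` in `[0, 1]`. Guarantees a well-conditioned matrix for the
#' Mahalanobis prewhitening even when voxels outnumber residual degrees of
#' freedom.
#'
#' @param R matrix of residuals (observations x voxels), already centred.
#' @param lambda shrinkage intensity; `NULL` for the analytic choice.
#' @return list with `sigma` (shrunk covariance) and `lambda`.
#' @export
shrinkage_cov <- function(R, lambda = NULL) {
  n <- nrow(R); p <- ncol(R)
  if (n < 2L) stop_data("need >= 2 residual rows for a covariance estimate")
  S <- crossprod(R) / (n - 1L)
  if (is.null(lambda)) {
    # var of each covariance entry, estimated from the per-observation
    # outer products; shrink off-diagonals toward zero (diagonal target)
    W <- array(0, c(p, p))
    for (i in seq_len(n)) {
      o <- tcrossprod(R[i, ])
      W <- W + (o - S)^2
    }
    V <- W * n / ((n - 1L)^3)
    off <- upper.tri(S) | lower.tri(S)
    denom <- sum(S[off]^2)
    lambda <- if (denom > 0) min(1, max(0, sum(V[off]) / denom)) else 1
  }
  sigma <- (1 - lambda) * S
  diag(sigma) <- diag(S)
  list(sigma = sigma, lambda = lambda)
}

cond_labels <- function(trials) {
  u <- !duplicated(trials$room)
  data.frame(room = trials$room[u], object = trials$object[u],
             trial_type = trials$trial_type[u], stringsAsFactors = FALSE)
}

#' Cross-validated Mahalanobis (crossnobis) RDM
#'
#' Distances between trial patterns computed with run-wise cross-validation
#' so that noise does not bias them upward: for conditions (rooms) i, j and
#' an unordered run pair (A, B), the contribution is
#' `(m_Ai - m_Aj)' W (m_Bi - m_Bj) / n_voxels`, where `m_r` are per-run
#' condition means and `W` the inverse noise covariance; contributions are
#' averaged over all run pairs. The estimator has expectation zero when the
#' two true patterns are equal, so entries can be negative. Trial pairs
#' inherit the distance of their condition pair (per-run condition means
#' are the fold estimates).
#'
#' @param patterns a `subject_patterns` with >= 2 runs; every room must
#'   occur in every run.
#' @param noise_cov `"shrinkage"` (default), `"diag"` (diagonal of the
#'   residual covariance) or `"identity"` (reduces to cross-validated
#'   Euclidean distance over voxels).
#' @param mode `"trial"` returns the matrix expanded to the trials of
#'   `ref_run` (the design's trial span); `"condition"` returns the compact
#'   room-by-room matrix.
#' @param lambda optional fixed shrinkage intensity for
#'   `noise_cov = "shrinkage"`.
#' @param ref_run run whose trial ordering labels the `"trial"`-mode matrix.
#' @return an `rdm` (metric `"crossnobis"`); `labels` carry room, object,
#'   trial_type (and run in trial mode).
#' @export
crossnobis_rdm <- function(patterns,
                           noise_cov = c("shrinkage", "diag", "identity"),
                           mode = c("trial", "condition"), lambda = NULL,
                           ref_run = NULL) {
  noise_cov <- match.arg(noise_cov)
  mode <- match.arg(mode)
  trials <- patterns$trials
  runs <- sort(unique(trials$run))
  if (length(runs) < 2L) stop_data("crossnobis needs >= 2 runs")
  conds <- sort(unique(trials$room))
  P <- ncol(patterns$X)
  # per-run condition means and pooled within-condition residuals
  M <- lapply(runs, function(r) {
    sel <- trials$run == r
    tab <- table(factor(trials$room[sel], levels = conds))
    if (any(tab == 0))
      stop_data("room(s) missing from run ", r, ": ",
                paste(conds[tab == 0], collapse = ", "))
    rowsum(patterns$X[sel, , drop = FALSE], trials$room[sel])[conds, ,
                                                             drop = FALSE] /
      as.numeric(tab)
  })
  resid <- patterns$X
  for (ri in seq_along(runs)) {
    sel <- which(trials$run == runs[ri])
    resid[sel, ] <- patterns$X[sel, , drop = FALSE] -
      M[[ri]][trials$room[sel], , drop = FALSE]
  }
  W <- switch(noise_cov,
    identity = diag(P),
    diag = {
      v <- colSums(resid^2) / max(1L, nrow(resid) - length(conds) * length(runs))
      if (any(v <= 0))
        stop_data("singular diagonal covariance (zero-variance voxel); ",
                  "use noise_cov = \"shrinkage\"")
      diag(1 / v, P)
    },
    shrinkage = {
      sg <- shrinkage_cov(resid, lambda = lambda)
      out <- try(solve(sg$sigma), silent = TRUE)
      if (inherits(out, "try-error"))
        stop_data("noise covariance is singular even after shrinkage; ",
                  "increase lambda")
      out
    })
  nc <- length(conds)
  D <- matrix(0, nc, nc)
  np <- 0L
  for (a in seq_along(runs)[-length(runs)]) {
    for (b in seq((a + 1L), length(runs))) {
      K <- M[[a]] %*% W %*% t(M[[b]])
      K <- (K + t(K)) / 2
      D <- D + outer(diag(K), diag(K), "+") - 2 * K
      np <- np + 1L
    }
  }
  D <- D / (np * P)
  diag(D) <- 0
  cl <- cond_labels(trials)
  cl <- cl[match(conds, cl$room), ]
  if (mode == "condition") {
    cl$run <- NA_integer_
    return(new_rdm(D, cl, "crossnobis"))
  }
  ref_run <- ref_run %||% runs[1]
  tt <- trials[trials$run == ref_run, , drop = FALSE]
  idx <- match(tt$room, conds)
  lab <- data.frame(room = tt$room, object = tt$object,
                    trial_type = tt$trial_type, run = tt$run,
                    stringsAsFactors = FALSE)
  new_rdm(D[idx, idx, drop = FALSE], lab, "crossnobis")
}

#' Pearson correlation-distance RDM
#'
#' Entry (i, j) is `1 - r` between the voxel patterns of trials i and j;
#' used for the single-run sensory-template (feedforward) data.
#'
#' @param patterns a `subject_patterns` with >= 2 voxels.
#' @return an `rdm` (metric `"pearson_distance"`) with per-trial labels.
#' @export
pearson_rdm <- function(patterns) {
  X <- patterns$X
  if (ncol(X) < 2L) stop_data("pearson_rdm needs >= 2 voxels")
  v <- apply(X, 1L, var)
  if (any(v == 0))
    stop_data("zero-variance pattern row for trial(s): ",
              paste(which(v == 0), collapse = ", "))
  D <- 1 - cor(t(X))
  diag(D) <- 0
  tt <- patterns$trials
  lab <- data.frame(room = tt$room, object = tt$object,
                    trial_type = tt$trial_type, run = tt$run,
                    stringsAsFactors = FALSE)
  new_rdm(D, lab, "pearson_distance")
}

#' Binary model RDM with exclusion mask
#'
#' The contextual model predicts minimal dissimilarity (0) for
#' same-object-same-room pairs and maximal (1) elsewhere. The mnemonic
#' model predicts 0 for same-object-different-room pairs and 1 for
#' different-object-different-room pairs, with same-object-same-room pairs
#' excluded so that mere room similarity cannot deflate an object-driven
#' correlation. The diagonal is always excluded, as are pairs involving
#' trials outside the requested `trial_type`.
#'
#' @param labels a `trial_table`, an [crossnobis_rdm()] label frame, or any
#'   data frame with `room`, `object` and `trial_type` columns giving the
#'   axis ordering of the target neural RDM.
#' @param kind `"contextual"` or `"mnemonic"`.
#' @param trial_type `"episodic"`, `"semantic"` or `"all"`.
#' @return an object of class `model_rdm`: list with the binary matrix `M`,
#'   logical `include` mask, `kind`, `trial_type` and `labels`.
#' @export
build_model_rdm <- function(labels, kind = c("contextual", "mnemonic"),
                            trial_type = c("all", "episodic", "semantic")) {
  kind <- match.arg(kind)
  trial_type <- match.arg(trial_type)
  need <- c("room", "object", "trial_type")
  if (!all(need %in% names(labels)))
    stop_data("labels need columns room, object, trial_type")
  n <- nrow(labels)
  same_room <- outer(labels$room, labels$room, "==")
  same_obj <- outer(labels$object, labels$object, "==")
  include <- !diag(TRUE, n)
  if (trial_type != "all") {
    keep <- labels$trial_type == trial_type
    include <- include & outer(keep, keep, "&")
  }
  if (kind == "contextual") {
    M <- 1 - (same_room & same_obj)
  } else {
    M <- 1 - same_obj
    include <- include & !(same_room & same_obj)
  }
  mode(M) <- "numeric"
  structure(list(M = M, include = include, kind = kind,
                 trial_type = trial_type, labels = labels),
            class = "model_rdm")
}

#' @export
print.model_rdm <- function(x, ...) {
  cat(sprintf("Model RDM [%s, %s]: %d x %d, %d included cells (upper triangle)\n",
              x$kind, x$trial_type, nrow(x$M), ncol(x$M),
              sum(x$include & upper.tri(x$M))))
  invisible(x)
}

#' Rank-correlate a neural RDM with a model RDM
#'
#' Spearman rank correlation between the neural and model dissimilarities
#' over the included cells of the upper triangle (the matrices are
#' symmetric, so the lower triangle is redundant), followed by the Fisher z
#' transform. A perfect `rho = +/-1` is capped at `atanh(1 - 1e-12)` to
#' keep z finite.
#'
#' @param neural an `rdm`.
#' @param model a `model_rdm` built on the same trial ordering.
#' @return an object of class `model_fit`: list with `rho`, `z`, `n_cells`,
#'   `model`, `trial_type`, `metric`.
#' @export
fit_model <- function(neural, model) {
  if (!inherits(neural, "rdm") || !inherits(model, "model_rdm"))
    stop_data("fit_model expects an rdm and a model_rdm")
  if (!all(dim(neural$D) == dim(model$M)))
    stop_data("neural and model RDM dimensions differ")
  if (!identical(neural$labels$room, model$labels$room) ||
      !identical(neural$labels$object, model$labels$object))
    stop_data("neural and model RDM trial orderings differ")
  sel <- model$include & upper.tri(model$M)
  if (sum(sel) < 3L) stop_data("fewer than 3 included cells")
  rho <- cor(neural$D[sel], model$M[sel], method = "spearman")
  structure(list(rho = rho, z = atanh(max(-1 + 1e-12, min(1 - 1e-12, rho))),
                 n_cells = sum(sel), model = model$kind,
                 trial_type = model$trial_type, metric = neural$metric),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Model fit [%s, %s]: rho = %.4f (z = %.4f) on %d cells\n",
              x$model, x$trial_type, x$rho, x$z, x$n_cells))
  invisible(x)
}
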