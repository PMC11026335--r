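# Decoding: classification schemes, leave-one-run-out CV, permutation and
# bootstrap group-level inference.

new_scheme_spec <- function(kind, trial_type, train_cells, test_cells, label) {
  structure(list(kind = kind, trial_type = trial_type,
                 train_cells = train_cells, test_cells = test_cells,
                 label = label),
            class = "scheme_spec")
}

cells_df <- function(room, object, class) {
  data.frame(room = room, object = object, class = class,
             stringsAsFactors = FALSE)
}

#' Build the contextual classification scheme
#'
#' One binary problem per object: the two classes share the object but
#' differ in the room (each object has exactly two rooms within a trial
#' type), and train and test cells are identical, so only contextual room
#' information can drive classification in the occluded voxels. Returns 4
#' problems per trial type; subject-level accuracy is their unweighted
#' mean (see [decode_subject()]).
#'
#' @param stim a `stimulus_set`.
#' @param trial_type `"episodic"` or `"semantic"`.
#' @return list of `scheme_spec` (kind `"contextual"`).
#' @export
build_contextual_scheme <- function(stim,
                                    trial_type = c("episodic", "semantic")) {
  trial_type <- match.arg(trial_type)
  map <- room_object_map(stim)
  map <- map[map$trial_type == trial_type, ]
  lapply(stim$objects, function(ob) {
    rooms <- map$room[map$object == ob]
    if (length(rooms) != 2L)
      stop_data("object ", ob, " has ", length(rooms), " rooms in ",
                trial_type, " pairs; need exactly 2")
    cells <- cells_df(rooms, ob, c("A", "B"))
    new_scheme_spec("contextual", trial_type, cells, cells,
                    sprintf("ctx_%s_%s", trial_type, ob))
  })
}

#' Build the mnemonic cross-classification scheme
#'
#' Training classes differ in both object and room ("different object,
#' different room"); testing uses each object's other room, so train and
#' test rooms are disjoint while the object pair is shared. Above-chance
#' transfer is then possible only through retrieved object (mnemonic)
#' information. For each of the 6 unordered object pairs both room
#' assignments are emitted, giving 12 problems per trial type whose
#' accuracies are averaged.
#'
#' @inheritParams build_contextual_scheme
#' @return list of `scheme_spec` (kind `"mnemonic_crossclass"`).
#' @export
build_mnemonic_scheme <- function(stim,
                                  trial_type = c("episodic", "semantic")) {
  trial_type <- match.arg(trial_type)
  map <- room_object_map(stim)
  map <- map[map$trial_type == trial_type, ]
  rooms_of <- lapply(stim$objects, function(ob) {
    r <- map$room[map$object == ob]
    if (length(r) != 2L)
      stop_data("object ", ob, " has ", length(r), " rooms in ", trial_type,
                " pairs; need exactly 2")
    r
  })
  names(rooms_of) <- stim$objects
  pairs <- combn(stim$objects, 2L, simplify = FALSE)
  out <- list()
  for (pr in pairs) {
    r1 <- rooms_of[[pr[1]]]; r2 <- rooms_of[[pr[2]]]
    for (swap in 0:1) {
      i <- 1L + swap; j <- 2L - swap
      train <- cells_df(c(r1[i], r2[i]), pr, c("A", "B"))
      test <- cells_df(c(r1[j], r2[j]), pr, c("A", "B"))
      out[[length(out) + 1L]] <- new_scheme_spec(
        "mnemonic_crossclass", trial_type, train, test,
        sprintf("mne_%s_%s-%s_%d", trial_type, pr[1], pr[2], swap + 1L))
    }
  }
  out
}

#' @export
print.scheme_spec <- function(x, ...) {
  cat(sprintf("Scheme %s [%s, %s]\n", x$label, x$kind, x$trial_type))
  cat("  train:", paste(x$train_cells$room, x$train_cells$class, sep = ":",
                        collapse = " "), "\n")
  cat("  test: ", paste(x$test_cells$room, x$test_cells$class, sep = ":",
                        collapse = " "), "\n")
  invisible(x)
}

# Rows of the pattern matrix matching a cell set; returns index vector and
# class labels.
match_cells <- function(trials, cells) {
  key <- paste(trials$room, trials$object)
  ck <- paste(cells$room, cells$object)
  hit <- match(key, ck)
  idx <- which(!is.na(hit))
  list(idx = idx, class = cells$class[hit[idx]])
}

# Fit the linear classifier and return decision values for Xt.
# engine "dualcd": compiled dual coordinate-descent linear SVM (default);
# engine "libsvm": e1071/libsvm C-classification, identical contract.
linear_classify <- function(X, y, Xt, cost = 1, engine = "dualcd") {
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop_data("need exactly 2 classes, got ",
                                   length(lev))
  if (engine == "dualcd") {
    yy <- ifelse(y == lev[2], 1, -1)
    w <- .svm_dualcd(X, yy, cost, 0.1, 200L, 42L)
    d <- drop(Xt %*% w[-length(w)]) + w[length(w)]
    ifelse(d > 0, lev[2], lev[1])
  } else if (engine == "libsvm") {
    m <- e1071::svm(X, factor(y, levels = lev), kernel = "linear",
                    cost = cost, scale = FALSE)
    as.character(predict(m, Xt))
  } else stop_data("unknown engine: ", engine)
}

#' Leave-one-run-out cross-validated classification
#'
#' Trains a binary linear max-margin classifier (fixed regularization
#' `cost`, no feature scaling by default) on the scheme's train cells in
#' all-but-one run and evaluates on the scheme's test cells in the held-out
#' run; every run serves as test once. Deterministic given inputs and
#' configuration.
#'
#' @param patterns a `subject_patterns` (multi-run occlusion phase).
#' @param scheme a single `scheme_spec`.
#' @param cost regularization constant C of the margin classifier.
#' @param zscore if `TRUE`, z-score each voxel within fold using training
#'   statistics before fitting.
#' @param engine `"dualcd"` (compiled, default) or `"libsvm"` (e1071).
#' @return an object of class `classification_result`: list with
#'   `fold_accuracy`, `mean_accuracy` (unweighted fold average), `n_train`,
#'   `n_test`, `scheme`.
#' @export
run_loro_cv <- function(patterns, scheme, cost = 1, zscore = FALSE,
                        engine = c("dualcd", "libsvm")) {
  engine <- match.arg(engine)
  trials <- patterns$trials
  runs <- sort(unique(trials$run))
  if (length(runs) < 2L) stop_data("need >= 2 runs for leave-one-run-out")
  tr_match <- match_cells(trials, scheme$train_cells)
  te_match <- match_cells(trials, scheme$test_cells)
  acc <- n_tr <- n_te <- numeric(length(runs))
  for (f in seq_along(runs)) {
    test_run <- runs[f]
    tr_idx <- tr_match$idx[trials$run[tr_match$idx] != test_run]
    tr_cls <- tr_match$class[trials$run[tr_match$idx] != test_run]
    te_idx <- te_match$idx[trials$run[te_match$idx] == test_run]
    te_cls <- te_match$class[trials$run[te_match$idx] == test_run]
    if (length(unique(tr_cls)) < 2L)
      stop_data("fold ", f, " (test run ", test_run,
                "): training class missing for scheme ", scheme$label)
    if (length(unique(te_cls)) < 2L)
      stop_data("fold ", f, " (test run ", test_run,
                "): empty test class for scheme ", scheme$label)
    X <- patterns$X[tr_idx, , drop = FALSE]
    Xt <- patterns$X[te_idx, , drop = FALSE]
    if (zscore) {
      mu <- colMeans(X)
      s <- apply(X, 2L, sd)
      s[s == 0] <- 1
      X <- scale(X, mu, s); Xt <- scale(Xt, mu, s)
    }
    pred <- linear_classify(X, tr_cls, Xt, cost = cost, engine = engine)
    acc[f] <- mean(pred == te_cls)
    n_tr[f] <- length(tr_idx); n_te[f] <- length(te_idx)
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 n_train = n_tr, n_test = n_te, scheme = scheme$label),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("LORO-CV [%s]: mean accuracy %.3f over %d folds (%s)\n",
              x$scheme, x$mean_accuracy, length(x$fold_accuracy),
              paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  invisible(x)
}

#' Subject-level accuracy for a list of binary problems
#'
#' Runs [run_loro_cv()] for every `scheme_spec` in `schemes` and aggregates
#' by the unweighted mean of the per-problem mean accuracies.
#'
#' @inheritParams run_loro_cv
#' @param schemes list of `scheme_spec` (e.g. from
#'   [build_contextual_scheme()]).
#' @return list with `accuracy` (scalar), `per_problem` (named numeric) and
#'   `results` (list of `classification_result`).
#' @export
decode_subject <- function(patterns, schemes, cost = 1, zscore = FALSE,
                           engine = c("dualcd", "libsvm")) {
  engine <- match.arg(engine)
  res <- lapply(schemes, function(s)
    run_loro_cv(patterns, s, cost = cost, zscore = zscore, engine = engine))
  per <- vapply(res, `[[`, 0, "mean_accuracy")
  names(per) <- vapply(schemes, `[[`, "", "label")
  list(accuracy = mean(per), per_problem = per, results = res)
}

#' Permutation null distribution of subject-level accuracy
#'
#' Permutes the trial labels within each run (preserving the run structure
#' that the cross-validation folds rely on) and recomputes the full
#' leave-one-run-out subject accuracy for every permutation. Implemented by
#' shuffling pattern rows within run, which is equivalent to shuffling the
#' (room, object) labels jointly.
#'
#' @inheritParams decode_subject
#' @param n_perm number of permutations (>= 1), default 100.
#' @param seed RNG seed for the permutations.
#' @return numeric vector of `n_perm` null subject accuracies.
#' @export
permutation_null <- function(patterns, schemes, n_perm = 100L, seed = NULL,
                             cost = 1, zscore = FALSE,
                             engine = c("dualcd", "libsvm")) {
  engine <- match.arg(engine)
  if (n_perm < 1L) stop_data("n_perm must be >= 1")
  trials <- patterns$trials
  run_rows <- split(seq_len(nrow(trials)), trials$run)
  if (engine == "libsvm" || zscore) {
    # generic path: rebuild the patterns object per permutation
    return(with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        perm <- unlist(lapply(run_rows, sample), use.names = FALSE)
        pp <- patterns
        pp$X[unlist(run_rows, use.names = FALSE), ] <-
          patterns$X[perm, , drop = FALSE]
        decode_subject(pp, schemes, cost = cost, zscore = zscore,
                       engine = engine)$accuracy
      }, 0)
    }))
  }
  # fast path (compiled solver, no scaling): precompute the fold layout
  # once; a permutation is just an index remapping of the pattern rows
  X <- patterns$X
  runs <- sort(unique(trials$run))
  folds <- list()
  for (sc in schemes) {
    trm <- match_cells(trials, sc$train_cells)
    tem <- match_cells(trials, sc$test_cells)
    for (f in seq_along(runs)) {
      tr_sel <- trials$run[trm$idx] != runs[f]
      te_sel <- trials$run[tem$idx] == runs[f]
      cls <- trm$class[tr_sel]
      lev <- sort(unique(cls))
      if (length(lev) != 2L)
        stop_data("training class missing in fold ", f, " of scheme ",
                  sc$label)
      folds[[length(folds) + 1L]] <- list(
        tr = trm$idx[tr_sel], yy = ifelse(cls == lev[2], 1, -1),
        te = tem$idx[te_sel],
        yy_te = ifelse(tem$class[te_sel] == lev[2], 1, -1),
        problem = sc$label)
    }
  }
  n_prob <- length(schemes)
  base <- unlist(run_rows, use.names = FALSE)
  map <- integer(nrow(X))
  with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      map[base] <- unlist(lapply(run_rows, sample), use.names = FALSE)
      acc <- vapply(folds, function(fd) {
        w <- .svm_dualcd(X[map[fd$tr], , drop = FALSE], fd$yy, cost, 0.1,
                         200L, 42L)
        d <- X[map[fd$te], , drop = FALSE] %*% w[-length(w)] + w[length(w)]
        mean((d > 0) == (fd$yy_te == 1))
      }, 0)
      # unweighted mean over problems of per-problem fold means
      mean(vapply(split(acc, rep(seq_len(n_prob), each = length(runs))),
                  mean, 0))
    }, 0)
  })
}

#' Two-step bootstrap group-level significance test
#'
#' Step one produces a permutation null of subject accuracies per subject
#' ([permutation_null()]). Step two draws, `n_boot` times, one null
#' accuracy per subject with replacement and averages across subjects,
#' yielding a null distribution of group-mean accuracies. The observed
#' group mean is called significant when it exceeds the `prob` quantile of
#' that null (the default 0.999 corresponds to p < 0.001).
#'
#' @param per_subject_nulls list of numeric null vectors, one per subject.
#' @param observed observed group-mean accuracy.
#' @param n_boot bootstrap iterations (>= 1), default 1000.
#' @param seed RNG seed.
#' @param prob significance quantile of the null distribution.
#' @return list with `null` (length `n_boot`), `p` (proportion of null
#'   group means >= observed), `crit` (the `prob` quantile) and
#'   `significant`.
#' @export
group_bootstrap_test <- function(per_subject_nulls, observed,
                                 n_boot = 1000L, seed = NULL, prob = 0.999) {
  if (!length(per_subject_nulls)) stop_data("empty subject list")
  if (any(!vapply(per_subject_nulls, length, 0L)))
    stop_data("every subject needs >= 1 null accuracy")
  if (n_boot < 1L) stop_data("n_boot must be >= 1")
  null_means <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b)
      mean(vapply(per_subject_nulls, function(v)
        v[sample.int(length(v), 1L)], 0)), 0)
  })
  crit <- unname(quantile(null_means, prob, type = 7))
  list(null = null_means, p = mean(null_means >= observed), crit = crit,
       significant = observed > crit)
}

#' One-sided one-sample t test of accuracies against chance
#'
#' Companion parametric test to [group_bootstrap_test()]: tests whether a
#' group's subject accuracies exceed the chance level.
#'
#' @param accuracies numeric vector of subject accuracies.
#' @param chance chance level, default 0.5.
#' @return the `htest` object from [stats::t.test()] (alternative
#'   `"greater"`).
#' @export
accuracy_ttest <- function(accuracies, chance = 0.5) {
  t.test(accuracies, mu = chance, alternative = "greater")
}
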