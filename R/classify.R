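# PCA embedding with elbow selection, leave-one-subject-out multinomial
# classification (winner-take-all), balanced-bootstrap training variant,
# confusion matrices, and between-task comparison.

#' Principal component analysis of a profile matrix
#'
#' Column-mean centred (no variance scaling) singular value decomposition,
#' with a deterministic sign convention: each loading vector's
#' largest-magnitude entry is positive.
#'
#' @param pm a `profile_matrix` or plain numeric matrix.
#' @return object of class `vtcwm_pca`: `loadings` (parcels x components),
#'   `scores` (rows x components), `variance_explained` (percent, all
#'   components), `n_components_elbow`, `center`.
#' @export
fit_pca <- function(pm) {
  X <- if (inherits(pm, "profile_matrix")) pm$matrix else as.matrix(pm)
  stopifnot(nrow(X) >= 2)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  varexp <- pc$sdev^2
  varexp <- if (sum(varexp) > 0) 100 * varexp / sum(varexp) else varexp
  elbow <- if (length(varexp) >= 3 && sum(varexp) > 0) {
    find_elbow(varexp)
  } else 1L
  structure(list(loadings = loadings, scores = scores,
                 variance_explained = varexp,
                 n_components_elbow = elbow, center = pc$center),
            class = "vtcwm_pca")
}

#' @exportS3Method
print.vtcwm_pca <- function(x, ...) {
  k <- x$n_components_elbow
  cat("PCA:", ncol(x$scores), "components; elbow at", k, "(",
      round(sum(x$variance_explained[1:k]), 1), "% variance )\n")
  invisible(x)
}

#' Elbow of a scree curve
#'
#' Returns the 1-based index of the curve point with maximum perpendicular
#' distance to the straight line joining the first and last points; ties go
#' to the smaller index.
#'
#' @param curve non-increasing numeric vector (e.g. variance-explained
#'   percentages), length >= 3.
#' @return integer index.
#' @export
find_elbow <- function(curve) {
  stopifnot(length(curve) >= 3)
  if (any(diff(curve) > 1e-9)) stop("curve must be non-increasing")
  n <- length(curve)
  p1 <- c(1, curve[1]); p2 <- c(n, curve[n])
  v <- p2 - p1
  vn <- sqrt(sum(v^2))
  d <- vapply(seq_len(n), function(i) {
    w <- c(i, curve[i]) - p1
    if (vn == 0) return(0)
    abs(v[1] * w[2] - v[2] * w[1]) / vn
  }, numeric(1))
  which.max(d)  # first maximum: ties break to the smaller index
}

#' Multinomial logistic regression (ridge-stabilized)
#'
#' Fits a softmax classifier by penalized maximum likelihood via
#' [nnet::multinom]; a small ridge (`decay`) keeps the fit well-defined on
#' separable classes.
#'
#' @param X rows x features matrix; @param y labels (coerced to factor with
#'   `levels` as canonical order).
#' @param levels canonical label order (default: levels present, sorted by
#'   first appearance in `.vtcwm` canonical tables when applicable).
#' @param ridge nonnegative weight-decay penalty.
#' @param max_iter maximum iterations.
#' @return object of class `vtcwm_multinom`: the `nnet` fit plus `levels` and
#'   a `converged` flag.
#' @export
fit_multinomial <- function(X, y, levels = NULL, ridge = 1e-6,
                            max_iter = 200) {
  X <- as.matrix(X)
  if (is.null(levels)) levels <- unique(as.character(y))
  y <- factor(as.character(y), levels = levels)
  if (length(unique(y[!is.na(y)])) < 2) stop("need at least 2 classes present")
  dat <- data.frame(.y = y, X, check.names = TRUE)
  fit <- nnet::multinom(.y ~ ., data = dat, decay = ridge, maxit = max_iter,
                        trace = FALSE, MaxNWts = 1e5,
                        reltol = 1e-12, abstol = 1e-10)
  structure(list(fit = fit, levels = levels,
                 converged = fit$convergence == 0,
                 feature_names = colnames(dat)[-1]),
            class = "vtcwm_multinom")
}

#' Winner-take-all prediction
#'
#' Softmax class probabilities and the argmax label; exact probability ties
#' go to the first class in canonical label order.
#'
#' @param model a `vtcwm_multinom`.
#' @param X new data matrix (same feature layout as training).
#' @return list: `labels` (character), `probabilities` (rows x classes).
#' @export
predict_wta <- function(model, X) {
  stopifnot(inherits(model, "vtcwm_multinom"))
  X <- as.matrix(X)
  nd <- as.data.frame(X)
  colnames(nd) <- model$feature_names
  pr <- predict(model$fit, newdata = nd, type = "probs")
  if (is.null(dim(pr))) {
    if (length(model$fit$lev) > 2) {  # single row, >2 classes: named vector
      pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
    } else {  # two-class case returns P(second level)
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- model$fit$lev
    }
  }
  pr <- pr[, model$levels[model$levels %in% colnames(pr)], drop = FALSE]
  win <- max.col(pr, ties.method = "first")
  list(labels = colnames(pr)[win], probabilities = pr)
}

#' Leave-one-subject-out classification of profile features
#'
#' PCA is fitted once on the full profile matrix; classification then
#' iterates over subjects, training a multinomial softmax on the PCA scores
#' of all other subjects' profiles and predicting every held-out profile with
#' winner-take-all. Correctness is aggregated to one accuracy per session
#' (mean over that session's fROIs); the confusion matrix pools all
#' predictions and is row-normalized to percent. Optionally each training
#' fold is balanced by drawing `n_resample_per_label` rows per label with
#' replacement.
#'
#' @param pm a `profile_matrix`.
#' @param task `"category"`, `"cytoarchitecture"`, or `"age_group"`.
#' @param n_components PCA scores used as features (`"elbow"` or an integer).
#' @param balanced balance training folds by resampling.
#' @param n_resample_per_label rows drawn per label when `balanced`.
#' @param seed RNG seed (used only for balanced resampling).
#' @param refit_pca_per_fold if `TRUE`, PCA is refit within each training
#'   fold (leakage-free variant) instead of once on the full matrix.
#' @param labels optional label vector overriding the task's metadata column
#'   (e.g. permuted labels for a null calibration); length = rows of `pm`.
#' @return object of class `classification_result`: `task`,
#'   `per_session_accuracy` (data.frame session_id, accuracy),
#'   `overall_mean`, `overall_sd`, `confusion` (row percentages), `chance`,
#'   `predictions` (per-profile data.frame), `n_components`.
#' @export
loo_classify <- function(pm, task = c("cytoarchitecture", "category", "age_group"),
                         n_components = "elbow", balanced = FALSE,
                         n_resample_per_label = 200, seed = 1,
                         refit_pca_per_fold = FALSE, labels = NULL) {
  task <- match.arg(task)
  meta <- pm$meta
  truth_lab <- if (!is.null(labels)) {
    as.character(labels)
  } else as.character(meta[[task]])
  canonical <- switch(task, category = .vtcwm_categories,
                      cytoarchitecture = .vtcwm_cytos,
                      age_group = .vtcwm_age_groups)
  canonical <- canonical[canonical %in% unique(truth_lab)]
  pca <- fit_pca(pm)
  k <- if (identical(n_components, "elbow")) pca$n_components_elbow
       else as.integer(n_components)
  stopifnot(k >= 1, k <= ncol(pca$scores))
  subjects <- unique(meta$subject_id)
  pred <- rep(NA_character_, nrow(meta))
  for (sub in subjects) {
    test_ix <- which(meta$subject_id == sub)
    train_ix <- which(meta$subject_id != sub)
    stopifnot(length(intersect(test_ix, train_ix)) == 0)  # fold hygiene
    if (refit_pca_per_fold) {
      fold_pca <- fit_pca(pm$matrix[train_ix, , drop = FALSE])
      ctr <- fold_pca$center
      tr <- fold_pca$scores[, 1:k, drop = FALSE]
      te <- (sweep(pm$matrix[test_ix, , drop = FALSE], 2, ctr) %*%
               fold_pca$loadings)[, 1:k, drop = FALSE]
    } else {
      tr <- pca$scores[train_ix, 1:k, drop = FALSE]
      te <- pca$scores[test_ix, 1:k, drop = FALSE]
    }
    ytr <- truth_lab[train_ix]
    absent <- setdiff(canonical, unique(ytr))
    if (length(absent) > 0) {
      stop("label(s) ", paste(absent, collapse = ", "),
           " absent from training fold for held-out subject ", sub)
    }
    if (balanced) {
      bix <- .with_seed(seed + .string_seed(sub), {
        unlist(lapply(canonical, function(lv) {
          pool <- which(ytr == lv)
          pool[sample.int(length(pool), n_resample_per_label, replace = TRUE)]
        }))
      })
      tr <- tr[bix, , drop = FALSE]
      ytr <- ytr[bix]
    }
    model <- fit_multinomial(tr, ytr, levels = canonical)
    pred[test_ix] <- predict_wta(model, te)$labels
  }
  correct <- as.integer(pred == truth_lab)
  acc <- tapply(correct, meta$session_id, mean)
  per_session <- data.frame(session_id = names(acc), accuracy = as.numeric(acc),
                            row.names = NULL, stringsAsFactors = FALSE)
  # keep session order as first appearance in meta
  per_session <- per_session[match(unique(meta$session_id),
                                   per_session$session_id), ]
  rownames(per_session) <- NULL
  conf_counts <- table(factor(truth_lab, levels = canonical),
                       factor(pred, levels = canonical))
  confusion <- 100 * prop.table(conf_counts, margin = 1)
  structure(list(
    task = task,
    per_session_accuracy = per_session,
    overall_mean = mean(per_session$accuracy),
    overall_sd = sd(per_session$accuracy),
    confusion = as.matrix(confusion),
    chance = 1 / length(canonical),
    predictions = data.frame(meta[, c("froi", "subject_id", "session_id")],
                             truth = truth_lab, predicted = pred,
                             correct = correct, stringsAsFactors = FALSE),
    n_components = k, balanced = balanced
  ), class = "classification_result")
}

#' @exportS3Method
print.classification_result <- function(x, ...) {
  cat(sprintf("LOO classification of %s: mean accuracy %.1f%% +/- %.1f%% (chance %.1f%%)\n",
              x$task, 100 * x$overall_mean, 100 * x$overall_sd, 100 * x$chance))
  invisible(x)
}

#' Compare classification tasks by binomial logistic regression
#'
#' Models per-prediction correctness (0/1) on the classification task and
#' reports pairwise odds ratios with Wald 95% CIs.
#'
#' @param results list of `classification_result`s.
#' @return data.frame: task_a, task_b, or (odds of a correct prediction in
#'   task_a relative to task_b), ci_lo, ci_hi, p.
#' @export
compare_tasks <- function(results) {
  stopifnot(length(results) >= 2)
  dat <- do.call(rbind, lapply(results, function(r)
    data.frame(task = r$task, correct = r$predictions$correct,
               stringsAsFactors = FALSE)))
  tasks <- unique(dat$task)
  out <- list()
  for (i in seq_along(tasks)) for (j in seq_along(tasks)) {
    if (i >= j) next
    sub <- dat[dat$task %in% tasks[c(i, j)], ]
    bl <- binomial_logit(sub$correct,
                         factor(sub$task, levels = tasks[c(j, i)]))
    o <- bl$odds_ratios
    out[[length(out) + 1L]] <- data.frame(
      task_a = tasks[i], task_b = tasks[j], or = o$or,
      ci_lo = o$ci_lo, ci_hi = o$ci_hi, p = o$p, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Session accuracies against chance
#'
#' One-sample t test of per-session accuracies against the chance level, with
#' Cohen's d = (mean - chance) / SD.
#'
#' @param result a `classification_result` (or numeric accuracy vector).
#' @param chance chance level; defaults to the result's `1/#classes`.
#' @return list: t, df, p, cohens_d, ci, mean, sd.
#' @export
accuracy_vs_chance <- function(result, chance = NULL) {
  acc <- if (inherits(result, "classification_result")) {
    if (is.null(chance)) chance <- result$chance
    result$per_session_accuracy$accuracy
  } else {
    stopifnot(!is.null(chance))
    result
  }
  tt <- t_test_d(acc, mu = chance)
  list(t = tt$t, df = tt$df, p = tt$p, cohens_d = tt$cohens_d, ci = tt$ci,
       mean = tt$estimate, sd = tt$sd)
}
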