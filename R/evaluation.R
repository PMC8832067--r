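# Threshold-free and recall-first metrics, plus episode-grouped k-fold
# cross-validation.

#' Area under the ROC curve by pair counting
#'
#' Computes AUC as the probability that a uniformly random crash sample
#' receives a higher score than a uniformly random non-crash sample, with
#' ties counting one half -- the rank-statistic (Mann-Whitney) form, not a
#' curve integration.
#'
#' @param predictions a `prediction_records` data.frame (or any data.frame
#'   with `score` and `label` columns).
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(data.frame(score = c(0.8, 0.6, 0.4, 0.2), label = c(1, 0, 1, 0)))
#' @export
auc_score <- function(predictions) {
  y <- predictions$label
  s <- predictions$score
  stopifnot(all(is.finite(s)))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: need both classes present (",
         n_pos, " positives, ", n_neg, " negatives)")
  }
  r <- rank(s)                        # midranks handle ties as 1/2
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision at a target recall
#'
#' Sweeps decision thresholds over the observed scores (predicted crash iff
#' `score >= threshold`; no interpolation) and returns, among all cuts whose
#' recall reaches `target_recall`, the one with the highest precision
#' (ties broken toward the larger threshold).  Because the qualifying cut
#' sets are nested, the returned precision is non-increasing in the target.
#' With the default target 0.95 this is the P\@0.95R model-selection
#' criterion: minimize missed crashes first, then compare models by
#' precision.
#'
#' @param predictions data.frame with `score` and `label`.
#' @param target_recall required recall in (0, 1\] (default 0.95).
#' @return A list with `precision`, `threshold`, `recall` (achieved), and
#'   `degenerate` (TRUE when even the all-positive cut was needed).
#' @examples
#' pr <- data.frame(score = c(0.9, 0.8, 0.4, 0.7, 0.2),
#'                  label = c(1, 1, 1, 0, 0))
#' precision_at_recall(pr, 0.95)   # threshold 0.4, precision 0.75
#' @export
precision_at_recall <- function(predictions, target_recall = 0.95) {
  y <- predictions$label
  s <- predictions$score
  if (target_recall <= 0 || target_recall > 1) {
    stop("target_recall must be in (0, 1]")
  }
  n_pos <- sum(y == 1)
  if (n_pos == 0) stop("no positive samples: recall undefined")
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]; ss <- s[ord]
  tp <- cumsum(ys == 1)
  fp <- cumsum(ys == 0)
  # candidate cuts: the last index of each tied score block
  last_of_block <- c(ss[-1] != ss[-length(ss)], TRUE)
  cand <- which(last_of_block)
  rec <- tp[cand] / n_pos
  ok <- which(rec >= target_recall)
  if (length(ok) == 0) {
    # unreachable for target <= 1: the all-positive cut has recall 1
    return(list(precision = mean(y == 1), threshold = -Inf, recall = 1,
                degenerate = TRUE))
  }
  prec <- tp[cand[ok]] / (tp[cand[ok]] + fp[cand[ok]])
  i <- cand[ok[which.max(prec)]]      # best precision; ties -> larger cut
  list(precision = tp[i] / (tp[i] + fp[i]),
       threshold = ss[i],
       recall = tp[i] / n_pos,
       degenerate = FALSE)
}

#' Confusion counts at a threshold
#'
#' Predicted crash iff `score >= threshold`.
#'
#' @param predictions data.frame with `score` and `label`.
#' @param threshold finite decision threshold (or `-Inf`/`Inf`).
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_at <- function(predictions, threshold) {
  stopifnot(!is.na(threshold))
  pred <- predictions$score >= threshold
  y <- predictions$label == 1
  c(tp = sum(pred & y), fp = sum(pred & !y),
    fn = sum(!pred & y), tn = sum(!pred & !y))
}

#' Attach prediction types (TP/FP/FN/TN) at a threshold
#'
#' @inheritParams confusion_at
#' @return `predictions` with a `type` factor column.
#' @export
classify_predictions <- function(predictions, threshold) {
  pred <- predictions$score >= threshold
  y <- predictions$label == 1
  predictions$type <- factor(
    ifelse(pred & y, "TP", ifelse(pred & !y, "FP",
                                  ifelse(!pred & y, "FN", "TN"))),
    levels = c("FN", "FP", "TN", "TP"))
  predictions
}

#' Episode-grouped k-fold cross-validation
#'
#' Trains one model per fold on the other k-1 folds and evaluates it on the
#' held-out fold; folds are episode-level (from [assign_folds()]), so no
#' episode contributes windows to both sides.  Channel standardization
#' statistics are recomputed from each fold's training windows.  A fraction
#' of training episodes is carved out as the early-stopping validation set.
#' Folds whose held-out windows contain a single class are skipped with a
#' warning.
#'
#' @param windows a `window_set` over the training pool.
#' @param folds data.frame `episode_id`/`fold` from [assign_folds()].
#' @param spec a [model_spec()].
#' @param target_recall recall target for the precision metric.
#' @param es_fraction fraction of training episodes used for early stopping.
#' @param verbose print per-fold progress.
#' @return An `eval_report`: `per_fold` (fold, auc, precision, threshold,
#'   recall, n_test), `mean_auc`, `sd_auc`, `mean_precision`,
#'   `sd_precision` (sample SD over folds), `predictions` (pooled held-out
#'   `prediction_records` with `fold`), `best_fold`, `best_model`,
#'   `window_ms`, `advance_ms`, `family`.
#' @export
cross_validate <- function(windows, folds, spec, target_recall = 0.95,
                           es_fraction = 0.15, verbose = FALSE) {
  stopifnot(inherits(windows, "window_set"), inherits(spec, "model_spec"))
  if (!all(c("episode_id", "fold") %in% names(folds))) {
    stop("folds must have columns episode_id and fold")
  }
  k <- length(unique(folds$fold))
  if (k < 2) stop("need at least 2 folds")
  fold_of <- folds$fold[match(windows$meta$episode_id, folds$episode_id)]
  if (anyNA(fold_of)) stop("windows reference episodes missing from folds")
  per_fold <- NULL
  preds_all <- NULL
  models <- vector("list", k)
  fold_levels <- sort(unique(folds$fold))
  for (fi in seq_along(fold_levels)) {
    f <- fold_levels[fi]
    te <- windows[fold_of == f]
    tr <- windows[fold_of != f]
    if (length(unique(te$y)) < 2) {
      warning("fold ", f, " has a single class in its held-out windows; skipped")
      next
    }
    st <- channel_stats(tr)
    tr_s <- standardize_windows(tr, st)
    te_s <- standardize_windows(te, st)
    # episode-level early-stopping split inside the training folds;
    # es_fraction = 0 trains flat on all k-1 folds for spec$max_epochs
    if (es_fraction > 0) {
      tr_eps <- unique(tr_s$meta$episode_id)
      set.seed(spec$seed + 100L + fi)
      n_es <- max(1L, floor(es_fraction * length(tr_eps)))
      es_eps <- sample(tr_eps, n_es)
      es_mask <- tr_s$meta$episode_id %in% es_eps
      va <- tr_s[es_mask]
      tr_fit <- tr_s[!es_mask]
      if (length(unique(va$y)) < 2) va <- NULL
    } else {
      va <- NULL
      tr_fit <- tr_s
    }
    model <- build_model(spec, dim(windows$X)[2], dim(windows$X)[3])
    model <- train_model(model, tr_fit, va)
    pr <- predict(model, te_s)
    pr$fold <- f
    a <- auc_score(pr)
    pa <- precision_at_recall(pr, target_recall)
    per_fold <- rbind(per_fold, data.frame(
      fold = f, auc = a, precision = pa$precision,
      threshold = pa$threshold, recall = pa$recall,
      n_test = nrow(pr)))
    preds_all <- rbind(preds_all, pr)
    models[[fi]] <- model
    if (verbose) {
      message(sprintf("fold %s: AUC %.4f  P@%.2fR %.4f", f, a,
                      target_recall, pa$precision))
    }
  }
  if (is.null(per_fold)) stop("all folds skipped: no usable evaluation")
  best_i <- which.max(per_fold$auc)
  structure(list(
    per_fold = per_fold,
    mean_auc = mean(per_fold$auc), sd_auc = stats::sd(per_fold$auc),
    mean_precision = mean(per_fold$precision),
    sd_precision = stats::sd(per_fold$precision),
    target_recall = target_recall,
    predictions = preds_all,
    best_fold = per_fold$fold[best_i],
    best_model = models[[best_i]],
    window_ms = windows$window_ms, advance_ms = windows$advance_ms,
    family = spec$family
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %s, window %g ms, advance %g ms, %d folds\n",
              x$family, x$window_ms, x$advance_ms, nrow(x$per_fold)))
  cat(sprintf("  AUC  %.4f +/- %.4f\n", x$mean_auc, x$sd_auc))
  cat(sprintf("  P@%.2fR %.4f +/- %.4f (best fold %s)\n",
              x$target_recall, x$mean_precision, x$sd_precision,
              x$best_fold))
  invisible(x)
}
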