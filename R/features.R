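#' Gradient-boosting gain importances
#'
#' Fits a small gradient-boosted tree ensemble (xgboost, multi-class
#' softprob) and returns each feature's total split gain, normalized to sum
#' to 1. Features the booster never splits on (including constant columns)
#' score 0.
#'
#' @param data Data frame of numeric features.
#' @param labels Class labels (>= 2 classes present).
#' @param seed Integer seed (booster is run single-threaded for
#'   reproducibility).
#' @param nrounds Boosting rounds. Default 50.
#' @return Named numeric vector of normalized gains, in the original column
#'   order, summing to 1.
#' @export
gain_importances <- function(data, labels, seed = 1L, nrounds = 50L) {
  data <- as.data.frame(data)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  X <- as.matrix(data)
  y <- match(labels, classes) - 1L
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(classes),
                  max_depth = 4, eta = 0.3, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = booster)
  scores <- stats::setNames(rep(0, ncol(data)), colnames(data))
  scores[imp$Feature] <- imp$Gain
  if (sum(scores) > 0) scores <- scores / sum(scores)
  scores
}

#' Retain features whose normalized gain exceeds a threshold
#'
#' Strict inequality: a score exactly at `tau` is dropped. If nothing
#' survives, a warning is raised and the top two features by score are
#' returned instead.
#'
#' @param scores Named numeric score vector (e.g. [gain_importances()]).
#' @param tau Threshold on the normalized gain. Default 0.06.
#' @return Character vector of retained feature names, original order
#'   preserved.
#' @export
threshold_filter <- function(scores, tau = 0.06) {
  keep <- names(scores)[scores > tau]
  if (!length(keep)) {
    warning("no feature exceeds the gain threshold; falling back to the top 2 by score",
            call. = FALSE)
    keep <- names(sort(scores, decreasing = TRUE))[seq_len(min(2L, length(scores)))]
    keep <- names(scores)[names(scores) %in% keep]
  }
  keep
}

#' Sequential forward selection on validation accuracy
#'
#' Greedy forward loop: at every step the candidate whose inclusion
#' maximizes validation accuracy is added; the loop stops as soon as no
#' candidate strictly improves it. Ties break by gain-score rank (higher
#' first) and then by name, making the trajectory deterministic. Jointly
#' informative feature pairs can be missed: the search is forward-only by
#' design.
#'
#' @param candidates Character vector of candidate feature names.
#' @param train_data,train_labels Training records and labels.
#' @param val_data,val_labels Validation records and labels (disjoint).
#' @param model_builder Function `(features, train_data, train_labels,
#'   val_data, val_labels, seed)` returning a validation accuracy. Default:
#'   a flat belief rule base trained with a reduced DE-PSO budget (G = 40).
#' @param gain_scores Optional named scores used for tie-breaking.
#' @param seed Integer seed threaded into the builder.
#' @return Object of class `sfs_report`: list with `final_subset`,
#'   `trajectory` (data frame: step, feature, val_accuracy) and
#'   `candidates`.
#' @export
sequential_forward_select <- function(candidates, train_data, train_labels,
                                      val_data, val_labels,
                                      model_builder = NULL,
                                      gain_scores = NULL, seed = 1L) {
  if (!length(candidates)) stop("`candidates` must be non-empty", call. = FALSE)
  if (is.null(model_builder)) model_builder <- brb_sfs_builder()
  rank_of <- if (is.null(gain_scores)) {
    stats::setNames(rep(0, length(candidates)), candidates)
  } else {
    gain_scores[candidates]
  }
  # deterministic evaluation order: by gain rank (desc), then name
  order_candidates <- function(cs) cs[order(-rank_of[cs], cs)]

  selected <- character(0)
  best_acc <- -Inf
  trajectory <- data.frame(step = integer(0), feature = character(0),
                           val_accuracy = numeric(0))
  remaining <- candidates
  step <- 0L
  repeat {
    remaining_ord <- order_candidates(remaining)
    accs <- vapply(remaining_ord, function(f) {
      model_builder(c(selected, f), train_data, train_labels,
                    val_data, val_labels, seed + step)
    }, numeric(1))
    i_best <- which.max(accs)  # first max wins: ties fall to higher rank/name order
    if (accs[i_best] <= best_acc && step > 0L) break
    if (step == 0L || accs[i_best] > best_acc) {
      step <- step + 1L
      selected <- c(selected, remaining_ord[i_best])
      best_acc <- accs[i_best]
      trajectory <- rbind(trajectory,
                          data.frame(step = step, feature = remaining_ord[i_best],
                                     val_accuracy = best_acc))
      remaining <- setdiff(remaining, selected)
      if (!length(remaining)) break
    } else {
      break
    }
  }
  structure(list(final_subset = selected, trajectory = trajectory,
                 candidates = candidates),
            class = "sfs_report")
}

#' Default SFS inner model: a small flat BRB
#'
#' Builds and trains a flat conjunctive rule base on the given features with
#' a reduced DE-PSO budget, and returns validation accuracy.
#'
#' @param n_refs Reference values per attribute. Default 3.
#' @param config An [optimizer_config()]; default uses a reduced budget
#'   (G = 40, NP = 20) appropriate for a wrapper criterion.
#' @return A builder function for [sequential_forward_select()].
#' @export
brb_sfs_builder <- function(n_refs = 3,
                            config = optimizer_config(NP = 20, G = 40)) {
  function(features, train_data, train_labels, val_data, val_labels, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    rb <- brb_rulebase(frame_from_data(train_data, features, n_refs),
                       sort(unique(as.character(train_labels))))
    fit <- train_rulebase(rb, train_data[, features, drop = FALSE], train_labels,
                          config = cfg)
    out <- infer_batch(fit, as.data.frame(val_data)[, features, drop = FALSE])
    mean(decide_batch(out$masses) == val_labels)
  }
}

#' Two-stage feature selection report
#'
#' Stage 1 scores all features by normalized boosting gain and keeps those
#' above the threshold; stage 2 runs sequential forward selection over the
#' survivors on validation accuracy.
#'
#' @inheritParams sequential_forward_select
#' @param tau Gain threshold. Default 0.06.
#' @param nrounds Boosting rounds for the gain stage.
#' @return Object of class `feature_selection_report`: list with
#'   `gain_scores`, `retained_after_threshold`, `sfs_trajectory`,
#'   `final_subset`.
#' @export
select_features <- function(train_data, train_labels, val_data, val_labels,
                            tau = 0.06, model_builder = NULL, seed = 1L,
                            nrounds = 50L) {
  scores <- gain_importances(train_data, train_labels, seed = seed,
                             nrounds = nrounds)
  retained <- threshold_filter(scores, tau)
  sfs <- sequential_forward_select(retained, train_data, train_labels,
                                   val_data, val_labels,
                                   model_builder = model_builder,
                                   gain_scores = scores, seed = seed)
  structure(list(gain_scores = scores,
                 retained_after_threshold = retained,
                 sfs_trajectory = sfs$trajectory,
                 final_subset = sfs$final_subset),
            class = "feature_selection_report")
}

#' @export
print.feature_selection_report <- function(x, ...) {
  cat("<feature_selection_report>\n")
  cat("  gain > threshold:", paste(x$retained_after_threshold, collapse = ", "), "\n")
  cat("  final subset:    ", paste(x$final_subset, collapse = ", "), "\n")
  invisible(x)
}
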