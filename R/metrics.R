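#' Classification metrics report
#'
#' Accuracy, per-class precision/recall/F1 and their macro (unweighted)
#' averages, plus the true-by-predicted confusion matrix. A class with zero
#' predicted support gets precision 0 (with a warning), so macro averages
#' stay defined.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param labels Optional class ordering; default: sorted union.
#' @return Object of class `metrics_report`: list with `accuracy`,
#'   `per_class` (data frame), `macro_precision`, `macro_recall`,
#'   `macro_f1`, `confusion` (matrix, rows = true).
#' @export
compute_metrics <- function(true_labels, predicted_labels, labels = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have the same length", call. = FALSE)
  }
  if (!length(true_labels)) stop("need at least one record", call. = FALSE)
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (is.null(labels)) labels <- sort(unique(c(true_labels, predicted_labels)))
  tf <- factor(true_labels, levels = labels)
  pf <- factor(predicted_labels, levels = labels)
  confusion <- table(true = tf, predicted = pf)
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  true_n <- rowSums(confusion)
  if (any(pred_n == 0 & true_n > 0)) {
    warning("class(es) never predicted; precision reported as 0: ",
            paste(labels[pred_n == 0 & true_n > 0], collapse = ", "),
            call. = FALSE)
  }
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    accuracy = sum(tp) / length(true_labels),
    per_class = data.frame(class = labels, support = as.integer(true_n),
                           precision = as.numeric(precision),
                           recall = as.numeric(recall), f1 = as.numeric(f1),
                           row.names = NULL),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    confusion = unclass(confusion)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Ablation study over model variants
#'
#' Trains and evaluates four variants on byte-identical stratified splits:
#' \describe{
#'   \item{flat_de}{single flat rule base, DE only (baseline)}
#'   \item{flat_depso}{single flat rule base, cascaded DE-PSO}
#'   \item{hier_de}{dual-layer hierarchy, DE only}
#'   \item{hier_depso}{dual-layer hierarchy, cascaded DE-PSO (full model)}
#' }
#' The flat variants use `flat_features` (default: the six survey features,
#' giving the 3^6 = 729 rule pattern); the hierarchical variants use
#' `feature_subsets` (default subsets give 3^2+3^3+3^3+3^4 = 144 rules).
#'
#' @param dataset A [brb_dataset()] with >= 3 records per fine class.
#' @param config An [optimizer_config()]; DE-only variants move the whole
#'   generation budget into the DE stage.
#' @param flat_features Features of the flat variants.
#' @param feature_subsets Hierarchy subsets (see [build_hierarchy()]).
#' @param split_seed Seed of the shared 6:2:2 split.
#' @param n_refs Reference values per attribute.
#' @return Object of class `ablation_report`: list with `metrics` (one
#'   [compute_metrics()] report per variant), `rule_counts`, `split`, and
#'   `split_digest` (checksum certifying all variants shared the split).
#' @export
run_ablation <- function(dataset, config = optimizer_config(),
                         flat_features = c("gender", "age", "height",
                                           "weight", "fcvc", "ncp"),
                         feature_subsets = default_feature_subsets(dataset$scheme),
                         split_seed = 2024L, n_refs = 3) {
  stopifnot(inherits(dataset, "brb_dataset"))
  sp <- stratified_split(dataset$fine_labels, seed = split_seed)
  split_digest <- sum(c(sp$train, 2L * sp$validation, 3L * sp$test))
  rec <- dataset$records
  tr <- rec[sp$train, , drop = FALSE]
  va <- rec[sp$validation, , drop = FALSE]
  te <- rec[sp$test, , drop = FALSE]
  y_tr <- dataset$fine_labels[sp$train]
  y_va <- dataset$fine_labels[sp$validation]
  y_te <- dataset$fine_labels[sp$test]
  scheme <- dataset$scheme

  cfg_de <- config
  cfg_de$de_fraction <- 1            # DE-only variants: full budget to DE

  fit_flat <- function(cfg) {
    rb <- brb_rulebase(frame_from_data(tr, flat_features, n_refs),
                       scheme$fine_labels)
    fit <- train_rulebase(rb, tr[, flat_features, drop = FALSE], y_tr,
                          va[, flat_features, drop = FALSE], y_va, cfg)
    pred <- decide_batch(infer_batch(fit, te[, flat_features, drop = FALSE])$masses)
    list(metrics = compute_metrics(y_te, pred, scheme$fine_labels),
         rules = nrow(fit$antecedents))
  }
  fit_hier <- function(cfg) {
    model <- build_hierarchy(tr, scheme, feature_subsets, n_refs,
                             fine_labels = y_tr)
    model <- train_hierarchy(model, tr, y_tr, va, y_va, cfg)
    pred <- predict(model, te)$fine
    rules <- nrow(model$coarse$antecedents) +
      sum(vapply(model$submodules, function(s) nrow(s$antecedents), numeric(1)))
    list(metrics = compute_metrics(y_te, pred, scheme$fine_labels),
         rules = rules)
  }

  variants <- list(
    flat_de = fit_flat(cfg_de),
    flat_depso = fit_flat(config),
    hier_de = fit_hier(cfg_de),
    hier_depso = fit_hier(config)
  )
  structure(list(
    metrics = lapply(variants, `[[`, "metrics"),
    rule_counts = vapply(variants, `[[`, numeric(1), "rules"),
    split = sp,
    split_digest = split_digest
  ), class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report>\n")
  for (v in names(x$metrics)) {
    cat(sprintf("  %-11s rules %4d  accuracy %.4f  macro-F1 %.4f\n", v,
                x$rule_counts[[v]], x$metrics[[v]]$accuracy,
                x$metrics[[v]]$macro_f1))
  }
  invisible(x)
}
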