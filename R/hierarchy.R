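#' Label scheme: fine classes, coarse groups and BMI thresholds
#'
#' Binds together the ordered fine class labels, the coarse groups they merge
#' into, the (total, surjective) fine-to-coarse merge map, and the strictly
#' increasing BMI breakpoints that carve the fine classes out of the BMI axis
#' (lower bound inclusive, upper exclusive; the last class is unbounded
#' above).
#'
#' @param fine_labels Ordered character vector of fine class labels.
#' @param coarse_labels Ordered character vector of coarse group labels.
#' @param merge_map Named character vector mapping every fine label to a
#'   coarse label; must be surjective onto `coarse_labels`.
#' @param bmi_thresholds Strictly increasing numeric breakpoints
#'   (kg/m^2), length `length(fine_labels) - 1`.
#' @return Object of class `label_scheme`.
#' @export
label_scheme <- function(fine_labels, coarse_labels, merge_map, bmi_thresholds) {
  fine_labels <- as.character(fine_labels)
  coarse_labels <- as.character(coarse_labels)
  if (!setequal(names(merge_map), fine_labels)) {
    stop("`merge_map` must map every fine label", call. = FALSE)
  }
  merge_map <- merge_map[fine_labels]
  if (!all(merge_map %in% coarse_labels)) {
    stop("`merge_map` values must be coarse labels", call. = FALSE)
  }
  if (!setequal(unique(merge_map), coarse_labels)) {
    stop("`merge_map` must be surjective onto the coarse labels", call. = FALSE)
  }
  bmi_thresholds <- as.numeric(bmi_thresholds)
  if (length(bmi_thresholds) != length(fine_labels) - 1 ||
      any(diff(bmi_thresholds) <= 0)) {
    stop("`bmi_thresholds` must be strictly increasing with one breakpoint between consecutive fine labels",
         call. = FALSE)
  }
  structure(list(fine_labels = fine_labels, coarse_labels = coarse_labels,
                 merge_map = merge_map, bmi_thresholds = bmi_thresholds),
            class = "label_scheme")
}

#' Default 7-class obesity label scheme
#'
#' Fine labels follow the WHO-style BMI bands: insufficient (< 18.5), normal
#' (18.5-25), overweight I/II (25-30, split at `overweight_split`), obesity
#' I (30-35), II (35-40), III (>= 40). Coarse groups merge these into Lean
#' (< 25), Overweight (25-30) and Obese (>= 30). The internal overweight I/II
#' boundary is not part of the WHO bands and is exposed as a parameter
#' (default: the 25-30 midpoint, 27.5).
#'
#' @param overweight_split BMI boundary between overweight levels I and II,
#'   strictly inside (25, 30). Default 27.5.
#' @return A [label_scheme()].
#' @export
obesity_scheme <- function(overweight_split = 27.5) {
  if (overweight_split <= 25 || overweight_split >= 30) {
    stop("`overweight_split` must lie strictly inside (25, 30)", call. = FALSE)
  }
  fine <- c("Insufficient weight", "Normal weight",
            "Overweight level I", "Overweight level II",
            "Obesity type I", "Obesity type II", "Obesity type III")
  coarse <- c("Lean", "Overweight", "Obese")
  merge <- stats::setNames(c("Lean", "Lean", "Overweight", "Overweight",
                             "Obese", "Obese", "Obese"), fine)
  label_scheme(fine, coarse, merge,
               c(18.5, 25, overweight_split, 30, 35, 40))
}

#' Fine obesity label from height and weight
#'
#' BMI = weight / height^2 (kg/m^2); the label is the BMI band containing the
#' value, lower bound inclusive.
#'
#' @param height Height in metres (> 0); vectorized.
#' @param weight Weight in kilograms (> 0); vectorized.
#' @param scheme A [label_scheme()]. Default [obesity_scheme()].
#' @return Character vector of fine labels.
#' @export
#' @examples
#' bmi_label(1.70, 49)   # Insufficient weight
#' bmi_label(1.70, 130)  # Obesity type III
bmi_label <- function(height, weight, scheme = obesity_scheme()) {
  stopifnot(inherits(scheme, "label_scheme"))
  if (any(!is.finite(height)) || any(!is.finite(weight)) ||
      any(height <= 0) || any(weight <= 0)) {
    stop("`height` and `weight` must be positive and finite", call. = FALSE)
  }
  bmi <- weight / height^2
  idx <- findInterval(bmi, scheme$bmi_thresholds) + 1L
  scheme$fine_labels[idx]
}

#' Merge a fine label into its coarse group
#'
#' @param fine_label Character vector of fine labels.
#' @param scheme A [label_scheme()].
#' @return Character vector of coarse labels.
#' @export
coarsen <- function(fine_label, scheme = obesity_scheme()) {
  stopifnot(inherits(scheme, "label_scheme"))
  unknown <- setdiff(unique(fine_label), scheme$fine_labels)
  if (length(unknown)) {
    stop("unknown fine label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(scheme$merge_map[fine_label])
}

#' Dual-layer (coarse-to-fine) belief rule base model
#'
#' A coarse rule base over the coarse groups routes each record to one fine
#' submodule per coarse label; each submodule is a rule base over the fine
#' labels of its group, on its own feature subset. Routing is hard: the fine
#' prediction is constrained to the routed group's labels.
#'
#' @param coarse A [brb_rulebase()] whose class labels are the scheme's
#'   coarse labels.
#' @param submodules Named list of [brb_rulebase()], keyed by coarse label;
#'   each submodule's class labels must be exactly the fine labels mapped to
#'   its coarse label.
#' @param scheme A [label_scheme()].
#' @return Object of class `dbrb_model`.
#' @export
dbrb_model <- function(coarse, submodules, scheme) {
  stopifnot(inherits(coarse, "brb_rulebase"), inherits(scheme, "label_scheme"))
  if (!setequal(coarse$class_labels, scheme$coarse_labels)) {
    stop("coarse rule base labels must equal the scheme's coarse labels", call. = FALSE)
  }
  if (!setequal(names(submodules), scheme$coarse_labels)) {
    stop("`submodules` must be keyed by exactly the coarse labels", call. = FALSE)
  }
  for (g in scheme$coarse_labels) {
    sm <- submodules[[g]]
    stopifnot(inherits(sm, "brb_rulebase"))
    expected <- scheme$fine_labels[scheme$merge_map == g]
    if (!identical(sm$class_labels, expected)) {
      stop(sprintf("submodule '%s' must classify exactly: %s", g,
                   paste(expected, collapse = ", ")), call. = FALSE)
    }
  }
  feature_subsets <- c(list(coarse = coarse$frame$attribute_names),
                       lapply(submodules, function(s) s$frame$attribute_names))
  structure(list(coarse = coarse, submodules = submodules[scheme$coarse_labels],
                 scheme = scheme, feature_subsets = feature_subsets),
            class = "dbrb_model")
}

#' @export
print.dbrb_model <- function(x, ...) {
  cat("<dbrb_model> coarse:", paste(x$coarse$frame$attribute_names, collapse = ", "),
      sprintf("(%d rules)\n", nrow(x$coarse$antecedents)))
  for (g in names(x$submodules)) {
    sm <- x$submodules[[g]]
    cat(sprintf("  %s: %s (%d rules) -> %s\n", g,
                paste(sm$frame$attribute_names, collapse = ", "),
                nrow(sm$antecedents),
                paste(sm$class_labels, collapse = " | ")))
  }
  invisible(x)
}

#' Route a record through the coarse layer
#'
#' Runs coarse forward inference and returns the decided coarse label with
#' the submodule it selects (hard routing).
#'
#' @param model A [dbrb_model()].
#' @param record Named list/vector supplying at least the coarse features.
#' @return List with `coarse_label`, `submodule` (a `brb_rulebase`) and the
#'   coarse `dist` ([belief_dist()]).
#' @export
route <- function(model, record) {
  stopifnot(inherits(model, "dbrb_model"))
  dist <- infer(model$coarse, record[model$coarse$frame$attribute_names])
  lab <- decide(dist, model$coarse$class_labels)
  list(coarse_label = lab, submodule = model$submodules[[lab]], dist = dist)
}

#' Predict fine labels with a dual-layer model
#'
#' Coarse inference decides the group; the routed submodule then decides the
#' fine label within that group. Both belief distributions are returned for
#' traceability. Because routing is hard, a coarse error confines the fine
#' prediction to the wrong branch's labels.
#'
#' @param object A [dbrb_model()].
#' @param newdata Data frame supplying the union of all modules' features.
#' @param ... Unused.
#' @return List with `fine` (labels), `coarse` (labels), `coarse_masses`
#'   (n x 3 matrix), `fine_masses` (n x 7 matrix over all fine labels; zero
#'   outside the routed group), `coarse_residual`, `fine_residual`.
#' @export
predict.dbrb_model <- function(object, newdata, ...) {
  model <- object
  newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  co <- infer_batch(model$coarse,
                    newdata[, model$coarse$frame$attribute_names, drop = FALSE])
  coarse_lab <- decide_batch(co$masses)
  fine_lab <- character(n)
  fine_masses <- matrix(0, n, length(model$scheme$fine_labels),
                        dimnames = list(NULL, model$scheme$fine_labels))
  fine_residual <- numeric(n)
  for (g in model$scheme$coarse_labels) {
    sel <- which(coarse_lab == g)
    if (!length(sel)) next
    sm <- model$submodules[[g]]
    fo <- infer_batch(sm, newdata[sel, sm$frame$attribute_names, drop = FALSE])
    fine_lab[sel] <- decide_batch(fo$masses)
    fine_masses[sel, sm$class_labels] <- fo$masses
    fine_residual[sel] <- fo$residual
  }
  list(fine = fine_lab, coarse = coarse_lab,
       coarse_masses = co$masses, fine_masses = fine_masses,
       coarse_residual = co$residual, fine_residual = fine_residual)
}

#' Single-record dual-layer prediction with traceable distributions
#'
#' @param model A [dbrb_model()].
#' @param record Named list/vector of attribute values.
#' @return List with `fine_label`, `coarse_label`, `coarse_dist` and
#'   `fine_dist` (both [belief_dist()]).
#' @export
dbrb_predict <- function(model, record) {
  r <- route(model, record)
  sm <- r$submodule
  fine_dist <- infer(sm, record[sm$frame$attribute_names])
  list(fine_label = decide(fine_dist, sm$class_labels),
       coarse_label = r$coarse_label,
       coarse_dist = r$dist, fine_dist = fine_dist)
}

#' Total rule count of a modular hierarchy
#'
#' Sum over modules of \eqn{R^{size_m}}: with the default subset sizes
#' (2, 3, 3, 4) and R = 3 this gives 144 rules, against 729 for a flat
#' 6-attribute base.
#'
#' @param feature_subset_sizes Integer vector of per-module feature counts.
#' @param refs_per_attribute Reference values per attribute (scalar R).
#' @return Total rule count.
#' @export
#' @examples
#' hierarchical_rule_count(c(2, 3, 3, 4), 3)  # 144
hierarchical_rule_count <- function(feature_subset_sizes, refs_per_attribute = 3) {
  if (any(feature_subset_sizes < 1)) stop("subset sizes must be >= 1", call. = FALSE)
  sum(vapply(feature_subset_sizes, rule_count,
             numeric(1), refs_per_attribute = refs_per_attribute))
}

#' Default feature subsets for the obesity hierarchy
#'
#' Coarse layer: height, weight. Submodule A (Lean): height, weight, NCP.
#' Submodule B (Overweight): age, height, weight. Submodule C (Obese):
#' gender, height, weight, FCVC. Fully overridable when constructing models.
#'
#' @param scheme A [label_scheme()]; subset names follow its coarse labels.
#' @return Named list of character vectors (`coarse` plus one per group).
#' @export
default_feature_subsets <- function(scheme = obesity_scheme()) {
  stats::setNames(
    list(c("height", "weight"),
         c("height", "weight", "ncp"),
         c("age", "height", "weight"),
         c("gender", "height", "weight", "fcvc")),
    c("coarse", scheme$coarse_labels)
  )
}

#' Build an untrained dual-layer model from data
#'
#' Reference frames are placed on the training data (equally spaced over each
#' attribute's observed range); all rule bases start with uniform beliefs,
#' unit rule weights and unit attribute weights. When `fine_labels` are
#' supplied, each submodule's frame spans only the attribute range of its own
#' coarse group's records — a submodule resolves its local range instead of
#' compressing it into one cell of the global range.
#'
#' @param data Data frame of numeric features covering the union of subsets.
#' @param scheme A [label_scheme()].
#' @param feature_subsets Named list (`coarse` plus one entry per coarse
#'   label). Default [default_feature_subsets()].
#' @param n_refs Reference values per attribute. Default 3.
#' @param fine_labels Optional fine labels of `data`, used to scope each
#'   submodule's frame to its own group's records.
#' @return An untrained [dbrb_model()].
#' @export
build_hierarchy <- function(data, scheme = obesity_scheme(),
                            feature_subsets = default_feature_subsets(scheme),
                            n_refs = 3, fine_labels = NULL) {
  needed <- c("coarse", scheme$coarse_labels)
  if (!all(needed %in% names(feature_subsets))) {
    stop("`feature_subsets` must name 'coarse' and every coarse label", call. = FALSE)
  }
  data <- as.data.frame(data)
  coarse_lab <- if (!is.null(fine_labels)) coarsen(fine_labels, scheme)
  coarse <- brb_rulebase(frame_from_data(data, feature_subsets$coarse, n_refs),
                         scheme$coarse_labels)
  subs <- lapply(scheme$coarse_labels, function(g) {
    d <- if (is.null(coarse_lab)) data else data[coarse_lab == g, , drop = FALSE]
    brb_rulebase(frame_from_data(d, feature_subsets[[g]], n_refs),
                 scheme$fine_labels[scheme$merge_map == g])
  })
  names(subs) <- scheme$coarse_labels
  dbrb_model(coarse, subs, scheme)
}

#' Write / read a hierarchy configuration (YAML)
#'
#' The configuration records the label scheme (fine/coarse labels, merge map,
#' BMI thresholds), the per-module feature subsets and the reference count,
#' so a model structure can be rebuilt on any dataset.
#'
#' @param scheme A [label_scheme()].
#' @param feature_subsets Named list of feature subsets.
#' @param n_refs Reference values per attribute.
#' @param path File path.
#' @return `write_hierarchy_config()` returns `path` invisibly;
#'   `read_hierarchy_config()` returns a list with `scheme`,
#'   `feature_subsets`, `n_refs`.
#' @export
write_hierarchy_config <- function(scheme, feature_subsets, n_refs, path) {
  doc <- list(
    fine_labels = scheme$fine_labels,
    coarse_labels = scheme$coarse_labels,
    merge_map = as.list(scheme$merge_map),
    bmi_thresholds = scheme$bmi_thresholds,
    feature_subsets = feature_subsets,
    n_refs = n_refs
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_hierarchy_config
#' @export
read_hierarchy_config <- function(path) {
  doc <- yaml::read_yaml(path)
  scheme <- label_scheme(doc$fine_labels, doc$coarse_labels,
                         unlist(doc$merge_map), doc$bmi_thresholds)
  list(scheme = scheme,
       feature_subsets = lapply(doc$feature_subsets, unlist),
       n_refs = doc$n_refs)
}
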