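#' Class-conditional probabilities for the dietary survey variables
#'
#' Defaults encode the effect directions the model is meant to detect:
#' vegetable-consumption frequency (FCVC, levels 1-3) shifts downward with
#' increasing obesity severity, and the number of daily main meals (NCP,
#' levels 1-4) separates insufficient from normal weight (few meals vs
#' regular three). Rows are fine classes in scheme order.
#'
#' @name synthetic-probabilities
#' @keywords internal
NULL

.default_fcvc_probs <- matrix(c(
  0.10, 0.30, 0.60,   # Insufficient weight
  0.10, 0.30, 0.60,   # Normal weight
  0.15, 0.40, 0.45,   # Overweight level I
  0.20, 0.45, 0.35,   # Overweight level II
  0.30, 0.45, 0.25,   # Obesity type I
  0.45, 0.35, 0.20,   # Obesity type II
  0.60, 0.30, 0.10),  # Obesity type III
  nrow = 7, byrow = TRUE)

.default_ncp_probs <- matrix(c(
  0.55, 0.30, 0.10, 0.05,  # Insufficient weight: few meals
  0.05, 0.15, 0.60, 0.20,  # Normal weight: regular three meals
  0.10, 0.25, 0.45, 0.20,  # Overweight level I
  0.10, 0.25, 0.45, 0.20,  # Overweight level II
  0.10, 0.20, 0.40, 0.30,  # Obesity type I
  0.10, 0.20, 0.35, 0.35,  # Obesity type II
  0.10, 0.15, 0.35, 0.40), # Obesity type III
  nrow = 7, byrow = TRUE)

#' Generate a synthetic obesity cohort
#'
#' Emulates the statistical structure of the survey data the model assumes:
#' height is normal (mean 1.70 m, sd 0.09 m, truncated to plausible adult
#' stature), BMI is uniform within each fine class's band (the unbounded top
#' class is capped at 50 kg/m^2), weight follows as BMI x height^2, age is
#' uniform on 14-61 years, gender is Bernoulli(0.5) coded 0/1, and the
#' dietary variables FCVC (1-3) and NCP (1-4) are drawn from
#' class-conditional distributions with the effect directions described in
#' [synthetic-probabilities]. With `label_noise = 0` every record's BMI
#' reproduces its stored label exactly; with noise rate eps, an eps fraction
#' of labels is resampled uniformly from the other classes.
#'
#' @param n_per_class Records per fine class (>= 1).
#' @param seed Integer seed; the cohort is deterministic given it.
#' @param label_noise Noise rate eps in \[0, 1\). Default 0.
#' @param scheme A [label_scheme()] (7 fine classes).
#' @param bmi_cap Upper BMI bound for the top class. Default 50.
#' @param height_mean,height_sd Height distribution (m). Defaults 1.70/0.09.
#' @param age_range Age span (years). Default `c(14, 61)`.
#' @param fcvc_probs,ncp_probs Class-by-level probability matrices; rows
#'   follow `scheme$fine_labels`.
#' @return A [brb_dataset()] with columns `gender`, `age`, `height`,
#'   `weight`, `fcvc`, `ncp` (schema id `"synthetic"`).
#' @export
#' @examples
#' ds <- generate_cohort(10, seed = 1)
#' all(bmi_label(ds$records$height, ds$records$weight) == ds$fine_labels)
generate_cohort <- function(n_per_class = 100L, seed = 1L, label_noise = 0,
                            scheme = obesity_scheme(), bmi_cap = 50,
                            height_mean = 1.70, height_sd = 0.09,
                            age_range = c(14, 61),
                            fcvc_probs = .default_fcvc_probs,
                            ncp_probs = .default_ncp_probs) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  if (label_noise < 0 || label_noise >= 1) {
    stop("`label_noise` must lie in [0, 1)", call. = FALSE)
  }
  K <- length(scheme$fine_labels)
  edges <- c(10, scheme$bmi_thresholds, bmi_cap)  # K+1 interval edges
  if (any(diff(edges) <= 0)) stop("invalid BMI interval configuration", call. = FALSE)
  if (!all(dim(fcvc_probs) == c(K, 3)) || !all(dim(ncp_probs) == c(K, 4))) {
    stop("probability matrices must be classes x levels (3 for FCVC, 4 for NCP)",
         call. = FALSE)
  }
  set.seed(seed)
  n <- n_per_class * K
  cls <- rep(seq_len(K), each = n_per_class)
  height <- stats::rnorm(n, height_mean, height_sd)
  height <- pmin(pmax(height, height_mean - 3 * height_sd),
                 height_mean + 3 * height_sd)
  bmi <- stats::runif(n, edges[cls], edges[cls + 1L])
  weight <- bmi * height^2
  age <- stats::runif(n, age_range[1], age_range[2])
  gender <- stats::rbinom(n, 1L, 0.5)
  draw_level <- function(probs) {
    vapply(seq_len(n), function(i) {
      sample.int(ncol(probs), 1L, prob = probs[cls[i], ])
    }, integer(1))
  }
  fcvc <- draw_level(fcvc_probs)
  ncp <- draw_level(ncp_probs)
  labels <- scheme$fine_labels[cls]
  if (label_noise > 0) {
    flip <- stats::runif(n) < label_noise
    for (i in which(flip)) {
      labels[i] <- sample(setdiff(scheme$fine_labels, labels[i]), 1L)
    }
  }
  records <- data.frame(gender = gender, age = age, height = height,
                        weight = weight, fcvc = fcvc, ncp = ncp)
  brb_dataset(records, labels, scheme, schema_id = "synthetic")
}

#' Simulate records and labels from a known rule base
#'
#' Parameter-recovery harness: attribute values are uniform over the
#' frame's ranges and each record's label is sampled from the forward
#' inference masses (residual mass redistributed uniformly over classes).
#'
#' @param rulebase A [brb_rulebase()].
#' @param n Number of records.
#' @param seed Integer seed.
#' @return List with `records` (data frame) and `labels` (character).
#' @export
generate_from_rulebase <- function(rulebase, n, seed = 1L) {
  stopifnot(inherits(rulebase, "brb_rulebase"))
  set.seed(seed)
  attrs <- rulebase$frame$attribute_names
  lo <- vapply(rulebase$frame$ranges, `[`, numeric(1), 1L)
  hi <- vapply(rulebase$frame$ranges, `[`, numeric(1), 2L)
  records <- as.data.frame(lapply(stats::setNames(seq_along(attrs), attrs),
                                  function(j) stats::runif(n, lo[j], hi[j])))
  out <- infer_batch(rulebase, records)
  N <- ncol(out$masses)
  prob <- out$masses + out$residual / N
  labels <- vapply(seq_len(n), function(i) {
    sample(rulebase$class_labels, 1L, prob = prob[i, ])
  }, character(1))
  list(records = records, labels = labels)
}

#' Known-truth recovery benchmark rule base
#'
#' A crisp 2-attribute, 3-reference, 2-class generating rule base used for
#' simulate-then-refit experiments: both attributes span \[0, 1\] with
#' reference values (0, 0.93, 1), beliefs are one-hot, and the positive
#' class occupies the rules whose antecedent touches the top reference of
#' either attribute. The high middle reference keeps the class-mixing band
#' narrow, so sampled labels are nearly deterministic over most of the
#' input space and refitting can approach the generator's accuracy.
#'
#' @return A [brb_rulebase()] with classes `"neg"`, `"pos"`.
#' @export
recovery_rulebase <- function() {
  fr <- brb_frame(list(x = c(0, 0.93, 1), y = c(0, 0.93, 1)))
  ante <- as.matrix(expand.grid(1:3, 1:3))
  pos <- ante[, 1] == 3 | ante[, 2] == 3
  brb_rulebase(fr, c("neg", "pos"),
               beta = cbind(neg = as.numeric(!pos), pos = as.numeric(pos)))
}

#' Simulate-then-refit parameter recovery experiment
#'
#' Simulates labelled records from [recovery_rulebase()], trains a fresh
#' rule base of the same structure with the cascaded DE-PSO strategy, and
#' evaluates held-out accuracy.
#'
#' @param seed Integer seed driving both simulation and training.
#' @param n_train,n_test Training / held-out record counts (600 / 200).
#' @param config An [optimizer_config()] (training seed is derived from
#'   `seed`).
#' @return List: `accuracy` (held-out), `bayes_accuracy` (the generating
#'   rule base's own held-out accuracy), `history` (fitness trace), and
#'   `fit` (the trained rule base).
#' @export
recovery_experiment <- function(seed = 1L, n_train = 600L, n_test = 200L,
                                config = optimizer_config()) {
  gen <- recovery_rulebase()
  sim <- generate_from_rulebase(gen, n_train + n_test, seed = seed)
  tr_i <- seq_len(n_train)
  te_i <- n_train + seq_len(n_test)
  config$seed <- as.integer(seed + 1L)
  fit <- train_rulebase(brb_rulebase(gen$frame, gen$class_labels),
                        sim$records[tr_i, ], sim$labels[tr_i], config = config)
  pred <- decide_batch(infer_batch(fit, sim$records[te_i, ])$masses)
  bayes <- decide_batch(infer_batch(gen, sim$records[te_i, ])$masses)
  list(accuracy = mean(pred == sim$labels[te_i]),
       bayes_accuracy = mean(bayes == sim$labels[te_i]),
       history = attr(fit, "history"),
       fit = fit)
}
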