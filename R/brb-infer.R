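#' Transform an input value into matching degrees over reference values
#'
#' Rule-based input transformation: the value is clamped to the reference
#' span, then distributed over the two adjacent reference values by linear
#' interpolation. The resulting vector is non-negative, sums to 1, and has at
#' most two adjacent non-zero entries.
#'
#' @param value A finite numeric scalar (attribute units).
#' @param refs Strictly increasing numeric vector of >= 2 reference values.
#' @return Numeric matching-degree vector of `length(refs)`.
#' @export
#' @examples
#' transform_input(1.625, c(1.50, 1.75, 2.00))  # 0.5 0.5 0
transform_input <- function(value, refs) {
  if (length(refs) < 2) stop("need at least 2 reference values", call. = FALSE)
  if (length(value) != 1 || !is.finite(value)) {
    stop("`value` must be a finite scalar", call. = FALSE)
  }
  drop(matching_matrix(value, refs))
}

# vectorized transformation: values (length n) -> n x R matching matrix
matching_matrix <- function(values, refs) {
  R <- length(refs)
  x <- pmin(pmax(values, refs[1L]), refs[R])
  i <- findInterval(x, refs, rightmost.closed = TRUE)
  i[i >= R] <- R - 1L
  t <- (x - refs[i]) / (refs[i + 1L] - refs[i])
  n <- length(x)
  M <- matrix(0, n, R)
  M[cbind(seq_len(n), i)] <- 1 - t
  idx <- cbind(seq_len(n), i + 1L)
  M[idx] <- M[idx] + t
  M
}

# per-attribute matching matrices for a data frame/matrix of records
matching_list <- function(rulebase, data) {
  frame <- rulebase$frame
  lapply(frame$attribute_names, function(a) {
    v <- data[[a]]
    if (is.null(v)) stop(sprintf("record is missing attribute '%s'", a), call. = FALSE)
    if (any(!is.finite(v))) {
      stop(sprintf("attribute '%s' contains non-finite values", a), call. = FALSE)
    }
    matching_matrix(as.numeric(v), frame$reference_values[[a]])
  })
}

#' Rule activation weights
#'
#' Standard RIMER activation: rule k's weight is proportional to
#' \eqn{\theta_k \prod_i \alpha_{i,k}^{\bar\delta_i}} where
#' \eqn{\alpha_{i,k}} is the matching degree of attribute i at rule k's
#' reference value and \eqn{\bar\delta_i = \delta_i / \max_j \delta_j} the
#' normalized attribute weight; weights are normalized to sum to 1.
#'
#' @param rulebase A [brb_rulebase()].
#' @param matching List of per-attribute matching-degree vectors (one per
#'   attribute, each of that attribute's reference count), e.g. from
#'   [transform_input()].
#' @return Numeric vector of L activation weights summing to 1.
#' @export
activation_weights <- function(rulebase, matching) {
  stopifnot(inherits(rulebase, "brb_rulebase"))
  if (length(matching) != ncol(rulebase$antecedents)) {
    stop("one matching vector per attribute is required", call. = FALSE)
  }
  m <- lapply(matching, function(v) matrix(v, nrow = 1))
  drop(activation_matrix(rulebase, m))
}

# batch activation: list of n x R_i matching matrices -> n x L weight matrix
activation_matrix <- function(rulebase, matchlist) {
  ante <- rulebase$antecedents
  L <- nrow(ante)
  n <- nrow(matchlist[[1L]])
  W <- matrix(rep(rulebase$theta, each = n), n, L)
  dbar <- rulebase$delta / max(rulebase$delta)
  for (i in seq_along(matchlist)) {
    A <- matchlist[[i]][, ante[, i], drop = FALSE]
    if (dbar[i] != 1) A <- A^dbar[i]
    W <- W * A
  }
  s <- rowSums(W)
  if (any(s <= 0)) {
    stop("internal error: no rule activated (all activation weights zero)", call. = FALSE)
  }
  W / s
}

#' Belief distribution over output classes
#'
#' Carrier of evidential-reasoning output: per-class masses plus the residual
#' (unassigned) mass left by incomplete rule beliefs. Masses and residual sum
#' to 1.
#'
#' @param masses Named numeric vector of class masses in \[0,1\].
#' @param residual Unassigned mass in \[0,1\].
#' @return Object of class `belief_dist`.
#' @export
belief_dist <- function(masses, residual = 0) {
  masses <- unlist(masses)
  if (any(masses < -1e-9) || residual < -1e-9) {
    stop("masses and residual must be non-negative", call. = FALSE)
  }
  tot <- sum(masses) + residual
  if (abs(tot - 1) > 1e-9) {
    stop("masses + residual must sum to 1", call. = FALSE)
  }
  structure(list(masses = masses, residual = residual), class = "belief_dist")
}

#' @export
print.belief_dist <- function(x, ...) {
  cat("<belief_dist>\n")
  print(round(x$masses, 4))
  cat("residual:", round(x$residual, 4), "\n")
  invisible(x)
}

#' Combine activated rules by the analytic evidential-reasoning algorithm
#'
#' Each activated rule contributes basic probability masses
#' \eqn{m_{n,k} = w_k \beta_{n,k}}; the unassigned remainder splits into
#' \eqn{\bar m_{D,k} = 1 - w_k} (caused by weighting) and
#' \eqn{\tilde m_{D,k} = w_k (1 - \sum_n \beta_{n,k})} (caused by belief
#' incompleteness). The analytic closed form of the recursive ER combination
#' yields the aggregated class masses and residual; when every activated
#' rule's beliefs are complete, the residual is exactly 0.
#'
#' @param rulebase A [brb_rulebase()].
#' @param activation Activation weight vector over the L rules, summing to 1.
#' @return A [belief_dist()].
#' @export
er_combine <- function(rulebase, activation) {
  stopifnot(inherits(rulebase, "brb_rulebase"))
  if (length(activation) != nrow(rulebase$beta)) {
    stop("`activation` must have one weight per rule", call. = FALSE)
  }
  if (abs(sum(activation) - 1) > 1e-6) {
    stop("`activation` must sum to 1", call. = FALSE)
  }
  out <- er_combine_masses(matrix(activation, nrow = 1), rulebase$beta)
  belief_dist(stats::setNames(out$masses[1, ], rulebase$class_labels),
              out$residual[1])
}

# batch analytic ER: W n x L activation matrix, beta L x N -> masses / residual
er_combine_masses <- function(W, beta) {
  N <- ncol(beta)
  s <- rowSums(beta)
  # log-products over rules; zero factors map to exp(-Inf) = 0
  logp <- function(M) {
    M[M < 0] <- 0  # guard tiny negatives from floating point
    exp(rowSums(log(M)))
  }
  P <- matrix(0, nrow(W), N)
  for (n in seq_len(N)) {
    co <- s - beta[, n]
    P[, n] <- logp(1 - sweep(W, 2L, co, "*"))
  }
  Q <- logp(1 - sweep(W, 2L, s, "*"))
  R0 <- logp(1 - W)
  mu <- 1 / (rowSums(P) - (N - 1) * Q)
  denom <- 1 - mu * R0
  masses <- (P - Q) * (mu / denom)
  residual <- (Q - R0) * mu / denom
  # clamp floating-point dust
  masses[masses < 0] <- 0
  residual[residual < 0] <- 0
  list(masses = masses, residual = residual)
}

#' Forward evidential-reasoning inference for one record
#'
#' Composition of input transformation, rule activation and ER combination.
#'
#' @param rulebase A [brb_rulebase()].
#' @param record Named list or vector supplying every frame attribute.
#' @return A [belief_dist()] over the rule base's class labels.
#' @export
#' @seealso [infer_batch()] for vectorized inference, [decide()] for the
#'   class decision.
infer <- function(rulebase, record) {
  stopifnot(inherits(rulebase, "brb_rulebase"))
  record <- as.list(record)
  out <- infer_batch(rulebase, as.data.frame(record))
  belief_dist(stats::setNames(out$masses[1, ], rulebase$class_labels),
              out$residual[1])
}

#' Vectorized forward inference
#'
#' @param rulebase A [brb_rulebase()].
#' @param data Data frame (or named list of columns) with one column per
#'   frame attribute.
#' @return List with `masses` (n x N matrix, columns named by class) and
#'   `residual` (length-n vector).
#' @export
infer_batch <- function(rulebase, data) {
  stopifnot(inherits(rulebase, "brb_rulebase"))
  ml <- matching_list(rulebase, data)
  W <- activation_matrix(rulebase, ml)
  out <- er_combine_masses(W, rulebase$beta)
  colnames(out$masses) <- rulebase$class_labels
  out
}

#' Decide a class label from a belief distribution
#'
#' Argmax of the combined class masses; ties resolve to the lowest class
#' index (deterministic). Residual mass is not redistributed.
#'
#' @param dist A [belief_dist()], or a bare numeric mass vector.
#' @param labels Optional class labels; default: names of the masses, else
#'   indices.
#' @return A single class label.
#' @export
decide <- function(dist, labels = NULL) {
  masses <- if (inherits(dist, "belief_dist")) dist$masses else dist
  if (is.null(labels)) {
    labels <- if (!is.null(names(masses))) names(masses) else seq_along(masses)
  }
  labels[[which.max(masses)]]
}

# batch decision: masses matrix -> label vector (ties -> first column)
decide_batch <- function(masses, labels = colnames(masses)) {
  labels[max.col(masses, ties.method = "first")]
}
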