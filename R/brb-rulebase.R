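#' Conjunctive belief rule base
#'
#' A rule base couples a reference frame with the full Cartesian product of
#' antecedent reference-value combinations. Each rule k carries a rule weight
#' \eqn{\theta_k \in [0,1]} and a consequent belief distribution
#' \eqn{\beta_k} over the N output classes with \eqn{\sum_n \beta_{n,k} \le 1}
#' (strict inequality encodes ignorance). Attribute weights
#' \eqn{\delta_i \in (0,1]} modulate how strongly each antecedent attribute
#' constrains rule activation.
#'
#' Rules are stored column-wise for speed: `antecedents` is an L x T integer
#' matrix of reference indices, `beta` an L x N matrix. The antecedent grid is
#' generated with the first attribute varying fastest (as `expand.grid()`).
#'
#' @param frame A [brb_frame()].
#' @param class_labels Character vector of N >= 2 output class labels.
#' @param theta Rule weights; scalar or length-L vector in \[0,1\]. Default 1.
#' @param delta Attribute weights; scalar or length-T vector in (0,1\]. Default 1.
#' @param beta Optional L x N belief matrix; rows must sum to <= 1. Default:
#'   uniform complete beliefs `1/N`.
#'
#' @return An object of class `brb_rulebase`.
#' @export
#' @examples
#' fr <- brb_frame(list(x = c(0, 0.5, 1)))
#' rb <- brb_rulebase(fr, c("low", "high"))
#' nrow(rb$beta)  # 3 rules
brb_rulebase <- function(frame, class_labels, theta = 1, delta = 1, beta = NULL) {
  stopifnot(inherits(frame, "brb_frame"))
  class_labels <- as.character(class_labels)
  if (length(class_labels) < 2 || anyDuplicated(class_labels)) {
    stop("`class_labels` must be >= 2 unique labels", call. = FALSE)
  }
  n_ref <- vapply(frame$reference_values, length, integer(1))
  antecedents <- as.matrix(expand.grid(lapply(n_ref, seq_len), KEEP.OUT.ATTRS = FALSE))
  dimnames(antecedents) <- list(NULL, frame$attribute_names)
  storage.mode(antecedents) <- "integer"
  L <- nrow(antecedents)
  T_k <- ncol(antecedents)
  N <- length(class_labels)

  theta <- rep_len(as.numeric(theta), L)
  if (any(theta < 0 | theta > 1)) stop("`theta` must lie in [0,1]", call. = FALSE)
  delta <- rep_len(as.numeric(delta), T_k)
  if (any(delta <= 0 | delta > 1)) stop("`delta` must lie in (0,1]", call. = FALSE)
  if (is.null(beta)) {
    beta <- matrix(1 / N, L, N)
  } else {
    beta <- as.matrix(beta)
    if (!all(dim(beta) == c(L, N))) {
      stop(sprintf("`beta` must be %d x %d", L, N), call. = FALSE)
    }
    if (any(beta < 0 | beta > 1)) stop("beliefs must lie in [0,1]", call. = FALSE)
    if (any(rowSums(beta) > 1 + 1e-9)) {
      stop("each rule's beliefs must sum to <= 1", call. = FALSE)
    }
  }
  colnames(beta) <- class_labels

  structure(
    list(frame = frame, antecedents = antecedents, theta = theta,
         delta = delta, beta = beta, class_labels = class_labels),
    class = "brb_rulebase"
  )
}

#' Number of rules in a full conjunctive rule base
#'
#' With M attributes and R reference values each, the Cartesian product holds
#' \eqn{R^M} rules; with heterogeneous counts, \eqn{\prod_i R_i}.
#'
#' @param attribute_count Number of attributes M (>= 1). Ignored when
#'   `refs_per_attribute` has length > 1.
#' @param refs_per_attribute Reference values per attribute: a scalar R >= 2,
#'   or a vector of per-attribute counts.
#' @return Integer-valued rule count.
#' @export
#' @examples
#' rule_count(6, 3)  # 729
rule_count <- function(attribute_count, refs_per_attribute) {
  if (length(refs_per_attribute) > 1) {
    if (any(refs_per_attribute < 2)) stop("each attribute needs >= 2 reference values", call. = FALSE)
    return(prod(refs_per_attribute))
  }
  if (attribute_count < 1) stop("`attribute_count` must be >= 1", call. = FALSE)
  if (refs_per_attribute < 2) stop("`refs_per_attribute` must be >= 2", call. = FALSE)
  refs_per_attribute^attribute_count
}

#' Extract one rule as a list
#'
#' @param rulebase A [brb_rulebase()].
#' @param k Rule index in `1:L`.
#' @return List with `antecedent` (reference indices), `rule_weight`, and
#'   `beliefs` (named over class labels).
#' @export
brb_rule <- function(rulebase, k) {
  stopifnot(inherits(rulebase, "brb_rulebase"))
  L <- nrow(rulebase$antecedents)
  if (k < 1 || k > L) stop("rule index out of range", call. = FALSE)
  list(antecedent = rulebase$antecedents[k, ],
       rule_weight = rulebase$theta[k],
       beliefs = stats::setNames(rulebase$beta[k, ], rulebase$class_labels))
}

#' @export
print.brb_rulebase <- function(x, ...) {
  cat("<brb_rulebase> ", nrow(x$antecedents), " rules, ",
      ncol(x$antecedents), " attribute(s), ",
      length(x$class_labels), " classes\n", sep = "")
  cat("  attributes: ", paste(x$frame$attribute_names, collapse = ", "), "\n", sep = "")
  cat("  classes:    ", paste(x$class_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Save / load a rule base as JSON
#'
#' The on-disk format is a versioned plain-JSON document holding the frame,
#' the rule parameters and the class labels; `read_rulebase()` restores a
#' numerically identical object.
#'
#' @param rulebase A [brb_rulebase()].
#' @param path File path.
#' @return `write_rulebase()` returns `path` invisibly; `read_rulebase()`
#'   returns the restored `brb_rulebase`.
#' @export
write_rulebase <- function(rulebase, path) {
  stopifnot(inherits(rulebase, "brb_rulebase"))
  doc <- list(
    format = "dbrbc-rulebase",
    version = 1L,
    attribute_names = rulebase$frame$attribute_names,
    reference_values = rulebase$frame$reference_values,
    ranges = rulebase$frame$ranges,
    class_labels = rulebase$class_labels,
    theta = rulebase$theta,
    delta = rulebase$delta,
    beta = rulebase$beta,
    antecedents = rulebase$antecedents
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rulebase
#' @export
read_rulebase <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "dbrbc-rulebase")) {
    stop("not a dbrbc rule-base document", call. = FALSE)
  }
  frame <- brb_frame(as.list(doc$reference_values), as.list(doc$ranges))
  rb <- brb_rulebase(frame, doc$class_labels, theta = doc$theta,
                     delta = doc$delta, beta = doc$beta)
  # the antecedent grid is canonical; verify the document agrees
  stored <- as.matrix(doc$antecedents)
  if (!all(dim(stored) == dim(rb$antecedents)) ||
      !all(as.integer(stored) == as.integer(rb$antecedents))) {
    stop("stored antecedent grid is not the canonical Cartesian product", call. = FALSE)
  }
  rb
}
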