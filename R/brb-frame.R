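#' Reference frame for a belief rule base
#'
#' A reference frame discretizes the input space: every attribute carries an
#' ordered set of reference values spanning the attribute's observed range.
#' Continuous inputs are matched against these anchors by piecewise-linear
#' interpolation (see [transform_input()]), so with \eqn{R_i} reference values
#' per attribute a conjunctive rule base holds \eqn{\prod_i R_i} rules.
#'
#' @param reference_values Named list; one strictly increasing numeric vector
#'   of length >= 2 per attribute. The first and last entries define the
#'   attribute's admissible range.
#' @param ranges Optional named list of `c(min, max)` per attribute. Defaults
#'   to the span of the reference values; when supplied it must contain the
#'   reference span.
#'
#' @return An object of class `brb_frame` with elements `attribute_names`,
#'   `reference_values` and `ranges`.
#' @seealso [frame_from_data()], [brb_rulebase()]
#' @export
#' @examples
#' brb_frame(list(height = c(1.45, 1.70, 1.98), weight = c(39, 85, 173)))
brb_frame <- function(reference_values, ranges = NULL) {
  if (!is.list(reference_values) || length(reference_values) < 1) {
    stop("`reference_values` must be a non-empty named list", call. = FALSE)
  }
  nm <- names(reference_values)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("`reference_values` must have unique non-empty names", call. = FALSE)
  }
  for (a in nm) {
    rv <- reference_values[[a]]
    if (!is.numeric(rv) || length(rv) < 2) {
      stop(sprintf("attribute '%s' needs at least 2 reference values", a),
           call. = FALSE)
    }
    if (any(!is.finite(rv)) || any(diff(rv) <= 0)) {
      stop(sprintf("reference values for '%s' must be finite and strictly increasing", a),
           call. = FALSE)
    }
  }
  reference_values <- lapply(reference_values, as.numeric)
  if (is.null(ranges)) {
    ranges <- lapply(reference_values, function(rv) c(rv[1L], rv[length(rv)]))
  } else {
    if (!setequal(names(ranges), nm)) {
      stop("`ranges` must be named like `reference_values`", call. = FALSE)
    }
    ranges <- ranges[nm]
    for (a in nm) {
      r <- as.numeric(ranges[[a]])
      rv <- reference_values[[a]]
      if (length(r) != 2 || r[1] > rv[1] || r[2] < rv[length(rv)]) {
        stop(sprintf("range for '%s' must contain its reference span", a),
             call. = FALSE)
      }
      ranges[[a]] <- r
    }
  }
  structure(
    list(attribute_names = nm,
         reference_values = reference_values,
         ranges = lapply(ranges, as.numeric)),
    class = "brb_frame"
  )
}

#' Build a reference frame from training data
#'
#' Reference values are placed equally spaced between the observed minimum and
#' maximum of each attribute, so the frame spans the training range exactly.
#'
#' @param data Data frame (or matrix) of numeric attribute columns.
#' @param attributes Character vector of column names to include; defaults to
#'   all columns.
#' @param n_refs Number of reference values per attribute (scalar or named
#'   vector), >= 2. Default 3.
#'
#' @return A [brb_frame()].
#' @export
frame_from_data <- function(data, attributes = NULL, n_refs = 3) {
  data <- as.data.frame(data)
  if (is.null(attributes)) attributes <- names(data)
  missing_attrs <- setdiff(attributes, names(data))
  if (length(missing_attrs)) {
    stop("attributes not in data: ", paste(missing_attrs, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(n_refs))) {
    n_refs <- stats::setNames(rep_len(n_refs, length(attributes)), attributes)
  }
  refs <- lapply(attributes, function(a) {
    x <- data[[a]]
    if (!is.numeric(x)) stop(sprintf("attribute '%s' is not numeric", a), call. = FALSE)
    lo <- min(x, na.rm = TRUE)
    hi <- max(x, na.rm = TRUE)
    if (!is.finite(lo) || !is.finite(hi) || lo == hi) {
      stop(sprintf("attribute '%s' is constant or non-finite; cannot place reference values", a),
           call. = FALSE)
    }
    seq(lo, hi, length.out = n_refs[[a]])
  })
  names(refs) <- attributes
  brb_frame(refs)
}

#' @export
print.brb_frame <- function(x, ...) {
  cat("<brb_frame> ", length(x$attribute_names), " attribute(s)\n", sep = "")
  for (a in x$attribute_names) {
    cat("  ", a, ": refs [", paste(signif(x$reference_values[[a]], 4), collapse = ", "),
        "]\n", sep = "")
  }
  invisible(x)
}
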