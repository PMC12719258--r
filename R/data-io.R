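#' A tabular cohort with fine and coarse labels
#'
#' Container tying together the numeric record table, per-record fine and
#' coarse labels, the categorical encoding map and a schema identifier.
#'
#' @param records Data frame of numeric attribute columns.
#' @param fine_labels Character vector, one per record.
#' @param scheme A [label_scheme()] used to derive coarse labels.
#' @param encoding_map Named list: categorical column -> named integer codes.
#' @param schema_id One of `"dataset-1"`, `"dataset-2"`, `"custom"`,
#'   `"synthetic"`.
#' @return Object of class `brb_dataset`.
#' @export
brb_dataset <- function(records, fine_labels, scheme = obesity_scheme(),
                        encoding_map = list(), schema_id = "custom") {
  records <- as.data.frame(records)
  fine_labels <- as.character(fine_labels)
  if (nrow(records) != length(fine_labels)) {
    stop("records and labels must have the same length", call. = FALSE)
  }
  structure(list(records = records,
                 fine_labels = fine_labels,
                 coarse_labels = coarsen(fine_labels, scheme),
                 encoding_map = encoding_map,
                 scheme = scheme,
                 schema_id = schema_id),
            class = "brb_dataset")
}

#' @export
print.brb_dataset <- function(x, ...) {
  cat("<brb_dataset> ", nrow(x$records), " records, ",
      ncol(x$records), " attributes [", x$schema_id, "]\n", sep = "")
  print(table(x$fine_labels))
  invisible(x)
}

# canonical column sets (lower-cased) for the two public survey schemas
.schema_columns <- list(
  "dataset-1" = c("gender", "age", "height", "weight",
                  "family_history_with_overweight", "favc", "fcvc", "ncp",
                  "caec", "smoke", "ch2o", "scc", "faf", "tue", "calc",
                  "mtrans", "nobeyesdad")
)

# ordinal survey levels (dataset-1): natural order, not alphabetical
.ordinal_levels <- list(
  caec = c("no", "Sometimes", "Frequently", "Always"),
  calc = c("no", "Sometimes", "Frequently", "Always")
)

#' Read a cohort CSV
#'
#' Reads a comma-separated file with a header row (case-insensitive column
#' matching). Categorical columns are encoded to integer codes: alphabetical
#' order by default, natural order (no < Sometimes < Frequently < Always)
#' for the ordinal survey variables of the public 17-variable schema. Rows
#' with missing or unparseable required values are rejected and reported by
#' row number. Labels come from `label_column` when present, otherwise they
#' are derived from height and weight via [bmi_label()].
#'
#' @param path CSV file path.
#' @param schema `"dataset-1"` (validates against the 17-variable survey
#'   schema) or `"custom"` (all columns accepted). Default `"custom"`.
#' @param label_column Column holding fine labels; `NULL` derives labels
#'   from BMI. For `"dataset-1"` defaults to `"nobeyesdad"`.
#' @param scheme A [label_scheme()].
#' @return A [brb_dataset()]; rejected row numbers are kept in attribute
#'   `"rejected_rows"`.
#' @export
read_cohort <- function(path, schema = c("custom", "dataset-1"),
                        label_column = NULL, scheme = obesity_scheme()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(names(raw))
  if (schema == "dataset-1") {
    unknown <- setdiff(names(raw), .schema_columns[["dataset-1"]])
    if (length(unknown)) {
      stop("unknown column(s) for the dataset-1 schema: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (is.null(label_column) && "nobeyesdad" %in% names(raw)) {
      label_column <- "nobeyesdad"
    }
  }
  if (!is.null(label_column)) {
    label_column <- tolower(label_column)
    if (!label_column %in% names(raw)) {
      stop("label column '", label_column, "' not found", call. = FALSE)
    }
  }

  feature_cols <- setdiff(names(raw), label_column)
  # reject rows with missing required fields
  is_missing <- Reduce(`|`, lapply(raw, function(col) {
    is.na(col) | (is.character(col) & !nzchar(trimws(col)))
  }))
  rejected <- which(is_missing)
  if (length(rejected)) {
    warning("rejected ", length(rejected), " row(s) with missing fields: ",
            paste(utils::head(rejected, 10L), collapse = ", "),
            if (length(rejected) > 10L) ", ..." else "", call. = FALSE)
    raw <- raw[-rejected, , drop = FALSE]
  }
  if (!nrow(raw)) stop("no usable rows in ", path, call. = FALSE)

  encoding_map <- list()
  records <- raw[feature_cols]
  for (col in feature_cols) {
    v <- records[[col]]
    if (is.character(v) || is.logical(v) || is.factor(v)) {
      v <- as.character(v)
      # a mostly-numeric character column signals unparseable entries, not
      # a categorical level set; anthropometrics are always numeric
      parsed <- suppressWarnings(as.numeric(v))
      if ((any(!is.na(parsed)) || col %in% c("height", "weight", "age")) &&
          any(is.na(parsed))) {
        bad <- which(is.na(parsed))
        stop("unparseable numeric value(s) in column '", col, "', row(s) ",
             paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
      }
      if (all(!is.na(parsed))) {
        records[[col]] <- parsed
        next
      }
      lv <- if (col %in% names(.ordinal_levels) && schema == "dataset-1" &&
                all(v %in% .ordinal_levels[[col]])) {
        .ordinal_levels[[col]]
      } else {
        sort(unique(v))
      }
      codes <- stats::setNames(seq_along(lv) - 1L, lv)
      encoding_map[[col]] <- codes
      records[[col]] <- unname(codes[v])
    } else {
      suppressWarnings(records[[col]] <- as.numeric(v))
      if (any(is.na(records[[col]]))) {
        bad <- which(is.na(records[[col]]))
        stop("unparseable numeric value(s) in column '", col, "', row(s) ",
             paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
      }
    }
  }

  fine <- if (!is.null(label_column)) {
    as.character(raw[[label_column]])
  } else {
    if (!all(c("height", "weight") %in% names(records))) {
      stop("no label column and no height/weight to derive labels from", call. = FALSE)
    }
    bmi_label(records$height, records$weight, scheme)
  }
  ds <- brb_dataset(records, fine, scheme, encoding_map,
                    schema_id = if (schema == "custom") "custom" else schema)
  attr(ds, "rejected_rows") <- rejected
  ds
}

#' Write a cohort to CSV
#'
#' Writes the numeric records plus a `label` column; [read_cohort()] on the
#' result restores the records and labels losslessly.
#'
#' @param dataset A [brb_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(dataset, path) {
  stopifnot(inherits(dataset, "brb_dataset"))
  out <- dataset$records
  out$label <- dataset$fine_labels
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Per label (processed in sorted label order): indices are shuffled with
#' the seeded RNG, then `floor(r1 n)` go to training, `floor(r2 n)` to
#' validation and the remainder to test, so label proportions are preserved
#' exactly whenever counts divide evenly. Deterministic given the seed.
#'
#' @param labels Vector of class labels, one per record.
#' @param ratios Length-3 ratios summing to 1. Default `c(0.6, 0.2, 0.2)`.
#' @param seed Integer seed.
#' @return Object of class `brb_split`: list with integer index vectors
#'   `train`, `validation`, `test`, plus `seed`.
#' @export
#' @examples
#' stratified_split(rep(c("a", "b"), each = 10), seed = 7)
stratified_split <- function(labels, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-9) {
    stop("`ratios` must be three shares summing to 1", call. = FALSE)
  }
  labels <- as.character(labels)
  counts <- table(labels)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    stop("label(s) with fewer than 3 samples: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  tr <- va <- te <- integer(0)
  for (lab in sort(names(counts))) {
    idx <- which(labels == lab)           # ascending original order
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_tr <- floor(ratios[1] * n)
    n_va <- floor(ratios[2] * n)
    tr <- c(tr, idx[seq_len(n_tr)])
    va <- c(va, idx[n_tr + seq_len(n_va)])
    te <- c(te, idx[seq.int(n_tr + n_va + 1L, n)])
  }
  structure(list(train = sort(tr), validation = sort(va), test = sort(te),
                 seed = as.integer(seed)),
            class = "brb_split")
}

#' @export
print.brb_split <- function(x, ...) {
  cat("<brb_split> train:", length(x$train),
      " validation:", length(x$validation),
      " test:", length(x$test), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write split manifests as CSV index lists
#'
#' @param split A [stratified_split()] result.
#' @param path Output CSV path (columns: index, subset).
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  man <- rbind(data.frame(index = split$train, subset = "train"),
               data.frame(index = split$validation, subset = "validation"),
               data.frame(index = split$test, subset = "test"))
  utils::write.csv(man[order(man$index), ], path, row.names = FALSE)
  invisible(path)
}
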