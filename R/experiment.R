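# The processed two-group experiment container and its preprocessing.

#' Construct a lipid experiment
#'
#' Low-level constructor; most users should call [preprocess()]. The matrix
#' is expected on the log2 scale with no missing values.
#'
#' @param matrix Numeric lipids x samples matrix with row and column names.
#' @param groups Named character vector mapping each sample to `"case"` or
#'   `"control"`.
#' @param processing_log Character vector describing applied transforms.
#' @return A `lipid_experiment` object.
#' @export
new_experiment <- function(matrix, groups, processing_log = character(0)) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix must have lipid row names and sample column names")
  }
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("experiment matrix must be finite with no missing values")
  }
  if (!setequal(names(groups), colnames(matrix))) {
    stop("group assignment must cover exactly the matrix samples")
  }
  groups <- groups[colnames(matrix)]
  if (!all(groups %in% c("case", "control"))) {
    stop("groups must be 'case' or 'control'")
  }
  if (sum(groups == "case") == 0L || sum(groups == "control") == 0L) {
    stop("both groups must be non-empty")
  }
  structure(
    list(lipid_names = rownames(matrix),
         samples = colnames(matrix),
         matrix = matrix,
         group_of = groups,
         processing_log = processing_log),
    class = "lipid_experiment"
  )
}

#' @export
print.lipid_experiment <- function(x, ...) {
  cat("<lipid_experiment> ", length(x$lipid_names), " lipids x ",
      length(x$samples), " samples (", sum(x$group_of == "case"), " case, ",
      sum(x$group_of == "control"), " control)\n", sep = "")
  for (step in x$processing_log) cat("  - ", step, "\n", sep = "")
  invisible(x)
}

#' Preprocess a raw abundance table into an analysis-ready experiment
#'
#' Applies the standard lipidomics preprocessing chain: filtering of
#' species with too many missing values, half-minimum imputation of the
#' remainder, optional per-sample normalization, and a log2 transform.
#' Every step is recorded, with its parameters, in the experiment's
#' `processing_log`.
#'
#' @param raw Numeric lipids x samples matrix (nonnegative; `NA` allowed)
#'   with lipid row names and sample column names.
#' @param metadata Data frame with columns `sample_id` and `group`
#'   assigning each sample to one of exactly two groups.
#' @param case Which `group` level is the case group. Defaults to
#'   `"case"` when the levels are `case`/`control`; otherwise it must be
#'   given explicitly.
#' @param max_missing_fraction Species missing in more than this fraction
#'   of samples are dropped (default 0.5).
#' @param impute Imputation rule for remaining missing values; only
#'   `"halfmin"` (half of the per-species observed minimum) is provided.
#' @param normalization One of `"none"`, `"median"` (per-sample median
#'   scaling to the mean of sample medians) or `"sum"` (per-sample total
#'   scaling to the mean of sample totals).
#' @param log2_transform Apply `log2(x + pseudocount)` (default `TRUE`).
#'   Set to `FALSE` only for data that is already on the log2 scale.
#' @param pseudocount Added before the log; `NULL` (default) uses 1 when
#'   zeros are present after imputation and 0 otherwise.
#' @return A `lipid_experiment`.
#' @export
preprocess <- function(raw, metadata, case = NULL,
                       max_missing_fraction = 0.5,
                       impute = "halfmin",
                       normalization = c("none", "median", "sum"),
                       log2_transform = TRUE,
                       pseudocount = NULL) {
  normalization <- match.arg(normalization)
  impute <- match.arg(impute, "halfmin")
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("abundance matrix must be numeric")
  # Already-log2 input (log2_transform = FALSE) may legitimately be negative.
  if (log2_transform && any(raw < 0, na.rm = TRUE)) {
    stop("abundances must be nonnegative")
  }
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    stop("metadata needs 'sample_id' and 'group' columns")
  }
  if (anyDuplicated(metadata$sample_id)) stop("duplicated sample_id in metadata")
  if (!setequal(metadata$sample_id, colnames(raw))) {
    stop("metadata samples and matrix columns do not match")
  }
  metadata <- metadata[match(colnames(raw), metadata$sample_id), ]
  lv <- sort(unique(as.character(metadata$group)))
  if (length(lv) != 2L) stop("exactly two groups are required, got: ",
                             paste(lv, collapse = ", "))
  if (is.null(case)) {
    if (setequal(lv, c("case", "control"))) case <- "case"
    else stop("groups are ", paste(lv, collapse = "/"),
              "; specify which level is the case group via 'case'")
  }
  if (!case %in% lv) stop("case level '", case, "' not among groups")
  groups <- ifelse(metadata$group == case, "case", "control")
  names(groups) <- metadata$sample_id
  if (sum(groups == "case") < 2L || sum(groups == "control") < 2L) {
    stop("each group needs at least 2 samples")
  }
  log <- character(0)

  miss_frac <- rowMeans(is.na(raw))
  drop <- miss_frac > max_missing_fraction
  if (all(drop)) stop("all species exceed the missing-value threshold")
  if (any(drop)) {
    log <- c(log, sprintf(
      "dropped %d/%d species with missing fraction > %.3g: %s",
      sum(drop), nrow(raw), max_missing_fraction,
      paste(utils::head(rownames(raw)[drop], 10L), collapse = ", ")))
    raw <- raw[!drop, , drop = FALSE]
  }

  if (anyNA(raw)) {
    n_imp <- sum(is.na(raw))
    mins <- apply(raw, 1L, function(v) min(v, na.rm = TRUE))
    for (i in which(rowSums(is.na(raw)) > 0L)) {
      raw[i, is.na(raw[i, ])] <- mins[i] / 2
    }
    log <- c(log, sprintf("imputed %d missing values with half the per-species observed minimum", n_imp))
  }

  if (normalization == "median") {
    med <- apply(raw, 2L, stats::median)
    if (any(med <= 0)) stop("non-positive sample median; cannot median-normalize")
    raw <- sweep(raw, 2L, mean(med) / med, `*`)
    log <- c(log, "median normalization: samples scaled to the mean of sample medians")
  } else if (normalization == "sum") {
    tot <- colSums(raw)
    if (any(tot <= 0)) stop("non-positive sample total; cannot sum-normalize")
    raw <- sweep(raw, 2L, mean(tot) / tot, `*`)
    log <- c(log, "sum normalization: samples scaled to the mean of sample totals")
  } else {
    log <- c(log, "normalization: none")
  }

  if (log2_transform) {
    if (is.null(pseudocount)) pseudocount <- if (any(raw == 0)) 1 else 0
    if (any(raw + pseudocount <= 0)) stop("non-positive values before log2; increase pseudocount")
    raw <- log2(raw + pseudocount)
    log <- c(log, sprintf("log2 transform with pseudocount %g", pseudocount))
  } else {
    log <- c(log, "log2 transform: skipped (input taken as log2 scale)")
  }

  new_experiment(raw, groups, processing_log = log)
}
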