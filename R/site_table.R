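#' Construct a site (or protein) intensity table
#'
#' The central container of the package: a matrix of log2 intensities for
#' modified-site or protein-group entries across annotated samples, with
#' `NA` as the explicit missing-value marker, plus per-entry identity and
#' quality flags and per-sample design annotations.
#'
#' @param values Numeric matrix of log2 intensities, entries in rows and
#'   samples in columns. `NA` marks a missing (not identified/quantified)
#'   cell; all other values must be finite.
#' @param entries Data frame with one row per matrix row. Must contain
#'   `entry_id` (unique character key). Site-level tables carry `accession`
#'   (leading protein), `accessions` (full `;`-separated list), `position`
#'   (1-based residue index in the leading accession), `residue` (one-letter
#'   amino acid), `window` (31-character sequence context padded with `_`),
#'   and `multiplicity`. Flag columns `reverse`, `contaminant` and
#'   `only_by_site` are logical and default to `FALSE` when absent.
#' @param samples Data frame with one row per matrix column: `sample_id`
#'   (unique), `treatment`, `timepoint` (minutes, numeric) and `replicate`.
#' @param level `"site"` or `"protein"`.
#'
#' @return An object of class `site_table`.
#' @export
site_table <- function(values, entries, samples, level = c("site", "protein")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  if (!"entry_id" %in% names(entries)) {
    stop("'entries' must contain an 'entry_id' column")
  }
  if (anyDuplicated(entries$entry_id)) {
    stop("duplicate entry_id values in 'entries'")
  }
  for (flag in c("reverse", "contaminant", "only_by_site")) {
    if (!flag %in% names(entries)) entries[[flag]] <- FALSE
    entries[[flag]] <- as.logical(entries[[flag]])
  }
  needed <- c("sample_id", "treatment", "timepoint", "replicate")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    stop("'samples' lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id values in 'samples'")
  }
  if (nrow(entries) != nrow(values) || nrow(samples) != ncol(values)) {
    stop("matrix dimensions do not match entries x samples")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("'values' must be finite or NA")
  }
  rownames(values) <- entries$entry_id
  colnames(values) <- samples$sample_id

  structure(
    list(values = values, entries = entries, samples = samples, level = level),
    class = "site_table"
  )
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf(
    "<site_table> %s-level: %d entries x %d samples (%.1f%% missing)\n",
    x$level, nrow(x$values), ncol(x$values),
    100 * mean(is.na(x$values))
  ))
  trt <- table(x$samples$treatment)
  cat("  treatments:", paste(sprintf("%s(%d)", names(trt), trt), collapse = " "), "\n")
  invisible(x)
}

#' Number of entries / samples in a site table
#' @param x A `site_table`.
#' @return Integer count.
#' @export
n_entries <- function(x) nrow(x$values)

#' @rdname n_entries
#' @export
n_samples <- function(x) ncol(x$values)

#' Subset a site table by entries and/or samples
#'
#' @param x A `site_table`.
#' @param i Entry selector (indices, logical mask, or entry_id characters).
#' @param j Sample selector (indices, logical mask, or sample_id characters).
#' @return A `site_table` restricted to the selected rows/columns.
#' @export
subset_table <- function(x, i = NULL, j = NULL) {
  stopifnot(inherits(x, "site_table"))
  if (is.null(i)) i <- seq_len(nrow(x$values))
  if (is.null(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$entries$entry_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  site_table(
    x$values[i, j, drop = FALSE],
    x$entries[i, , drop = FALSE],
    x$samples[j, , drop = FALSE],
    level = x$level
  )
}

# Group label per sample: treatment, or treatment.timepoint when more than
# one timepoint is present. Filtering and testing treat each such
# combination as a replicate group.
sample_groups <- function(x, group_by = c("treatment", "timepoint")) {
  s <- x$samples
  group_by <- intersect(group_by, names(s))
  if (identical(group_by, c("treatment", "timepoint")) &&
      length(unique(s$timepoint)) == 1L) {
    group_by <- "treatment"
  }
  if (length(group_by) == 1L) {
    as.character(s[[group_by]])
  } else {
    do.call(paste, c(unname(s[group_by]), sep = "."))
  }
}

# Columns belonging to one treatment (optionally at one timepoint).
sample_index <- function(x, treatment, timepoint = NULL) {
  idx <- x$samples$treatment == treatment
  if (!is.null(timepoint)) idx <- idx & x$samples$timepoint == timepoint
  which(idx)
}
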