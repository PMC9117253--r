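#' Parameters for left-censored imputation
#'
#' Missing cells are drawn from a normal distribution shifted into the lower
#' tail of each sample's observed intensity distribution, the standard
#' treatment of missing-not-at-random values in label-free proteomics.
#'
#' @param width Standard deviation of the imputation distribution, as a
#'   fraction of the per-sample observed standard deviation. Default 0.3.
#' @param downshift Downshift of the imputation mean below the per-sample
#'   observed mean, in multiples of the observed standard deviation.
#'   Default 1.8.
#' @param seed Integer seed for the imputation draws.
#' @return An `imputation_params` object.
#' @export
imputation_params <- function(width = 0.3, downshift = 1.8, seed = 1) {
  if (width <= 0) stop("width must be > 0")
  if (downshift < 0) stop("downshift must be >= 0")
  structure(list(width = width, downshift = downshift, seed = seed),
            class = "imputation_params")
}

#' Impute left-censored missing values
#'
#' Per sample column with observed mean `m` and standard deviation `s`,
#' each missing cell is replaced by an independent draw from
#' `Normal(m - downshift * s, (width * s)^2)`. Observed cells are never
#' altered; the result has no missing values. Imputation is per column
#' because censoring is an acquisition property of each run.
#'
#' @param table A log2-scale [site_table()].
#' @param params An [imputation_params()].
#' @return A [site_table()] with all cells observed.
#' @export
impute_left_censored <- function(table, params = imputation_params()) {
  stopifnot(inherits(table, "site_table"), inherits(params, "imputation_params"))
  v <- table$values
  set.seed(params$seed)
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    obs <- v[!miss, j]
    if (length(obs) < 2) {
      stop("sample '", colnames(v)[j],
           "' has fewer than 2 observed values; moments undefined")
    }
    m <- mean(obs)
    s <- sd(obs)
    v[miss, j] <- rnorm(sum(miss), m - params$downshift * s, params$width * s)
  }
  out <- table
  out$values <- v
  out
}

#' Centre each entry's intensities on zero
#'
#' Subtracts the row mean (over observed values) from every row. No scaling
#' by the standard deviation is applied: this mean-subtraction is the
#' row-wise normalisation used before clustering heatmaps of site
#' intensities.
#'
#' @param table A [site_table()].
#' @return A [site_table()] with row means zero (over observed cells).
#' @export
center_rows <- function(table) {
  stopifnot(inherits(table, "site_table"))
  v <- table$values
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs == 0)) {
    stop("entry with no observed values at row(s): ",
         paste(which(n_obs == 0), collapse = ", "))
  }
  out <- table
  out$values <- v - rowMeans(v, na.rm = TRUE)
  out
}
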