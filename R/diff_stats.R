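# S0-moderated two-sample testing with SAM-style permutation FDR, plus the
# correlation / PCA / clustering helpers used by the downstream summaries.

# Tie tolerance when counting permuted statistics at least as extreme as a
# threshold; guards the exact ties produced by mirror-image relabelings.
STAT_TIE_TOL <- 1e-8

#' Configuration for permutation testing
#'
#' @param s0 Non-negative fudge constant added to the standard-error
#'   denominator of the t statistic, de-emphasising small-variance entries.
#'   Default 0.1.
#' @param fdr Target q-value cutoff for the significance call. Default 0.05.
#' @param sidedness `"two_sided"` or `"right_sided"`.
#' @param n_permutations Number of sampled label permutations when full
#'   enumeration is infeasible. Default 250. Full enumeration is used
#'   whenever `choose(nA + nB, nA) <= 10000`.
#' @param seed Integer seed for sampled permutations.
#' @return A `test_config` object.
#' @export
test_config <- function(s0 = 0.1, fdr = 0.05,
                        sidedness = c("two_sided", "right_sided"),
                        n_permutations = 250, seed = 1) {
  sidedness <- match.arg(sidedness)
  if (s0 < 0) stop("s0 must be non-negative")
  if (fdr < 0 || fdr > 1) stop("fdr must be in [0, 1]")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(s0 = s0, fdr = fdr, sidedness = sidedness,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "test_config")
}

#' S0-moderated two-sample statistic
#'
#' `t_s0 = (mean(x) - mean(y)) / (s + s0)` where `s` is the classical
#' pooled-variance two-sample standard error. With `s0 = 0` this is exactly
#' the textbook Student statistic.
#'
#' @param x,y Numeric vectors of at least 2 finite values each.
#' @param s0 Non-negative moderation constant.
#' @return List with `difference` (`mean(x) - mean(y)`, log2 units when the
#'   inputs are log2 intensities) and `t_s0`.
#' @export
moderated_statistic <- function(x, y, s0 = 0.1) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (s0 < 0) stop("s0 must be non-negative")
  d <- mean(x) - mean(y)
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  s <- sqrt(sp2 * (1 / nx + 1 / ny))
  list(difference = d, t_s0 = d / (s + s0))
}

# Row-wise moderated statistics for a matrix split into the first nx and the
# remaining ny columns (columns given by idx for group 1).
mod_stat_rows <- function(V, idx, s0) {
  X <- V[, idx, drop = FALSE]
  Y <- V[, -idx, drop = FALSE]
  nx <- ncol(X)
  ny <- ncol(Y)
  mx <- rowMeans(X)
  my <- rowMeans(Y)
  vx <- (rowSums(X * X) - nx * mx * mx) / (nx - 1)
  vy <- (rowSums(Y * Y) - ny * my * my) / (ny - 1)
  # clamp tiny negatives from cancellation
  vx[vx < 0] <- 0
  vy[vy < 0] <- 0
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  s <- sqrt(sp2 * (1 / nx + 1 / ny))
  list(difference = mx - my, t_s0 = (mx - my) / (s + s0))
}

#' Permutation test of a treatment-versus-control contrast
#'
#' For every entry the S0-moderated statistic is computed for the observed
#' labelling, and a null distribution is built by permuting the group labels:
#' all distinct relabelings are enumerated when `choose(nA + nB, nA) <=
#' 10000`, otherwise `n_permutations` random relabelings are drawn under the
#' config seed. Per-entry p-values are the proportion of permuted statistics
#' at least as extreme as the observed one (the observed labelling counts as
#' one permutation; sampled runs use the `(b + 1)/(N + 1)` correction).
#'
#' q-values follow the SAM convention: entries are ordered by decreasing
#' `|t_s0|` (signed `t_s0` for right-sided tests, ties broken by entry id);
#' at rank `i` the estimated FDR is the mean count, per permutation, of
#' permuted statistics at least as extreme as the rank-`i` statistic,
#' divided by `i`; q-values are the running minimum of these estimates from
#' the bottom rank upward, capped at 1. An entry is significant when its
#' q-value is at most `config$fdr`.
#'
#' @param table A filtered, imputed (complete) [site_table()].
#' @param treatment,control Treatment labels defining the contrast.
#' @param config A [test_config()].
#' @param timepoint Optional timepoint restricting the treatment columns.
#' @param control_timepoint Optional timepoint restricting the control
#'   columns.
#' @return Data frame with one row per entry: `entry_id`, `difference`
#'   (log2 fold-change versus control), `t_s0`, `p`, `q`, `significant`,
#'   `direction`; attributes `config`, `contrast`, `exact`,
#'   `n_permutations`.
#' @export
permutation_test <- function(table, treatment, control,
                             config = test_config(), timepoint = NULL,
                             control_timepoint = NULL) {
  stopifnot(inherits(table, "site_table"), inherits(config, "test_config"))
  xi <- sample_index(table, treatment, timepoint)
  yi <- sample_index(table, control, control_timepoint)
  if (length(xi) < 2 || length(yi) < 2) {
    stop("need >= 2 replicates per group for contrast ", treatment, " vs ",
         control)
  }
  V <- table$values[, c(xi, yi), drop = FALSE]
  if (anyNA(V)) stop("matrix contains missing values; impute before testing")
  nx <- length(xi)
  ny <- length(yi)
  n <- nx + ny
  n_e <- nrow(V)

  total <- choose(n, nx)
  if (total < 2) stop("fewer than 2 distinct permutations possible")
  exact <- total <= 10000

  obs <- mod_stat_rows(V, seq_len(nx), config$s0)

  if (exact) {
    combs <- combn(n, nx)
    B <- ncol(combs)
    perm_idx <- lapply(seq_len(B), function(b) combs[, b])
  } else {
    set.seed(config$seed)
    B <- config$n_permutations
    perm_idx <- lapply(seq_len(B), function(b) sample.int(n, nx))
  }
  Tperm <- vapply(perm_idx, function(idx) mod_stat_rows(V, idx, config$s0)$t_s0,
                  numeric(n_e))
  Tperm <- matrix(Tperm, nrow = n_e)

  if (config$sidedness == "two_sided") {
    obs_stat <- abs(obs$t_s0)
    perm_stat <- abs(Tperm)
  } else {
    obs_stat <- obs$t_s0
    perm_stat <- Tperm
  }

  # per-entry p: share of permuted statistics at least as extreme
  count_ge <- rowSums(perm_stat >= obs_stat - STAT_TIE_TOL)
  p <- if (exact) count_ge / B else (count_ge + 1) / (B + 1)

  # SAM-style step-down q over the pooled permutation distribution
  ord <- order(-obs_stat, table$entries$entry_id)
  thr <- obs_stat[ord]
  pooled <- sort(as.vector(perm_stat))
  n_pool <- length(pooled)
  n_ge <- n_pool - findInterval(thr - STAT_TIE_TOL, pooled)
  fdr_hat <- pmin((n_ge / B) / seq_len(n_e), 1)
  q_sorted <- rev(cummin(rev(fdr_hat)))
  q <- numeric(n_e)
  q[ord] <- q_sorted

  res <- data.frame(
    entry_id = table$entries$entry_id,
    difference = obs$difference,
    t_s0 = obs$t_s0,
    p = p,
    q = q,
    significant = q <= config$fdr,
    direction = sign(obs$difference),
    stringsAsFactors = FALSE
  )
  attr(res, "config") <- config
  attr(res, "contrast") <- c(treatment = treatment, control = control)
  attr(res, "exact") <- exact
  attr(res, "n_permutations") <- B
  res
}

#' Gate protein entries on enrichment over a parental background
#'
#' Right-sided (one-sided, greater) pooled-variance two-sample Student test
#' of each protein's tagged-pulldown intensities against the matching
#' parental-background intensities; entries with unadjusted `p < alpha` are
#' retained as tagged-ubiquitin substrates.
#'
#' @param his10_table,parental_table Protein-level, imputed [site_table()]s
#'   sharing entry ids.
#' @param alpha Unadjusted p-value cutoff, default 0.05.
#' @return Character vector of retained entry ids; the full per-entry test
#'   table is attached as attribute `"details"`.
#' @export
his10_substrate_gate <- function(his10_table, parental_table, alpha = 0.05) {
  common <- intersect(his10_table$entries$entry_id,
                      parental_table$entries$entry_id)
  if (!length(common)) stop("no overlapping entries between tables")
  X <- his10_table$values[match(common, his10_table$entries$entry_id), ,
                          drop = FALSE]
  Y <- parental_table$values[match(common, parental_table$entries$entry_id), ,
                             drop = FALSE]
  if (anyNA(X) || anyNA(Y)) stop("impute tables before gating")
  V <- cbind(X, Y)
  st <- mod_stat_rows(V, seq_len(ncol(X)), s0 = 0)
  df <- ncol(X) + ncol(Y) - 2
  p <- pt(st$t_s0, df = df, lower.tail = FALSE)
  details <- data.frame(entry_id = common, difference = st$difference,
                        t = st$t_s0, p = p, retained = p < alpha,
                        stringsAsFactors = FALSE)
  out <- common[details$retained]
  attr(out, "details") <- details
  attr(out, "alpha") <- alpha
  out
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper used for replicate/treatment agreement and the
#' sites-versus-molecular-weight comparison.
#'
#' @param x,y Equal-length numeric vectors (length >= 3), neither constant.
#' @return The correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input has undefined correlation")
  cor(x, y, method = "pearson")
}

#' Project samples onto principal components
#'
#' Mean-centred (unscaled) PCA of the samples of a complete intensity
#' matrix.
#'
#' @param table A complete [site_table()].
#' @param n_components Number of components to return.
#' @return List with `coordinates` (samples x components), and
#'   `explained_variance` (non-increasing fractions summing to at most 1).
#' @export
pca_project <- function(table, n_components = 2) {
  v <- table$values
  if (anyNA(v)) stop("matrix contains missing values")
  pc <- prcomp(t(v), center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (n_components > rank) {
    stop("n_components = ", n_components, " exceeds matrix rank (", rank, ")")
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(coords) <- table$samples$sample_id
  list(coordinates = coords, explained_variance = expl[seq_len(n_components)])
}

#' Row ordering for a k-means-preprocessed clustered heatmap
#'
#' Rows are partitioned by k-means (seeded, with an iteration cap), cluster
#' centroids are clustered hierarchically with Euclidean distance and
#' average linkage, and rows are returned grouped by cluster in the
#' centroid-dendrogram leaf order (original order within a cluster). With
#' `k` equal to the number of rows each row is its own cluster and the
#' ordering reduces to plain hierarchical clustering of the rows.
#'
#' @param table A complete, row-centred [site_table()].
#' @param k Number of k-means clusters (default 300).
#' @param iterations k-means iteration cap (default 1000).
#' @param seed Integer seed.
#' @return List with `order` (row indices) and `clusters` (per-row cluster
#'   assignment).
#' @export
cluster_heatmap <- function(table, k = 300, iterations = 1000, seed = 1) {
  v <- table$values
  if (anyNA(v)) stop("matrix contains missing values")
  n <- nrow(v)
  if (k > n) stop("k = ", k, " exceeds number of rows (", n, ")")
  if (k == n) {
    clusters <- seq_len(n)
    centers <- v
  } else {
    set.seed(seed)
    km <- suppressWarnings(kmeans(v, centers = k, iter.max = iterations))
    clusters <- km$cluster
    centers <- km$centers
  }
  hc <- hclust(dist(centers, method = "euclidean"), method = "average")
  ord <- unlist(lapply(hc$order, function(cl) which(clusters == cl)))
  list(order = as.integer(ord), clusters = as.integer(clusters))
}
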