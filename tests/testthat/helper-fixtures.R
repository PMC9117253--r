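# Shared fixtures and independent oracles used across the test files.

# A small site table built directly from a matrix; default two treatments
# with `reps` replicates each at one timepoint.
make_table <- function(values, treatments = c("DMSO", "PR619"),
                       reps = ncol(values) / length(treatments),
                       level = "site") {
  n <- nrow(values)
  samples <- data.frame(
    sample_id = paste0(rep(treatments, each = reps), "_180_",
                       rep(seq_len(reps), length(treatments))),
    treatment = rep(treatments, each = reps),
    timepoint = 180,
    replicate = rep(seq_len(reps), length(treatments)),
    stringsAsFactors = FALSE
  )
  entries <- data.frame(
    entry_id = sprintf("e%03d", seq_len(n)),
    accession = sprintf("P%03d", seq_len(n)),
    accessions = sprintf("P%03d", seq_len(n)),
    position = seq_len(n) + 10L,
    residue = "K",
    window = make_windows(n),
    multiplicity = 1L,
    stringsAsFactors = FALSE
  )
  site_table(values, entries, samples, level = level)
}

# Deterministic 31-mer windows with K at the centre.
make_windows <- function(n, seed = 99) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]]  # no K off-centre
  vapply(seq_len(n), function(i) {
    w <- sample(aa, 31, replace = TRUE)
    w[16] <- "K"
    paste(w, collapse = "")
  }, character(1))
}

# Independent brute-force permutation test: enumerates every relabeling,
# computes the moderated statistic from its defining formula, and counts
# statistics at least as extreme as the observed one (tie tolerance 1e-8).
oracle_perm_p <- function(x, y, s0 = 0.1, two_sided = TRUE) {
  v <- c(x, y)
  nx <- length(x)
  tstat <- function(idx) {
    a <- v[idx]
    b <- v[-idx]
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    (mean(a) - mean(b)) / (se + s0)
  }
  t_obs <- tstat(seq_len(nx))
  combs <- utils::combn(length(v), nx)
  ts <- apply(combs, 2, tstat)
  if (two_sided) {
    mean(abs(ts) >= abs(t_obs) - 1e-8)
  } else {
    mean(ts >= t_obs - 1e-8)
  }
}

# Rule-literal profile classifier used as enumeration oracle.
oracle_classify <- function(fc, threshold = 1) {
  fc <- fc[is.finite(fc)]
  lab <- character(0)
  if (any(fc > threshold)) lab <- c(lab, "Enriched")
  if (any(fc < -threshold)) lab <- c(lab, "Depleted")
  if (!length(lab)) lab <- "Unchanged"
  lab
}

tmp_file <- function(ext = ".tsv") tempfile(fileext = ext)
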