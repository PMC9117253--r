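#' Describe a treatment/timepoint/replicate study design
#'
#' @param treatments Character vector of treatment labels, including the
#'   control (e.g. `c("DMSO", "TAK243", "MG132", "PR619")`). Combination
#'   treatments such as `"TAK243+MG132"` are ordinary labels.
#' @param control The control label; must occur exactly once in `treatments`.
#' @param timepoints Strictly increasing numeric vector of minutes.
#' @param replicates Number of biological replicates per treatment/timepoint
#'   group; at least 2.
#' @param mode Acquisition mode, one of `"HIS10"`, `"DDA"`, `"DIA"`. Carried
#'   as an annotation only.
#'
#' @return A `study_design` object.
#' @export
study_design <- function(treatments, control = "DMSO", timepoints = 180,
                         replicates = 3, mode = c("DDA", "DIA", "HIS10")) {
  mode <- match.arg(mode)
  if (sum(treatments == control) != 1L) {
    stop("control label '", control, "' must appear exactly once in treatments")
  }
  if (replicates < 2) stop("replicates must be >= 2")
  if (length(timepoints) < 1 || any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing")
  }
  structure(
    list(treatments = treatments, control = control,
         timepoints = as.numeric(timepoints),
         replicates = as.integer(replicates), mode = mode),
    class = "study_design"
  )
}

design_samples <- function(design) {
  grid <- expand.grid(
    replicate = seq_len(design$replicates),
    timepoint = design$timepoints,
    treatment = design$treatments,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("treatment", "timepoint", "replicate")]
  grid$sample_id <- sprintf("%s_%g_%d", grid$treatment, grid$timepoint,
                            grid$replicate)
  grid[, c("sample_id", "treatment", "timepoint", "replicate")]
}

#' Simulate a site-level intensity table with known ground truth
#'
#' Generates log2-normal label-free intensities for `n_entries` synthetic
#' diGly sites under a treatment/timepoint/replicate design. Each entry is
#' assigned a class (`null`, `enriched`, `depleted`); non-null entries carry
#' a planted log2 effect in every non-control treatment, applied identically
#' at all timepoints unless a per-timepoint profile is given. Cells are then
#' independently censored with probability decreasing logistically in the
#' true intensity, emulating the left-censored (missing-not-at-random)
#' missingness of label-free proteomics.
#'
#' @param design A [study_design()].
#' @param n_entries Number of site entries (> 0).
#' @param effect_fractions Named proportions over classes
#'   `c(null = , enriched = , depleted = )`; must sum to 1.
#' @param effect_size Planted effect magnitude in log2 units (> 0); enriched
#'   entries get `+effect_size`, depleted entries `-effect_size`.
#' @param baseline_mean Baseline log2 intensity; default 25, a typical LFQ
#'   scale.
#' @param baseline_sd Between-entry spread of baselines (log2); default 0,
#'   so every null entry has expectation `baseline_mean`.
#' @param noise_sd Replicate noise in log2 units (> 0); default 0.25.
#' @param missing_location,missing_scale Parameters of the logistic
#'   censoring curve: a cell with true log2 intensity `I` is missing with
#'   probability `plogis((missing_location - I) / missing_scale)`. Defaults:
#'   `baseline_mean - 1.5` and 0.3.
#' @param timepoint_profile Optional named multiplier per timepoint applied
#'   to the planted effect (names = timepoints); default: effect identical at
#'   all timepoints.
#' @param seed Integer seed; the same seed reproduces the table bit for bit.
#'
#' @return List with `table` (a [site_table()]) and `truth` (data frame with
#'   `entry_id`, `class`, `mu`, `sigma`, and one `delta_<treatment>` column
#'   per non-control treatment).
#' @export
simulate_site_table <- function(design, n_entries,
                                effect_fractions = c(null = 0.6,
                                                     enriched = 0.2,
                                                     depleted = 0.2),
                                effect_size = 2,
                                baseline_mean = 25,
                                baseline_sd = 0,
                                noise_sd = 0.25,
                                missing_location = baseline_mean - 1.5,
                                missing_scale = 0.3,
                                timepoint_profile = NULL,
                                seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (n_entries <= 0) stop("n_entries must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  fr <- effect_fractions[c("null", "enriched", "depleted")]
  fr[is.na(fr)] <- 0
  names(fr) <- c("null", "enriched", "depleted")
  if (abs(sum(fr) - 1) > 1e-8) stop("effect_fractions must sum to 1")
  if (is.null(timepoint_profile)) {
    timepoint_profile <- setNames(rep(1, length(design$timepoints)),
                                  design$timepoints)
  }

  set.seed(seed)
  cls <- sample(c("null", "enriched", "depleted"), n_entries,
                replace = TRUE, prob = fr)
  delta <- ifelse(cls == "enriched", effect_size,
                  ifelse(cls == "depleted", -effect_size, 0))
  mu <- baseline_mean + if (baseline_sd > 0) rnorm(n_entries, 0, baseline_sd) else 0

  samples <- design_samples(design)
  n_s <- nrow(samples)
  is_ctrl <- samples$treatment == design$control
  tp_mult <- timepoint_profile[as.character(samples$timepoint)]
  tp_mult[is.na(tp_mult)] <- 1

  true_mean <- matrix(mu, n_entries, n_s)
  eff_cols <- which(!is_ctrl)
  if (length(eff_cols)) {
    true_mean[, eff_cols] <- true_mean[, eff_cols] +
      outer(delta, tp_mult[eff_cols])
  }
  values <- true_mean + matrix(rnorm(n_entries * n_s, 0, noise_sd),
                               n_entries, n_s)
  p_miss <- plogis((missing_location - values) / missing_scale)
  values[matrix(runif(n_entries * n_s), n_entries, n_s) < p_miss] <- NA

  entries <- data.frame(
    entry_id = sprintf("site_%05d", seq_len(n_entries)),
    accession = sprintf("P%05d", seq_len(n_entries)),
    accessions = sprintf("P%05d", seq_len(n_entries)),
    position = sample(20:800, n_entries, replace = TRUE),
    residue = "K",
    window = random_windows(n_entries),
    multiplicity = 1L,
    stringsAsFactors = FALSE
  )
  tab <- site_table(values, entries, samples, level = "site")

  truth <- data.frame(entry_id = entries$entry_id, class = cls,
                      mu = mu, sigma = noise_sd, stringsAsFactors = FALSE)
  for (trt in setdiff(design$treatments, design$control)) {
    truth[[paste0("delta_", trt)]] <- delta
  }
  list(table = tab, truth = truth)
}

# Random 31-mer windows with K at the centre (position 16).
random_windows <- function(n) {
  if (n == 0) return(character(0))
  chars <- matrix(sample(AMINO_ACIDS, n * WINDOW_WIDTH, replace = TRUE),
                  n, WINDOW_WIDTH)
  chars[, WINDOW_FLANK + 1L] <- "K"
  apply(chars, 1, paste, collapse = "")
}

#' Simulate site entries on ubiquitin/Ubl reference sequences
#'
#' Emits one site entry per internal lysine of each reference sequence, with
#' the 31-residue sequence window cut from the reference (padded with `_` at
#' the termini) and intensities following planted per-lysine, per-treatment
#' log2 effects. Used to exercise the chain-linkage topology pipeline with a
#' known answer.
#'
#' @param design A [study_design()].
#' @param references List of [ubl_reference()] objects (see
#'   [read_ubl_fasta()]).
#' @param effects Data frame with columns `ubl`, `position`, `treatment`,
#'   `delta` planting log2 effects; positions absent from it get delta 0.
#'   Every (`ubl`, `position`) pair must be a lysine of that reference.
#' @param baseline_mean,noise_sd Baseline log2 intensity and replicate noise.
#' @param seed Integer seed.
#'
#' @return A [site_table()] with one entry per reference lysine.
#' @export
simulate_ubl_sites <- function(design, references, effects = NULL,
                               baseline_mean = 25, noise_sd = 0.25,
                               seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (noise_sd <= 0) stop("noise_sd must be positive")
  ref_names <- vapply(references, function(r) r$name, character(1))
  names(references) <- ref_names

  if (!is.null(effects)) {
    for (i in seq_len(nrow(effects))) {
      ref <- references[[effects$ubl[i]]]
      if (is.null(ref)) stop("unknown Ubl '", effects$ubl[i], "' in effects")
      if (!effects$position[i] %in% ref$lysines) {
        stop("position ", effects$position[i], " is not a lysine in ",
             effects$ubl[i])
      }
    }
  }

  rows <- do.call(rbind, lapply(references, function(r) {
    if (!length(r$lysines)) return(NULL)
    data.frame(ubl = r$name, accession = r$accession, position = r$lysines,
               stringsAsFactors = FALSE)
  }))
  rows$entry_id <- sprintf("%s_K%d", rows$ubl, rows$position)
  rows$window <- mapply(function(u, p) cut_window(references[[u]]$sequence, p),
                        rows$ubl, rows$position)

  samples <- design_samples(design)
  n_e <- nrow(rows)
  n_s <- nrow(samples)
  delta <- matrix(0, n_e, n_s)
  if (!is.null(effects)) {
    for (i in seq_len(nrow(effects))) {
      e_idx <- which(rows$ubl == effects$ubl[i] &
                     rows$position == effects$position[i])
      s_idx <- which(samples$treatment == effects$treatment[i])
      delta[e_idx, s_idx] <- effects$delta[i]
    }
  }

  set.seed(seed)
  values <- baseline_mean + delta +
    matrix(rnorm(n_e * n_s, 0, noise_sd), n_e, n_s)

  entries <- data.frame(
    entry_id = rows$entry_id,
    accession = rows$ubl,
    accessions = rows$accession,
    position = rows$position,
    residue = "K",
    window = rows$window,
    multiplicity = 1L,
    stringsAsFactors = FALSE
  )
  site_table(values, entries, samples, level = "site")
}

# 31-mer window around position `pos` of `seq`, padded with "_" past the
# termini.
cut_window <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  idx <- (pos - WINDOW_FLANK):(pos + WINDOW_FLANK)
  out <- ifelse(idx >= 1 & idx <= length(chars), chars[pmax(idx, 1)], WINDOW_PAD)
  paste(out, collapse = "")
}

#' Generate random peptide sequences
#'
#' Uniform i.i.d. draws from the 20 standard amino acids, e.g. to build the
#' randomised 31-mer control set for surface-accessibility or motif
#' comparisons.
#'
#' @param n Number of peptides (>= 0).
#' @param length Peptide length (>= 1); default 31.
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
random_peptides <- function(n, length = 31, seed = 1) {
  if (length < 1) stop("length must be >= 1")
  if (n == 0) return(character(0))
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(AMINO_ACIDS, length, replace = TRUE), collapse = "")
  }, character(1))
}

#' Write a synthetic-truth record to TSV
#'
#' @param truth Truth data frame from [simulate_site_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
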