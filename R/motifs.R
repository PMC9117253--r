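# Positional amino-acid frequency profiles around modified lysines and the
# site-selection rules feeding motif and surface-accessibility comparisons.

#' Build a positional amino-acid profile from sequence windows
#'
#' Counts residues per position over a set of 31-mer windows (15 residues
#' either side of the modified lysine, `_`-padded at protein termini) and
#' converts them to per-position frequencies. Padding is excluded from the
#' frequency denominators. The centre residue must be a lysine.
#'
#' @param windows Character vector of 31-character windows.
#' @return A `motif_profile`: list with `counts` and `frequencies`
#'   (31 positions x 20 amino acids), `n_windows`, and `padding` counts per
#'   position.
#' @export
build_profile <- function(windows) {
  if (!length(windows)) stop("no windows supplied")
  bad <- which(nchar(windows) != WINDOW_WIDTH)
  if (length(bad)) {
    stop("window(s) of wrong length at index: ", paste(bad, collapse = ", "))
  }
  centre <- substr(windows, WINDOW_FLANK + 1L, WINDOW_FLANK + 1L)
  if (any(centre != "K")) {
    stop("window(s) without K at the centre at index: ",
         paste(which(centre != "K"), collapse = ", "))
  }
  chars <- matrix(unlist(strsplit(windows, "")), ncol = WINDOW_WIDTH,
                  byrow = TRUE)
  positions <- seq_len(WINDOW_WIDTH) - WINDOW_FLANK - 1L
  counts <- t(vapply(seq_len(WINDOW_WIDTH), function(p) {
    table(factor(chars[, p], levels = AMINO_ACIDS))
  }, integer(length(AMINO_ACIDS))))
  dimnames(counts) <- list(positions, AMINO_ACIDS)
  padding <- vapply(seq_len(WINDOW_WIDTH), function(p) {
    sum(chars[, p] == WINDOW_PAD)
  }, integer(1))
  denom <- rowSums(counts)
  freq <- counts / ifelse(denom > 0, denom, 1)
  structure(
    list(counts = counts, frequencies = freq,
         n_windows = length(windows),
         padding = setNames(padding, positions)),
    class = "motif_profile"
  )
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("<motif_profile> %d windows, %d positions x %d residues\n",
              x$n_windows, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Log2 fold-change of positional amino-acid frequencies
#'
#' `log2((f_fg + pc_fg) / (f_ctrl + pc_ctrl))` per position and residue.
#' Each profile contributes its own pseudocount, by default
#' `1 / (n_windows + 20)`, so identical profiles give an exactly zero
#' matrix and zero frequencies stay finite.
#'
#' @param foreground,control `motif_profile` objects.
#' @param pseudocount Optional common pseudocount overriding the per-profile
#'   default.
#' @return 31 x 20 matrix of log2 ratios.
#' @export
frequency_fold_change <- function(foreground, control, pseudocount = NULL) {
  stopifnot(inherits(foreground, "motif_profile"),
            inherits(control, "motif_profile"))
  pc_fg <- if (is.null(pseudocount)) 1 / (foreground$n_windows + 20) else pseudocount
  pc_ct <- if (is.null(pseudocount)) 1 / (control$n_windows + 20) else pseudocount
  log2((foreground$frequencies + pc_fg) / (control$frequencies + pc_ct))
}

#' Select background (control) sites for motif comparison
#'
#' Sites observed in every control replicate (pre-imputation) and not
#' significant in any treatment contrast.
#'
#' @param test_results Named list of result data frames from
#'   [permutation_test()], one per treatment.
#' @param identification A pre-imputation [site_table()] recording observed
#'   cells.
#' @param control Control treatment label.
#' @return Character vector of entry ids.
#' @export
select_control_sites <- function(test_results, identification,
                                 control = "DMSO") {
  cols <- sample_index(identification, control)
  obs_all <- rowSums(is.na(identification$values[, cols, drop = FALSE])) == 0
  ids <- identification$entries$entry_id[obs_all]
  for (res in test_results) {
    sig <- res$entry_id[res$significant]
    ids <- setdiff(ids, sig)
  }
  ids
}

#' Select the top treatment-exclusive sites
#'
#' Ranks the shared sites by decreasing fold-change in treatment A, keeps
#' those whose fold-change in treatment B stays below `threshold` log2 units
#' (less than twofold by default), and truncates to the top `n`. Ties are
#' broken by entry id.
#'
#' @param test_results_a,test_results_b Result data frames from
#'   [permutation_test()] over a shared site-key space.
#' @param n Number of sites to keep, default 100.
#' @param threshold Exclusivity cutoff on the B fold-change (log2), default 1.
#' @return Character vector of at most `n` entry ids; a warning is issued
#'   when fewer qualify.
#' @export
select_top_exclusive <- function(test_results_a, test_results_b, n = 100,
                                 threshold = 1) {
  common <- intersect(test_results_a$entry_id, test_results_b$entry_id)
  fa <- test_results_a$difference[match(common, test_results_a$entry_id)]
  fb <- test_results_b$difference[match(common, test_results_b$entry_id)]
  qualify <- fb < threshold
  ids <- common[qualify]
  fa <- fa[qualify]
  ord <- order(-fa, ids)
  ids <- ids[ord]
  if (length(ids) < n) {
    warning("only ", length(ids), " sites qualify (requested ", n, ")")
    return(ids)
  }
  ids[seq_len(n)]
}
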