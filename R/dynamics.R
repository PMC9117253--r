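# Substrate dynamics summaries: fold-change-profile classification over the
# time course, cross-treatment group distributions, Venn membership of
# treatment-exclusive identifications, and sites-per-protein counts.

#' Classify a fold-change profile as Enriched / Unchanged / Depleted
#'
#' A substrate is `Enriched` when its log2 fold-change versus control
#' exceeds the threshold (default 1, i.e. more than twofold) at one or more
#' timepoints, `Depleted` when it falls below the negative threshold at one
#' or more timepoints, and `Unchanged` otherwise. A profile crossing both
#' thresholds receives the dual label `{Enriched, Depleted}`. The
#' comparisons are strict (`>`, `<`).
#'
#' @param fc Numeric vector of log2 fold-changes over timepoints; at least
#'   one finite value required (NAs are ignored).
#' @param threshold Log2 threshold, default 1.
#' @return Character vector: a non-empty subset of
#'   `c("Enriched", "Depleted")`, or `"Unchanged"`.
#' @export
classify_profile <- function(fc, threshold = 1) {
  fc <- fc[is.finite(fc)]
  if (!length(fc)) stop("profile has no finite fold-changes")
  labels <- c(if (max(fc) > threshold) "Enriched",
              if (min(fc) < -threshold) "Depleted")
  if (is.null(labels)) "Unchanged" else labels
}

#' Classify many substrates from a fold-change matrix
#'
#' @param fc_matrix Matrix of log2 fold-changes, substrates in rows and
#'   timepoints in columns; rownames are substrate ids.
#' @param threshold Passed to [classify_profile()].
#' @return Named list mapping substrate id to its label set.
#' @export
classify_substrates <- function(fc_matrix, threshold = 1) {
  out <- lapply(seq_len(nrow(fc_matrix)), function(i) {
    classify_profile(fc_matrix[i, ], threshold)
  })
  names(out) <- rownames(fc_matrix)
  out
}

DYNAMICS_CATEGORIES <- c("Enriched", "Unchanged", "Depleted", "Not identified")

#' Cross-tabulate dynamics groups between two treatments
#'
#' For each group of treatment A (`Enriched`, `Unchanged`, `Depleted`), the
#' percentage distribution of its member substrates' status under treatment
#' B. Substrates absent from B count as `Not identified`. A dual-labelled
#' substrate contributes to both A-groups it belongs to; as a B-status it is
#' counted once, with `Enriched` taking precedence over `Depleted`.
#'
#' @param groups_a,groups_b Named lists mapping substrate id to label set,
#'   as returned by [classify_substrates()].
#' @return Matrix of percentages, A-groups in rows and the four B categories
#'   in columns; each row sums to 100.
#' @export
cross_tabulate <- function(groups_a, groups_b) {
  a_groups <- c("Enriched", "Unchanged", "Depleted")
  b_status <- function(id) {
    lab <- groups_b[[id]]
    if (is.null(lab)) return("Not identified")
    for (g in c("Enriched", "Depleted", "Unchanged")) {
      if (g %in% lab) return(g)
    }
    "Unchanged"
  }
  out <- matrix(NA_real_, length(a_groups), length(DYNAMICS_CATEGORIES),
                dimnames = list(a_groups, DYNAMICS_CATEGORIES))
  for (g in a_groups) {
    members <- names(groups_a)[vapply(groups_a, function(l) g %in% l,
                                      logical(1))]
    if (!length(members)) {
      out[g, ] <- NA_real_
      next
    }
    status <- vapply(members, b_status, character(1))
    tab <- table(factor(status, levels = DYNAMICS_CATEGORIES))
    out[g, ] <- 100 * as.numeric(tab) / length(members)
  }
  out
}

#' Venn-region membership of site identifications across treatments
#'
#' A site counts as identified in a treatment when it is observed
#' (non-missing, pre-imputation) in at least one replicate of that
#' treatment. Each site is assigned to the exact region of the treatment
#' power set where it is identified; region counts partition the distinct
#' identified sites.
#'
#' @param tables Either a single [site_table()] (treatments taken from its
#'   sample annotations) or a named list of per-treatment [site_table()]s.
#' @return Data frame with `region` (treatment names joined by `"+"`) and
#'   `count`, covering every non-empty region.
#' @export
venn_membership <- function(tables) {
  if (inherits(tables, "site_table")) {
    trts <- unique(tables$samples$treatment)
    ident <- lapply(trts, function(trt) {
      cols <- sample_index(tables, trt)
      ids <- tables$entries$entry_id
      ids[rowSums(!is.na(tables$values[, cols, drop = FALSE])) > 0]
    })
    names(ident) <- trts
  } else {
    ident <- lapply(tables, function(tb) {
      tb$entries$entry_id[rowSums(!is.na(tb$values)) > 0]
    })
    trts <- names(tables)
  }
  all_ids <- unique(unlist(ident))
  if (!length(all_ids)) {
    return(data.frame(region = character(0), count = integer(0)))
  }
  member <- vapply(ident, function(ids) all_ids %in% ids,
                   logical(length(all_ids)))
  member <- matrix(member, nrow = length(all_ids),
                   dimnames = list(NULL, trts))
  region <- apply(member, 1, function(m) paste(trts[m], collapse = "+"))
  tab <- table(region)
  data.frame(region = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sites per protein and correlation with molecular weight
#'
#' Counts distinct modified positions per leading accession and, when
#' molecular weights are supplied, their Pearson correlation with protein
#' molecular weight. Accessions lacking a weight are excluded from the
#' correlation with a warning.
#'
#' @param table A site-level [site_table()].
#' @param weights Optional named numeric vector of molecular weights (kDa)
#'   per accession.
#' @return List with `counts` (data frame `accession`, `n_sites`) and
#'   `correlation` (Pearson r, or `NA` when no weights given).
#' @export
sites_per_protein <- function(table, weights = NULL) {
  stopifnot(inherits(table, "site_table"))
  e <- table$entries
  key <- unique(data.frame(accession = e$accession, position = e$position,
                           stringsAsFactors = FALSE))
  tab <- table(key$accession)
  counts <- data.frame(accession = names(tab), n_sites = as.integer(tab),
                       stringsAsFactors = FALSE, row.names = NULL)
  r <- NA_real_
  if (!is.null(weights)) {
    has_w <- counts$accession %in% names(weights)
    if (any(!has_w)) {
      warning(sum(!has_w), " accession(s) lacking a molecular weight were ",
              "excluded from the correlation")
    }
    sub <- counts[has_w, , drop = FALSE]
    r <- pearson(sub$n_sites, unname(weights[sub$accession]))
  }
  list(counts = counts, correlation = r)
}
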