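# Chain-linkage topology: locate diGly peptides on Ub/Ubl reference
# sequences, merge homolog-ambiguous matches, build per-lysine radar
# profiles, and compute pairwise Ub/Ubl homology.

#' Map a modified peptide onto reference sequences
#'
#' Exact substring search of the peptide in every reference; each occurrence
#' contributes a `(reference, start + modified_index - 1)` match with
#' 1-based coordinates. Matches whose mapped residue is not a lysine are
#' discarded with a warning. Overlapping occurrences are all reported.
#'
#' @param peptide Amino-acid string, length >= 5.
#' @param modified_index 1-based position of the modified residue within the
#'   peptide.
#' @param references List of [ubl_reference()] objects.
#' @return Data frame with `ubl`, `accession`, `position` (possibly empty).
#' @export
map_modified_peptide <- function(peptide, modified_index, references) {
  if (nchar(peptide) < 5) stop("peptide must be at least 5 residues")
  if (modified_index < 1 || modified_index > nchar(peptide)) {
    stop("modified_index outside the peptide")
  }
  out <- list()
  for (ref in references) {
    starts <- find_occurrences(ref$sequence, peptide)
    for (st in starts) {
      pos <- st + modified_index - 1L
      if (substr(ref$sequence, pos, pos) != "K") {
        warning("match of peptide in ", ref$name, " at ", st,
                " maps the modified residue to a non-lysine; discarded")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        ubl = ref$name, accession = ref$accession, position = pos,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(ubl = character(0), accession = character(0),
                      position = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# All (possibly overlapping) 1-based start positions of `pattern` in
# `subject`, via repeated fixed-string search.
find_occurrences <- function(subject, pattern) {
  starts <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(pattern, substring(subject, from), fixed = TRUE)
    if (hit == -1L) break
    st <- from + as.integer(hit) - 1L
    starts <- c(starts, st)
    from <- st + 1L
  }
  starts
}

#' Collapse homolog-ambiguous matches into linkage records
#'
#' All matches originating from one peptide merge into a single record with
#' joint reference and position sets (e.g. a peptide shared verbatim by
#' SUMO2 and SUMO3 yields one record with accessions `{SUMO2, SUMO3}` and
#' the offset position pair). Matches from distinct peptides never merge.
#'
#' @param matches Named list: one element per peptide (name = entry id),
#'   each a match data frame from [map_modified_peptide()].
#' @return Data frame with `entry_id`, `ubls`, `positions` (both
#'   `/`-joined, sorted), `label` and `n_matches`; peptides with no match
#'   are dropped.
#' @export
collapse_ambiguity <- function(matches) {
  rows <- lapply(names(matches), function(id) {
    m <- matches[[id]]
    if (!nrow(m)) return(NULL)
    ubls <- sort(unique(m$ubl))
    poss <- sort(unique(m$position))
    data.frame(
      entry_id = id,
      ubls = paste(ubls, collapse = "/"),
      positions = paste(poss, collapse = "/"),
      label = paste0(paste(ubls, collapse = "/"), "-K",
                     paste(poss, collapse = "/")),
      n_matches = nrow(m),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(entry_id = character(0), ubls = character(0),
                      positions = character(0), label = character(0),
                      n_matches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Per-lysine linkage fold-change profiles (radar table)
#'
#' Joins per-entry test results (one set per treatment contrast) onto
#' collapsed linkage records and reports one row per (reference,
#' position-set) with the log2 fold-change versus control per treatment.
#' Entries sharing a record are averaged; combinations without data are
#' `NA`, never zero.
#'
#' @param records Collapsed records from [collapse_ambiguity()].
#' @param test_results Named list (treatment -> result data frame from
#'   [permutation_test()]).
#' @return Data frame: `ubls`, `positions`, `label`, then one
#'   `fc_<treatment>` column per treatment.
#' @export
linkage_radar <- function(records, test_results) {
  keys <- unique(records[, c("ubls", "positions", "label")])
  out <- keys
  for (trt in names(test_results)) {
    res <- test_results[[trt]]
    fc <- vapply(seq_len(nrow(keys)), function(i) {
      ids <- records$entry_id[records$label == keys$label[i]]
      d <- res$difference[match(ids, res$entry_id)]
      d <- d[!is.na(d)]
      if (!length(d)) NA_real_ else mean(d)
    }, numeric(1))
    out[[paste0("fc_", trt)]] <- fc
  }
  rownames(out) <- NULL
  out
}

#' Pairwise identity and similarity of two Ubl sequences
#'
#' Equal-length sequences are compared position by position; unequal
#' lengths are first globally aligned (match +1, mismatch 0, gap -1).
#' Identity is the fraction of alignment positions with identical residues.
#' Similarity additionally counts positions whose residue pair has a
#' non-negative (default) or strictly positive (`strict = TRUE`) score in
#' the substitution matrix. The default matrix is BLOSUM80, the appropriate
#' hard matrix for closely related sequences such as Ub and NEDD8.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param matrix Substitution matrix name available from Biostrings
#'   (default `"BLOSUM80"`).
#' @param strict Count only strictly positive substitution scores as
#'   similar.
#' @return List with `identity` and `similarity` fractions of the alignment
#'   length.
#' @export
ubl_homology <- function(a, b, matrix = "BLOSUM80", strict = FALSE) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (nchar(a) == nchar(b)) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
  } else {
    aln <- align_global(a, b)
    av <- aln$a
    bv <- aln$b
  }
  subst <- load_substitution_matrix(matrix)
  ident <- av == bv & av != "-"
  scores <- rep(-Inf, length(av))
  ok <- av != "-" & bv != "-"
  scores[ok] <- subst[cbind(av[ok], bv[ok])]
  similar <- ident | (if (strict) scores > 0 else scores >= 0)
  list(identity = mean(ident), similarity = mean(similar))
}

load_substitution_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

# Needleman-Wunsch with match +1, mismatch 0, gap -1; returns the aligned
# character vectors (gaps as "-"). Small sequences only.
align_global <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n)
  S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(
        S[i, j] + (av[i] == bv[j]),
        S[i, j + 1] - 1,
        S[i + 1, j] - 1
      )
    }
  }
  ra <- character(0)
  rb <- character(0)
  i <- n
  j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (av[i] == bv[j])) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1
    }
  }
  list(a = ra, b = rb)
}

#' Map every site of a table onto Ubl references
#'
#' Convenience wrapper running [map_modified_peptide()] on the de-padded
#' sequence window of every entry and collapsing the results.
#'
#' @param table A site-level [site_table()] whose windows derive from the
#'   reference sequences (e.g. from [simulate_ubl_sites()]).
#' @param references List of [ubl_reference()] objects.
#' @return Collapsed records, see [collapse_ambiguity()].
#' @export
map_table_sites <- function(table, references) {
  e <- table$entries
  matches <- lapply(seq_len(nrow(e)), function(i) {
    w <- e$window[i]
    stripped <- gsub(WINDOW_PAD, "", w, fixed = TRUE)
    n_lead <- nchar(w) - nchar(sub(paste0("^", WINDOW_PAD, "+"), "", w))
    map_modified_peptide(stripped, WINDOW_FLANK + 1L - n_lead, references)
  })
  names(matches) <- e$entry_id
  collapse_ambiguity(matches)
}
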