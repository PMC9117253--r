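# Readers, writers and identification filters for the two quantification
# dialects (MaxQuant-style sites/proteinGroups, Spectronaut-style DIA wide)
# and the Ub/Ubl reference FASTA.

DEFAULT_SAMPLE_PATTERN <- "^(.+)_([0-9.]+)_([0-9]+)$"

# Parse sample annotations from column names following
# "<treatment>_<timepoint>_<replicate>".
parse_sample_names <- function(sample_names,
                               pattern = DEFAULT_SAMPLE_PATTERN) {
  m <- regmatches(sample_names, regexec(pattern, sample_names))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("sample name(s) not matching pattern '", pattern, "': ",
         paste(sample_names[bad], collapse = ", "))
  }
  data.frame(
    sample_id = sample_names,
    treatment = vapply(m, `[`, character(1), 2L),
    timepoint = as.numeric(vapply(m, `[`, character(1), 3L)),
    replicate = as.integer(vapply(m, `[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
}

# Raw-scale intensity text -> log2 with 0/blank/non-numeric mapped to NA.
raw_to_log2 <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[!is.finite(v) | v <= 0] <- NA
  log2(v)
}

# MaxQuant-style flag column: "+" marks the flag; blanks (read as NA when a
# column is entirely empty) mean unflagged.
flag_col <- function(x) !is.na(x) & x == "+"

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Read a MaxQuant-style diGly sites table
#'
#' Expects a tab-separated file with columns `Leading proteins`, `Proteins`,
#' `Position`, `Amino acid`, `Sequence window`, `Reverse`,
#' `Potential contaminant` (flag columns use `"+"`), an optional
#' `Multiplicity`, and one raw intensity column per sample named
#' `<intensity_prefix><treatment>_<timepoint>_<replicate>`. Intensities of
#' zero or blank are mapped to missing; everything else is log2-transformed.
#'
#' @param path File path.
#' @param intensity_prefix Prefix of intensity columns (default
#'   `"Intensity "`).
#' @param sample_pattern Regex with three capture groups
#'   (treatment, timepoint, replicate) applied to the de-prefixed column
#'   names.
#' @return A site-level [site_table()] with flags populated.
#' @export
read_maxquant_sites <- function(path, intensity_prefix = "Intensity ",
                                sample_pattern = DEFAULT_SAMPLE_PATTERN) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  require_columns(df, c("Leading proteins", "Proteins", "Position",
                        "Amino acid", "Sequence window", "Reverse",
                        "Potential contaminant"), path)
  int_cols <- grep(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                    intensity_prefix)),
                   names(df), value = TRUE)
  if (!length(int_cols)) {
    stop("file '", path, "' has no intensity columns with prefix '",
         intensity_prefix, "'")
  }
  pos <- suppressWarnings(as.integer(df$Position))
  if (anyNA(pos)) {
    stop("malformed 'Position' field at row(s): ",
         paste(which(is.na(pos)), collapse = ", "))
  }
  samples <- parse_sample_names(substring(int_cols, nchar(intensity_prefix) + 1L),
                                sample_pattern)
  values <- vapply(int_cols, function(cn) raw_to_log2(df[[cn]]),
                   numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(NULL, samples$sample_id))
  mult <- if ("Multiplicity" %in% names(df)) as.integer(df$Multiplicity) else 1L
  entries <- data.frame(
    entry_id = sprintf("%s_K%d_%d", df$`Leading proteins`, pos, mult),
    accession = df$`Leading proteins`,
    accessions = df$Proteins,
    position = pos,
    residue = df$`Amino acid`,
    window = df$`Sequence window`,
    multiplicity = mult,
    reverse = flag_col(df$Reverse),
    contaminant = flag_col(df$`Potential contaminant`),
    only_by_site = FALSE,
    stringsAsFactors = FALSE
  )
  site_table(values, entries, samples, level = "site")
}

#' Read a MaxQuant-style protein groups table
#'
#' Protein-level companion of [read_maxquant_sites()]. Requires
#' `Protein IDs`, `Reverse`, `Potential contaminant` and
#' `Only identified by site`; an optional `Mol. weight [kDa]` column is kept
#' as entry metadata for [sites_per_protein()]-style analyses.
#'
#' @inheritParams read_maxquant_sites
#' @return A protein-level [site_table()].
#' @export
read_maxquant_proteins <- function(path, intensity_prefix = "LFQ intensity ",
                                   sample_pattern = DEFAULT_SAMPLE_PATTERN) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  require_columns(df, c("Protein IDs", "Reverse", "Potential contaminant",
                        "Only identified by site"), path)
  int_cols <- grep(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                    intensity_prefix)),
                   names(df), value = TRUE)
  if (!length(int_cols)) {
    stop("file '", path, "' has no intensity columns with prefix '",
         intensity_prefix, "'")
  }
  samples <- parse_sample_names(substring(int_cols, nchar(intensity_prefix) + 1L),
                                sample_pattern)
  values <- vapply(int_cols, function(cn) raw_to_log2(df[[cn]]),
                   numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(NULL, samples$sample_id))
  lead <- vapply(strsplit(df$`Protein IDs`, ";", fixed = TRUE), `[`,
                 character(1), 1L)
  entries <- data.frame(
    entry_id = lead,
    accession = lead,
    accessions = df$`Protein IDs`,
    reverse = flag_col(df$Reverse),
    contaminant = flag_col(df$`Potential contaminant`),
    only_by_site = flag_col(df$`Only identified by site`),
    stringsAsFactors = FALSE
  )
  if ("Mol. weight [kDa]" %in% names(df)) {
    entries$mol_weight_kda <- as.numeric(df$`Mol. weight [kDa]`)
  }
  site_table(values, entries, samples, level = "protein")
}

DIGLY_TOKEN <- "[GlyGly (K)]"

#' Read a Spectronaut-style wide DIA site report
#'
#' Expects tab-separated columns `PG.ProteinAccessions`,
#' `EG.ModifiedSequence`, `PTM.SiteLocation`, `PTM.SiteAA`,
#' `PTM.FlankingRegion`, and one quantity column per sample named
#' `<treatment>_<timepoint>_<replicate><quantity_suffix>`. Rows whose
#' modified sequence lacks the diGly token `[GlyGly (K)]` are dropped;
#' quantities are log2-transformed with `Filtered`/`NaN`/blank/0 mapped to
#' missing.
#'
#' @param path File path.
#' @param quantity_suffix Suffix identifying quantity columns (default
#'   `".PEP.Quantity"`).
#' @param sample_pattern Regex for the de-suffixed sample names.
#' @return A site-level [site_table()].
#' @export
read_spectronaut_wide <- function(path, quantity_suffix = ".PEP.Quantity",
                                  sample_pattern = DEFAULT_SAMPLE_PATTERN) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  require_columns(df, c("PG.ProteinAccessions", "EG.ModifiedSequence",
                        "PTM.SiteLocation", "PTM.SiteAA",
                        "PTM.FlankingRegion"), path)
  suffix_re <- paste0(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", quantity_suffix),
                      "$")
  q_cols <- grep(suffix_re, names(df), value = TRUE)
  if (!length(q_cols)) {
    stop("file '", path, "' has no quantity columns with suffix '",
         quantity_suffix, "'")
  }
  keep <- grepl(DIGLY_TOKEN, df$EG.ModifiedSequence, fixed = TRUE)
  df <- df[keep, , drop = FALSE]
  samples <- parse_sample_names(sub(suffix_re, "", q_cols), sample_pattern)
  values <- vapply(q_cols, function(cn) raw_to_log2(df[[cn]]),
                   numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(NULL, samples$sample_id))
  lead <- vapply(strsplit(df$PG.ProteinAccessions, ";", fixed = TRUE), `[`,
                 character(1), 1L)
  pos <- as.integer(df$PTM.SiteLocation)
  entries <- data.frame(
    entry_id = sprintf("%s_K%d_1", lead, pos),
    accession = lead,
    accessions = df$PG.ProteinAccessions,
    position = pos,
    residue = df$PTM.SiteAA,
    window = df$PTM.FlankingRegion,
    multiplicity = 1L,
    modified_sequence = df$EG.ModifiedSequence,
    stringsAsFactors = FALSE
  )
  site_table(values, entries, samples, level = "site")
}

#' Write a site table in either dialect
#'
#' Inverse of the readers: `maxquant` writes raw-scale intensities
#' (`2^log2`, 0 for missing) with MaxQuant-style metadata columns;
#' `spectronaut` writes quantity columns with `Filtered` for missing cells
#' and synthesises the modified-sequence token from the window. Reading a
#' written table reproduces the matrix exactly.
#'
#' @param table A [site_table()].
#' @param path Output file.
#' @param dialect `"maxquant"` or `"spectronaut"`.
#' @param intensity_prefix,quantity_suffix Column naming, matching the
#'   readers' defaults.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path,
                             dialect = c("maxquant", "spectronaut"),
                             intensity_prefix = NULL,
                             quantity_suffix = ".PEP.Quantity") {
  dialect <- match.arg(dialect)
  e <- table$entries
  v <- table$values
  if (dialect == "maxquant") {
    if (is.null(intensity_prefix)) {
      intensity_prefix <- if (table$level == "protein") "LFQ intensity "
                          else "Intensity "
    }
    raw <- round(2^v, 6)
    raw[is.na(raw)] <- 0
    if (table$level == "protein") {
      out <- data.frame(
        `Protein IDs` = e$accessions,
        Reverse = ifelse(e$reverse, "+", ""),
        `Potential contaminant` = ifelse(e$contaminant, "+", ""),
        `Only identified by site` = ifelse(e$only_by_site, "+", ""),
        check.names = FALSE, stringsAsFactors = FALSE
      )
      if ("mol_weight_kda" %in% names(e)) {
        out$`Mol. weight [kDa]` <- e$mol_weight_kda
      }
    } else {
      out <- data.frame(
        `Leading proteins` = e$accession,
        Proteins = e$accessions,
        Position = e$position,
        `Amino acid` = e$residue,
        `Sequence window` = e$window,
        Multiplicity = e$multiplicity,
        Reverse = ifelse(e$reverse, "+", ""),
        `Potential contaminant` = ifelse(e$contaminant, "+", ""),
        check.names = FALSE, stringsAsFactors = FALSE
      )
    }
    colnames(raw) <- paste0(intensity_prefix, table$samples$sample_id)
    out <- cbind(out, as.data.frame(raw, check.names = FALSE))
  } else {
    if (table$level != "site") {
      stop("spectronaut dialect supports site-level tables only")
    }
    modseq <- if ("modified_sequence" %in% names(e)) {
      e$modified_sequence
    } else {
      # Build a tryptic-like modified sequence from the window: residues up
      # to the site lysine carry the diGly token.
      vapply(e$window, function(w) {
        stripped <- gsub(WINDOW_PAD, "", w, fixed = TRUE)
        n_lead <- nchar(w) - nchar(sub(paste0("^", WINDOW_PAD, "+"), "", w))
        k_at <- WINDOW_FLANK + 1L - n_lead
        paste0("_", substr(stripped, 1, k_at), DIGLY_TOKEN,
               substr(stripped, k_at + 1, nchar(stripped)), "_")
      }, character(1), USE.NAMES = FALSE)
    }
    q <- round(2^v, 6)
    qc <- matrix(as.character(q), nrow = nrow(v))
    qc[is.na(v)] <- "Filtered"
    colnames(qc) <- paste0(table$samples$sample_id, quantity_suffix)
    out <- data.frame(
      PG.ProteinAccessions = e$accessions,
      EG.ModifiedSequence = modseq,
      PTM.SiteLocation = e$position,
      PTM.SiteAA = e$residue,
      PTM.FlankingRegion = e$window,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(qc, check.names = FALSE,
                                    stringsAsFactors = FALSE))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop decoy, contaminant and (optionally) only-identified-by-site entries
#'
#' @param table A [site_table()] with flags populated.
#' @param drop_only_by_site Also drop entries flagged as only identified by
#'   site (protein-level convention).
#' @return Filtered [site_table()].
#' @export
filter_flags <- function(table, drop_only_by_site = FALSE) {
  keep <- !table$entries$reverse & !table$entries$contaminant
  if (drop_only_by_site) keep <- keep & !table$entries$only_by_site
  subset_table(table, which(keep))
}

#' Filter entries by valid (observed) values per replicate group
#'
#' Replicate groups are the unique treatment(/timepoint) combinations.
#' Schemes:
#' * `ALL_IN_GROUP_VS_CONTROL` — for a treatment-versus-control contrast,
#'   keep entries fully observed in every replicate of the treatment group
#'   or of the control group. With `treatment = NULL` the union over all
#'   non-control contrasts is returned.
#' * `ALL_IN_ANY_GROUP` — keep entries fully observed in at least one group.
#' * `AT_LEAST_K` — keep entries with at least `k` observed values in some
#'   group.
#'
#' @param table A [site_table()].
#' @param scheme One of the schemes above.
#' @param k Minimum observed count for `AT_LEAST_K`; must not exceed the
#'   largest group size.
#' @param control Control treatment label (needed for
#'   `ALL_IN_GROUP_VS_CONTROL`).
#' @param treatment Optional single treatment restricting
#'   `ALL_IN_GROUP_VS_CONTROL` to one contrast.
#' @param group_by Sample columns defining replicate groups.
#' @return Filtered [site_table()]; always a subset of the input rows.
#' @export
filter_valid_values <- function(table,
                                scheme = c("ALL_IN_GROUP_VS_CONTROL",
                                           "ALL_IN_ANY_GROUP",
                                           "AT_LEAST_K"),
                                k = NULL, control = NULL, treatment = NULL,
                                group_by = c("treatment", "timepoint")) {
  scheme <- match.arg(scheme)
  groups <- sample_groups(table, group_by)
  if (n_entries(table) == 0) return(table)
  obs <- !is.na(table$values)
  grp_names <- unique(groups)
  # observed counts and completeness per entry x group
  cnt <- vapply(grp_names, function(g) rowSums(obs[, groups == g, drop = FALSE]),
                numeric(nrow(obs)))
  cnt <- matrix(cnt, nrow = nrow(obs), dimnames = list(NULL, grp_names))
  size <- vapply(grp_names, function(g) sum(groups == g), integer(1))
  complete <- sweep(cnt, 2, size, `==`)

  keep <- switch(scheme,
    ALL_IN_ANY_GROUP = rowSums(complete) > 0,
    AT_LEAST_K = {
      if (is.null(k)) stop("scheme AT_LEAST_K requires 'k'")
      if (k > max(size)) {
        stop("k = ", k, " exceeds the largest replicate group size (",
             max(size), ")")
      }
      rowSums(cnt >= k) > 0
    },
    ALL_IN_GROUP_VS_CONTROL = {
      if (is.null(control)) {
        stop("scheme ALL_IN_GROUP_VS_CONTROL requires 'control'")
      }
      ctrl_groups <- unique(groups[table$samples$treatment == control])
      trt_samples <- if (is.null(treatment)) {
        table$samples$treatment != control
      } else {
        table$samples$treatment == treatment
      }
      trt_groups <- setdiff(unique(groups[trt_samples]), ctrl_groups)
      if (!length(trt_groups)) stop("no treatment groups found for contrast")
      ctrl_ok <- rowSums(complete[, ctrl_groups, drop = FALSE]) > 0
      trt_ok <- rowSums(complete[, trt_groups, drop = FALSE]) > 0
      ctrl_ok | trt_ok
    }
  )
  subset_table(table, which(keep))
}

#' A ubiquitin/Ubl reference sequence
#'
#' @param name Short name (e.g. `"Ub"`, `"SUMO2"`).
#' @param accession Database accession.
#' @param sequence Mature (processed) amino-acid sequence.
#' @return An `ubl_reference` with derived `lysines` (1-based positions of
#'   every K).
#' @export
ubl_reference <- function(name, accession, sequence) {
  if (!nzchar(sequence)) stop("empty sequence for reference '", name, "'")
  structure(
    list(name = name, accession = accession, sequence = sequence,
         lysines = which(strsplit(sequence, "")[[1]] == "K")),
    class = "ubl_reference"
  )
}

#' @export
print.ubl_reference <- function(x, ...) {
  cat(sprintf("<ubl_reference> %s (%s), %d aa, K at %s\n", x$name,
              x$accession, nchar(x$sequence),
              paste(x$lysines, collapse = ",")))
  invisible(x)
}

#' Read Ub/Ubl reference sequences from FASTA
#'
#' Headers follow `name|accession description`. The package bundles the five
#' mature Ub/Ubl sequences (Ub, NEDD8, SUMO1, SUMO2, SUMO3) at
#' `system.file("extdata", "ubl_mature.fasta", package = "ubidyn")`; the
#' sequences are truncated at the C-terminal diGly of the conjugatable form,
#' which fixes the lysine numbering used in linkage reports.
#'
#' @param path FASTA file.
#' @return Named list of [ubl_reference()] objects.
#' @export
read_ubl_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("no records in FASTA '", path, "'")
  if (any(Biostrings::width(seqs) == 0)) stop("empty record in FASTA '", path, "'")
  refs <- lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    parts <- strsplit(sub(" .*$", "", header), "|", fixed = TRUE)[[1]]
    ubl_reference(
      name = parts[1],
      accession = if (length(parts) > 1) parts[2] else parts[1],
      sequence = as.character(seqs[[i]])
    )
  })
  names(refs) <- vapply(refs, function(r) r$name, character(1))
  refs
}

#' Write Ub/Ubl references to FASTA
#'
#' @param references List of [ubl_reference()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ubl_fasta <- function(references, path) {
  seqs <- Biostrings::AAStringSet(vapply(references, function(r) r$sequence,
                                         character(1)))
  names(seqs) <- vapply(references, function(r) paste0(r$name, "|", r$accession),
                        character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Load the bundled mature Ub/Ubl reference set
#'
#' @return Named list of [ubl_reference()] objects for Ub, NEDD8, SUMO1,
#'   SUMO2 and SUMO3.
#' @export
ubl_references <- function() {
  read_ubl_fasta(system.file("extdata", "ubl_mature.fasta",
                             package = "ubidyn", mustWork = TRUE))
}
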