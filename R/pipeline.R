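# Config-driven end-to-end runs: simulate/read -> filter -> impute -> test
# -> summaries, with a structured log and a content-hash manifest.

#' Assemble a pipeline run configuration
#'
#' Presets bundle the analysis conventions of the three acquisition modes:
#' * `dda` — site-level; contaminant/decoy filter; per-contrast
#'   all-replicates identification filter; S0 = 0.1, FDR = 0.05.
#' * `dia` — site-level; diGly-peptide filter at read time; complete in all
#'   replicates of at least one treatment group; S0 = 0.1, FDR = 0.05.
#' * `his10` — protein-level; contaminant/decoy/only-by-site filter;
#'   at-least-3-replicates filter; right-sided parental gate at p = 0.05;
#'   then S0 = 0.1, FDR = 0.05 treatment tests.
#'
#' @param preset One of `"dda"`, `"dia"`, `"his10"`.
#' @param input Optional path to a quantification table; when `NULL` a
#'   synthetic table is generated from `design`.
#' @param parental_input Optional path to the parental-background protein
#'   table (his10 preset).
#' @param dialect Input dialect, `"maxquant"` or `"spectronaut"`.
#' @param design A [study_design()] used for simulation when no input is
#'   given.
#' @param control Control treatment label.
#' @param s0,fdr,n_permutations Test parameters, see [test_config()].
#' @param gate_alpha Parental-gate p-value cutoff (his10 preset).
#' @param impute_width,impute_downshift Imputation parameters, see
#'   [imputation_params()].
#' @param valid_k Minimum replicates for the `AT_LEAST_K` scheme.
#' @param n_entries Number of simulated entries when simulating.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `run_config` object.
#' @export
run_config <- function(preset = c("dda", "dia", "his10"),
                       input = NULL, parental_input = NULL,
                       dialect = c("maxquant", "spectronaut"),
                       design = NULL, control = "DMSO",
                       s0 = 0.1, fdr = 0.05, n_permutations = 250,
                       gate_alpha = 0.05,
                       impute_width = 0.3, impute_downshift = 1.8,
                       valid_k = 3, n_entries = 500, seed = 1) {
  preset <- match.arg(preset)
  dialect <- match.arg(dialect)
  if (is.null(design)) {
    design <- switch(preset,
      dda = study_design(c("DMSO", "TAK243", "MG132", "PR619"),
                         control = control, timepoints = 180,
                         replicates = 3, mode = "DDA"),
      dia = study_design(c("DMSO", "MG132", "PR619"), control = control,
                         timepoints = 180, replicates = 5, mode = "DIA"),
      his10 = study_design(c("DMSO", "TAK243", "MG132", "PR619"),
                           control = control,
                           timepoints = c(10, 30, 60, 180),
                           replicates = 3, mode = "HIS10")
    )
  }
  scheme <- switch(preset,
    dda = "ALL_IN_GROUP_VS_CONTROL",
    dia = "ALL_IN_ANY_GROUP",
    his10 = "AT_LEAST_K"
  )
  structure(
    list(preset = preset, input = input, parental_input = parental_input,
         dialect = dialect, design = design, control = control,
         scheme = scheme, valid_k = valid_k,
         s0 = s0, fdr = fdr, n_permutations = n_permutations,
         gate_alpha = gate_alpha,
         impute_width = impute_width, impute_downshift = impute_downshift,
         n_entries = n_entries, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirroring the arguments of [run_config()]; `design` is given as
#' `treatments`, `control`, `timepoints`, `replicates`, `mode`.
#'
#' @param path YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- NULL
  if (!is.null(y$treatments)) {
    design <- study_design(
      treatments = unlist(y$treatments),
      control = y$control %||% "DMSO",
      timepoints = unlist(y$timepoints) %||% 180,
      replicates = y$replicates %||% 3,
      mode = toupper(y$mode %||% "DDA")
    )
  }
  args <- y[intersect(names(y), names(formals(run_config)))]
  args$design <- design
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute an end-to-end pipeline run
#'
#' Simulates or reads the input table, applies the preset's flag and
#' valid-value filters, imputes left-censored missing values, tests every
#' non-control treatment (per timepoint) against the control, and writes
#' per-contrast result TSVs, identification Venn counts, a parameter log
#' and a content-hash manifest into `out_dir`. Two runs with the same
#' configuration produce identical manifests.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the run log lines, the per-contrast test
#'   results, and the manifest data frame.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("preset: %s", config$preset),
    sprintf("seed: %d", config$seed)
  )
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  level <- if (config$preset == "his10") "protein" else "site"
  if (is.null(config$input)) {
    sim <- simulate_site_table(config$design, n_entries = config$n_entries,
                               seed = config$seed)
    tab <- sim$table
    if (level == "protein") tab$level <- "protein"
    write_truth(sim$truth, file.path(out_dir, "truth.tsv"))
    say("input: simulated, %d entries", n_entries(tab))
  } else {
    tab <- switch(config$dialect,
      maxquant = if (level == "protein") {
        read_maxquant_proteins(config$input)
      } else {
        read_maxquant_sites(config$input)
      },
      spectronaut = read_spectronaut_wide(config$input)
    )
    say("input: %s (%s dialect), %d entries", config$input, config$dialect,
        n_entries(tab))
  }

  tab <- filter_flags(tab, drop_only_by_site = config$preset == "his10")
  say("flag filter (drop_only_by_site=%s): %d entries",
      config$preset == "his10", n_entries(tab))

  tab <- switch(config$scheme,
    ALL_IN_GROUP_VS_CONTROL = filter_valid_values(
      tab, "ALL_IN_GROUP_VS_CONTROL", control = config$control),
    ALL_IN_ANY_GROUP = filter_valid_values(tab, "ALL_IN_ANY_GROUP"),
    AT_LEAST_K = filter_valid_values(tab, "AT_LEAST_K", k = config$valid_k)
  )
  say("valid-value filter %s%s: %d entries", config$scheme,
      if (config$scheme == "AT_LEAST_K") sprintf(" (k=%d)", config$valid_k)
      else "", n_entries(tab))

  venn <- venn_membership(tab)
  write.table(venn, file.path(out_dir, "venn.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  imp <- imputation_params(width = config$impute_width,
                           downshift = config$impute_downshift,
                           seed = config$seed)
  say("imputation from lower tail of the normal distribution (default settings): width=%g downshift=%g",
      imp$width, imp$downshift)
  tab_imp <- impute_left_censored(tab, imp)

  if (config$preset == "his10" && !is.null(config$parental_input)) {
    parental <- read_maxquant_proteins(config$parental_input)
    parental <- filter_flags(parental, drop_only_by_site = TRUE)
    parental <- impute_left_censored(parental, imp)
    substrates <- his10_substrate_gate(tab_imp, parental,
                                       alpha = config$gate_alpha)
    say("parental gate: right-sided test at p = %g, %d substrates retained",
        config$gate_alpha, length(substrates))
    tab_imp <- subset_table(tab_imp, substrates)
    writeLines(substrates, file.path(out_dir, "substrates.txt"))
  }

  cfg <- test_config(s0 = config$s0, fdr = config$fdr,
                     n_permutations = config$n_permutations,
                     seed = config$seed)
  say("test: s0=%g fdr=%g permutations=%d", cfg$s0, cfg$fdr,
      cfg$n_permutations)

  results <- list()
  timepoints <- unique(tab_imp$samples$timepoint)
  for (trt in setdiff(unique(tab_imp$samples$treatment), config$control)) {
    for (tp in timepoints) {
      if (!length(sample_index(tab_imp, trt, tp))) next
      res <- permutation_test(tab_imp, trt, config$control, cfg,
                              timepoint = if (length(timepoints) > 1) tp)
      key <- if (length(timepoints) > 1) sprintf("%s_%g", trt, tp) else trt
      results[[key]] <- res
      out_file <- file.path(out_dir, sprintf("test_%s_vs_%s.tsv", key,
                                             config$control))
      write.table(res, out_file, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      say("contrast %s vs %s: %d entries, %d significant", key,
          config$control, nrow(res), sum(res$significant))
    }
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE
  )
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(log = log_lines, results = results, manifest = manifest))
}
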