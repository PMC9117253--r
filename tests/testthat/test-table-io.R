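test_that("maxquant round trip reproduces the matrix exactly", {
  set.seed(1)
  v <- matrix(rnorm(60, 25), 10, 6)
  v[sample(60, 12)] <- NA
  tab <- make_table(v)
  f <- tmp_file()
  write_site_table(tab, f, "maxquant")
  back <- read_maxquant_sites(f)
  expect_equal(unname(back$values), unname(tab$values), tolerance = 1e-6)
  expect_identical(unname(is.na(back$values)), unname(is.na(tab$values)))
  expect_identical(back$entries$window, tab$entries$window)
  expect_identical(back$samples$treatment, tab$samples$treatment)
})

test_that("spectronaut round trip reproduces the matrix and diGly filter works", {
  set.seed(2)
  v <- matrix(rnorm(40, 24), 8, 5)
  v[c(3, 17, 30)] <- NA
  tab <- make_table(v, treatments = c("DMSO"), reps = 5)
  f <- tmp_file()
  write_site_table(tab, f, "spectronaut")
  back <- read_spectronaut_wide(f)
  expect_equal(unname(back$values), unname(tab$values), tolerance = 1e-6)
  expect_identical(unname(is.na(back$values)), unname(is.na(tab$values)))
  # rows without the diGly token are dropped
  lines <- readLines(f)
  lines[2] <- gsub("[GlyGly (K)]", "[Oxidation (M)]", lines[2], fixed = TRUE)
  writeLines(lines, f)
  again <- read_spectronaut_wide(f)
  expect_equal(n_entries(again), n_entries(tab) - 1)
})

test_that("zero intensity reads as missing and flags are parsed", {
  f <- tmp_file()
  writeLines(c(
    paste("Leading proteins", "Proteins", "Position", "Amino acid",
          "Sequence window", "Multiplicity", "Reverse",
          "Potential contaminant", "Intensity PR619_180_1",
          "Intensity PR619_180_2", sep = "\t"),
    paste("P1", "P1", "10", "K", make_windows(1), "1", "", "",
          "1000", "0", sep = "\t"),
    paste("P2", "P2", "20", "K", make_windows(1, seed = 2), "1", "+", "",
          "500", "600", sep = "\t"),
    paste("P3", "P3", "30", "K", make_windows(1, seed = 3), "1", "", "+",
          "70", "80", sep = "\t")
  ), f)
  tab <- read_maxquant_sites(f)
  expect_equal(n_entries(tab), 3)
  expect_true(is.na(tab$values[1, 2]))
  expect_equal(tab$values[1, 1], log2(1000))
  expect_equal(tab$entries$reverse, c(FALSE, TRUE, FALSE))
  expect_equal(tab$entries$contaminant, c(FALSE, FALSE, TRUE))
  expect_equal(n_entries(filter_flags(tab)), 1)
})

test_that("readers name the missing column in errors", {
  f <- tmp_file()
  writeLines(c("Proteins\tPosition", "P1\t10"), f)
  expect_error(read_maxquant_sites(f), "Leading proteins")
  f2 <- tmp_file()
  writeLines(c("PG.ProteinAccessions\tEG.ModifiedSequence", "P1\t_AK_"), f2)
  expect_error(read_spectronaut_wide(f2), "PTM.SiteLocation")
})

test_that("malformed position fields are reported with the row", {
  f <- tmp_file()
  writeLines(c(
    paste("Leading proteins", "Proteins", "Position", "Amino acid",
          "Sequence window", "Reverse", "Potential contaminant",
          "Intensity A_180_1", sep = "\t"),
    paste("P1", "P1", "ten", "K", make_windows(1), "", "", "12", sep = "\t")
  ), f)
  expect_error(read_maxquant_sites(f), "row")
})

test_that("filter_flags handles only-by-site in protein mode", {
  v <- matrix(rnorm(20, 25), 5, 4)
  tab <- make_table(v, reps = 2, level = "protein")
  tab$entries$only_by_site <- c(FALSE, TRUE, FALSE, FALSE, FALSE)
  tab$entries$contaminant <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  tab$entries$reverse <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(n_entries(filter_flags(tab)), 3)
  expect_equal(n_entries(filter_flags(tab, drop_only_by_site = TRUE)), 2)
  clean <- make_table(v, reps = 2)
  expect_equal(filter_flags(clean)$values, clean$values)
})

test_that("valid-value schemes match hand enumeration", {
  # 6 entries x (3 DMSO + 3 PR619 + 3 MG132); patterns chosen by hand
  v <- matrix(25, 6, 9)
  colnames_groups <- rep(c("DMSO", "PR619", "MG132"), each = 3)
  v[2, 4:6] <- NA          # complete in DMSO & MG132
  v[3, c(1:3, 7:9)] <- NA  # complete only in PR619
  v[4, c(2, 5, 8)] <- NA   # 2/3 in every group
  v[5, 1:6] <- NA          # complete only in MG132
  v[6, c(1:4, 7)] <- NA    # 2/3 PR619, 2/3 MG132, 0/3 DMSO
  tab <- make_table(v, treatments = c("DMSO", "PR619", "MG132"), reps = 3)
  ids <- function(t) t$entries$entry_id

  all_any <- filter_valid_values(tab, "ALL_IN_ANY_GROUP")
  expect_identical(ids(all_any), sprintf("e%03d", c(1, 2, 3, 5)))

  vs_ctrl <- filter_valid_values(tab, "ALL_IN_GROUP_VS_CONTROL",
                                 control = "DMSO")
  expect_identical(ids(vs_ctrl), sprintf("e%03d", c(1, 2, 3, 5)))

  one_contrast <- filter_valid_values(tab, "ALL_IN_GROUP_VS_CONTROL",
                                      control = "DMSO", treatment = "PR619")
  expect_identical(ids(one_contrast), sprintf("e%03d", c(1, 2, 3)))

  k2 <- filter_valid_values(tab, "AT_LEAST_K", k = 2)
  expect_identical(ids(k2), sprintf("e%03d", 1:6))
  k3 <- filter_valid_values(tab, "AT_LEAST_K", k = 3)
  expect_identical(ids(k3), sprintf("e%03d", c(1, 2, 3, 5)))
  expect_error(filter_valid_values(tab, "AT_LEAST_K", k = 4), "exceeds")
})

test_that("a fully observed matrix passes every scheme unchanged", {
  v <- matrix(rnorm(30, 25), 5, 6)
  tab <- make_table(v)
  for (s in c("ALL_IN_ANY_GROUP", "AT_LEAST_K", "ALL_IN_GROUP_VS_CONTROL")) {
    out <- filter_valid_values(tab, s, k = 3, control = "DMSO")
    expect_equal(out$values, tab$values)
  }
})

test_that("filtering is monotone in k", {
  set.seed(4)
  v <- matrix(rnorm(200, 25), 20, 10)
  v[sample(200, 80)] <- NA
  tab <- make_table(v, reps = 5)
  sizes <- vapply(1:5, function(k) {
    n_entries(filter_valid_values(tab, "AT_LEAST_K", k = k))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("bundled Ubl FASTA has the expected lysine maps", {
  refs <- ubl_references()
  expect_named(refs, c("Ub", "NEDD8", "SUMO1", "SUMO2", "SUMO3"))
  expect_identical(refs$Ub$lysines, c(6L, 11L, 27L, 29L, 33L, 48L, 63L))
  expect_equal(nchar(refs$Ub$sequence), 76)
  expect_equal(nchar(refs$NEDD8$sequence), 76)
  # SUMO3 lysines sit one position below their SUMO2 homologs from K20/21 on
  expect_true(all(c(21L, 33L, 45L) %in% refs$SUMO2$lysines))
  expect_true(all(c(20L, 32L, 44L) %in% refs$SUMO3$lysines))
})

test_that("FASTA round trip preserves sequences and no-K edge case works", {
  refs <- ubl_references()
  f <- tmp_file(".fasta")
  write_ubl_fasta(refs, f)
  back <- read_ubl_fasta(f)
  expect_identical(
    vapply(back, function(r) r$sequence, character(1)),
    vapply(refs, function(r) r$sequence, character(1))
  )
  expect_length(ubl_reference("X", "X1", "AAAGGG")$lysines, 0)
  expect_error(ubl_reference("X", "X1", ""), "empty")
})
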