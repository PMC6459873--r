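test_that("protein_context validates sequence and numbering", {
  p <- protein_context("MSTAV", residue_offset = 10, name = "frag")
  expect_equal(nchar(p$sequence), 5)
  expect_error(protein_context(""), class = "hdx_validation_error")
  expect_error(protein_context("MSTXZ"), class = "hdx_validation_error")
  expect_error(protein_context("MSTAV", residue_offset = 0),
               class = "hdx_validation_error")
})

test_that("compute_n_amides follows both conventions", {
  expect_equal(compute_n_amides("AAAA"), 3L)
  expect_equal(compute_n_amides("APAP"), 1L)
  expect_equal(compute_n_amides("PAAA"), 3L)
  expect_equal(compute_n_amides("AAAA", "skip_first_two"), 2L)
  expect_equal(compute_n_amides("APAP", "skip_first_two"), 1L)
  expect_error(compute_n_amides("A"), class = "hdx_validation_error")
})

test_that("amide count depends only on proline positions", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:15, 1)
    aa <- sample(c("A", "G", "L", "S", "P"), n, replace = TRUE,
                 prob = c(1, 1, 1, 1, 0.5))
    seq1 <- paste(aa, collapse = "")
    # shuffle only non-proline identities, keep proline positions fixed
    non_p <- which(aa != "P")
    aa2 <- aa
    aa2[non_p] <- sample(aa[non_p])
    seq2 <- paste(aa2, collapse = "")
    expect_equal(compute_n_amides(seq1), compute_n_amides(seq2))
  }
})

test_that("peptide_records validates against the protein and deduplicates", {
  prot <- toy_protein()
  peps <- toy_peptides(prot)
  expect_equal(nrow(peps), 4)
  expect_true(all(peps$n_amides >= 1 & peps$n_amides <= nchar(peps$sequence) - 1))
  expect_true(all(diff(peps$start) >= 0))
  bad <- data.frame(start = 1, end = 10, sequence = "AAAAAAAAAA")
  expect_error(peptide_records(bad, prot), class = "hdx_validation_error")
  short <- data.frame(start = 1, end = 10, sequence = "MST")
  expect_error(peptide_records(short, prot), class = "hdx_validation_error")
})

test_that("read_uptake_table ingests the uptake dialect and keeps provenance", {
  prot <- toy_protein()
  rows <- data.frame(
    Start = c(1, 1, 1), End = c(10, 10, 10),
    Sequence = "MSTAVKELGH", State = c("Na", "Na", "K"),
    Exposure = 0.25, Replicate = c(1, 2, 1),
    Uptake = c(1.1, 1.2, 0.9), note = c("a", "b", "c"))
  path <- write_toy_uptake_csv(tempfile(fileext = ".csv"), rows)
  got <- read_uptake_table(path, prot)
  expect_equal(nrow(got$measurements), 3)
  expect_equal(nrow(got$peptides), 1)
  expect_equal(got$measurements$source_row, 1:3)
  expect_true("note" %in% names(got$measurements))  # extra columns survive
  expect_equal(got$measurements$uptake_D, c(1.1, 1.2, 0.9))
})

test_that("read_uptake_table reports missing columns and bad rows by name", {
  prot <- toy_protein()
  rows <- data.frame(Start = 1, End = 10, Sequence = "MSTAVKELGH",
                     State = "Na", Exposure = 0.25, Uptake = 1)
  path <- write_toy_uptake_csv(tempfile(fileext = ".csv"), rows)
  expect_error(read_uptake_table(path, prot), "replicate",
               class = "hdx_format_error")

  rows2 <- data.frame(Start = 1, End = 10, Sequence = "WRONGSEQXYZ",
                      State = "Na", Exposure = 0.25, Replicate = 1, Uptake = 1)
  rows2$Sequence <- "AAAAAAAAAA"
  path2 <- write_toy_uptake_csv(tempfile(fileext = ".csv"), rows2)
  expect_error(read_uptake_table(path2, prot), class = "hdx_validation_error")

  rows3 <- data.frame(Start = 1, End = 10, Sequence = "MSTAVKELGH",
                      State = "Na", Exposure = -1, Replicate = 1, Uptake = 1)
  path3 <- write_toy_uptake_csv(tempfile(fileext = ".csv"), rows3)
  expect_error(read_uptake_table(path3, prot), class = "hdx_validation_error")
})

test_that("centroid dialect computes uptake against m0", {
  prot <- toy_protein()
  m0 <- peptide_mass("MSTAVKELGH")
  z <- 2
  mz0 <- (m0 + z * 1.00728) / z
  rows <- data.frame(start = 1, end = 10, sequence = "MSTAVKELGH",
                     state = "Na", exposure = 0.25, replicate = 1,
                     center_mz = mz0, charge = z)
  path <- write_toy_uptake_csv(tempfile(fileext = ".csv"), rows)
  got <- read_uptake_table(path, prot)
  expect_equal(got$measurements$uptake_D, 0, tolerance = 1e-9)

  rows$center_mz <- (m0 + 3 * 1.00628 + z * 1.00728) / z
  path <- write_toy_uptake_csv(tempfile(fileext = ".csv"), rows)
  got <- read_uptake_table(path, prot)
  expect_equal(got$measurements$uptake_D, 3 * 1.00628, tolerance = 1e-9)
})

test_that("summary table round-trips means exactly", {
  st <- generate_study(study_truth(seed = 3, n_peptides = 10, ex1 = NULL))
  series <- summarize_uptake(st$measurements)
  path <- file.path(tempdir(), "summary_rt.csv")
  written <- write_summary_table(series, path,
                                 design = labeling_design())
  back <- read_summary_table(path)
  mean_cols <- grep("^mean_uptake", names(written), value = TRUE)
  for (cc in mean_cols) {
    expect_equal(back[[cc]], written[[cc]], tolerance = 1e-9)
  }
  # empty input still yields a readable header-only file
  empty <- summarize_uptake(st$measurements[0, ])
  p2 <- file.path(tempdir(), "summary_empty.csv")
  write_summary_table(empty, p2)
  expect_true(file.exists(p2))
})

test_that("labeling design enforces its invariants", {
  expect_error(labeling_design(d_frac = 0), class = "hdx_validation_error")
  expect_error(labeling_design(time_grid_min = c(1, 1, 2)),
               class = "hdx_validation_error")
  d <- labeling_design()
  expect_equal(d$d_frac, 0.85)
  expect_equal(d$time_grid_min, c(0.25, 1, 10, 60, 480))
})
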