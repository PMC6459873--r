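two_state_series <- function(na, k, t = c(0.25, 1, 10), sd = 0.05, n = 3L) {
  tibble::tibble(
    peptide_id = "1-10", start = 1L, end = 10L, sequence = "MSTAVKELGH",
    state = rep(c("Na", "K"), each = length(t)),
    exposure_min = rep(t, 2), mean_uptake_D = c(na, k),
    sd_uptake_D = sd, n = n)
}

test_that("difference profiles use the decreased-exchange sign convention", {
  s <- two_state_series(c(3, 3, 3), c(3, 3, 3))
  p <- difference_profile(s, "Na", "K")
  expect_equal(p$delta_D, c(0, 0, 0))
  s2 <- two_state_series(c(3, 3, 3), c(2.4, 2.4, 2.4))
  p2 <- difference_profile(s2, "Na", "K")
  expect_equal(p2$delta_D, rep(0.6, 3), tolerance = 1e-12)  # decreased HDX in K
  expect_error(difference_profile(s2, "Na", "X"),
               class = "hdx_validation_error")
})

test_that("swapping states negates every difference and keeps the verdict magnitude", {
  st <- generate_study(study_truth(
    seed = 13, n_peptides = 12, ex1 = NULL,
    effects = list(list(start = 50, end = 80, delta_D = 1.2, state = "K"))))
  s <- summarize_uptake(st$measurements)
  fwd <- difference_profile(s, "Na", "K")
  rev <- difference_profile(s, "K", "Na")
  m <- dplyr::inner_join(fwd, rev, by = c("peptide_id", "exposure_min"))
  expect_equal(m$delta_D.x, -m$delta_D.y, tolerance = 1e-12)

  ci_f <- ci_threshold_from_series(s, "Na", "K")
  ci_r <- ci_threshold_from_series(s, "K", "Na")
  expect_equal(ci_f$ci, ci_r$ci)
  calls_f <- classify_all(fwd, ci_f, st$measurements)
  calls_r <- classify_all(rev, ci_r, st$measurements)
  flip <- c(increase = "decrease", decrease = "increase", none = "none")
  expect_equal(unname(flip[calls_f$verdict]), calls_r$verdict)
})

test_that("ci_threshold reproduces the closed form t x sigma_bar", {
  expect_equal(ci_threshold(c(0, 0, 0), n = 3)$ci, 0)
  th <- ci_threshold(0.079, n = 3)
  expect_equal(th$t_crit, qt(0.975, 2))
  expect_equal(th$ci, th$t_crit * 0.079, tolerance = 1e-12)
  # sigma_ave = sqrt(n) sigma_bar and ci = t sigma_ave / sqrt(n) identically
  set.seed(4)
  for (i in 1:20) {
    sds <- runif(sample(1:10, 1), 0, 0.3)
    n <- sample(2:6, 1)
    th <- ci_threshold(sds, n = n)
    expect_equal(th$sigma_ave, sqrt(n) * mean(sds), tolerance = 1e-12)
    expect_equal(th$ci, qt(0.975, n - 1) * mean(sds), tolerance = 1e-12)
  }
  expect_error(ci_threshold(NA_real_), class = "hdx_validation_error")
  expect_error(ci_threshold(0.1, n = 1), class = "hdx_validation_error")
})

test_that("the hybrid rule fires in order: consecutive CI, t-test, last point", {
  ci <- ci_threshold(0.079, n = 3)  # ci = 0.34
  base <- two_state_series(c(2, 2, 2, 2, 2), c(2, 2, 2, 2, 2),
                           t = c(0.25, 1, 10, 60, 480))

  none <- classify_significance(difference_profile(base, "Na", "K"), ci)
  expect_equal(none$verdict, "none")
  expect_equal(none$rule_fired, "none")

  # 1.2 x CI at 10 and 60 min only -> rule (a)
  s_a <- two_state_series(c(2, 2, 2, 2, 2),
                          c(2, 2, 2 - 1.2 * ci$ci, 2 - 1.2 * ci$ci, 2),
                          t = c(0.25, 1, 10, 60, 480))
  call_a <- classify_significance(difference_profile(s_a, "Na", "K"), ci)
  expect_equal(call_a$verdict, "decrease")
  expect_equal(call_a$rule_fired, "consecutive_CI")
  expect_equal(call_a$support_times, "10;60")

  # only the 480-min point elevated, at 2.5 x CI -> rule (c)
  s_c <- two_state_series(c(2, 2, 2, 2, 2),
                          c(2, 2, 2, 2, 2 + 2.5 * ci$ci),
                          t = c(0.25, 1, 10, 60, 480))
  call_c <- classify_significance(difference_profile(s_c, "Na", "K"), ci)
  expect_equal(call_c$verdict, "increase")
  expect_equal(call_c$rule_fired, "last_point_2xCI")

  # small consistent difference, tight replicates -> rule (b) via t-test
  set.seed(2)
  reps <- dplyr::bind_rows(
    toy_reps <- tidyr::expand_grid(state = c("Na", "K"),
                                   exposure_min = c(0.25, 1, 10),
                                   replicate = 1:3))
  reps$peptide_id <- "1-10"
  reps$uptake_D <- ifelse(reps$state == "Na", 2, 2 - 0.2) +
    rnorm(nrow(reps), 0, 0.005)
  s_b <- summarize_uptake(dplyr::mutate(reps, start = 1L, end = 10L,
                                        sequence = "MSTAVKELGH"))
  big_ci <- ci_threshold(0.15, n = 3)  # CI 0.645 keeps rule (a) silent
  call_b <- classify_significance(difference_profile(s_b, "Na", "K"),
                                  big_ci, reps)
  expect_equal(call_b$rule_fired, "t_test")
  expect_equal(call_b$verdict, "decrease")
})

test_that("consecutiveness is required and direction conflicts are flagged", {
  ci <- ci_threshold(0.079, n = 3)
  # single isolated exceedance -> not significant
  s <- two_state_series(c(2, 2, 2, 2, 2),
                        c(2, 2 - 1.5 * ci$ci, 2, 2 - 1.5 * ci$ci, 2),
                        t = c(0.25, 1, 10, 60, 480))
  call <- classify_significance(difference_profile(s, "Na", "K"), ci)
  expect_equal(call$verdict, "none")

  # consecutive exceedances of opposite sign: verdict by larger |dD|, flagged
  s2 <- two_state_series(c(2, 2, 2, 2, 2),
                         c(2, 2 - 1.5 * ci$ci, 2 + 3 * ci$ci, 2, 2),
                         t = c(0.25, 1, 10, 60, 480))
  call2 <- classify_significance(difference_profile(s2, "Na", "K"), ci)
  expect_true(call2$direction_unstable)
  expect_equal(call2$verdict, "increase")
})

test_that("residue consolidation applies precedence, conflicts and coverage", {
  prot <- protein_context(strrep("A", 40))
  peps <- peptide_records(
    data.frame(start = c(1, 5), end = c(10, 20),
               sequence = c(strrep("A", 10), strrep("A", 16))), prot)
  calls <- tibble::tibble(peptide_id = c("1-10", "5-20"),
                          start = c(1L, 5L), end = c(10L, 20L),
                          verdict = c("increase", "none"),
                          rule_fired = c("consecutive_CI", "none"),
                          delta_max = c(1.5, 0.1))
  res <- consolidate_residues(calls, peps, prot)
  expect_equal(res$map$label[1:10], rep("increase", 10))
  expect_equal(res$map$label[11:20], rep("none", 10))
  expect_equal(res$map$label[21:40], rep("no_coverage", 20))
  expect_equal(res$coverage_percent, 50)
  expect_equal(peptide_coverage(peps, prot), 50)

  # conflicting significant peptides mark the overlap mixed
  calls2 <- tibble::tibble(peptide_id = c("1-10", "8-12"),
                           start = c(1L, 8L), end = c(10L, 12L),
                           verdict = c("increase", "decrease"),
                           rule_fired = "consecutive_CI",
                           delta_max = c(1, -1))
  peps2 <- peptide_records(
    data.frame(start = c(1, 8), end = c(10, 12),
               sequence = c(strrep("A", 10), strrep("A", 5))), prot)
  res2 <- consolidate_residues(calls2, peps2, prot)
  expect_equal(res2$map$label[8:10], rep("mixed", 3))
  expect_equal(res2$map$label[1:7], rep("increase", 7))
  expect_equal(res2$map$label[11:12], rep("decrease", 2))

  path <- file.path(tempdir(), "attrs.txt")
  write_residue_attributes(res2, path)
  expect_equal(length(readLines(path)), 41)  # header + one line per residue
})
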