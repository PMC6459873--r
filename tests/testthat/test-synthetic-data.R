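test_that("EX2 uptake matches its closed form and limits", {
  expect_equal(simulate_ex2_uptake(pf = rep(10, 5), t_min = 0), 0)
  # saturation: 10 amides at d_frac 0.85
  expect_equal(simulate_ex2_uptake(pf = rep(100, 10), t_min = 1e9,
                                   d_frac = 0.85), 8.5, tolerance = 1e-9)
  # one amide, k_obs = ln2 per min, t = 1 -> half exchanged
  expect_equal(simulate_ex2_uptake(pf = 1, t_min = 1, d_frac = 1,
                                   k_int = log(2)), 0.5, tolerance = 1e-12)
  expect_error(simulate_ex2_uptake(pf = 1, t_min = -1),
               class = "hdx_validation_error")
})

test_that("EX2 uptake is monotone in time and in protection", {
  set.seed(11)
  for (i in 1:20) {
    pf <- 10^runif(8, 1, 5)
    ts <- sort(runif(6, 0, 500))
    u <- simulate_ex2_uptake(pf, ts)
    expect_true(all(diff(u) >= -1e-12))
    # lowering protection (raising 1/pf) can only increase uptake
    u2 <- simulate_ex2_uptake(pf / 2, ts)
    expect_true(all(u2 - u >= -1e-12))
  }
})

test_that("EX1 mixture weights follow the opening kinetics", {
  spec <- ex1_spec(k_open = log(2), closed_probs = rep(0.1, 6),
                   open_probs = rep(0.9, 6))
  expect_equal(simulate_ex1_mixture(spec, 0)$fraction_open, 0)
  expect_equal(simulate_ex1_mixture(spec, 1)$fraction_open, 0.5,
               tolerance = 1e-12)
  # separation 6, fraction 0.5 -> mixture mean = closed + 3
  spec6 <- ex1_spec(k_open = log(2), closed_probs = rep(0.2, 8),
                    open_probs = rep(0.2 + 0.75, 8))
  expect_equal(spec6$separation_D, 6)
  mix <- simulate_ex1_mixture(spec6, 1)
  expect_equal(mix$mean_uptake, mix$closed_uptake + 3, tolerance = 1e-12)
  expect_error(ex1_spec(1, c(0.5, 0.5), c(0.4, 0.9)),
               class = "hdx_validation_error")
})

test_that("Poisson-binomial agrees with exhaustive enumeration", {
  set.seed(7)
  for (n in c(3, 5, 8, 10)) {
    probs <- runif(n)
    expect_equal(poisson_binomial(probs), pb_enumerate(probs),
                 tolerance = 1e-12)
  }
  expect_equal(sum(poisson_binomial(runif(10))), 1, tolerance = 1e-12)
})

test_that("envelopes place peaks correctly and respect mixing linearity", {
  pep <- toy_peptides()[1, ]
  z <- 2
  # all probabilities zero -> single peak at the undeuterated m/z
  e0 <- envelope_from_uptake(pep, rep(0, 6), charge = z)
  expect_equal(e0$mz[which.max(e0$intensity)],
               (pep$m0 + z * 1.00728) / z, tolerance = 1e-9)
  # all probabilities one -> single peak shifted by N deuterons
  e1 <- envelope_from_uptake(pep, rep(1, 6), charge = z)
  expect_equal(e1$mz[which.max(e1$intensity)],
               (pep$m0 + 6 * 1.00628 + z * 1.00728) / z, tolerance = 1e-9)
  # binomial N=3 p=0.5 -> intensities (1,3,3,1)/3 after max-normalisation
  e3 <- envelope_from_uptake(pep, rep(0.5, 3), charge = 1)
  expect_equal(e3$intensity[1:4], c(1, 3, 3, 1) / 3, tolerance = 1e-12)

  # two-population envelope equals the weighted sum of single-population
  # envelopes (before normalisation), exactly
  pa <- runif(6); pb <- runif(6); w <- 0.3
  da <- poisson_binomial(pa); db <- poisson_binomial(pb)
  mixed <- (1 - w) * da + w * db
  em <- envelope_from_uptake(pep, pa, charge = 1,
                             mixing = list(probs = pb, weight = w))
  expect_equal(em$intensity, mixed / max(mixed), tolerance = 1e-12)
  expect_error(envelope_from_uptake(pep, c(0.5, 1.2)),
               class = "hdx_validation_error")
})

test_that("back-exchange attenuation is linear thinning", {
  expect_equal(apply_back_exchange(8.5, 0), 8.5)
  expect_equal(apply_back_exchange(8.5, 0.2), 6.8, tolerance = 1e-12)
  expect_error(apply_back_exchange(1, 1), class = "hdx_validation_error")
  # near-total back-exchange collapses an envelope toward the light peak
  pep <- toy_peptides()[1, ]
  probs <- rep(0.9, 6)
  e <- envelope_from_uptake(pep, apply_back_exchange(probs, 0.999), charge = 1)
  expect_equal(which.max(e$intensity), 1L)
})

test_that("generated studies are reproducible and recover input kinetics", {
  tr <- study_truth(seed = 21, n_peptides = 15, ex1 = NULL)
  a <- generate_study(tr)
  b <- generate_study(tr)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$controls, b$controls)

  # mean uptake matches the designed kinetics: nearly all replicated cells
  # within 3 SD / sqrt(n), every cell within 5 (the zero-clamp on noisy
  # draws biases cells whose true uptake is close to zero)
  s <- summarize_uptake(a$measurements)
  design <- labeling_design()
  s3 <- s[s$n >= 3, ]
  z <- vapply(seq_len(nrow(s3)), function(k) {
    mu <- hdxstat:::truth_base_uptake(tr, design, s3$peptide_id[k],
                                      s3$exposure_min[k])
    abs(s3$mean_uptake_D[k] - mu) / (tr$noise_sd / sqrt(s3$n[k]))
  }, numeric(1))
  expect_gte(mean(z <= 3), 0.95)
  expect_true(all(z <= 5))

  # max-label controls sit at N x d_frac x (1 - be) up to noise
  n_am <- a$peptides$n_amides
  expect_true(all(abs(a$controls$uptake_max_D -
                        n_am * design$d_frac * (1 - tr$be)) <
                    4 * tr$noise_sd))
})

test_that("study files round-trip through the readers byte-identically", {
  dir1 <- file.path(tempdir(), "study_a")
  dir2 <- file.path(tempdir(), "study_b")
  unlink(c(dir1, dir2), recursive = TRUE)
  tr <- study_truth(seed = 9, n_peptides = 8)
  st1 <- generate_study(tr, out_dir = dir1)
  st2 <- generate_study(tr, out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "uptake.csv")),
                   readLines(file.path(dir2, "uptake.csv")))

  prot <- read_protein(file.path(dir1, "protein.fasta"))
  got <- read_uptake_table(file.path(dir1, "uptake.csv"), prot)
  expect_equal(nrow(got$measurements), nrow(st1$measurements))
  expect_equal(got$measurements$uptake_D, st1$measurements$uptake_D,
               tolerance = 1e-6)
  ctl <- read_max_label_controls(file.path(dir1, "controls.csv"), prot)
  expect_equal(ctl$uptake_max_D, st1$controls$uptake_max_D, tolerance = 1e-6)

  env_files <- list.files(file.path(dir1, "envelopes"), full.names = TRUE)
  env <- read_envelope(env_files[1])
  orig <- st1$envelopes[[sub("\\.txt$", "", basename(env_files[1]))]]
  expect_equal(env$mz, orig$mz, tolerance = 1e-6)
  expect_equal(env$intensity, orig$intensity, tolerance = 1e-6)
})

test_that("designed regions must overlap peptides", {
  expect_error(
    study_truth(seed = 1, n_peptides = 5, ex1 = NULL,
                effects = list(list(start = 620, end = 629, delta_D = 1,
                                    state = "K"))),
    class = "hdx_validation_error")
})

test_that("binding assay simulator honours the one-site model", {
  d <- simulate_binding_assay(kd_nM = 10, bmax = 100, ns_slope = 2,
                              conc_grid_nM = 10, n_rep = 1, noise_cv = 0)
  expect_equal(d$total - d$nonspecific, 50)  # L = kd -> bmax/2
  d2 <- simulate_binding_assay(kd_nM = 10, bmax = 100, ns_slope = 0,
                               conc_grid_nM = c(1, 5, 25), n_rep = 1,
                               noise_cv = 0)
  expect_equal(d2$total, d2$total - d2$nonspecific)  # no nonspecific signal
  d3 <- simulate_binding_assay(kd_nM = 7.5, bmax = 1, ns_slope = 0,
                               conc_grid_nM = 48, n_rep = 1, noise_cv = 0)
  expect_equal(d3$total, 48 / 55.5, tolerance = 1e-12)
  expect_error(simulate_binding_assay(-1), class = "hdx_validation_error")
})
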