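# Forward simulation of HDX studies under the Linderstrom-Lang picture:
# each backbone amide exchanges with pseudo-first-order rate
# k_obs = k_int / pf, and EX2 uptake at time t is the sum of independent
# per-amide exchange probabilities scaled by the labeling deuterium
# fraction. EX1 behaviour is modelled as a slow two-state opening with rate
# k_open mixing a protected ("closed") and an exchanged ("open") population.

#' EX2 deuterium uptake from per-amide kinetics
#'
#' \deqn{D(t) = D_{frac} \sum_i \left(1 - e^{-k_{obs,i} t}\right)},
#' with \eqn{k_{obs,i} = k_{int} / pf_i}.
#'
#' @param pf per-amide protection factors (>= 1).
#' @param t_min exposure time(s) in minutes (>= 0).
#' @param d_frac labeling deuterium fraction.
#' @param k_int intrinsic exchange rate, min^-1. A single constant by
#'   default; supply a vector for per-amide rates.
#' @return uptake in deuterons, one value per element of `t_min`.
#' @export
#' @examples
#' simulate_ex2_uptake(pf = 1, t_min = 1, d_frac = 1, k_int = log(2))  # 0.5
simulate_ex2_uptake <- function(pf, t_min, d_frac = 0.85, k_int = 100) {
  if (any(t_min < 0)) hdx_abort("t_min must be >= 0", "hdx_validation_error")
  if (any(pf < 1)) hdx_abort("protection factors must be >= 1", "hdx_validation_error")
  if (any(k_int <= 0)) hdx_abort("k_int must be > 0", "hdx_validation_error")
  k_obs <- k_int / pf
  vapply(t_min, function(t) d_frac * sum(1 - exp(-k_obs * t)), numeric(1))
}

#' EX1 two-population specification
#'
#' Per-amide deuteration probabilities of the protected (closed) and the
#' exchanged (open) populations, plus the slow opening rate that sets the
#' population mixing over time. Probabilities are on the observation scale
#' (whatever labeling fraction / back-exchange the caller bakes in).
#'
#' @param k_open opening rate, min^-1 (> 0).
#' @param closed_probs,open_probs per-amide exchange probabilities in
#'   \[0, 1\]; `open_probs` must dominate `closed_probs` amide-wise.
#' @return object of class `ex1_spec` with a `separation_D` field
#'   (`sum(open_probs - closed_probs)`).
#' @export
ex1_spec <- function(k_open, closed_probs, open_probs) {
  if (k_open <= 0) hdx_abort("k_open must be > 0", "hdx_validation_error")
  if (length(closed_probs) != length(open_probs)) {
    hdx_abort("population profiles must have equal length", "hdx_validation_error")
  }
  if (any(closed_probs < 0 | closed_probs > 1 | open_probs < 0 | open_probs > 1)) {
    hdx_abort("exchange probabilities must lie in [0, 1]", "hdx_validation_error")
  }
  if (any(open_probs < closed_probs)) {
    hdx_abort("open population must dominate the closed population amide-wise",
              "hdx_validation_error")
  }
  structure(list(k_open = k_open, closed_probs = closed_probs,
                 open_probs = open_probs,
                 separation_D = sum(open_probs - closed_probs)),
            class = "ex1_spec")
}

#' Mix the EX1 populations at a given time
#'
#' @param spec an [ex1_spec()].
#' @param t_min exposure time (minutes, >= 0).
#' @param d_frac optional extra scaling of the probability profiles.
#' @return list: `fraction_open` (`1 - exp(-k_open t)`), `closed_uptake`,
#'   `open_uptake`, `mean_uptake`, and the (scaled) per-amide profiles.
#' @export
simulate_ex1_mixture <- function(spec, t_min, d_frac = 1) {
  if (any(t_min < 0)) hdx_abort("t_min must be >= 0", "hdx_validation_error")
  f <- 1 - exp(-spec$k_open * t_min)
  closed <- spec$closed_probs * d_frac
  open <- spec$open_probs * d_frac
  list(fraction_open = f,
       closed_uptake = sum(closed), open_uptake = sum(open),
       mean_uptake = (1 - f) * sum(closed) + f * sum(open),
       closed_probs = closed, open_probs = open)
}

#' Exact Poisson-binomial deuterium-count distribution
#'
#' Iterative convolution of independent Bernoulli draws: element `d + 1` of
#' the result is the probability of incorporating exactly `d` deuterons.
#'
#' @param probs per-amide deuteration probabilities in \[0, 1\].
#' @return numeric vector of length `length(probs) + 1` summing to 1.
#' @export
poisson_binomial <- function(probs) {
  if (any(probs < 0 | probs > 1)) {
    hdx_abort("probabilities must lie in [0, 1]", "hdx_validation_error")
  }
  dist <- 1
  for (p in probs) {
    dist <- c(dist * (1 - p), 0) + c(0, dist * p)
  }
  dist
}

#' Build an isotope envelope from per-amide deuteration probabilities
#'
#' The deuterium-count distribution is the exact Poisson-binomial of the
#' per-amide probabilities; peaks sit at
#' `mz = (m0 + d * 1.00628 + z * 1.00728) / z`. A second population can be
#' mixed in with a given weight, and a natural-isotope distribution can be
#' convolved on top. Intensities are normalised to max 1.
#'
#' @param peptide one row of a [peptide_records()] table (needs `m0`,
#'   `n_amides`, `peptide_id`).
#' @param per_amide_probs deuteration probabilities, one per exchangeable
#'   amide.
#' @param charge positive integer charge state.
#' @param mixing optional list `(probs = ..., weight = ...)`: a second
#'   population's profile and its mixing weight in \[0, 1\].
#' @param iso_dist optional natural-isotope abundance vector (element 1 =
#'   monoisotopic) convolved with the deuteration distribution.
#' @param noise_sd additive Gaussian intensity noise (fraction of max).
#' @param state,exposure_min,seed metadata carried into the envelope.
#' @return an [isotope_envelope()].
#' @export
envelope_from_uptake <- function(peptide, per_amide_probs, charge = 2L,
                                 mixing = NULL, iso_dist = NULL,
                                 noise_sd = 0, state = NULL,
                                 exposure_min = NULL, seed = NULL) {
  if (charge < 1) hdx_abort("charge must be >= 1", "hdx_validation_error")
  dist <- poisson_binomial(per_amide_probs)
  if (!is.null(mixing)) {
    w <- mixing$weight
    if (w < 0 || w > 1) hdx_abort("mixing weight must be in [0, 1]", "hdx_validation_error")
    dist2 <- poisson_binomial(mixing$probs)
    n <- max(length(dist), length(dist2))
    dist <- (1 - w) * c(dist, rep(0, n - length(dist))) +
      w * c(dist2, rep(0, n - length(dist2)))
  }
  if (!is.null(iso_dist)) {
    dist <- as.numeric(stats::convolve(c(dist, rep(0, length(iso_dist) - 1)),
                                       rev(c(iso_dist, rep(0, length(dist) - 1))),
                                       type = "open"))
    dist <- dist[seq_len(length(per_amide_probs) + length(iso_dist))]
    dist[dist < 0] <- 0
  }
  if (length(dist) < 5) dist <- c(dist, rep(0, 5 - length(dist)))
  d <- seq_along(dist) - 1
  mz <- (peptide$m0 + d * MASS_D_MINUS_H + charge * MASS_PROTON) / charge
  intensity <- dist / max(dist)
  if (noise_sd > 0) {
    intensity <- intensity + rnorm(length(intensity), 0, noise_sd)
    intensity[intensity < 0] <- 0
    intensity <- intensity / max(intensity)
  }
  isotope_envelope(mz, intensity, charge = charge, m0 = peptide$m0,
                   peptide = peptide$peptide_id, state = state,
                   exposure_min = exposure_min, seed = seed)
}

#' Attenuate uptake (or thin probabilities) by back-exchange
#'
#' Deuterons survive quench and chromatography independently with
#' probability `1 - be_fraction`, so expected observed uptake is
#' `uptake * (1 - be_fraction)`; the same factor thins per-amide
#' probabilities when generating envelopes.
#'
#' @param uptake_D uptake in deuterons (or a probability vector).
#' @param be_fraction back-exchange fraction in \[0, 1).
#' @return attenuated values.
#' @export
apply_back_exchange <- function(uptake_D, be_fraction) {
  if (any(be_fraction < 0 | be_fraction >= 1)) {
    hdx_abort("be_fraction must lie in [0, 1)", "hdx_validation_error")
  }
  uptake_D * (1 - be_fraction)
}

#' Deterministic synthetic protein sequence
#'
#' Random canonical-letter sequence (proline kept rare so most peptides have
#' plenty of exchangeable amides), reproducible from the seed.
#'
#' @param length sequence length (default 630, a 12-TM transporter scale).
#' @param seed RNG seed.
#' @param name label.
#' @return a [protein_context()].
#' @export
synthetic_protein <- function(length = 630, seed = 1, name = "synthetic-transporter") {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  weights <- rep(1, 20)
  names(weights) <- CANONICAL_AA
  weights["P"] <- 0.3
  aa <- sample(CANONICAL_AA, length, replace = TRUE, prob = weights)
  protein_context(paste(aa, collapse = ""), name = name)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Ground truth of a synthetic HDX study
#'
#' Defines everything the simulator needs: the construct, a peptide map,
#' per-amide protection factors, designed uptake differences between
#' states, EX1 designations, the noise model and back-exchange. Defaults
#' emulate the statistical structure of a two-state membrane-transporter
#' study: 62 peptides over a 630-residue construct (~2/3 sequence
#' coverage), replicate noise SD 0.079 D, uniform 25% back-exchange,
#' triplicates at 0.25, 10 and 60 min and single measurements elsewhere.
#'
#' @param seed top-level seed; every stochastic draw flows from it.
#' @param states state labels; the first is the reference.
#' @param n_peptides number of peptides to tile (default 62).
#' @param effects list of designed differences, each a list
#'   `(start, end, delta_D, state)`: peptides overlapping the region get
#'   `delta_D` added to their observed uptake in `state` at all times.
#' @param ex1 EX1 designation, a list `(state, start, end, n_fast, n_corr,
#'   separation_D, k_open)`, or `NULL` for a pure-EX2 study. The default
#'   places one EX1 peptide at residues 99-109 in the second state:
#'   `n_fast` unprotected amides exchange within the first time point (so
#'   the closed, yet-to-exchange population sits near 2 D, not at zero),
#'   `n_corr` strongly protected amides carry the designed six-deuteron
#'   observed separation when the segment opens, and k_open = 0.025 min^-1
#'   puts clear two-population mixtures at the 10 and 60 min points
#'   (open fractions 0.22 and 0.78).
#' @param noise_sd replicate noise SD in D (default 0.079).
#' @param be uniform per-peptide back-exchange fraction (default 0.25).
#' @param k_int intrinsic exchange rate, min^-1.
#' @param replicate_times exposure times measured in triplicate.
#' @param protein optional [protein_context()]; generated when NULL.
#' @return object of class `study_truth`.
#' @export
study_truth <- function(seed = 1, states = c("Na", "K"), n_peptides = 62,
                        effects = list(),
                        ex1 = list(state = "K", start = 99, end = 109,
                                   n_fast = 3, n_corr = 7, separation_D = 6,
                                   k_open = 0.025),
                        noise_sd = 0.079, be = 0.25, k_int = 100,
                        replicate_times = c(0.25, 10, 60),
                        protein = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(protein)) {
    protein <- synthetic_protein(seed = seed)
    if (!is.null(ex1)) {
      # the EX1 segment models a helix whose amides all exchange on opening;
      # keep it proline-free so every position carries an amide hydrogen
      aa <- strsplit(protein$sequence, "")[[1]]
      win <- ex1$start:ex1$end
      aa[win][aa[win] == "P"] <- "L"
      protein <- protein_context(paste(aa, collapse = ""),
                                 protein$residue_offset, protein$name)
    }
  }
  len <- protein_length(protein)

  # Tile peptides N to C with overlaps and occasional gaps so the union
  # covers roughly two thirds of the construct.
  starts <- integer(0); ends <- integer(0)
  pos <- 3L
  for (i in seq_len(n_peptides)) {
    plen <- sample(8:15, 1)
    if (pos + plen - 1L > len - 2L) pos <- sample(3:20, 1)  # wrap, keeps count
    starts <- c(starts, pos); ends <- c(ends, pos + plen - 1L)
    pos <- pos + sample(5:8, 1)
    if (i %% 8L == 0L) pos <- pos + sample(18:30, 1)
  }
  pep_df <- tibble::tibble(start = starts, end = ends)
  if (!is.null(ex1)) {
    # force one peptide to cover the EX1 region exactly
    k <- which.min(abs(pep_df$start - ex1$start))
    pep_df$start[k] <- ex1$start; pep_df$end[k] <- ex1$end
  }
  pep_df <- dplyr::distinct(pep_df, .data$start, .data$end)
  pep_df$sequence <- protein_subseq(protein, pep_df$start, pep_df$end)
  peptides <- peptide_records(pep_df, protein)

  # per-amide protection factors, log-uniform over 10^[1, 5]
  pf <- lapply(seq_len(nrow(peptides)), function(k) {
    10^runif(peptides$n_amides[k], 1, 5)
  })
  names(pf) <- peptides$peptide_id

  ex1_id <- NULL
  if (!is.null(ex1)) {
    ex1_id <- sprintf("%d-%d", ex1$start, ex1$end)
    if (!ex1$state %in% states) {
      hdx_abort("EX1 state not among study states", "hdx_validation_error")
    }
    n_am_ex1 <- peptides$n_amides[peptides$peptide_id == ex1_id]
    if (n_am_ex1 < ex1$n_fast + ex1$n_corr) {
      hdx_abort(sprintf("EX1 peptide %s has %d exchangeable amides, fewer than the %d designed (n_fast + n_corr)",
                        ex1_id, n_am_ex1, ex1$n_fast + ex1$n_corr),
                "hdx_validation_error")
    }
    # a few unprotected amides give the closed population a non-zero
    # centre; the rest are strongly protected until the segment opens
    pf[[ex1_id]] <- c(rep(10, ex1$n_fast), rep(1e6, n_am_ex1 - ex1$n_fast))
  }

  # validate designed regions against the peptide map
  if (length(effects) > 0) {
    bad <- vapply(effects, function(e) {
      !any(peptides$start <= e$end & peptides$end >= e$start)
    }, logical(1))
    if (any(bad)) {
      offenders <- vapply(effects[bad], function(e)
        sprintf("%d-%d", e$start, e$end), "")
      hdx_abort(sprintf("designed region(s) overlap no peptide: %s",
                        paste(offenders, collapse = ", ")),
                "hdx_validation_error")
    }
    bad_state <- vapply(effects, function(e) !e$state %in% states, logical(1))
    if (any(bad_state)) {
      hdx_abort("designed effect names a state absent from the study",
                "hdx_validation_error")
    }
  }

  structure(list(seed = seed, states = states, reference = states[1],
                 protein = protein, peptides = peptides, pf = pf,
                 effects = effects, ex1 = ex1, ex1_id = ex1_id,
                 noise_sd = noise_sd, be = be, k_int = k_int,
                 replicate_times = replicate_times),
            class = "study_truth")
}

# Expected observed uptake of a peptide at time t: EX2 kinetics, labeling
# fraction and back-exchange attenuation, plus any EX1 mixture shift.
truth_base_uptake <- function(truth, design, peptide_id, t) {
  pf <- truth$pf[[peptide_id]]
  apply_back_exchange(
    simulate_ex2_uptake(pf, t, d_frac = design$d_frac, k_int = truth$k_int),
    truth$be)
}

truth_effect_delta <- function(truth, peptide_id, state) {
  pep <- truth$peptides[truth$peptides$peptide_id == peptide_id, ]
  delta <- 0
  for (e in truth$effects) {
    if (e$state == state && pep$start <= e$end && pep$end >= e$start) {
      delta <- delta + e$delta_D
    }
  }
  delta
}

# Observed-scale per-amide probability profiles of the two EX1 populations
# at time t. The open population carries the designed separation spread
# uniformly over the n_corr correlated (protected) amides on top of the
# closed profile; the separation is specified on the observed scale, so the
# correlated amides are taken to retain their label through quench (their
# probabilities are not bounded by the mean back-exchange).
truth_ex1_profiles <- function(truth, design, t) {
  ex1 <- truth$ex1
  pf <- truth$pf[[truth$ex1_id]]
  closed <- apply_back_exchange(
    design$d_frac * (1 - exp(-(truth$k_int / pf) * t)), truth$be)
  open <- closed
  corr <- ex1$n_fast + seq_len(ex1$n_corr)
  bump <- ex1$separation_D / ex1$n_corr
  open[corr] <- pmin(1, open[corr] + bump)
  ex1_spec(ex1$k_open, closed, open)
}

#' Generate a full synthetic HDX study
#'
#' Forward-simulates uptake tables, maximally labelled controls and (for
#' EX1-designated peptides) isotope envelopes from a [study_truth()], in the
#' exact dialects the readers of this package consume. Replicate noise is
#' additive Gaussian on uptake (clamped at zero); the maximally labelled
#' control is `N x d_frac x (1 - be)` plus the same noise. The same seed
#' yields byte-identical outputs.
#'
#' @param truth a [study_truth()].
#' @param design a [labeling_design()].
#' @param out_dir optional directory; when given, writes `uptake.csv`,
#'   `controls.csv`, `protein.fasta`, `truth.yaml` and `envelopes/*.txt`.
#' @param envelope_noise_sd intensity noise for emitted envelopes (default
#'   0.01, i.e. 1% of the base peak).
#' @param envelope_charge charge state of emitted envelopes.
#' @return list: `measurements`, `peptides`, `controls`, `envelopes`
#'   (named list of [isotope_envelope()]), `protein`, `truth`, and
#'   `files` when `out_dir` was given.
#' @export
generate_study <- function(truth, design = labeling_design(), out_dir = NULL,
                           envelope_noise_sd = 0.01, envelope_charge = 2L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(truth$seed)
  peptides <- truth$peptides
  grid <- design$time_grid_min
  n_rep <- ifelse(grid %in% truth$replicate_times, 3L, 1L)

  rows <- list()
  for (k in seq_len(nrow(peptides))) {
    pid <- peptides$peptide_id[k]
    base <- truth_base_uptake(truth, design, pid, grid)
    cap <- peptides$n_amides[k] * design$d_frac * (1 - truth$be)
    for (st in truth$states) {
      mu <- base + truth_effect_delta(truth, pid, st)
      is_ex1 <- !is.null(truth$ex1_id) && pid == truth$ex1_id &&
        st == truth$ex1$state
      if (is_ex1) {
        # centroid of the two-population mixture; the open population's
        # extra label sits above the mean back-exchange cap by design
        f <- 1 - exp(-truth$ex1$k_open * grid)
        mu <- mu + f * truth$ex1$separation_D
      }
      over <- !is_ex1 & mu > cap + 1e-9
      if (any(over)) {
        hdx_log(sprintf("peptide %s state %s: designed uptake clipped at the theoretical maximum at %d time point(s)",
                        pid, st, sum(over)), "warn")
        mu <- pmin(mu, cap)
      }
      time_vec <- rep(grid, n_rep)
      u <- pmax(0, rep(mu, n_rep) + rnorm(length(time_vec), 0, truth$noise_sd))
      rows[[length(rows) + 1]] <- list(
        peptide_id = rep(pid, length(time_vec)),
        start = rep(peptides$start[k], length(time_vec)),
        end = rep(peptides$end[k], length(time_vec)),
        sequence = rep(peptides$sequence[k], length(time_vec)),
        state = rep(st, length(time_vec)), exposure_min = time_vec,
        replicate = sequence(n_rep), uptake_D = u)
    }
  }
  measurements <- tibble::as_tibble(lapply(stats::setNames(names(rows[[1]]),
                                                           names(rows[[1]])),
    function(col) unlist(lapply(rows, `[[`, col), use.names = FALSE)))
  measurements$source_row <- seq_len(nrow(measurements))

  uptake_max <- pmax(0, peptides$n_amides * design$d_frac * (1 - truth$be) +
                       rnorm(nrow(peptides), 0, truth$noise_sd))
  controls <- tibble::tibble(peptide_id = peptides$peptide_id,
                             m0 = peptides$m0,
                             m_max = peptides$m0 + uptake_max,
                             uptake_max_D = uptake_max)

  envelopes <- list()
  if (!is.null(truth$ex1_id)) {
    pep <- peptides[peptides$peptide_id == truth$ex1_id, ]
    for (st in truth$states) {
      for (t in grid) {
        spec <- truth_ex1_profiles(truth, design, t)
        mixing <- NULL
        probs <- spec$closed_probs
        if (st == truth$ex1$state) {
          mixing <- list(probs = spec$open_probs,
                         weight = 1 - exp(-spec$k_open * t))
        }
        env <- envelope_from_uptake(pep, probs, charge = envelope_charge,
                                    mixing = mixing,
                                    noise_sd = envelope_noise_sd,
                                    state = st, exposure_min = t,
                                    seed = truth$seed)
        envelopes[[sprintf("%s_%s_t%g", truth$ex1_id, st, t)]] <- env
      }
    }
  }

  out <- list(measurements = measurements, peptides = peptides,
              controls = controls, envelopes = envelopes,
              protein = truth$protein, truth = truth)
  if (!is.null(out_dir)) {
    out$files <- write_study(out, design, out_dir)
  }
  hdx_log(sprintf("generate_study: %d measurements, %d peptides, %d envelopes (seed %d)",
                  nrow(measurements), nrow(peptides), length(envelopes),
                  truth$seed))
  out
}

# Serialise a generated study into reader-compatible text files.
write_study <- function(study, design, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed_hdr <- sprintf("# seed: %d", study$truth$seed)

  up_path <- file.path(out_dir, "uptake.csv")
  m <- study$measurements
  con <- file(up_path, "w")
  writeLines(c("# hdxstat synthetic uptake table", seed_hdr), con)
  writeLines("start,end,sequence,state,exposure,replicate,uptake", con)
  writeLines(sprintf("%d,%d,%s,%s,%g,%d,%.6f", m$start, m$end, m$sequence,
                     m$state, m$exposure_min, m$replicate, m$uptake_D), con)
  close(con)

  ctl_path <- file.path(out_dir, "controls.csv")
  p <- study$peptides
  ctl <- study$controls
  con <- file(ctl_path, "w")
  writeLines(c("# hdxstat synthetic maximally labelled controls", seed_hdr), con)
  writeLines("start,end,sequence,m0,m_max", con)
  writeLines(sprintf("%d,%d,%s,%.6f,%.6f", p$start, p$end, p$sequence,
                     ctl$m0, ctl$m_max), con)
  close(con)

  fa_path <- file.path(out_dir, "protein.fasta")
  writeLines(c(sprintf(">%s", study$protein$name),
               study$protein$sequence), fa_path)

  env_paths <- character(0)
  if (length(study$envelopes) > 0) {
    env_dir <- file.path(out_dir, "envelopes")
    dir.create(env_dir, showWarnings = FALSE)
    for (nm in names(study$envelopes)) {
      ep <- file.path(env_dir, paste0(nm, ".txt"))
      write_envelope(study$envelopes[[nm]], ep)
      env_paths <- c(env_paths, ep)
    }
  }

  truth_path <- file.path(out_dir, "truth.yaml")
  tr <- study$truth
  yaml::write_yaml(list(
    seed = tr$seed, states = tr$states, reference = tr$reference,
    n_peptides = nrow(study$peptides), noise_sd = tr$noise_sd, be = tr$be,
    k_int = tr$k_int, replicate_times = tr$replicate_times,
    effects = tr$effects,
    ex1 = if (is.null(tr$ex1)) NULL else tr$ex1
  ), truth_path)

  c(uptake = up_path, controls = ctl_path, protein = fa_path,
    truth = truth_path, env_paths)
}

#' Simulate a saturation binding assay
#'
#' One-site binding with a linear nonspecific component:
#' `total = bmax * L / (kd + L) + ns_slope * L`, each observation multiplied
#' by mean-one lognormal noise of the given coefficient of variation. A
#' paired nonspecific-only series shares the noise model.
#'
#' @param kd_nM ground-truth dissociation constant (nM).
#' @param bmax saturating specific signal (counts).
#' @param ns_slope nonspecific counts per nM of ligand.
#' @param conc_grid_nM ligand concentrations (nM); default a two-fold series
#'   over 1-48 nM.
#' @param n_rep replicates per concentration (default triplicate).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @return tibble: `conc_nM`, `replicate`, `total`, `nonspecific`.
#' @export
simulate_binding_assay <- function(kd_nM, bmax = 1000, ns_slope = 5,
                                   conc_grid_nM = c(1, 2, 4, 8, 16, 32, 48),
                                   n_rep = 3, noise_cv = 0.05, seed = NULL) {
  if (kd_nM <= 0) hdx_abort("kd must be > 0", "hdx_validation_error")
  if (any(conc_grid_nM <= 0)) {
    hdx_abort("concentrations must be positive", "hdx_validation_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(conc_nM = conc_grid_nM, replicate = seq_len(n_rep))
  L <- grid$conc_nM
  mu_total <- bmax * L / (kd_nM + L) + ns_slope * L
  mu_ns <- ns_slope * L
  noise <- function(n) {
    if (noise_cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + noise_cv^2))
    exp(rnorm(n, -sdlog^2 / 2, sdlog))
  }
  grid$total <- mu_total * noise(nrow(grid))
  grid$nonspecific <- mu_ns * noise(nrow(grid))
  grid
}
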