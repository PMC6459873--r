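#' Isotope envelope container
#'
#' An m/z-intensity spectrum for one peptide charge state. Intensities are
#' normalised to max 1 on ingest and points are sorted by ascending m/z.
#'
#' @param mz m/z values.
#' @param intensity non-negative intensities (same length, >= 5 points).
#' @param charge positive integer charge state.
#' @param m0 undeuterated neutral mass (Da), if known.
#' @param peptide,state,exposure_min,seed optional metadata.
#' @return object of class `isotope_envelope`.
#' @export
isotope_envelope <- function(mz, intensity, charge, m0 = NULL, peptide = NULL,
                             state = NULL, exposure_min = NULL, seed = NULL) {
  if (length(mz) != length(intensity)) {
    hdx_abort("mz and intensity must have equal length", "hdx_validation_error")
  }
  if (length(mz) < 5) {
    hdx_abort("an envelope needs at least 5 points", "hdx_validation_error")
  }
  if (any(intensity < 0)) {
    hdx_abort("intensities must be non-negative", "hdx_validation_error")
  }
  if (charge < 1) hdx_abort("charge must be >= 1", "hdx_validation_error")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (max(intensity) == 0) {
    hdx_abort("envelope has all-zero intensities", "hdx_validation_error")
  }
  structure(list(mz = mz, intensity = intensity / max(intensity),
                 charge = as.integer(charge), m0 = m0, peptide = peptide,
                 state = state, exposure_min = exposure_min, seed = seed),
            class = "isotope_envelope")
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat(sprintf("<isotope_envelope> %s%s z=%d, %d points, m/z %.3f-%.3f\n",
              x$peptide %||% "?",
              if (!is.null(x$state)) sprintf(" [%s, %g min]", x$state,
                                             x$exposure_min) else "",
              x$charge, length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

# m/z -> deuteration axis (deuterons relative to m0)
envelope_d_axis <- function(env, m0) {
  neutral <- env$mz * env$charge - env$charge * MASS_PROTON
  (neutral - m0) / MASS_D_MINUS_H
}

#' Intensity-weighted envelope centroid
#'
#' @param env an [isotope_envelope()].
#' @param m0 undeuterated neutral mass; defaults to the envelope's own.
#' @return list: `centroid_mz`, `neutral_mass`, `uptake_D` (mass shift vs
#'   `m0`, in Da).
#' @export
envelope_centroid <- function(env, m0 = env$m0) {
  if (sum(env$intensity) == 0) {
    hdx_abort("cannot centroid an all-zero envelope", "hdx_validation_error")
  }
  cmz <- weighted.mean(env$mz, env$intensity)
  neutral <- cmz * env$charge - env$charge * MASS_PROTON
  list(centroid_mz = cmz, neutral_mass = neutral,
       uptake_D = if (is.null(m0)) NA_real_ else neutral - m0)
}

# Gaussian shape on the deuteration axis, unit height
gauss_d <- function(d, center, width) exp(-(d - center)^2 / (2 * width^2))

# Best amplitude and SSR for a fixed shape vector m against intensities I
amp_ssr <- function(I, m) {
  s2 <- sum(m^2)
  if (s2 == 0) return(list(A = 0, ssr = sum(I^2)))
  A <- sum(I * m) / s2
  list(A = A, ssr = sum(I^2) - A^2 * s2)
}

fit_unimodal_gauss <- function(d, I) {
  c0 <- weighted.mean(d, I)
  s0 <- max(sqrt(weighted.mean((d - c0)^2, I)), 0.4)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ A * exp(-(d - c)^2 / (2 * s^2)),
                      start = list(A = max(I), c = c0, s = s0),
                      lower = c(A = 1e-6, c = min(d) - 1, s = 0.15),
                      upper = c(A = 10, c = max(d) + 1, s = diff(range(d))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    m <- gauss_d(d, c0, s0)
    a <- amp_ssr(I, m)
    return(list(center = c0, width = s0, amplitude = a$A, ssr = a$ssr,
                converged = FALSE))
  }
  p <- coef(fit)
  list(center = unname(p["c"]), width = unname(p["s"]),
       amplitude = unname(p["A"]), ssr = sum(residuals(fit)^2),
       converged = TRUE)
}

#' Two-population (bimodal) envelope deconvolution
#'
#' Least-squares fit of the intensity profile on the deuteration axis as a
#' weighted sum of two Gaussian-shaped populations with a shared width,
#' \eqn{w \, G(d; c_{hi}, s) + (1 - w) \, G(d; c_{lo}, s)}, initialised by a
#' coarse grid over the two centres (0.25 D resolution) and the weight,
#' then refined by Levenberg-Marquardt. The best single-population fit is
#' always computed alongside; the nested bimodal model can never fit worse,
#' and when refinement fails the result is flagged rather than raised.
#'
#' @param env an [isotope_envelope()].
#' @param m0 undeuterated neutral mass; defaults to the envelope's own.
#' @param n_amides optional amide count bounding the deuteration axis.
#' @param d_frac labeling deuterium fraction (with `n_amides`, bounds the
#'   grid).
#' @return object of class `bimodal_fit`: `center_low_D`, `center_high_D`,
#'   `fraction_high`, `separation_D`, `width`, `residual`,
#'   `unimodal_residual`, `unimodal_center`, `converged`.
#' @export
fit_bimodal <- function(env, m0 = env$m0, n_amides = NULL, d_frac = 0.85) {
  if (is.null(m0)) {
    hdx_abort("fit_bimodal needs the undeuterated mass m0", "hdx_validation_error")
  }
  d <- envelope_d_axis(env, m0)
  I <- env$intensity

  uni <- fit_unimodal_gauss(d, I)

  grid_lo <- max(min(d), -1)
  grid_hi <- if (!is.null(n_amides)) min(max(d), n_amides * d_frac + 2) else max(d)
  centers <- seq(grid_lo, grid_hi, by = 0.25)
  weights <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  s_grid <- sort(unique(round(pmax(
    c(0.5, 0.8, 1.2, uni$width / 2, uni$width), 0.4), 2)))
  sum_I2 <- sum(I^2)
  upper <- outer(seq_along(centers), seq_along(centers), ">=")  # c_hi >= c_lo
  best <- list(ssr = Inf, s = s_grid[1])
  for (s_try in s_grid) {
    # SSR for every (c_lo, c_hi, w) from the Gram matrix of unit Gaussians:
    # with m = w g_i + (1-w) g_j, min_A SSR = sum I^2 - (I.m)^2 / (m.m)
    S <- vapply(centers, function(cc) gauss_d(d, cc, s_try),
                numeric(length(d)))
    IS <- as.vector(crossprod(I, S))
    G <- crossprod(S)
    dG <- diag(G)
    for (w in weights) {
      one <- rep(1, length(IS))
      num <- w * outer(IS, one) + (1 - w) * outer(one, IS)
      # num[i, j] = w IS[i] + (1-w) IS[j]; rows index c_hi, cols c_lo
      den <- w^2 * outer(dG, rep(1, length(dG))) +
        (1 - w)^2 * outer(rep(1, length(dG)), dG) + 2 * w * (1 - w) * G
      ssr <- sum_I2 - num^2 / pmax(den, 1e-300)
      ssr[!upper] <- Inf
      k <- arrayInd(which.min(ssr), dim(ssr))
      if (ssr[k] < best$ssr) {
        best <- list(ssr = ssr[k], c_lo = centers[k[2]], c_hi = centers[k[1]],
                     w = w, A = (num / pmax(den, 1e-300))[k], s = s_try)
      }
    }
  }
  s0 <- best$s

  refined <- tryCatch(
    minpack.lm::nlsLM(
      I ~ A * (w * exp(-(d - chi)^2 / (2 * s^2)) +
                 (1 - w) * exp(-(d - clo)^2 / (2 * s^2))),
      start = list(A = max(best$A, 1e-3), w = best$w, chi = best$c_hi,
                   clo = best$c_lo, s = s0),
      lower = c(A = 1e-6, w = 0, chi = grid_lo - 1, clo = grid_lo - 1,
                s = 0.15),
      upper = c(A = 10, w = 1, chi = grid_hi + 1, clo = grid_hi + 1,
                s = diff(range(d))),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)

  if (!is.null(refined)) {
    p <- coef(refined)
    c_lo <- unname(p["clo"]); c_hi <- unname(p["chi"])
    w <- unname(p["w"]); s <- unname(p["s"]); A <- unname(p["A"])
    ssr <- sum(residuals(refined)^2)
    converged <- TRUE
  } else {
    c_lo <- best$c_lo; c_hi <- best$c_hi; w <- best$w; s <- s0; A <- best$A
    ssr <- best$ssr
    converged <- FALSE
  }
  if (c_hi < c_lo) {          # enforce the c_hi >= c_lo labelling
    tmp <- c_lo; c_lo <- c_hi; c_hi <- tmp; w <- 1 - w
  }
  if (ssr > uni$ssr) {        # nested models: degenerate to the unimodal fit
    c_lo <- uni$center; c_hi <- uni$center; w <- 0.5
    s <- uni$width; A <- uni$amplitude; ssr <- uni$ssr
  }
  structure(list(center_low_D = c_lo, center_high_D = c_hi,
                 fraction_high = w, separation_D = c_hi - c_lo, width = s,
                 amplitude = A, residual = ssr, unimodal_residual = uni$ssr,
                 unimodal_center = uni$center, converged = converged),
            class = "bimodal_fit")
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf("<bimodal_fit> centers %.2f / %.2f D (sep %.2f), fraction_high %.2f, SSR %.4g (unimodal %.4g)\n",
              x$center_low_D, x$center_high_D, x$separation_D,
              x$fraction_high, x$residual, x$unimodal_residual))
  invisible(x)
}

#' EX1 / EX2 verdict from bimodal fits over the time course
#'
#' A peptide is called EX1 when, at two or more consecutive time points, the
#' two-population fit shows (i) a population separation of at least
#' `min_separation` deuterons, (ii) both populations at least
#' `min_fraction` of the signal, and (iii) at least a `min_improvement`-fold
#' reduction of the residual relative to the single-population fit. These
#' numeric criteria quantify the qualitative bimodality of slow
#' unfolding-refolding kinetics and are deliberately config-exposed. An
#' opening rate is estimated by regressing `-log(1 - fraction_high)` on
#' time through the origin over the qualifying points.
#'
#' @param fits list of [fit_bimodal()] results, one per time point.
#' @param times exposure times (minutes), same order.
#' @param min_separation minimum inter-population separation (D).
#' @param min_fraction minimum minority-population fraction.
#' @param min_improvement minimum unimodal/bimodal residual ratio.
#' @param min_consecutive required run of qualifying time points.
#' @return object of class `ex1_call`: `verdict` ("EX1"/"EX2"), per-time
#'   criterion table, `mean_separation_D` over qualifying points, `k_open`
#'   estimate (NA for EX2).
#' @export
call_ex1 <- function(fits, times, min_separation = 2.0, min_fraction = 0.15,
                     min_improvement = 3.0, min_consecutive = 2L) {
  stopifnot(length(fits) == length(times))
  if (length(fits) < 2) {
    hdx_abort("EX1 calling needs fits at >= 2 time points", "hdx_validation_error")
  }
  o <- order(times)
  fits <- fits[o]; times <- times[o]
  tab <- tibble::tibble(
    exposure_min = times,
    separation_D = vapply(fits, function(f) f$separation_D, numeric(1)),
    fraction_high = vapply(fits, function(f) f$fraction_high, numeric(1)),
    improvement = vapply(fits, function(f) {
      if (f$residual <= 0) Inf else f$unimodal_residual / f$residual
    }, numeric(1))
  )
  tab$qualifies <- tab$separation_D >= min_separation &
    pmin(tab$fraction_high, 1 - tab$fraction_high) >= min_fraction &
    tab$improvement >= min_improvement
  hit <- first_consecutive(tab$qualifies, min_consecutive)
  verdict <- if (!is.na(hit)) "EX1" else "EX2"
  mean_sep <- if (verdict == "EX1") {
    mean(tab$separation_D[tab$qualifies])
  } else NA_real_
  k_open <- NA_real_
  if (verdict == "EX1") {
    q <- tab$qualifies & tab$fraction_high > 0 & tab$fraction_high < 1
    if (sum(q) >= 1) {
      y <- -log(1 - tab$fraction_high[q])
      k_open <- unname(coef(lm(y ~ 0 + tab$exposure_min[q]))[1])
    }
  }
  structure(list(verdict = verdict, fits = tab,
                 mean_separation_D = mean_sep, k_open = k_open,
                 criteria = list(min_separation = min_separation,
                                 min_fraction = min_fraction,
                                 min_improvement = min_improvement,
                                 min_consecutive = min_consecutive)),
            class = "ex1_call")
}

#' @export
print.ex1_call <- function(x, ...) {
  cat(sprintf("<ex1_call> %s%s\n", x$verdict,
              if (x$verdict == "EX1")
                sprintf(" (mean separation %.2f D, k_open %.3g /min)",
                        x$mean_separation_D, x$k_open) else ""))
  invisible(x)
}
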