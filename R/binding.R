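#' Equilibrium receptor occupancy, with or without ligand depletion
#'
#' With depletion (the default), the bound concentration is the physical
#' root of the mass-action quadratic
#' \deqn{B = \frac{(L + R + K_d) - \sqrt{(L + R + K_d)^2 - 4 L R}}{2}}
#' and occupancy is \eqn{B / R}. At the micromolar receptor concentrations
#' used during HDX labeling, free ligand is measurably depleted, so the
#' no-depletion textbook form \eqn{L / (L + K_d)} overestimates occupancy;
#' it remains selectable for comparison.
#'
#' @param l_total total ligand concentration.
#' @param kd dissociation constant (same units as `l_total`).
#' @param r_total total receptor concentration (same units); required in
#'   depletion mode.
#' @param depletion account for ligand/receptor depletion (default TRUE).
#' @return occupancy as a fraction in \[0, 1\] (vectorized).
#' @export
#' @examples
#' occupancy(10, kd = 1, r_total = 0.31)   # ~0.907
#' occupancy(10, kd = 1, depletion = FALSE)  # ~0.909
occupancy <- function(l_total, kd, r_total = NULL, depletion = TRUE) {
  if (any(l_total < 0) || any(kd <= 0)) {
    hdx_abort("l_total must be >= 0 and kd > 0", "hdx_validation_error")
  }
  if (!depletion) {
    return(l_total / (l_total + kd))
  }
  if (is.null(r_total) || any(r_total <= 0)) {
    hdx_abort("depletion mode needs r_total > 0", "hdx_validation_error")
  }
  s <- l_total + r_total + kd
  disc <- pmax(s^2 - 4 * l_total * r_total, 0)
  b <- (s - sqrt(disc)) / 2
  b / r_total
}

#' Ligand concentration required for a target occupancy
#'
#' Exact inversion of the depletion quadratic:
#' \deqn{L = occ \cdot R + K_d \frac{occ}{1 - occ}}
#' so that `occupancy(required_ligand(x, ...), ...) == x`.
#'
#' @param target_occ desired bound fraction, in (0, 1).
#' @param kd dissociation constant.
#' @param r_total total receptor concentration.
#' @return required total ligand (same units as `kd`).
#' @export
#' @examples
#' required_ligand(0.9, kd = 1, r_total = 0.31)  # 9.279
required_ligand <- function(target_occ, kd, r_total) {
  if (any(target_occ <= 0 | target_occ >= 1)) {
    hdx_abort("target occupancy must lie strictly between 0 and 1",
              "hdx_validation_error")
  }
  target_occ * r_total + kd * target_occ / (1 - target_occ)
}

#' Subtract the nonspecific series from total binding
#'
#' When the nonspecific series was measured on a different concentration
#' grid, it is interpolated linearly in concentration.
#'
#' @param data tibble with `conc_nM`, `total` and either a `nonspecific`
#'   column or a separate `ns_data` (conc_nM, nonspecific).
#' @param ns_data optional separate nonspecific table.
#' @return `data` with a `specific` column.
#' @export
subtract_nonspecific <- function(data, ns_data = NULL) {
  if (!is.null(ns_data)) {
    ns_mean <- ns_data |>
      dplyr::group_by(.data$conc_nM) |>
      dplyr::summarise(nonspecific = mean(.data$nonspecific), .groups = "drop")
    data$nonspecific <- approx(ns_mean$conc_nM, ns_mean$nonspecific,
                               xout = data$conc_nM, rule = 2)$y
  }
  if (is.null(data[["nonspecific"]])) {
    hdx_abort("no nonspecific series available to subtract", "hdx_format_error")
  }
  data$specific <- data$total - data$nonspecific
  data
}

#' One-site saturation binding fit
#'
#' Nonlinear least squares of `specific = bmax * L / (kd + L)` after
#' nonspecific subtraction. Start values: `kd0` is the concentration whose
#' mean specific signal is nearest half the maximum, `bmax0` is 1.2 times
#' the maximum. Non-convergence yields a flagged result with diagnostics,
#' never an error.
#'
#' @param data tibble with `conc_nM`, `total`, `nonspecific` (or `specific`)
#'   and optionally `replicate`.
#' @return object of class `binding_fit`: `kd_nM`, `bmax`, standard errors,
#'   `converged`, the fitted curve data.
#' @export
#' @examples
#' d <- simulate_binding_assay(7.5, noise_cv = 0, seed = 1)
#' fit_one_site(d)$kd_nM   # 7.5
fit_one_site <- function(data) {
  if (is.null(data[["specific"]])) data <- subtract_nonspecific(data)
  if (length(unique(data$conc_nM)) < 4) {
    hdx_abort("one-site fit needs >= 4 distinct concentrations",
              "hdx_validation_error")
  }
  by_conc <- data |>
    dplyr::group_by(.data$conc_nM) |>
    dplyr::summarise(specific = mean(.data$specific), .groups = "drop")
  bmax0 <- 1.2 * max(by_conc$specific)
  half <- max(by_conc$specific) / 2
  kd0 <- by_conc$conc_nM[which.min(abs(by_conc$specific - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(specific ~ bmax * conc_nM / (kd + conc_nM),
                      data = data,
                      start = list(bmax = bmax0, kd = kd0),
                      lower = c(bmax = 0, kd = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(kd_nM = NA_real_, bmax = NA_real_,
                          kd_se = NA_real_, bmax_se = NA_real_,
                          converged = FALSE,
                          diagnostics = conditionMessage(fit), data = data),
                     class = "binding_fit"))
  }
  sm <- summary(fit)$coefficients
  structure(list(kd_nM = unname(coef(fit)["kd"]),
                 bmax = unname(coef(fit)["bmax"]),
                 kd_se = sm["kd", "Std. Error"],
                 bmax_se = sm["bmax", "Std. Error"],
                 converged = TRUE, diagnostics = NULL, data = data),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<binding_fit> did not converge:", x$diagnostics, "\n")
  } else {
    cat(sprintf("<binding_fit> Kd = %.3g +/- %.2g nM, Bmax = %.4g +/- %.2g\n",
                x$kd_nM, x$kd_se, x$bmax, x$bmax_se))
  }
  invisible(x)
}

#' Read a saturation binding table
#'
#' Comma-separated with columns `concentration_nM` (or `conc_nM`), `total`,
#' `nonspecific`, optional `replicate`.
#'
#' @param path CSV path.
#' @return tibble ready for [fit_one_site()].
#' @export
read_binding_table <- function(path) {
  if (!file.exists(path)) {
    hdx_abort(sprintf("binding table not found: %s", path), "hdx_io_error")
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  nm <- tolower(names(raw))
  nm[nm == "concentration_nm"] <- "conc_nm"
  names(raw) <- nm
  if (!all(c("conc_nm", "total", "nonspecific") %in% nm)) {
    hdx_abort("binding table needs concentration_nM, total, nonspecific",
              "hdx_format_error")
  }
  dplyr::rename(raw, conc_nM = "conc_nm")
}
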