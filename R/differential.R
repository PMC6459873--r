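#' State-vs-state difference profiles
#'
#' Per peptide and shared exposure time, the uptake difference
#' `dD = mean(reference) - mean(test)`. The sign convention follows the
#' difference-plot layout: positive values mean decreased exchange in the
#' test state relative to the reference. Times present in only one state are
#' omitted and logged; peptides sharing no time points raise an error when
#' `strict = TRUE` and are dropped with a warning otherwise.
#'
#' @param series an `uptake_series` summary covering both states.
#' @param reference,test state labels.
#' @param strict error (rather than drop) on peptides with no shared times.
#' @return tibble of class `difference_profile`: `peptide_id`, `start`,
#'   `end`, `exposure_min`, `delta_D`, per-state SD and n.
#' @export
difference_profile <- function(series, reference, test, strict = FALSE) {
  ref <- dplyr::filter(series, .data$state == reference)
  tst <- dplyr::filter(series, .data$state == test)
  if (nrow(ref) == 0 || nrow(tst) == 0) {
    hdx_abort(sprintf("state '%s' absent from the uptake summary",
                      if (nrow(ref) == 0) reference else test),
              "hdx_validation_error")
  }
  joined <- dplyr::inner_join(
    dplyr::select(ref, "peptide_id", "start", "end", "sequence",
                  "exposure_min", mean_ref = "mean_uptake_D",
                  sd_ref = "sd_uptake_D", n_ref = "n"),
    dplyr::select(tst, "peptide_id", "exposure_min",
                  mean_test = "mean_uptake_D", sd_test = "sd_uptake_D",
                  n_test = "n"),
    by = c("peptide_id", "exposure_min")
  )
  lost <- setdiff(intersect(ref$peptide_id, tst$peptide_id), joined$peptide_id)
  orphans <- setdiff(union(ref$peptide_id, tst$peptide_id),
                     c(joined$peptide_id, lost))
  no_shared <- c(lost, orphans)
  if (length(no_shared) > 0) {
    msg <- sprintf("%d peptide(s) share no time points between '%s' and '%s': %s",
                   length(no_shared), reference, test,
                   paste(head(no_shared, 5), collapse = ", "))
    if (strict) hdx_abort(msg, "hdx_validation_error")
    hdx_log(msg, "warn")
  }
  dropped_times <- nrow(ref) + nrow(tst) - 2 * nrow(joined)
  if (dropped_times > 0) {
    hdx_log(sprintf("difference_profile: %d state-time cell(s) unmatched and omitted",
                    dropped_times), "debug")
  }
  out <- joined |>
    dplyr::mutate(delta_D = .data$mean_ref - .data$mean_test,
                  reference = reference, test = test) |>
    dplyr::arrange(.data$start, .data$end, .data$exposure_min)
  structure(out, class = c("difference_profile", class(out)))
}

#' Pooled-SD confidence-interval threshold for a comparison
#'
#' The per-peptide replicate standard deviations of the two states are
#' averaged into \eqn{\bar\sigma}, accumulated as
#' \eqn{\sigma_{ave} = \sqrt{n \, \bar\sigma^2}}, and converted to a single
#' zero-centred two-tailed confidence threshold
#' \eqn{CI = t_{1-\alpha/2, n-1} \cdot \sigma_{ave} / \sqrt{n}}, which
#' algebraically equals \eqn{t \cdot \bar\sigma}. One threshold serves the
#' whole comparison.
#'
#' @param sds_ref,sds_test per-peptide-time replicate SDs for the two states
#'   (NAs, i.e. unreplicated cells, are dropped).
#' @param n nominal replicate count (default 3, giving df = 2).
#' @param confidence two-tailed confidence level (default 0.95).
#' @return object of class `ci_threshold` with `sigma_bar`, `sigma_ave`,
#'   `t_crit`, `n`, `ci`.
#' @export
#' @examples
#' ci_threshold(c(0.07, 0.09), c(0.08, 0.08), n = 3)
ci_threshold <- function(sds_ref, sds_test = numeric(0), n = 3,
                         confidence = 0.95) {
  if (n < 2) hdx_abort("n must be >= 2", "hdx_validation_error")
  sds <- c(sds_ref, sds_test)
  sds <- sds[!is.na(sds)]
  if (length(sds) == 0) {
    hdx_abort(paste("no replicate standard deviations available;",
                    "at least one time point needs n >= 2 in both states"),
              "hdx_validation_error")
  }
  sigma_bar <- mean(sds)
  t_crit <- qt(1 - (1 - confidence) / 2, df = n - 1)
  sigma_ave <- sqrt(n * sigma_bar^2)
  ci <- t_crit * sigma_ave / sqrt(n)
  structure(list(sigma_bar = sigma_bar, sigma_ave = sigma_ave,
                 t_crit = t_crit, n = n, confidence = confidence, ci = ci,
                 n_sds = length(sds)),
            class = "ci_threshold")
}

#' @export
print.ci_threshold <- function(x, ...) {
  cat(sprintf("<ci_threshold> CI = %.4f D (sigma_bar %.4f over %d SDs, t[%d df] = %.3f, %g%%)\n",
              x$ci, x$sigma_bar, x$n_sds, x$n - 1, x$t_crit,
              100 * x$confidence))
  invisible(x)
}

#' CI threshold straight from an uptake summary
#'
#' Convenience wrapper pooling every available replicate SD of the two
#' states being compared.
#'
#' @param series `uptake_series` summary.
#' @param reference,test state labels.
#' @inheritParams ci_threshold
#' @return a [ci_threshold()] object.
#' @export
ci_threshold_from_series <- function(series, reference, test, n = 3,
                                     confidence = 0.95) {
  ci_threshold(series$sd_uptake_D[series$state == reference],
               series$sd_uptake_D[series$state == test],
               n = n, confidence = confidence)
}

# Runs of consecutive TRUEs of length >= k: returns index of first window.
first_consecutive <- function(flag, k = 2) {
  if (length(flag) < k) return(NA_integer_)
  flag[is.na(flag)] <- FALSE
  for (i in seq_len(length(flag) - k + 1)) {
    if (all(flag[i:(i + k - 1)])) return(i)
  }
  NA_integer_
}

#' Hybrid significance decision for one peptide
#'
#' A peptide's uptake difference is significant when (a) |dD| exceeds the
#' comparison CI at two consecutive time points, or (b) a two-tailed
#' pooled-variance two-sample t-test on replicate uptake rejects at `alpha`
#' at two consecutive time points where both states are replicated, or (c)
#' the last time point alone shows |dD| at least twice the CI (an expanding
#' difference the time course did not fully sample). Rules are tried in the
#' order a, b, c and the first that fires is recorded. Direction comes from
#' the sign of dD at the triggering points; if those signs disagree the
#' verdict follows the larger |dD| and the call is flagged
#' direction-unstable.
#'
#' @param profile rows of a [difference_profile()] for one peptide, ordered
#'   by time.
#' @param ci a [ci_threshold()].
#' @param replicate_data optional measurement tibble (for rule b); rule (b)
#'   is simply disabled without it.
#' @param alpha t-test significance level (default 0.01).
#' @return one-row tibble: `peptide_id`, `verdict` (increase/decrease/none,
#'   exchange in the test state relative to reference), `rule_fired`,
#'   `support_times`, `direction_unstable`, `delta_max`.
#' @export
classify_significance <- function(profile, ci, replicate_data = NULL,
                                  alpha = 0.01) {
  stopifnot(length(unique(profile$peptide_id)) == 1)
  profile <- dplyr::arrange(profile, .data$exposure_min)
  if (nrow(profile) < 2) {
    hdx_abort("significance classification needs >= 2 time points",
              "hdx_validation_error")
  }
  times <- profile$exposure_min
  dd <- profile$delta_D
  rule <- "none"; idx <- NA_integer_; support <- numeric(0)

  i <- first_consecutive(abs(dd) > ci$ci)
  if (!is.na(i)) {
    rule <- "consecutive_CI"; support <- times[c(i, i + 1)]
  } else if (!is.null(replicate_data)) {
    pvals <- vapply(seq_along(times), function(j) {
      ref_v <- replicate_data$uptake_D[
        replicate_data$peptide_id == profile$peptide_id[1] &
          replicate_data$state == profile$reference[1] &
          replicate_data$exposure_min == times[j]]
      tst_v <- replicate_data$uptake_D[
        replicate_data$peptide_id == profile$peptide_id[1] &
          replicate_data$state == profile$test[1] &
          replicate_data$exposure_min == times[j]]
      if (length(ref_v) < 2 || length(tst_v) < 2) return(NA_real_)
      if (sd(ref_v) == 0 && sd(tst_v) == 0) {
        return(if (mean(ref_v) == mean(tst_v)) 1 else 0)
      }
      t.test(ref_v, tst_v, var.equal = TRUE)$p.value
    }, numeric(1))
    i <- first_consecutive(pvals < alpha)
    if (!is.na(i)) {
      rule <- "t_test"; support <- times[c(i, i + 1)]
    }
  }
  if (rule == "none" && abs(dd[length(dd)]) >= 2 * ci$ci) {
    rule <- "last_point_2xCI"; support <- times[length(times)]
  }

  verdict <- "none"; unstable <- FALSE
  if (rule != "none") {
    trig <- dd[match(support, times)]
    signs <- sign(trig)
    if (length(unique(signs[signs != 0])) > 1) {
      unstable <- TRUE
      trig <- trig[which.max(abs(trig))]
    }
    # positive dD (= ref - test) means the test state took up less deuterium
    verdict <- if (trig[which.max(abs(trig))] > 0) "decrease" else "increase"
  }
  tibble::tibble(
    peptide_id = profile$peptide_id[1], start = profile$start[1],
    end = profile$end[1], verdict = verdict, rule_fired = rule,
    support_times = paste(support, collapse = ";"),
    direction_unstable = unstable,
    delta_max = dd[which.max(abs(dd))]
  )
}

#' Classify every peptide of a comparison
#'
#' @param profiles a [difference_profile()] over many peptides.
#' @inheritParams classify_significance
#' @return tibble of per-peptide calls (see [classify_significance()]).
#' @export
classify_all <- function(profiles, ci, replicate_data = NULL, alpha = 0.01) {
  out <- profiles |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::group_map(~ classify_significance(.x |>
                       dplyr::mutate(peptide_id = .y$peptide_id),
                       ci, replicate_data, alpha)) |>
    dplyr::bind_rows()
  dplyr::arrange(out, .data$start, .data$end)
}

#' Consolidate peptide calls onto residues
#'
#' Residue labels: the unanimous verdict of covering significant peptides;
#' `mixed` when significant peptides disagree; `none` when covered only by
#' non-significant peptides; `no_coverage` otherwise. Coverage percent is
#' the union of all peptide intervals over the construct length.
#'
#' @param calls per-peptide calls from [classify_all()].
#' @param peptides [peptide_records()] table (all peptides, for coverage).
#' @param protein a [protein_context()].
#' @return list with `map` (tibble: `residue`, `label`, `delta_max`) and
#'   `coverage_percent`.
#' @export
consolidate_residues <- function(calls, peptides, protein) {
  len <- protein_length(protein)
  off <- protein$residue_offset
  residues <- seq.int(off, off + len - 1L)
  label <- rep("no_coverage", len)
  delta_max <- rep(NA_real_, len)

  covered <- rep(FALSE, len)
  for (k in seq_len(nrow(peptides))) {
    idx <- (peptides$start[k]:peptides$end[k]) - off + 1L
    covered[idx] <- TRUE
  }
  label[covered] <- "none"

  sig <- calls[calls$verdict != "none", , drop = FALSE]
  inc <- rep(FALSE, len); dec <- rep(FALSE, len)
  for (k in seq_len(nrow(sig))) {
    idx <- (sig$start[k]:sig$end[k]) - off + 1L
    if (sig$verdict[k] == "increase") inc[idx] <- TRUE else dec[idx] <- TRUE
    delta_max[idx] <- pmax(delta_max[idx], abs(sig$delta_max[k]), na.rm = TRUE)
  }
  label[inc & !dec] <- "increase"
  label[dec & !inc] <- "decrease"
  label[inc & dec] <- "mixed"

  list(
    map = tibble::tibble(residue = residues, label = label,
                         delta_max = delta_max),
    coverage_percent = 100 * sum(covered) / len
  )
}

#' Sequence coverage of a peptide set
#'
#' Fraction of the construct covered by the union of peptide intervals.
#'
#' @param peptides tibble with `start`, `end` (construct numbering).
#' @param protein a [protein_context()], or a plain integer length.
#' @return coverage in percent.
#' @export
#' @examples
#' prot <- protein_context(strrep("A", 40))
#' peptide_coverage(data.frame(start = c(1, 5), end = c(10, 20)), prot)  # 50
peptide_coverage <- function(peptides, protein) {
  len <- if (inherits(protein, "protein_context")) protein_length(protein)
         else as.integer(protein)
  off <- if (inherits(protein, "protein_context")) protein$residue_offset else 1L
  covered <- rep(FALSE, len)
  for (k in seq_len(nrow(peptides))) {
    idx <- (peptides$start[k]:peptides$end[k]) - off + 1L
    covered[idx[idx >= 1 & idx <= len]] <- TRUE
  }
  100 * sum(covered) / len
}

#' Export a residue classification for structure painting
#'
#' Writes a flat per-residue attribute table (residue, label, delta_max)
#' suitable for colouring a structure in external viewers.
#'
#' @param residue_map result of [consolidate_residues()].
#' @param path output path (plain text, tab-separated).
#' @return `path`, invisibly.
#' @export
write_residue_attributes <- function(residue_map, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- residue_map$map
  lines <- c("# residue\tlabel\tdelta_max_D",
             sprintf("%d\t%s\t%s", df$residue, df$label,
                     ifelse(is.na(df$delta_max), "NA",
                            sprintf("%.6f", df$delta_max))))
  writeLines(lines, path)
  invisible(path)
}
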