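#' Intraclass correlation, two-way model, absolute agreement, single measures
#'
#' ICC for absolute agreement between two measurement methods across
#' subjects (the form SPSS labels "two-way mixed, absolute agreement, single
#' measures"; its estimate coincides with ICC(2,1)). From the two-way ANOVA
#' mean squares with n subjects and k = 2 raters:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' The 95% confidence interval follows the standard two-way absolute-
#' agreement formulation and the p-value is the F-test of the subject effect
#' against error (true value 0), F = MS_R/MS_E on (n-1, (n-1)(k-1)) df.
#'
#' @param data A data frame of paired values (one row per subject).
#' @param sim,meas Columns holding the two methods' values (tidy-eval;
#'   defaults `sim_cms`, `meas_cms`).
#' @param conf_level Confidence level for the interval.
#' @return An object of class `cow_icc` with elements `icc`, `ci_low`,
#'   `ci_high`, `p_value`, `label`, `n`, `k` and the ANOVA mean squares.
#' @export
#' @examples
#' d <- tibble::tibble(sim_cms = c(10, 20, 30, 40, 50, 61),
#'                     meas_cms = c(11, 19, 33, 38, 52, 60))
#' icc_absolute_agreement(d)
icc_absolute_agreement <- function(data, sim = sim_cms, meas = meas_cms,
                                   conf_level = 0.95) {
  x <- dplyr::pull(data, {{ sim }})
  y <- dplyr::pull(data, {{ meas }})
  if (length(x) != length(y) || anyNA(x) || anyNA(y)) {
    abort("Paired values must be complete and of equal length.",
          class = "cowflow_invalid_input")
  }
  n <- length(x); k <- 2
  if (n < 3) {
    abort("At least 3 pairs are required.", class = "cowflow_invalid_input")
  }
  mat <- cbind(x, y)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot <= 0) {
    abort("Zero total variance: ICC undefined.",
          class = "cowflow_degenerate_input")
  }
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # confidence interval (two-way absolute agreement, single measures)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  f0 <- msr / mse
  p <- pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 p_value = p, label = icc_interpret(max(min(icc, 1), -1)),
                 n = n, k = k, msr = msr, msc = msc, mse = mse,
                 conf_level = conf_level),
            class = "cow_icc")
}

#' @export
print.cow_icc <- function(x, ...) {
  cat(sprintf("ICC (two-way, absolute agreement) = %.3f [%.3f, %.3f], p = %.2g (%s)\n",
              x$icc, x$ci_low, x$ci_high, x$p_value, x$label))
  invisible(x)
}

#' @export
tidy.cow_icc <- function(x, ...) {
  tibble(estimate = x$icc, conf.low = x$ci_low, conf.high = x$ci_high,
         p.value = x$p_value, label = x$label, n = x$n)
}

#' Interpret an ICC value
#'
#' Conventional reliability labels: below 0.5 poor, 0.5 to 0.75 moderate,
#' 0.75 to 0.9 good, 0.9 and above excellent.
#'
#' @param icc ICC value(s) in `[-1, 1]`.
#' @return Character vector of labels.
#' @export
#' @examples
#' icc_interpret(c(0.4, 0.695, 0.755, 0.95))
icc_interpret <- function(icc) {
  if (any(!is.finite(icc)) || any(icc < -1) || any(icc > 1)) {
    abort("`icc` must lie in [-1, 1].", class = "cowflow_invalid_input")
  }
  dplyr::case_when(icc < 0.5 ~ "poor",
                   icc < 0.75 ~ "moderate",
                   icc < 0.9 ~ "good",
                   TRUE ~ "excellent")
}

#' Pearson correlation between paired velocities
#'
#' @inheritParams icc_absolute_agreement
#' @return A tibble with `r` and `p_value`.
#' @export
pearson_agreement <- function(data, sim = sim_cms, meas = meas_cms) {
  x <- dplyr::pull(data, {{ sim }})
  y <- dplyr::pull(data, {{ meas }})
  if (length(x) < 3) {
    abort("At least 3 pairs are required.", class = "cowflow_invalid_input")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance on one side: correlation undefined.",
          class = "cowflow_degenerate_input")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Mean difference between methods (one table row)
#'
#' The difference convention of the per-artery comparison table:
#' `mean_diff = mean_meas - mean_sim` (measured minus simulated, cm/s) and
#' `pct_diff = 100 * mean_diff / mean_sim` (percent of the simulation mean).
#' Full precision is returned; apply [round_report()] for table cells.
#'
#' @param mean_sim Simulation mean, cm/s (must be positive).
#' @param mean_meas Measured (TCCD) mean, cm/s.
#' @return A tibble with `mean_diff_cms` and `pct_diff` (vectorised).
#' @export
#' @examples
#' difference_row(57.8, 50.2) # -7.6 cm/s, -13.1 %
difference_row <- function(mean_sim, mean_meas) {
  if (any(!is.finite(mean_sim)) || any(mean_sim <= 0)) {
    abort("`mean_sim` must be positive.", class = "cowflow_invalid_input")
  }
  d <- mean_meas - mean_sim
  tibble(mean_diff_cms = d, pct_diff = 100 * d / mean_sim)
}

#' Overall difference across arteries
#'
#' Unweighted arithmetic mean, across per-artery rows, of the mean
#' differences and of the percent differences (full-precision values
#' averaged; round only for reporting). A grand overall is the same average
#' applied to the per-velocity-type overalls.
#'
#' @param rows A data frame with columns `mean_diff_cms` and `pct_diff`.
#' @return A one-row tibble with `mean_diff_cms`, `pct_diff`, `n_rows`.
#' @export
overall_difference <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) < 1 ||
      !all(c("mean_diff_cms", "pct_diff") %in% names(rows))) {
    abort("`rows` must have >= 1 row with mean_diff_cms and pct_diff.",
          class = "cowflow_invalid_input")
  }
  tibble(mean_diff_cms = mean(rows$mean_diff_cms),
         pct_diff = mean(rows$pct_diff),
         n_rows = nrow(rows))
}

#' Bland-Altman analysis with normality-gated limits
#'
#' Differences d = measured - simulated are tested for normality
#' (Shapiro-Wilk). If normality is rejected at `normality_alpha` the centre
#' is the median and the limits of agreement are the 2.5th and 97.5th
#' percentiles (linear interpolation between order statistics, the default
#' quantile definition); otherwise the centre is the mean and the limits are
#' mean +/- 1.96 SD.
#'
#' @inheritParams icc_absolute_agreement
#' @param normality_alpha Significance level of the normality gate.
#' @return An object of class `cow_bland_altman` with `center`, `loa_low`,
#'   `loa_high`, `method` ("percentile" or "parametric"), `normality_p`, and
#'   the per-pair `means`/`differences`.
#' @export
bland_altman <- function(data, sim = sim_cms, meas = meas_cms,
                         normality_alpha = 0.05) {
  x <- dplyr::pull(data, {{ sim }})
  y <- dplyr::pull(data, {{ meas }})
  n <- length(x)
  if (n < 3) {
    abort("At least 3 pairs are required.", class = "cowflow_invalid_input")
  }
  if (n < 10) {
    warn("Fewer than 10 pairs: percentile limits of agreement are unstable.")
  }
  d <- y - x
  if (all(d == d[1])) {
    # degenerate: identical differences (e.g. perfect agreement)
    res <- list(center = d[1], loa_low = d[1], loa_high = d[1],
                method = "percentile", normality_p = NA_real_,
                means = (x + y) / 2, differences = d, n = n)
    return(structure(res, class = "cow_bland_altman"))
  }
  sw <- shapiro.test(d)
  if (sw$p.value < normality_alpha) {
    center <- median(d)
    loa <- unname(quantile(d, c(0.025, 0.975), type = 7))
    method <- "percentile"
  } else {
    center <- mean(d)
    loa <- center + c(-1.96, 1.96) * sd(d)
    method <- "parametric"
  }
  structure(list(center = center, loa_low = loa[1], loa_high = loa[2],
                 method = method, normality_p = sw$p.value,
                 means = (x + y) / 2, differences = d, n = n),
            class = "cow_bland_altman")
}

#' @export
print.cow_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): center %.2f, limits [%.2f, %.2f], n = %d\n",
              x$method, x$center, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
tidy.cow_bland_altman <- function(x, ...) {
  tibble(center = x$center, loa_low = x$loa_low, loa_high = x$loa_high,
         method = x$method, normality_p = x$normality_p, n = x$n)
}

#' @export
autoplot.cow_bland_altman <- function(object, ...) {
  df <- tibble(mean = object$means, difference = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$center, linetype = "dotted",
                        colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dotted", colour = "red") +
    ggplot2::labs(x = "mean of methods (cm/s)",
                  y = "difference, measured - simulated (cm/s)",
                  title = sprintf("Bland-Altman (%s limits)", object$method)) +
    ggplot2::theme_minimal()
}

#' Average left and right sides per patient
#'
#' Scatter and Bland-Altman comparisons of paired arteries use the mean of
#' the left and right side per patient; unpaired arteries (BA) pass through.
#'
#' @param pairs Long paired table with columns `patient_id`, `artery`,
#'   `side`, `phase`, `sim_cms`, `meas_cms`.
#' @param artery_name Artery to select (e.g. "MCA").
#' @param phase_name Velocity type (e.g. "PSV").
#' @return A tibble with one row per patient: `sim_cms`, `meas_cms`.
#' @export
side_averaged_pairs <- function(pairs, artery_name, phase_name) {
  pairs |>
    dplyr::filter(.data$artery == artery_name, .data$phase == phase_name) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(sim_cms = mean(.data$sim_cms),
                     meas_cms = mean(.data$meas_cms), .groups = "drop")
}

#' Build the full agreement report
#'
#' Produces the per-artery, per-velocity-type agreement table of a
#' validation study: for each of the nine arterial sites (MCA, ACA, PCA
#' left/right, BA, V4 left/right) and each velocity type (PSV, EDV, MFV) the
#' ICC with 95% CI, p-value and reliability label, the Pearson correlation,
#' the two methods' means and SDs, and the difference row; plus an overall
#' row per velocity type (unweighted mean over the nine sites) and a grand
#' overall averaging the three velocity-type overalls.
#'
#' @param pairs Long paired table: `patient_id`, `artery`, `side`, `phase`,
#'   `sim_cms`, `meas_cms`. All nine sites must be present per phase.
#' @return A `cow_agreement_report`: `$table` (per-site rows), `$overall`
#'   (per-phase and grand rows), `$pairs`.
#' @export
build_report <- function(pairs) {
  needed <- c("patient_id", "artery", "side", "phase", "sim_cms", "meas_cms")
  missing_col <- setdiff(needed, names(pairs))
  if (length(missing_col) > 0) {
    abort(paste0("Missing columns: ", paste(missing_col, collapse = ", ")),
          class = "cowflow_schema_error")
  }
  sites <- measurement_sites() |>
    dplyr::mutate(site = ifelse(is.na(.data$side), .data$artery,
                                paste(.data$artery, .data$side)))
  phases <- c("PSV", "EDV", "MFV")
  pairs <- dplyr::mutate(pairs,
                         site = ifelse(is.na(.data$side), .data$artery,
                                       paste(.data$artery, .data$side)))
  for (ph in phases) {
    have <- unique(pairs$site[pairs$phase == ph])
    miss <- setdiff(sites$site, have)
    if (length(miss) > 0) {
      abort(sprintf("Phase %s is missing site(s): %s", ph,
                    paste(miss, collapse = ", ")),
            class = "cowflow_schema_error")
    }
  }

  per_site <- tidyr::expand_grid(phase = phases, site = sites$site) |>
    purrr::pmap(function(phase, site) {
      d <- pairs[pairs$phase == phase & pairs$site == site, ]
      ic <- icc_absolute_agreement(d)
      pr <- pearson_agreement(d)
      diff <- difference_row(mean(d$sim_cms), mean(d$meas_cms))
      tibble(phase = phase, site = site, n = nrow(d),
             icc = ic$icc, icc_ci_low = ic$ci_low,
             icc_ci_high = ic$ci_high, icc_p = ic$p_value,
             icc_label = ic$label,
             pearson_r = pr$r, pearson_p = pr$p_value,
             mean_sim = mean(d$sim_cms), sd_sim = sd(d$sim_cms),
             mean_meas = mean(d$meas_cms), sd_meas = sd(d$meas_cms),
             mean_diff_cms = diff$mean_diff_cms, pct_diff = diff$pct_diff)
    }) |>
    dplyr::bind_rows()

  overall <- purrr::map_dfr(phases, function(ph) {
    o <- overall_difference(per_site[per_site$phase == ph, ])
    tibble(phase = ph, mean_diff_cms = o$mean_diff_cms,
           pct_diff = o$pct_diff)
  })
  grand <- overall_difference(overall)
  overall <- dplyr::bind_rows(
    overall,
    tibble(phase = "ALL", mean_diff_cms = grand$mean_diff_cms,
           pct_diff = grand$pct_diff))

  structure(list(table = per_site, overall = overall, pairs = pairs),
            class = "cow_agreement_report")
}

#' @export
print.cow_agreement_report <- function(x, ...) {
  cat(sprintf("<cow_agreement_report> %d site rows, overall rows:\n",
              nrow(x$table)))
  ov <- x$overall
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %s: %s cm/s; %s %%\n", ov$phase[i],
                format(round_report(ov$mean_diff_cms[i], 1)),
                format(round_report(ov$pct_diff[i], 1))))
  }
  invisible(x)
}

#' @export
tidy.cow_agreement_report <- function(x, ...) x$table

#' @export
glance.cow_agreement_report <- function(x, ...) {
  g <- x$overall[x$overall$phase == "ALL", ]
  tibble(mean_diff_cms = g$mean_diff_cms, pct_diff = g$pct_diff,
         n_sites = length(unique(x$table$site)),
         mean_icc = mean(x$table$icc))
}

#' @export
autoplot.cow_agreement_report <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$icc, y = .data$site,
                               colour = .data$phase)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$icc_ci_low,
                                         xmax = .data$icc_ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "ICC (absolute agreement)", y = NULL,
                  title = "Per-artery agreement, simulation vs TCCD") +
    ggplot2::theme_minimal()
}

#' Scatter plot of paired velocities for one artery
#'
#' @param pairs Long paired table (see [build_report()]).
#' @param artery_name,phase_name Artery and velocity type to plot; sides are
#'   averaged per patient as in the companion Bland-Altman analysis.
#' @return A ggplot.
#' @export
plot_agreement_scatter <- function(pairs, artery_name, phase_name = "PSV") {
  d <- side_averaged_pairs(pairs, artery_name, phase_name)
  pr <- pearson_agreement(d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sim_cms, y = .data$meas_cms)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(x = "simulated velocity (cm/s)",
                  y = "TCCD velocity (cm/s)",
                  title = sprintf("%s %s: r = %.2f", artery_name, phase_name,
                                  pr$r)) +
    ggplot2::theme_minimal()
}
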