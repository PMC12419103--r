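#' Unit conversions used at reporting boundaries
#'
#' Internally everything is strict SI (m, s, Pa, kg). Clinical quantities are
#' converted only at the user-facing edges: velocities to cm/s, pressures to
#' mmHg, flow volumes to mL/min.
#'
#' @param x Numeric vector.
#' @return Numeric vector in the target unit.
#' @name units
#' @examples
#' mmhg_to_pa(120)
#' ms_to_cms(0.6)
NULL

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * 133.322387415

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / 133.322387415

#' @rdname units
#' @export
cms_to_ms <- function(x) x / 100

#' @rdname units
#' @export
ms_to_cms <- function(x) x * 100

#' @rdname units
#' @export
m3s_to_mlmin <- function(x) x * 6e7

#' Round half away from zero
#'
#' Reporting cells use round-half-away-from-zero (the convention of clinical
#' tables), not the IEEE round-half-even of [base::round()]. Full precision is
#' always retained internally; this is applied only when formatting report
#' cells.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_report(c(0.25, -0.25), 1) # 0.3, -0.3
round_report <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared input check: scalar finite number
check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "cowflow_invalid_input")
  }
  if ((strict_min && x <= min) || (!strict_min && x < min) || x > max) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x),
          class = "cowflow_invalid_input")
  }
  invisible(x)
}

# draw from a lower-truncated normal by inverse CDF (vectorised, reproducible)
rtruncnorm_lower <- function(n, mean, sd, lower) {
  p0 <- pnorm(lower, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

# draw from a two-sided truncated normal by inverse CDF
rtruncnorm_both <- function(n, mean, sd, lower, upper) {
  p0 <- pnorm(lower, mean, sd)
  p1 <- pnorm(upper, mean, sd)
  qnorm(p0 + runif(n) * (p1 - p0), mean, sd)
}

# mean/sd of a lower-truncated normal
truncnorm_moments <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  lam <- dnorm(a) / (1 - pnorm(a))
  m <- mean + sd * lam
  v <- sd^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(v))
}

# underlying (mean, sd) such that the lower-truncated normal has the target
# moments; 2-d damped fixed-point/Newton via optim is overkill -- use nlm-free
# iteration on the closed-form moment map.
truncnorm_match_moments <- function(target_mean, target_sd, lower) {
  f <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), lower)
    sum((m - c(target_mean, target_sd))^2)
  }
  opt <- stats::optim(c(target_mean, log(target_sd)), f,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(mean = opt$par[1], sd = exp(opt$par[2]))
}
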