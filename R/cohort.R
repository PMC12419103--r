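#' Cohort distribution parameters
#'
#' Defaults emulate a consecutive minor-stroke/TIA cohort without large-
#' artery disease: inlet peak systolic velocities with mean 60.1 and SD 17.4
#' cm/s at the extracranial ICA and 41.6 and 17.5 cm/s at the vertebral
#' artery; systolic/diastolic pressure before the ultrasound examination
#' 133.7 +/- 21.0 and 80.3 +/- 14.7 mmHg; age 62.4 +/- 15.2 years. Velocities
#' are floored (ICA at 15, VA at 10 cm/s) by truncated-normal sampling whose
#' underlying parameters are moment-matched so the truncated distribution
#' reproduces the stated mean and SD. End-diastolic velocity is a fraction
#' 0.33 +/- 0.05 of PSV (truncated to 0.15-0.5) and the mean velocity follows
#' the Doppler convention MFV = (PSV + 2 EDV)/3. Anatomical-variant
#' prevalences and geometric variability are configurable.
#'
#' @param ... Overrides of any default element.
#' @return A list of class `cow_cohort_params`.
#' @export
cohort_params <- function(...) {
  p <- list(
    ica_psv_mean = 60.1, ica_psv_sd = 17.4, ica_psv_floor = 15,
    va_psv_mean = 41.6, va_psv_sd = 17.5, va_psv_floor = 10,
    edv_fraction_mean = 0.33, edv_fraction_sd = 0.05,
    edv_fraction_range = c(0.15, 0.5),
    sbp_mean = 133.7, sbp_sd = 21.0,
    dbp_mean = 80.3, dbp_sd = 14.7,
    age_mean = 62.4, age_sd = 15.2,
    p_acom_absent = 0.05,
    p_pcom_absent = 0.25,       # per side
    p_a1_hypoplasia = 0.10,     # per side; factor uniform in hypo_factor_range
    p_p1_hypoplasia = 0.15,
    hypo_factor_range = c(0.4, 0.7),
    geometry_sd = 0.08)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) {
    abort(paste0("Unknown cohort parameter(s): ", paste(bad, collapse = ", ")),
          class = "cowflow_invalid_input")
  }
  p <- utils::modifyList(p, over)
  probs <- unlist(p[c("p_acom_absent", "p_pcom_absent", "p_a1_hypoplasia",
                      "p_p1_hypoplasia")])
  if (any(probs < 0) || any(probs > 1) ||
      any(unlist(p[c("ica_psv_sd", "va_psv_sd", "edv_fraction_sd", "sbp_sd",
                     "dbp_sd", "age_sd", "geometry_sd")]) < 0)) {
    abort("Invalid cohort parameter set.", class = "cowflow_invalid_input")
  }
  structure(p, class = "cow_cohort_params")
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` synthetic patients: demographics, blood pressures at the time of
#' the ultrasound examination (diastolic below systolic enforced by
#' resampling; mean arterial pressure = DBP + (SBP - DBP)/3), per-side inlet
#' velocity triplets for both internal carotid and both vertebral arteries,
#' and an anatomical variant plus a geometry-perturbation seed. Fully
#' reproducible under `seed`; networks are materialised on demand with
#' [patient_network()].
#'
#' @param n Number of patients (>= 0).
#' @param seed Integer seed.
#' @param params A [cohort_params()].
#' @return A tibble with one row per patient.
#' @export
#' @examples
#' generate_cohort(3, seed = 1)
generate_cohort <- function(n, seed = 1, params = cohort_params()) {
  stopifnot(inherits(params, "cow_cohort_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    abort("`n` must be a non-negative integer.",
          class = "cowflow_invalid_input")
  }
  n <- as.integer(n)
  cols <- c("patient_id", "age", "sbp_mmhg", "dbp_mmhg", "mbp_mmhg",
            "ica_l_psv_cms", "ica_l_edv_cms", "ica_l_mfv_cms",
            "ica_r_psv_cms", "ica_r_edv_cms", "ica_r_mfv_cms",
            "va_l_psv_cms", "va_l_edv_cms", "va_l_mfv_cms",
            "va_r_psv_cms", "va_r_edv_cms", "va_r_mfv_cms",
            "acom_present", "pcom_l_present", "pcom_r_present",
            "a1_l_factor", "a1_r_factor", "p1_l_factor", "p1_r_factor",
            "geom_seed")
  if (n == 0) {
    out <- as_tibble(stats::setNames(
      lapply(cols, function(cc) {
        if (cc == "patient_id") character(0)
        else if (grepl("present", cc)) logical(0)
        else numeric(0)
      }), cols))
    return(out)
  }

  ica_par <- truncnorm_match_moments(params$ica_psv_mean, params$ica_psv_sd,
                                     params$ica_psv_floor)
  va_par <- truncnorm_match_moments(params$va_psv_mean, params$va_psv_sd,
                                    params$va_psv_floor)

  withr::with_seed(as.integer(seed), {
    age <- rnorm(n, params$age_mean, params$age_sd)
    sbp <- rnorm(n, params$sbp_mean, params$sbp_sd)
    dbp <- rnorm(n, params$dbp_mean, params$dbp_sd)
    bad <- which(dbp >= sbp)
    while (length(bad) > 0) {
      sbp[bad] <- rnorm(length(bad), params$sbp_mean, params$sbp_sd)
      dbp[bad] <- rnorm(length(bad), params$dbp_mean, params$dbp_sd)
      bad <- which(dbp >= sbp)
    }
    mbp <- dbp + (sbp - dbp) / 3

    draw_triplet <- function(psv) {
      frac <- rtruncnorm_both(n, params$edv_fraction_mean,
                              params$edv_fraction_sd,
                              params$edv_fraction_range[1],
                              params$edv_fraction_range[2])
      edv <- psv * frac
      list(psv = psv, edv = edv, mfv = (psv + 2 * edv) / 3)
    }
    ica_l <- draw_triplet(rtruncnorm_lower(n, ica_par$mean, ica_par$sd,
                                           params$ica_psv_floor))
    ica_r <- draw_triplet(rtruncnorm_lower(n, ica_par$mean, ica_par$sd,
                                           params$ica_psv_floor))
    va_l <- draw_triplet(rtruncnorm_lower(n, va_par$mean, va_par$sd,
                                          params$va_psv_floor))
    va_r <- draw_triplet(rtruncnorm_lower(n, va_par$mean, va_par$sd,
                                          params$va_psv_floor))

    hypo <- function(p) {
      hit <- runif(n) < p
      ifelse(hit, runif(n, params$hypo_factor_range[1],
                        params$hypo_factor_range[2]), 1)
    }
    tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = age,
      sbp_mmhg = sbp, dbp_mmhg = dbp, mbp_mmhg = mbp,
      ica_l_psv_cms = ica_l$psv, ica_l_edv_cms = ica_l$edv,
      ica_l_mfv_cms = ica_l$mfv,
      ica_r_psv_cms = ica_r$psv, ica_r_edv_cms = ica_r$edv,
      ica_r_mfv_cms = ica_r$mfv,
      va_l_psv_cms = va_l$psv, va_l_edv_cms = va_l$edv,
      va_l_mfv_cms = va_l$mfv,
      va_r_psv_cms = va_r$psv, va_r_edv_cms = va_r$edv,
      va_r_mfv_cms = va_r$mfv,
      acom_present = runif(n) >= params$p_acom_absent,
      pcom_l_present = runif(n) >= params$p_pcom_absent,
      pcom_r_present = runif(n) >= params$p_pcom_absent,
      a1_l_factor = hypo(params$p_a1_hypoplasia),
      a1_r_factor = hypo(params$p_a1_hypoplasia),
      p1_l_factor = hypo(params$p_p1_hypoplasia),
      p1_r_factor = hypo(params$p_p1_hypoplasia),
      geom_seed = sample.int(2^30, n))
  })
}

#' Materialise one patient's vascular network
#'
#' Builds the Circle-of-Willis template with the patient's anatomical
#' variant and applies the patient's reproducible geometric perturbation.
#'
#' @param patient One row of a [generate_cohort()] tibble.
#' @param params The [cohort_params()] used for the cohort.
#' @return A `cow_network`.
#' @export
patient_network <- function(patient, params = cohort_params()) {
  variant <- anatomical_variant(
    acom_present = patient$acom_present,
    pcom_left_present = patient$pcom_l_present,
    pcom_right_present = patient$pcom_r_present,
    a1_left_factor = patient$a1_l_factor,
    a1_right_factor = patient$a1_r_factor,
    p1_left_factor = patient$p1_l_factor,
    p1_right_factor = patient$p1_r_factor)
  net <- build_cow_template(variant)
  perturb_geometry(net, params$geometry_sd, patient$geom_seed)
}

#' Per-patient boundary conditions for the three phases
#'
#' @param patient One row of a [generate_cohort()] tibble.
#' @return Named list of [phase_bc()] objects (`PSV`, `EDV`, `MFV`).
#' @export
patient_bc <- function(patient) {
  v <- function(kind) c(ICA_L = patient[[paste0("ica_l_", kind, "_cms")]],
                        ICA_R = patient[[paste0("ica_r_", kind, "_cms")]],
                        VA_L = patient[[paste0("va_l_", kind, "_cms")]],
                        VA_R = patient[[paste0("va_r_", kind, "_cms")]])
  list(PSV = phase_bc("PSV", v("psv"), patient$sbp_mmhg),
       EDV = phase_bc("EDV", v("edv"), patient$dbp_mmhg),
       MFV = phase_bc("MFV", v("mfv"), patient$mbp_mmhg))
}

#' TCCD measurement-noise parameters
#'
#' Multiplicative noise model of transcranial color-coded duplex sonography:
#' each site's whole velocity triplet is scaled by one lognormal-like factor
#' (Doppler gain/placement error, SD `sd_mult`), and, when the site is
#' measured without angle correction, additionally by cos(theta) with theta
#' uniform on (0, `theta_max_deg`) — omitting the correction underestimates
#' the true velocity by the cosine of the insonation angle. Default
#' per-artery probabilities of an uncorrected measurement reflect clinical
#' practice: the basilar artery is rarely correctable through the nuchal
#' window (~87% uncorrected), V4 intermediate (~70%), MCA mostly corrected
#' (~32% uncorrected).
#'
#' @param sd_mult SD of the shared multiplicative error.
#' @param theta_max_deg Maximum insonation angle when uncorrected, degrees.
#' @param theta_min_deg Minimum insonation angle when uncorrected (equal to
#'   `theta_max_deg` for a fixed angle).
#' @param p_uncorrected Named per-artery probabilities of no angle
#'   correction.
#' @return A list of class `cow_noise_params`.
#' @export
tccd_noise_params <- function(sd_mult = 0.15, theta_max_deg = 30,
                              theta_min_deg = 0,
                              p_uncorrected = c(MCA = 0.32, ACA = 0.40,
                                                PCA = 0.40, BA = 0.87,
                                                V4 = 0.70)) {
  check_number(sd_mult, "sd_mult", min = 0)
  check_number(theta_max_deg, "theta_max_deg", min = 0, max = 90)
  check_number(theta_min_deg, "theta_min_deg", min = 0, max = theta_max_deg)
  if (any(p_uncorrected < 0) || any(p_uncorrected > 1)) {
    abort("`p_uncorrected` entries must be probabilities.",
          class = "cowflow_invalid_input")
  }
  structure(list(sd_mult = sd_mult, theta_max_deg = theta_max_deg,
                 theta_min_deg = theta_min_deg,
                 p_uncorrected = p_uncorrected),
            class = "cow_noise_params")
}

#' Synthesize TCCD observations of true site velocities
#'
#' Applies the measurement model of [tccd_noise_params()] to a table of true
#' per-site velocity triplets. The same multiplicative draw scales PSV, EDV
#' and MFV of a site (the whole Doppler envelope is mis-scaled together).
#' Deterministic under `seed`.
#'
#' @param true_sites Tibble with `artery`, `side`, `psv_cms`, `edv_cms`,
#'   `mfv_cms` (and optionally `patient_id`).
#' @param noise A [tccd_noise_params()].
#' @param seed Integer seed.
#' @return The input tibble with the velocity columns replaced by noisy
#'   observations plus `angle_corrected` and `insonation_angle_deg`.
#' @export
synthesize_tccd <- function(true_sites, noise = tccd_noise_params(),
                            seed = 1) {
  stopifnot(inherits(noise, "cow_noise_params"))
  m <- nrow(true_sites)
  withr::with_seed(as.integer(seed), {
    gain <- pmax(rnorm(m, 1, noise$sd_mult), 0.05)
    p_unc <- unname(noise$p_uncorrected[true_sites$artery])
    p_unc[is.na(p_unc)] <- 0
    uncorrected <- runif(m) < p_unc
    theta <- ifelse(uncorrected,
                    runif(m, noise$theta_min_deg, noise$theta_max_deg), 0)
  })
  fac <- gain * ifelse(uncorrected, cos(theta * pi / 180), 1)
  out <- true_sites
  out$psv_cms <- out$psv_cms * fac
  out$edv_cms <- out$edv_cms * fac
  out$mfv_cms <- out$mfv_cms * fac
  out$angle_corrected <- !uncorrected
  out$insonation_angle_deg <- ifelse(uncorrected, theta, NA_real_)
  out
}

#' Run a virtual validation study
#'
#' End-to-end harness mirroring a clinical validation design on synthetic
#' patients: generate a cohort, simulate each patient's intracranial
#' velocities from their anatomy and inlet/pressure boundary conditions
#' (these are the "simulation" values), pass the same true values through
#' the TCCD measurement model (the "measured" values), and collect the
#' paired per-artery tables. Per-patient solver failures are logged and the
#' patient excluded, with the count reported.
#'
#' @param n Number of patients.
#' @param seed Integer seed controlling cohort, anatomy and noise.
#' @param params A [cohort_params()].
#' @param noise A [tccd_noise_params()].
#' @param fluid A [casson_fluid()].
#' @return A `cow_virtual_study`: `$pairs` (long paired table with
#'   `patient_id`, `artery`, `side`, `phase`, `sim_cms`, `meas_cms`),
#'   `$cohort`, `$sites`, `$n_failed`.
#' @export
#' @examples
#' \donttest{
#' study <- run_virtual_study(10, seed = 7)
#' report <- build_report(study$pairs)
#' }
run_virtual_study <- function(n, seed = 1, params = cohort_params(),
                              noise = tccd_noise_params(),
                              fluid = casson_fluid()) {
  cohort <- generate_cohort(n, seed, params)
  failures <- character(0)
  all_sites <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    patient <- cohort[i, ]
    sim <- tryCatch({
      net <- patient_network(patient, params)
      simulate_patient(net, fluid, patient_bc(patient))
    }, error = function(e) e)
    if (inherits(sim, "error")) {
      failures <- c(failures, patient$patient_id)
      next
    }
    s <- sim$sites
    s$patient_id <- patient$patient_id
    all_sites[[i]] <- s
  }
  sites <- dplyr::bind_rows(all_sites)
  if (nrow(sites) == 0) {
    abort("Every patient solve failed.", class = "cowflow_nonconvergence")
  }
  meas <- synthesize_tccd(sites, noise, seed = as.integer(seed) + 1L)
  pairs <- pair_tables(sites, meas)
  structure(list(pairs = pairs, cohort = cohort, sites = sites,
                 measured = meas, n_failed = length(failures),
                 failed_ids = failures, seed = seed),
            class = "cow_virtual_study")
}

# reshape true/measured wide site tables into the long paired format
pair_tables <- function(sites, measured) {
  long <- function(d, label) {
    d |>
      dplyr::select("patient_id", "artery", "side", "psv_cms", "edv_cms",
                    "mfv_cms") |>
      tidyr::pivot_longer(cols = c("psv_cms", "edv_cms", "mfv_cms"),
                          names_to = "phase", values_to = label) |>
      dplyr::mutate(phase = toupper(sub("_cms$", "", .data$phase)))
  }
  dplyr::left_join(long(sites, "sim_cms"), long(measured, "meas_cms"),
                   by = c("patient_id", "artery", "side", "phase"))
}

#' @export
print.cow_virtual_study <- function(x, ...) {
  cat(sprintf("<cow_virtual_study> %d patients (%d failed), %d paired rows\n",
              nrow(x$cohort), x$n_failed, nrow(x$pairs)))
  invisible(x)
}
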