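test_that("ICC matches the ANOVA oracle on a hand table and at random", {
  sim <- c(10, 20, 30, 40, 50, 61)
  meas <- c(11, 19, 33, 38, 52, 60)
  d <- tibble::tibble(sim_cms = sim, meas_cms = meas)
  ic <- icc_absolute_agreement(d)
  # frozen reference values (two-way absolute-agreement, single measures)
  expect_equal(ic$icc, 0.995312646479798, tolerance = 1e-12)
  expect_equal(ic$p_value, 2.08357365135504e-06, tolerance = 1e-10)
  expect_equal(round(c(ic$ci_low, ic$ci_high), 2), c(0.97, 1.00))
  # equals the aov mean-squares decomposition to 1e-10
  expect_equal(ic$icc, oracle_icc_anova(sim, meas), tolerance = 1e-10)
  # property: random small tables, n in [3, 30]
  withr::with_seed(11, {
    for (k in 1:25) {
      n <- sample(3:30, 1)
      x <- rnorm(n, 50, 15)
      y <- x + rnorm(n, 0, sample(c(1, 5, 15), 1))
      got <- icc_absolute_agreement(tibble::tibble(sim_cms = x,
                                                   meas_cms = y))
      expect_equal(got$icc, oracle_icc_anova(x, y), tolerance = 1e-10)
      expect_true(got$ci_low <= got$icc && got$icc <= got$ci_high)
    }
  })
})

test_that("ICC handles identity and degenerate input", {
  d <- tibble::tibble(sim_cms = c(1, 2, 3, 4), meas_cms = c(1, 2, 3, 4))
  expect_equal(icc_absolute_agreement(d)$icc, 1)
  flat <- tibble::tibble(sim_cms = rep(5, 4), meas_cms = rep(5, 4))
  expect_error(icc_absolute_agreement(flat),
               class = "cowflow_degenerate_input")
  expect_error(icc_absolute_agreement(d[1:2, ]),
               class = "cowflow_invalid_input")
})

test_that("ICC labels follow the conventional thresholds", {
  expect_identical(icc_interpret(0.695), "moderate")
  expect_identical(icc_interpret(0.755), "good")
  expect_identical(icc_interpret(0.876), "good")
  expect_identical(icc_interpret(0.95), "excellent")
  expect_identical(icc_interpret(c(-0.2, 0.49, 0.5, 0.749, 0.75, 0.9)),
                   c("poor", "poor", "moderate", "moderate", "good",
                     "excellent"))
  expect_error(icc_interpret(1.2), class = "cowflow_invalid_input")
})

test_that("Pearson correlation matches its closed form", {
  x <- c(3.1, 4.5, 5.0, 6.2, 7.8, 8.1, 9.9, 11.0)
  y <- c(2.9, 5.1, 4.6, 6.8, 7.2, 8.9, 9.4, 12.1)
  got <- pearson_agreement(tibble::tibble(sim_cms = x, meas_cms = y))
  # covariance-formula oracle
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  expect_equal(got$r, 0.975638001962752, tolerance = 1e-12)
  expect_equal(got$p_value, 3.54902861669424e-05, tolerance = 1e-8)
  d <- tibble::tibble(sim_cms = 1:5, meas_cms = c(5, 4, 3, 2, 1))
  expect_equal(pearson_agreement(d)$r, -1)
  expect_equal(pearson_agreement(tibble::tibble(sim_cms = 1:5,
                                                meas_cms = 1:5))$r, 1)
  expect_error(pearson_agreement(tibble::tibble(sim_cms = rep(1, 5),
                                                meas_cms = 1:5)),
               class = "cowflow_degenerate_input")
})

test_that("difference rows use measured-minus-simulated over the simulation mean", {
  # worked rows from the published reference table
  expect_equal(round_report(unlist(difference_row(57.8, 50.2)), 1),
               c(mean_diff_cms = -7.6, pct_diff = -13.1))
  expect_equal(round_report(unlist(difference_row(98.6, 96.8)), 1),
               c(mean_diff_cms = -1.8, pct_diff = -1.8))
  expect_equal(round_report(unlist(difference_row(51.4, 42.2)), 1),
               c(mean_diff_cms = -9.2, pct_diff = -17.9))
  expect_identical(unlist(difference_row(40, 40)),
                   c(mean_diff_cms = 0, pct_diff = 0))
  # the alternative convention (TCCD denominator) fails the same rows,
  # which is what pins the convention down
  expect_false(round_report(100 * (50.2 - 57.8) / 50.2, 1) == -13.1)
  expect_error(difference_row(0, 10), class = "cowflow_invalid_input")
})

test_that("overall differences are unweighted means over arteries", {
  ref <- reference_agreement_table()
  psv <- overall_difference(ref[ref$phase == "PSV", ])
  expect_equal(round_report(psv$mean_diff_cms, 1), -2.6)
  expect_equal(round_report(psv$pct_diff, 1), -4.5)
  one <- overall_difference(difference_row(50, 47))
  expect_equal(one$mean_diff_cms, -3)
  expect_error(overall_difference(difference_row(50, 47)[0, ]),
               class = "cowflow_invalid_input")
})

test_that("Bland-Altman gates between parametric and percentile limits", {
  # identical pairs: degenerate zero interval
  same <- tibble::tibble(sim_cms = c(1, 2, 3, 4, 5) * 10,
                         meas_cms = c(1, 2, 3, 4, 5) * 10)
  ba0 <- suppressWarnings(bland_altman(same))
  expect_equal(c(ba0$center, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  # normal differences: parametric branch, limits near +/- 1.96 sd
  withr::with_seed(2, {
    x <- rnorm(200, 50, 10)
    dlt <- rnorm(200, 0, 1)
  })
  ban <- bland_altman(tibble::tibble(sim_cms = x, meas_cms = x + dlt))
  expect_identical(ban$method, "parametric")
  expect_equal(ban$loa_high - ban$center, 1.96, tolerance = 0.1)
  expect_equal(ban$center - ban$loa_low, 1.96, tolerance = 0.1)
  # skewed differences: percentile branch, exact order-statistic limits
  withr::with_seed(3, dsk <- rlnorm(40, 0, 0.9) - 1)
  bas <- bland_altman(tibble::tibble(sim_cms = rep(50, 40),
                                     meas_cms = 50 + dsk))
  expect_identical(bas$method, "percentile")
  expect_equal(bas$center, median(dsk))
  # sort-and-interpolate oracle for the 2.5th/97.5th percentiles
  srt <- sort(dsk)
  h <- function(p) {
    hh <- (40 - 1) * p + 1
    lo <- floor(hh)
    srt[lo] + (hh - lo) * (srt[min(lo + 1, 40)] - srt[lo])
  }
  expect_equal(bas$loa_low, h(0.025), tolerance = 1e-12)
  expect_equal(bas$loa_high, h(0.975), tolerance = 1e-12)
  expect_true(bas$loa_low <= bas$center && bas$center <= bas$loa_high)
  # percentile limits contain at least 95 % of a large sample
  withr::with_seed(4, dbig <- rexp(500) - 0.3)
  bab <- bland_altman(tibble::tibble(sim_cms = rep(10, 500),
                                     meas_cms = 10 + dbig))
  inside <- mean(dbig >= bab$loa_low & dbig <= bab$loa_high)
  expect_gte(inside, 0.945)   # 95 % up to order-statistic discreteness
  expect_error(bland_altman(same[1:2, ]), class = "cowflow_invalid_input")
})

test_that("the report covers all sites with coherent overalls and schema", {
  withr::with_seed(8, {
    sites <- cowflow:::measurement_sites()
    pairs <- tidyr::expand_grid(patient_id = sprintf("P%02d", 1:20),
                                sites[, c("artery", "side")],
                                phase = c("PSV", "EDV", "MFV"))
    pairs$sim_cms <- runif(nrow(pairs), 20, 100)
    pairs$meas_cms <- pairs$sim_cms * rnorm(nrow(pairs), 1, 0.1)
  })
  rep <- build_report(pairs)
  expect_identical(nrow(rep$table), 27L)
  expect_identical(sort(unique(rep$table$site)),
                   sort(c("MCA left", "MCA right", "ACA left", "ACA right",
                          "PCA left", "PCA right", "BA", "V4 left",
                          "V4 right")))
  expect_named(rep$table,
               c("phase", "site", "n", "icc", "icc_ci_low", "icc_ci_high",
                 "icc_p", "icc_label", "pearson_r", "pearson_p", "mean_sim",
                 "sd_sim", "mean_meas", "sd_meas", "mean_diff_cms",
                 "pct_diff"))
  # overall rows equal the unweighted mean of their site rows
  for (ph in c("PSV", "EDV", "MFV")) {
    o <- rep$overall[rep$overall$phase == ph, ]
    expect_equal(o$mean_diff_cms,
                 mean(rep$table$mean_diff_cms[rep$table$phase == ph]))
  }
  grand <- rep$overall[rep$overall$phase == "ALL", ]
  expect_equal(grand$mean_diff_cms,
               mean(rep$overall$mean_diff_cms[rep$overall$phase != "ALL"]))
  # pct_diff consistent with the means in every row
  expect_equal(rep$table$pct_diff,
               100 * rep$table$mean_diff_cms / rep$table$mean_sim)
  # a missing site is a structural error naming it
  broken <- pairs[!(pairs$artery == "BA" & pairs$phase == "EDV"), ]
  expect_error(build_report(broken), regexp = "BA",
               class = "cowflow_schema_error")
  expect_error(build_report(pairs[, -1]), class = "cowflow_schema_error")
})

test_that("side averaging pools left and right per patient", {
  pairs <- tibble::tibble(
    patient_id = rep(c("A", "B"), each = 2),
    artery = "MCA", side = rep(c("left", "right"), 2), phase = "PSV",
    sim_cms = c(80, 100, 60, 70), meas_cms = c(82, 98, 58, 74))
  avg <- side_averaged_pairs(pairs, "MCA", "PSV")
  expect_equal(avg$sim_cms, c(90, 65))
  expect_equal(avg$meas_cms, c(90, 66))
})
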