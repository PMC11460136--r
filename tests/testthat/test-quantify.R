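# Standard curves, the two-step weight math, presence calls and the
# sample-level quantification workflow.

test_that("standard-curve fit recovers exact lines and applies the R^2 gate", {
  exact <- fit_standard_curve(data.frame(proportion = c(0, 0.5, 1),
                                         frequency = c(0, 0.5, 1)))
  expect_equal(exact$slope, 1)
  expect_equal(exact$intercept, 0)
  expect_equal(exact$r_squared, 1)
  expect_true(exact$passes_linearity)

  # 7-level noise-free identity series: slope 1 within 1e-12
  lv7 <- c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1)
  c7 <- fit_standard_curve(data.frame(proportion = lv7, frequency = lv7))
  expect_equal(c7$slope, 1, tolerance = 1e-12)
  expect_equal(c7$r_squared, 1, tolerance = 1e-12)

  noisy <- fit_standard_curve(data.frame(proportion = c(0, 0.5, 1, 0.2),
                                         frequency = c(0.3, 0.2, 0.9, 0.6)))
  expect_false(noisy$passes_linearity)

  expect_error(fit_standard_curve(data.frame(proportion = c(0, 1),
                                             frequency = c(0, 1))),
               class = "herbq_input_error")
  # a single repeated proportion collapses to one averaged point
  expect_error(fit_standard_curve(data.frame(proportion = rep(0.5, 4),
                                             frequency = 1:4 / 4)),
               class = "herbq_input_error")

  # replicates are averaged before fitting
  rep_pts <- data.frame(proportion = rep(c(0, 0.5, 1), each = 2),
                        frequency = c(0.1, -0.1, 0.4, 0.6, 0.9, 1.1))
  expect_equal(fit_standard_curve(rep_pts)$r_squared, 1)
})

test_that("a simulated 10-level series recovers the generating response", {
  base <- mixture_spec(c("FCB sp" = 0.2), noise_sd = 0.003,
                       distortion = c(0.994, 0.002), seed = 41L)
  asite <- diagnostic_site("ITS", 341L, "species_diagnostic",
                           "Adulterant sp", "C", "T", 4L)
  lv <- c(0.01, 0.02, 0.04, 0.06, 0.08, 0.1, 0.2, 0.3, 0.4, 0.5)
  tab <- simulate_dilution_series(base, "Adulterant sp", lv, 3L, asite)
  adult <- tab[tab$allele == "C", ]
  curve <- fit_standard_curve(data.frame(proportion = adult$level,
                                         frequency = adult$frequency))
  expect_gt(curve$slope, 0.98)
  expect_lt(curve$slope, 1.01)
  expect_gte(curve$r_squared, 0.99)
  expect_true(curve$passes_linearity)
  # inversion maps a measured frequency back near the true proportion
  expect_equal(invert_curve(curve, curve$slope * 0.3 + curve$intercept), 0.3)
})

test_that("total weight is the spiked mass over the standard's frequency", {
  expect_equal(total_weight(0.1001, 0.50), 0.2002)
  expect_equal(total_weight(0.37, 1), 0.37)
  expect_error(total_weight(0.1, 0), class = "herbq_unquantifiable_error")
  expect_error(total_weight(0.1, -0.2), class = "herbq_unquantifiable_error")
  expect_error(total_weight(0.1, 1.2), class = "herbq_input_error")
  expect_error(total_weight(0, 0.5), class = "herbq_input_error")
})

test_that("component weight scales the total by the component frequency", {
  expect_equal(round(component_weight(0.2002, 0.33), 4), 0.0661)
  expect_equal(round(component_weight(0.2002, 0.20), 4), 0.0400)
  expect_equal(round(component_weight(0.2003, 0.34), 4), 0.0681)
  expect_equal(component_weight(0.5, 0), 0)
  expect_error(component_weight(0.5, 1.1), class = "herbq_input_error")
  expect_error(component_weight(0.5, -0.1), class = "herbq_input_error")
  expect_error(component_weight(0, 0.5), class = "herbq_input_error")
})

test_that("bias is relative percent deviation with a 25% pass flag", {
  expect_equal(as.numeric(compute_bias(0.5, 0.5)), 0)
  b <- compute_bias(1.1, 1.0)
  expect_equal(as.numeric(b), 10)
  expect_true(attr(b, "pass"))
  b2 <- compute_bias(c(1.3, 0.7), c(1, 1))
  expect_equal(as.numeric(b2), c(30, 30))
  expect_equal(attr(b2, "pass"), c(FALSE, FALSE))
  expect_error(compute_bias(1, 0), class = "herbq_input_error")
})

test_that("presence calls honour the threshold and complement missing alleles", {
  fix <- fcb_fixture()
  s341 <- fix$panel$sites[["ITS:341"]]

  pure <- call_presence(meas_rows("ITS", 341, "T", c(1, 1, 1)), s341)
  expect_equal(pure$call, "pure_target")

  mixed <- call_presence(
    rbind(meas_rows("ITS", 341, "T", c(0.66, 0.66)),
          meas_rows("ITS", 341, "C", c(0.34, 0.34))), s341)
  expect_equal(mixed$call, "mixed")
  expect_equal(unname(mixed$frequencies), c(0.66, 0.34))

  # background below threshold is called pure target
  low <- call_presence(meas_rows("ITS", 341, "C", 0.015), s341,
                       threshold = 0.02)
  expect_equal(low$call, "pure_target")
  expect_equal(unname(low$frequencies[["target"]]), 0.985)

  expect_error(call_presence(meas_rows("ITS", 999, "T", 1), s341),
               class = "herbq_missing_data_error")
  expect_error(call_presence(meas_rows("ITS", 341, "T", 1), s341,
                             threshold = 0.6),
               class = "herbq_input_error")
})

test_that("composition logic: pure target, typed adulterants, fail-safe unresolved", {
  fix <- fcb_fixture()
  panel <- fix$panel
  mk_calls <- function(freqs341_T, thunbergii_C = NULL, ussur_G = NULL) {
    m <- meas_rows("ITS", 341, "T", freqs341_T)
    if (!is.null(thunbergii_C)) {
      m <- rbind(m, meas_rows("ITS", 361, "C", thunbergii_C))
    }
    if (!is.null(ussur_G)) m <- rbind(m, meas_rows("ITS", 366, "G", ussur_G))
    calls <- list()
    for (id in names(panel$sites)) {
      calls[[id]] <- tryCatch(call_presence(m, panel$sites[[id]]),
                              herbq_missing_data_error = function(e) NULL)
    }
    calls
  }

  pure <- identify_composition(mk_calls(1), panel)
  expect_equal(pure$species, "FCB")
  expect_false(pure$unresolved)

  typed <- identify_composition(mk_calls(0.66, thunbergii_C = 0.34), panel)
  expect_setequal(typed$species, c("FCB", "Fritillaria thunbergii"))
  expect_false(typed$unresolved)

  untyped <- identify_composition(mk_calls(0.66, thunbergii_C = 0.005,
                                           ussur_G = 0.004), panel)
  expect_true(untyped$unresolved)
  expect_equal(untyped$species, "FCB")

  expect_error(identify_composition(list(), panel),
               class = "herbq_missing_data_error")
})

test_that("the external standard must be absent from the sample", {
  expect_equal(
    select_external_standard(c("FCB", "Fritillaria ussuriensis"),
                             c("Fritillaria hupehensis",
                               "Fritillaria thunbergii")),
    "Fritillaria hupehensis")
  expect_equal(
    select_external_standard("FCB",
                             c("Fritillaria thunbergii",
                               "Fritillaria hupehensis")),
    "Fritillaria thunbergii")
  expect_error(select_external_standard(c("FCB", "X"), c("X", "FCB")),
               class = "herbq_no_standard_error")
  expect_error(select_external_standard("FCB", character(0)),
               class = "herbq_input_error")
})

sdcb_measurements <- function(reps = 3L) {
  rbind(meas_rows("ITS", 361, "C", rep(0.50, reps)),
        meas_rows("ITS", 361, "T", rep(0.50, reps)),
        meas_rows("ITS", 341, "T", rep(0.33, reps)),
        meas_rows("ITS", 341, "C", rep(0.67, reps)),
        meas_rows("ITS", 366, "G", rep(0.20, reps)),
        meas_rows("ITS", 366, "A", rep(0.80, reps)))
}

test_that("the capsule scenario deconvolves into the expected weights", {
  fix <- fcb_fixture()
  smp <- quant_sample("sdcb", "Fritillaria thunbergii", 0.1001,
                      sdcb_measurements(),
                      actual_weights = c(FCB = 0.0666))
  res <- quantify_sample(smp, fix$panel)
  expect_equal(res$w_total, 0.2002)
  expect_equal(round(unname(res$component_weights["FCB"]), 4), 0.0661)
  expect_equal(round(unname(
    res$component_weights["Fritillaria ussuriensis"]), 4), 0.0400)
  expect_equal(unname(res$component_weights["Fritillaria thunbergii"]),
               0.1001)
  expect_setequal(res$composition$species,
                  c("FCB", "Fritillaria thunbergii",
                    "Fritillaria ussuriensis"))
  expect_named(res$biases, "FCB")
  expect_true(attr(res$biases, "pass"))

  report <- write_quant_result(res)
  expect_equal(report$weight_g[report$component == "FCB"], 0.0661)
  expect_equal(report$frequency_pct[report$component == "FCB"], 33)
})

test_that("quantification refuses unresolved samples and r_ext = 0", {
  fix <- fcb_fixture()
  m_untyped <- rbind(meas_rows("ITS", 341, "T", 0.66),
                     meas_rows("ITS", 341, "C", 0.34))
  smp <- quant_sample("s", "Fritillaria thunbergii", 0.1, m_untyped)
  expect_error(quantify_sample(smp, fix$panel),
               class = "herbq_unresolved_error")

  m_zero <- rbind(meas_rows("ITS", 341, "T", 1),
                  meas_rows("ITS", 361, "C", 0))
  smp0 <- quant_sample("s", "Fritillaria thunbergii", 0.1, m_zero)
  expect_error(quantify_sample(smp0, fix$panel),
               class = "herbq_unquantifiable_error")
})

test_that("inconsistent frequency sums trigger the consistency warning", {
  fix <- fcb_fixture()
  m <- rbind(meas_rows("ITS", 341, "T", 0.30),
             meas_rows("ITS", 341, "C", 0.70),
             meas_rows("ITS", 361, "C", 0.40),
             meas_rows("ITS", 361, "T", 0.60))
  smp <- quant_sample("s", "Fritillaria thunbergii", 0.1, m)
  expect_warning(quantify_sample(smp, fix$panel),
                 class = "herbq_consistency_warning")
})

test_that("curve inversion is applied when a standard curve is supplied", {
  fix <- fcb_fixture()
  curve <- fit_standard_curve(
    data.frame(proportion = c(0, 0.5, 1),
               frequency = 0.994 * c(0, 0.5, 1) + 0.002))
  m <- rbind(meas_rows("ITS", 341, "T", 0.994 * 0.33 + 0.002),
             meas_rows("ITS", 361, "C", 0.994 * 0.50 + 0.002),
             meas_rows("ITS", 366, "G", 0.994 * 0.17 + 0.002))
  smp <- quant_sample("s", "Fritillaria thunbergii", 0.1001, m)
  res <- quantify_sample(smp, fix$panel, curve = curve)
  expect_equal(res$w_total, 0.1001 / 0.5, tolerance = 1e-10)
  expect_equal(unname(res$component_weights["FCB"]), 0.2002 * 0.33,
               tolerance = 1e-10)
})

test_that("noise-free simulator round trip recovers every component mass", {
  fix <- fcb_fixture()
  truth <- c("Fritillaria cirrhosa" = 0.066,
             "Fritillaria ussuriensis" = 0.040,
             "Fritillaria thunbergii" = 0.100)
  mix <- mixture_spec(truth, impurity_mass = 0.02, noise_sd = 0, seed = 2L)
  meas <- simulate_measurements(mix, fix$panel, 3L, sample_id = "rt")
  smp <- quant_sample("rt", "Fritillaria thunbergii", 0.100, meas)
  res <- quantify_sample(smp, fix$panel)
  expect_equal(res$w_total, sum(truth), tolerance = 1e-12)
  expect_equal(unname(res$component_weights["FCB"]),
               unname(truth["Fritillaria cirrhosa"]), tolerance = 1e-12)
  expect_equal(unname(res$component_weights["Fritillaria ussuriensis"]),
               unname(truth["Fritillaria ussuriensis"]), tolerance = 1e-12)
})
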