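test_that("per-arm monthly rates reproduce the published table", {
  rates <- add_monthly_rates(catheter_trials())
  disp <- cathcea:::round_display(rates$monthly_rate, 2)
  pick <- function(study, type) {
    disp[rates$study_id == study & rates$catheter_type == type]
  }
  expect_equal(pick("sarica_2010", "pvc"), 2.67)      # 4.00 over 1.5 months
  expect_equal(pick("cardenas_2009", "pvc"), 0.14)    # 1.65 over 12 months
  expect_equal(pick("sarica_2010", "hydrophilic"), 0.67)
  expect_equal(pick("cardenas_2009", "hydrophilic"), 0.06)
  expect_equal(pick("cardenas_2011", "pvc"), 0.48)
  expect_equal(pick("de_ridder_2005", "pvc"), 0.38)
  # unrounded values retained internally
  expect_equal(rates$monthly_rate[rates$study_id == "cardenas_2009" &
                                    rates$catheter_type == "pvc"],
               1.65 / 12)
})

test_that("monthly_rate prefers the direct rate and flags missing data", {
  expect_equal(monthly_rate(0.48, NA, 4.5), 0.48)
  expect_equal(monthly_rate(NA, 4.00, 1.5), 4 / 1.5)
  expect_equal(monthly_rate(NA, 0, 7), 0)
  expect_error(monthly_rate(NA, NA, 12), "available")
})

test_that("study relative risks match the published column", {
  ev <- pool_evidence(catheter_trials())
  per <- tidy(ev)
  rr <- setNames(per$rr_display, per$study_id)
  expect_equal(rr[["cardenas_2011"]], 1.00)
  expect_equal(rr[["sarica_2010"]], 0.25)
  expect_equal(rr[["cardenas_2009"]], 0.47)
  expect_equal(rr[["de_ridder_2005"]], 0.89)
  expect_equal(per$rr[per$study_id == "sarica_2010"], (1 / 1.5) / (4 / 1.5))
  expect_error(study_rr(0.3, 0), "undefined")
  expect_equal(study_rr(0.4, 0.4), 1)
})

test_that("pooling reproduces the published pooled RR and PVC rate", {
  ev <- pool_evidence(catheter_trials())
  expect_equal(cathcea:::round_display(ev$pooled_rr, 2), 0.84)
  expect_equal(cathcea:::round_display(100 * ev$pooled_pvc_rate, 2), 62.48)

  # brute-force loop oracle over the arm table
  trials <- add_monthly_rates(catheter_trials())
  num_rr <- 0; den_rr <- 0; num_rate <- 0; den_rate <- 0
  for (sid in unique(trials$study_id)) {
    pvc <- trials[trials$study_id == sid & trials$catheter_type == "pvc", ]
    hyd <- trials[trials$study_id == sid &
                    trials$catheter_type == "hydrophilic", ]
    rr_i <- cathcea:::round_display(hyd$monthly_rate / pvc$monthly_rate, 2)
    num_rr <- num_rr + rr_i * hyd$n_patients
    den_rr <- den_rr + hyd$n_patients
    num_rate <- num_rate + pvc$monthly_rate * pvc$n_patients
    den_rate <- den_rate + pvc$n_patients
  }
  expect_equal(ev$pooled_rr, num_rr / den_rr, tolerance = 1e-12)
  expect_equal(ev$pooled_pvc_rate, num_rate / den_rate, tolerance = 1e-12)

  # unrounded pooling agrees at display precision
  exact <- pool_evidence(catheter_trials(), rr_mode = "exact")
  expect_equal(cathcea:::round_display(exact$pooled_rr, 2), 0.84)
  expect_false(identical(exact$pooled_rr, ev$pooled_rr))
})

test_that("pooled values are convex combinations of the per-study values", {
  ev <- pool_evidence(catheter_trials())
  per <- tidy(ev)
  expect_gte(ev$pooled_rr, min(per$rr_display))
  expect_lte(ev$pooled_rr, max(per$rr_display))
  expect_gte(ev$pooled_pvc_rate, min(per$rate_pvc))
  expect_lte(ev$pooled_pvc_rate, max(per$rate_pvc))
  expect_equal(sum(ev$weights), sum(per$n_hydro))
})

test_that("a single study pools to its own values", {
  one <- catheter_trials()[catheter_trials()$study_id == "sarica_2010", ]
  ev <- pool_evidence(one)
  expect_equal(ev$pooled_rr, 0.25)
  expect_equal(ev$pooled_pvc_rate, 4 / 1.5)
})

test_that("pooling validates its input", {
  trials <- catheter_trials()
  expect_error(pool_evidence(trials[0, ]), "pool")
  expect_error(pool_evidence(trials[trials$catheter_type == "pvc", ]),
               "both")
  bad <- trials
  bad$utis_per_month[1] <- NA
  bad$uti_incidence[1] <- NA
  expect_error(pool_evidence(bad), "neither")
})

test_that("pooled rate estimated from simulated counts is consistent", {
  build <- function(n, seed) {
    pvc <- simulate_trial(0.62, n, 6, seed = seed, arm_label = "pvc")
    hyd <- simulate_trial(0.52, n, 6, seed = seed + 1,
                          arm_label = "hydrophilic")
    tibble::tibble(
      study_id = "sim",
      catheter_type = c("pvc", "hydrophilic"),
      n_patients = as.integer(n),
      uti_incidence = NA_real_,
      followup_months = 6,
      utis_per_month = c(estimate_rate(pvc), estimate_rate(hyd))
    )
  }
  mean_err <- vapply(c(50, 5000), function(n) {
    mean(vapply(1:5, function(s) {
      ev <- pool_evidence(build(n, seed = 400 + 10 * s), rr_mode = "exact")
      abs(ev$pooled_pvc_rate - 0.62)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean_err[2], mean_err[1])
  expect_lt(mean_err[2], 3 * sqrt(0.62 / (5000 * 6)))
})
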