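test_that("UTI branch probabilities expand the resistance cascade", {
  b <- uti_branch_probs(0.6248, 0.34, 0.034)
  # independent product expansion
  expect_equal(unname(b),
               c(1 - 0.6248,
                 0.6248 * 0.66,
                 0.6248 * 0.34 * 0.966,
                 0.6248 * 0.34 * 0.034),
               tolerance = 1e-12)
  expect_equal(round(unname(b), 6), c(0.3752, 0.412368, 0.205209, 0.007223))
  expect_equal(sum(b), 1)

  expect_equal(unname(uti_branch_probs(0, 0.3, 0.1)), c(1, 0, 0, 0))
  expect_equal(unname(uti_branch_probs(0.4, 0, 0.1)), c(0.6, 0.4, 0, 0))
  expect_error(uti_branch_probs(1.2, 0.3, 0.1), "probability")

  # property: components sum to 1 over a parameter sweep
  set.seed(42)
  for (i in 1:50) {
    p <- runif(3)
    expect_equal(sum(uti_branch_probs(p[1], p[2], p[3])), 1,
                 tolerance = 1e-12)
  }
})

test_that("treatment effects scale probabilities with a capped product", {
  expect_equal(apply_treatment_effect(0.6248, 0.84), 0.524832)
  expect_equal(apply_treatment_effect(0.37, 1), 0.37)
  expect_equal(apply_treatment_effect(0.0032, 0.90), 0.00288)
  expect_equal(apply_treatment_effect(0.9, 2), 1) # capped
  expect_error(apply_treatment_effect(-0.1, 0.9), "probability")
  expect_error(apply_treatment_effect(0.5, -1), ">= 0")
})

test_that("mortality multipliers act on the hazard scale", {
  expect_equal(adjusted_death_prob(0.37, 0), 0.37)
  expect_equal(adjusted_death_prob(0, 100), 0)
  expect_equal(adjusted_death_prob(1, 5), 1)
  # closed-form oracle
  expect_equal(adjusted_death_prob(2e-4, 145.27),
               1 - exp(-(-log(1 - 2e-4)) * 146.27), tolerance = 1e-15)
  expect_equal(adjusted_death_prob(2e-4, 145.27), 0.028833085417,
               tolerance = 1e-9)
  expect_error(adjusted_death_prob(0.5, -1), ">= 0")
  # q' always in [q, 1]
  q <- seq(0, 1, by = 0.1)
  q2 <- adjusted_death_prob(q, 3)
  expect_true(all(q2 >= q & q2 <= 1))
})

test_that("the weighted UTI multiplier is the resistant share product", {
  expect_equal(weighted_uti_multiplier(145.27, 0.34), 145.27 * 0.34)
  expect_equal(cathcea:::round_display(weighted_uti_multiplier(145.27, 0.34), 2),
               49.39)
  expect_equal(weighted_uti_multiplier(7, 0), 0)
  expect_equal(weighted_uti_multiplier(100, 0.5), 50)
})

test_that("the transition matrix is row-stochastic and renal-monotone", {
  params <- model_parameters()
  for (arm in c("pvc", "hydrophilic")) {
    M <- build_transition_matrix(params, arm, 0.001)
    expect_equal(unname(rowSums(M)), rep(1, 13), tolerance = 1e-12)
    expect_true(all(M >= 0))
    # dead is absorbing
    expect_equal(unname(M[13, ]), c(rep(0, 12), 1))
    # no transition to a lower renal stage
    states <- health_states()
    for (s in 1:12) {
      lower <- which(states$alive &
                       match(states$renal_stage, cathcea:::RENAL_LEVELS) <
                         match(states$renal_stage[s], cathcea:::RENAL_LEVELS))
      expect_true(all(M[s, lower] == 0))
    }
  }
})

test_that("the transition matrix matches a brute-force branching oracle", {
  params <- model_parameters()
  q <- 0.002
  M <- build_transition_matrix(params, "hydrophilic", q)

  # independent enumeration: death branch, then renal branch, then UTI draw
  p_uti <- 0.6248 * 0.84
  u <- c(1 - p_uti, p_uti * (1 - 0.34), p_uti * 0.34 * (1 - 0.034),
         p_uti * 0.34 * 0.034)
  m_uti <- c(0, 49.3918, 49.3918, 49.3918) # weighted mode, no-UTI exempt
  m_renal <- c(0, 18, 54)
  m_sepsis <- (0.0032 * 0.9) * 797.6
  renal_next <- list(c(1 - 4e-4, 4e-4, 0), c(0, 1 - 29e-4, 29e-4), c(0, 0, 1))
  oracle <- matrix(0, 13, 13)
  for (r in 1:3) for (ul in 1:4) {
    s <- (r - 1) * 4 + ul
    h <- -log(1 - q)
    qd <- 1 - exp(-h * (1 + m_renal[r] + m_uti[ul] + m_sepsis))
    oracle[s, 13] <- qd
    for (r2 in 1:3) for (u2 in 1:4) {
      oracle[s, (r2 - 1) * 4 + u2] <- (1 - qd) * renal_next[[r]][r2] * u[u2]
    }
  }
  oracle[13, 13] <- 1
  expect_equal(unname(M), oracle, tolerance = 1e-12)
})

test_that("degenerate parameterisations collapse the matrix as expected", {
  p0 <- zero_disease_params()
  M <- build_transition_matrix(p0, "pvc", 0.01)
  # survival mass stays in the current renal stage with no UTI
  for (s in 1:12) {
    stay <- (cathcea:::renal_of(s) - 1) * 4 + 1
    expect_equal(unname(M[s, stay]), 0.99)
    expect_equal(unname(M[s, 13]), 0.01)
  }
  # no renal progression => block-diagonal in renal stage
  p_nr <- model_parameters(p_renal_progression = 0, p_renal_failure = 0)
  M2 <- build_transition_matrix(p_nr, "pvc", 0.001)
  for (s in 1:12) {
    other <- which(cathcea:::renal_of(1:12) != cathcea:::renal_of(s))
    expect_true(all(M2[s, other] == 0))
  }
})

test_that("a cohort facing certain death dies in one cycle", {
  lt <- flat_life_table(1, 30, 40)
  params <- model_parameters(entry_age = 30)
  tr <- run_cohort(params, "pvc", lt)
  expect_equal(tr$cycles, 1)
  expect_equal(unname(tr$occupancy[2, "dead"]), 1)
})

test_that("with disease off the trace reproduces background survival", {
  lt <- synthetic_life_table("male")
  tr <- run_cohort(zero_disease_params(), "pvc", lt)
  alive <- rowSums(tr$occupancy[, 1:12, drop = FALSE])
  # survival-product oracle at monthly resolution
  ages <- 36 + (seq_len(tr$cycles) - 1) %/% 12
  q_m <- annual_to_monthly_prob(lt$q_annual[match(ages, lt$age)])
  expect_equal(alive[-1], cumprod(1 - q_m), tolerance = 1e-12)
})

test_that("cohort traces conserve mass and are monotone where required", {
  lt <- synthetic_life_table("male")
  for (arm in c("pvc", "hydrophilic")) {
    tr <- run_cohort(model_parameters(), arm, lt)
    expect_equal(rowSums(tr$occupancy), rep(1, tr$cycles + 1),
                 tolerance = 1e-9)
    expect_true(all(tr$occupancy >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-12))
    # progressed-or-dead mass never decreases
    sick <- rowSums(tr$occupancy[, c(5:13), drop = FALSE])
    expect_true(all(diff(sick) >= -1e-12))
    # overlay event counts bounded by the at-risk mass
    alive_start <- rowSums(tr$occupancy[-nrow(tr$occupancy), 1:12,
                                        drop = FALSE])
    expect_true(all(tr$events <= alive_start + 1e-12))
  }
})

test_that("a protective UTI treatment effect reduces lifetime UTIs", {
  lt <- synthetic_life_table("male")
  tr_pvc <- run_cohort(model_parameters(), "pvc", lt)
  tr_hyd <- run_cohort(model_parameters(), "hydrophilic", lt)
  expect_lt(sum(tr_hyd$events[, "uti"]), sum(tr_pvc$events[, "uti"]))
})

test_that("cohort entry is validated against the life table", {
  lt <- flat_life_table(0.01, 0, 110)
  expect_error(run_cohort(model_parameters(entry_age = 111), "pvc", lt),
               "outside")
  expect_error(run_cohort(model_parameters(), "pvc", lt, max_age = 200),
               "terminal")
})

test_that("trace export and tidying carry all states and events", {
  lt <- flat_life_table(0.5, 36, 40)
  tr <- run_cohort(model_parameters(), "pvc", lt)
  df <- tibble::as_tibble(tr)
  expect_true(all(health_states()$state %in% names(df)))
  expect_true(all(paste0("events_",
                         c("uti", "bladder_stones", "kidney_stones",
                           "urethral_injury", "urosepsis")) %in% names(df)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)),
               tr$cycles + 1)
})
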