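test_that("discount factors follow the annual-rate closed form", {
  expect_equal(discount_factor(0.05, 0), 1)
  expect_equal(discount_factor(0.05, 12), 1 / 1.05)
  expect_equal(discount_factor(0, 240), 1)
  expect_equal(discount_factor(0.05, 6), 1.05^(-0.5))
  expect_error(discount_factor(-0.01, 3), ">= 0")
})

test_that("per-cycle costs price consumables, states and events", {
  # fully alive, no impairment, no events
  tr <- make_trace(constant_occupancy(1, 3), arm = "pvc")
  expect_equal(cycle_costs(tr, cost_schedule()), rep(74.27 + 132.75, 3))
  tr_h <- make_trace(constant_occupancy(1, 3), arm = "hydrophilic")
  expect_equal(cycle_costs(tr_h, cost_schedule()), rep(608.27, 3))
  # lubricant scales with tubes/day (PVC only)
  expect_equal(cycle_costs(tr, cost_schedule(tubes_per_day = 4)),
               rep(74.27 + 265.50, 3))
  expect_equal(cycle_costs(tr_h, cost_schedule(tubes_per_day = 4)),
               rep(608.27, 3))
  # all dead
  expect_equal(cycle_costs(make_trace(constant_occupancy(13, 3)),
                           cost_schedule()), rep(0, 3))
  # renal-failure state adds its monthly cost
  tr_rf <- make_trace(constant_occupancy(9, 2), arm = "pvc")
  expect_equal(cycle_costs(tr_rf, cost_schedule()),
               rep(74.27 + 132.75 + 2589.02, 2))
  # one expected UTI event adds treatment + antibiotics
  ev <- matrix(0, 2, 5); ev[, 1] <- 1
  tr_uti <- make_trace(constant_occupancy(1, 2), events = ev, arm = "pvc")
  expect_equal(cycle_costs(tr_uti, cost_schedule()),
               rep(74.27 + 132.75 + 554.16 + 60.50, 2))
})

test_that("per-cycle QALYs apply state and event decrements", {
  u <- utility_schedule()
  tr <- make_trace(constant_occupancy(1, 3))
  expect_equal(cycle_qalys(tr, u), rep(0.5 / 12, 3))
  expect_equal(cycle_qalys(make_trace(constant_occupancy(13, 3)), u),
               rep(0, 3))
  # renal failure with a resistant UTI: both decrements apply
  tr_rf <- make_trace(constant_occupancy(11, 2))
  expect_equal(cycle_qalys(tr_rf, u),
               rep(max(0, 0.5 - 0.250 - 0.104) / 12, 2))
  # utilities floor at zero per state
  u_low <- utility_schedule(u0 = 0.2)
  expect_equal(cycle_qalys(tr_rf, u_low), rep(0, 2))
  # urosepsis event decrement subtracts for one cycle
  ev <- matrix(0, 2, 5); ev[, 5] <- 0.5
  tr_ev <- make_trace(constant_occupancy(1, 2), events = ev)
  expect_equal(cycle_qalys(tr_ev, u), rep((0.5 - 0.5 * 0.160) / 12, 2))
})

test_that("accumulation reproduces closed-form and oracle values", {
  # 12 fully-alive cycles, no discounting: exactly one life year
  tr <- make_trace(constant_occupancy(1, 12))
  out <- accumulate_outcomes(tr, cost_schedule(), utility_schedule(),
                             annual_rate = 0)
  expect_equal(out$lyg, 1)
  expect_equal(out$qalys, 0.5)
  expect_equal(out$uti_count, 0)

  # zero-disease model: discounted LYG equals the discounted survival oracle
  lt <- synthetic_life_table("female")
  tr0 <- run_cohort(zero_disease_params(), "pvc", lt)
  out0 <- accumulate_outcomes(tr0, cost_schedule(), utility_schedule(),
                              annual_rate = 0.05)
  ages <- 36 + (seq_len(tr0$cycles) - 1) %/% 12
  q_m <- annual_to_monthly_prob(lt$q_annual[match(ages, lt$age)])
  S <- cumprod(1 - q_m)
  ly_mid <- (c(1, S[-length(S)]) + S) / 2 / 12
  oracle <- sum(ly_mid * 1.05^(-(seq_along(S) - 0.5) / 12))
  expect_equal(out0$lyg, oracle, tolerance = 1e-12)
})

test_that("costs are linear in unit costs", {
  lt <- flat_life_table(0.02, 36, 70)
  tr <- run_cohort(model_parameters(), "pvc", lt)
  base_sched <- cost_schedule()
  doubled <- cost_schedule(
    uti_event = 2 * base_sched$uti_event,
    uti_antibiotics = 2 * base_sched$uti_antibiotics,
    urosepsis = 2 * base_sched$urosepsis,
    urethral_injury = 2 * base_sched$urethral_injury,
    kidney_stones = 2 * base_sched$kidney_stones,
    bladder_stones = 2 * base_sched$bladder_stones
  )
  consumable_only <- cost_schedule(
    uti_event = 0, uti_antibiotics = 0, urosepsis = 0,
    urethral_injury = 0, kidney_stones = 0, bladder_stones = 0
  )
  event_part <- cycle_costs(tr, base_sched) - cycle_costs(tr, consumable_only)
  expect_equal(cycle_costs(tr, doubled),
               cycle_costs(tr, base_sched) + event_part, tolerance = 1e-10)
})

test_that("discounting is monotone and never touches UTI counts", {
  lt <- synthetic_life_table("male")
  tr <- run_cohort(model_parameters(), "hydrophilic", lt)
  outs <- lapply(c(0, 0.05, 0.10), function(r) {
    accumulate_outcomes(tr, cost_schedule(), utility_schedule(),
                        annual_rate = r)
  })
  for (m in c("cost", "qalys", "lyg")) {
    vals <- vapply(outs, function(o) o[[m]], numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  utis <- vapply(outs, function(o) o$uti_count, numeric(1))
  expect_equal(utis, rep(utis[1], 3))
  # undiscounted totals match plain sums
  expect_equal(outs[[1]]$cost, sum(cycle_costs(tr, cost_schedule())))
  # QALYs bounded by baseline utility times life years
  expect_lte(outs[[2]]$qalys, utility_schedule()$u0 * outs[[2]]$lyg)
})

test_that("sex combination is an outcome-level convex mix", {
  m <- outcomes_row("pvc", 100, 2, 4, 10)
  f <- outcomes_row("pvc", 200, 3, 5, 20)
  c80 <- combine_sexes(m, f, 0.8)
  expect_equal(c80$cost, 120)
  expect_equal(c80$qalys, 2.2)
  expect_equal(c80$lyg, 4.2)
  expect_equal(c80$uti_count, 12)
  expect_equal(c80$sex, "combined")
})
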