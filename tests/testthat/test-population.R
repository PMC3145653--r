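# Cell sampling, protocols, signal-response, reprogramming.

test_that("sample_cell reproduces the stated variability model", {
  m <- th_model("symmetric")
  avg <- average_cell(m)
  expect_identical(avg$weights, m$weights)
  expect_identical(avg$gamma, m$gamma)

  set.seed(11)
  draws <- replicate(1e4, sample_cell(m, 0.05)$weights["RORgt", "RORgt"])
  expect_equal(mean(draws), 1.24, tolerance = 0.005)
  expect_equal(sd(draws), 0.062, tolerance = 0.03)   # cv * |basal|

  cc <- th_model("asymmetric")
  set.seed(12)
  cell <- sample_cell(cc, 0.05)
  # structural zeros stay zero; sampled entries move; signs preserved
  expect_true(all(cell$weights[cc$weights == 0] == 0))
  nz <- cc$weights != 0
  expect_true(all(cell$weights[nz] != cc$weights[nz]))
  expect_identical(sign(cell$weights[nz]), sign(cc$weights[nz]))
  expect_true(all(sign(cell$beta) == sign(cc$beta)))

  c1 <- sample_cell(m, 0.05, seed = 99)
  c2 <- sample_cell(m, 0.05, seed = 99)
  expect_identical(c1$weights, c2$weights)
})

test_that("run_protocol calls naive under an all-zero schedule and rejects
           schedules without equilibration", {
  m <- th_model("symmetric")
  set.seed(3)
  for (k in 1:5) {
    cell <- sample_cell(m, 0.05)
    p <- run_protocol(m, cell, t_end = 60)
    expect_identical(p$phenotype$class, "naive")
    expect_true(p$settled)
  }
  expect_error(run_protocol(m, schedule = signal_schedule(m, TGFb = 0.5)),
               "equilibration")
})

test_that("signal-response fractions are consistent, deterministic, and
           heterogeneous at intermediate TGF-beta", {
  m <- th_model("symmetric")
  # a handful of cells near the basin boundary may be flagged unsettled at
  # the 500-unit cap; that warning is the documented behavior
  sr <- suppressWarnings(
    signal_response(m, c(0.3, 0.5), n_cells = 300, seed = 5))
  enum <- sr$frac_naive + sr$frac_ror_only + sr$frac_foxp3_only +
    sr$frac_double
  expect_equal(enum, rep(1, 2), tolerance = 1 / 300 + 1e-9)
  expect_true(all(sr$frac_foxp3_expr >= sr$frac_foxp3_only))
  sr2 <- suppressWarnings(
    signal_response(m, c(0.3, 0.5), n_cells = 300, seed = 5))
  expect_identical(sr, sr2)
  # three differentiated fates coexist near TGF-beta = 0.5
  at5 <- sr[sr$TGFb == 0.5, ]
  expect_gt(at5$frac_ror_only, 0.05)
  expect_gt(at5$frac_foxp3_only, 0.05)
  expect_gt(at5$frac_double, 0.05)
})

test_that("the cv -> 0 limit collapses the population onto the average
           cell's fate", {
  m <- th_model("symmetric")
  sr <- signal_response(m, 0.5, n_cells = 20, cv = 0, seed = 8)
  expect_equal(sr$frac_double, 1)   # symmetric average cell -> double state
})

test_that("reprogramming is inert without the IL-6 step", {
  mc <- th_model("asymmetric")
  rp <- reprogram(mc, n_cells = 150, il6 = 0, seed = 21, t_end = 250)
  late <- rp[rp$time >= 120, c("frac_ror_only", "frac_foxp3_only",
                               "frac_double", "frac_il17")]
  # fractions static once differentiated (signals unchanged after t = 10)
  expect_lt(max(apply(late, 2, function(x) diff(range(x)))), 0.03)
})

test_that("reprogramming fractions evolve on a uniform grid and sum to
           one", {
  mc <- th_model("asymmetric")
  rp <- reprogram(mc, n_cells = 100, seed = 22, t_end = 150, dt_out = 5)
  expect_equal(rp$time, seq(0, 150, by = 5))
  enum <- rp$frac_naive + rp$frac_ror_only + rp$frac_foxp3_only +
    rp$frac_double
  expect_equal(enum, rep(1, nrow(rp)), tolerance = 1e-9)
  expect_identical(rp, reprogram(mc, n_cells = 100, seed = 22,
                                 t_end = 150, dt_out = 5))
})

test_that("the (0, 0) grid corner reproduces plain induced
           differentiation", {
  mc <- th_model("asymmetric")
  gr <- il6_atra_grid(mc, 0, 0, n_cells = 200, seed = 33)
  sr <- signal_response(mc, 0.28, n_cells = 200, seed = 33)
  expect_equal(gr$frac_ror_only, sr$frac_ror_only, tolerance = 1e-9)
  expect_equal(gr$frac_foxp3_expr, sr$frac_foxp3_expr, tolerance = 1e-9)
  expect_equal(gr$frac_il17, sr$frac_il17, tolerance = 1e-9)
})
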