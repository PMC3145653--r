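# Time integration, steady-state enumeration, phase-plane analysis.

m_sym <- th_model("symmetric")

test_that("integration finds the naive state and honors t_end = 0", {
  tr <- integrate_cell(m_sym, t_end = 50)
  expect_true(all(tr$final < 0.1))          # RORgt-low / Foxp3-low
  expect_equal(unname(tr$final[1]), unname(tr$final[2]), tolerance = 1e-9)
  tr0 <- integrate_cell(m_sym, x0 = c(0.3, 0.7), t_end = 0)
  expect_equal(unname(tr0$final), c(0.3, 0.7))
  expect_equal(nrow(tr0$states), 1L)
})

test_that("signal steps steer the naive state into one of the tristable
           attractors", {
  sched <- signal_schedule(m_sym, data.frame(time = 10, signal = "TGFb",
                                             value = 0.5))
  tr <- integrate_cell(m_sym, schedule = sched, t_end = 200, ss_tol = 1e-10,
                       rtol = 1e-9, atol = 1e-12)
  ss <- find_steady_states(m_sym, c(TGFb = 0.5))
  stable <- ss$states[ss$stable, , drop = FALSE]
  d <- sqrt(colSums((t(stable) - tr$final)^2))
  expect_lt(min(d), 1e-6)
  # symmetric initial condition stays on the diagonal -> double state
  expect_true(all(tr$final > 0.9))
})

test_that("phenotype call is robust over a 10x integrator tolerance range", {
  sched <- signal_schedule(m_sym, data.frame(time = 10, signal = "TGFb",
                                             value = 0.4))
  calls <- vapply(c(1e-7, 1e-8, 1e-9), function(tol) {
    tr <- integrate_cell(m_sym, x0 = c(0.02, 0.01), schedule = sched,
                         t_end = 300, rtol = tol, atol = tol * 1e-3)
    classify_phenotype(tr$final, m_sym)$class
  }, "")
  expect_length(unique(calls), 1L)
})

test_that("steady-state counts match the paper scenario and the grid
           oracle", {
  ss0 <- find_steady_states(m_sym, c(TGFb = 0))
  expect_identical(sum(ss0$stable), 1L)
  expect_identical(unname(ss0$phenotype[ss0$stable]), "naive")

  ss5 <- find_steady_states(m_sym, c(TGFb = 0.5))
  expect_identical(sum(ss5$stable), 3L)    # tristable
  expect_setequal(ss5$phenotype[ss5$stable],
                  c("ror_only", "foxp3_only", "double"))

  for (s in c(0, 0.2, 0.5, 0.8)) {
    att <- oracle_attractors(m_sym, c(TGFb = s), grid_n = 12)
    found <- find_steady_states(m_sym, c(TGFb = s))
    stable <- found$states[found$stable, , drop = FALSE]
    expect_identical(nrow(att), nrow(stable))
    expect_lt(set_distance(att, unname(stable)), 1e-3)
  }
})

test_that("residuals and eigenvalues satisfy the steady-state contract", {
  ss <- find_steady_states(m_sym, c(TGFb = 0.5))
  for (k in seq_len(nrow(ss$states))) {
    expect_lt(max(abs(net_rhs(m_sym, ss$states[k, ], c(TGFb = 0.5)))), 1e-9)
    re <- Re(ss$eigenvalues[[k]])
    if (ss$stable[k]) expect_true(all(re < 0)) else expect_gt(max(re), 0)
  }
})

test_that("stability classification agrees with perturbed integration", {
  s <- c(TGFb = 0.5)
  ss <- find_steady_states(m_sym, s)
  for (k in seq_len(nrow(ss$states))) {
    x <- ss$states[k, ]
    end <- thfates:::settle(m_sym, x + 1e-3, s)$state
    if (ss$stable[k]) {
      expect_lt(sqrt(sum((end - x)^2)), 5e-3)
    } else {
      expect_gt(sqrt(sum((end - x)^2)), 0.1)
    }
  }
})

test_that("the steady-state set is swap-invariant for symmetric models", {
  for (id in c("symmetric", "symmetric_intermediates")) {
    m <- th_model(id)
    ss <- find_steady_states(m, c(TGFb = 0.45))
    swapped <- ss$states[, m$swap, drop = FALSE]
    expect_lt(set_distance(unname(ss$states), unname(swapped)), 1e-9)
  }
})

test_that("nullclines pass through the fixed points and mirror each other", {
  s <- c(TGFb = 0.5)
  nc <- nullclines(m_sym, s, resolution = 1001)
  ss <- find_steady_states(m_sym, s)
  for (k in seq_len(nrow(ss$states))) {
    x <- ss$states[k, ]
    # defining residuals vanish on both curves
    for (i in 1:2)
      expect_lt(abs(sigmoid(m_sym$sigma[i] * net_input(m_sym, i, x, s)) -
                      x[i]), 1e-8)
    d <- vapply(nc, function(df)
      min(sqrt((df[[1]] - x[1])^2 + (df[[2]] - x[2])^2)), 0)
    expect_lt(max(d), 1e-3)
  }
  # symmetry: the Foxp3 nullcline is the mirror of the RORgt nullcline
  mirrored <- nc[[1]][, 2:1]
  d <- vapply(sample(nrow(mirrored), 50), function(k)
    min(sqrt((nc[[2]][[1]] - mirrored[k, 1])^2 +
               (nc[[2]][[2]] - mirrored[k, 2])^2)), 0)
  expect_lt(max(d), 5e-3)
  expect_error(nullclines(th_model("asymmetric")), "2-species")
})

test_that("basin map partitions the lattice and matches direct
           integration", {
  s <- c(TGFb = 0.5)
  bm <- basin_map(m_sym, s, grid_n = 30)
  expect_identical(bm$n_unresolved, 0L)
  expect_true(all(bm$label %in% seq_len(nrow(bm$attractors))))
  # each attractor's own lattice cell is labelled by itself
  for (k in seq_len(nrow(bm$attractors))) {
    i <- which.min(abs(bm$grid - bm$attractors[k, 1]))
    j <- which.min(abs(bm$grid - bm$attractors[k, 2]))
    expect_identical(bm$label[i, j], k)
  }
  # crossing the diagonal basin boundary changes the outcome
  lo <- thfates:::settle(m_sym, c(0.1, 0.45), s)$state
  hi <- thfates:::settle(m_sym, c(0.45, 0.1), s)$state
  expect_gt(sqrt(sum((lo - hi)^2)), 0.5)
})
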