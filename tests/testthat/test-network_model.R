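# The sigmoidal formalism and the three registered models.

test_that("sigmoid is the logistic with the expected limits and symmetry", {
  expect_identical(sigmoid(0), 0.5)
  # naive-state basal drive of the symmetric model: 1/(1 + e^4)
  expect_equal(sigmoid(5 * -0.8), 0.017986209962091559, tolerance = 1e-12)
  u <- seq(-30, 30, length.out = 101)
  expect_equal(sigmoid(u) + sigmoid(-u), rep(1, 101), tolerance = 1e-12)
  expect_true(all(diff(sigmoid(u)) > 0))
  expect_equal(sigmoid(c(-1e3, 1e3)), c(0, 1))
  expect_equal(dsigmoid(0), 0.25)
})

test_that("registered models carry the published basal parameter values", {
  a <- th_model("symmetric")
  expect_identical(a$species, c("RORgt", "Foxp3"))
  expect_identical(a$signals, "TGFb")
  expect_equal(unname(a$beta), c(-0.8, -0.8))
  expect_equal(a$weights["RORgt", "RORgt"], 1.24)
  expect_equal(a$weights["RORgt", "Foxp3"], -0.4)
  expect_equal(a$weights["RORgt", "TGFb"], 1.2)

  b <- th_model("symmetric_intermediates")
  expect_equal(unname(b$sigma), c(5, 5, 10, 10))
  expect_equal(b$weights["RORgt", "UI"], 0.62)
  expect_equal(b$weights["UI", "TGFb"], 1.2)
  expect_equal(b$weights["RORgt", "TGFb"], 0)  # routed via UI only

  cc <- th_model("asymmetric")
  expect_equal(cc$sigma[["RORgt"]], 7)
  expect_equal(cc$beta[["Foxp3"]], -0.92)
  expect_equal(cc$weights["Foxp3", "RORgt"], -0.54)
  expect_equal(cc$weights["RORgt", "Foxp3"], 0)  # inhibition removed
  expect_equal(cc$weights["IL17", "Foxp3"], -0.8)
  expect_equal(cc$gamma[["STAT3"]], 0.1)
  expect_equal(cc$weights["STAT3", "IL6"], 0.2)
  expect_equal(cc$weights["Foxp3", "ATRA"], 0.035)
  # IL-17 is a pure readout: no outgoing weights
  expect_true(all(cc$weights[, "IL17"] == 0))
})

test_that("symmetric models are invariant under the species swap", {
  for (id in c("symmetric", "symmetric_intermediates")) {
    m <- th_model(id)
    p <- m$swap
    expect_equal(unname(m$weights[p, c(p, length(p) + 1)]),
                 unname(m$weights))
    expect_equal(unname(m$gamma[p]), unname(m$gamma))
    expect_equal(unname(m$beta[p]), unname(m$beta))
  }
  expect_null(th_model("asymmetric")$swap)
})

test_that("net_input reproduces hand-computed weighted sums", {
  a <- th_model("symmetric")
  expect_equal(net_input(a, "RORgt", c(0, 0), c(TGFb = 0)), -0.8)
  # -0.8 + 1.24*1 + 1.2*0.5 = 1.04
  expect_equal(net_input(a, "RORgt", c(1, 0), c(TGFb = 0.5)), 1.04)
  cc <- th_model("asymmetric")
  # -0.4 + 0.2 * 10 = 1.6
  expect_equal(net_input(cc, "STAT3", rep(0, 6), c(IL6 = 10)), 1.6)
  expect_error(net_input(a, "STAT3", c(0, 0)), "out of range")
})

test_that("rhs vanishes exactly at constructed fixed points and is linear
           in gamma", {
  set.seed(42)
  for (id in th_models()) {
    m <- th_model(id)
    n <- length(m$species)
    s <- setNames(runif(length(m$signals)), m$signals)
    # one fixed-point iteration sweep to build an exact fixed point is not
    # possible in general; instead verify the defining identity directly
    x <- runif(n)
    fx <- sigmoid(m$sigma * sapply(seq_len(n), function(i)
      net_input(m, i, x, s)))
    r <- net_rhs(m, x, s)
    expect_equal(r, unname(m$gamma * (fx - x)), tolerance = 1e-12)
    m2 <- m
    m2$gamma <- 2 * m$gamma
    expect_equal(net_rhs(m2, x, s), 2 * r, tolerance = 1e-12)
  }
})

test_that("the unit box is forward-invariant", {
  set.seed(7)
  m <- th_model("asymmetric")
  n <- length(m$species)
  for (rep in 1:50) {
    x <- runif(n)
    i <- sample(n, 1)
    s <- c(TGFb = runif(1), IL6 = 10 * runif(1), ATRA = 1.5 * runif(1))
    x[i] <- 0
    expect_gt(net_rhs(m, x, s)[i], 0)
    x[i] <- 1
    expect_lt(net_rhs(m, x, s)[i], 0)
  }
})

test_that("constructor validates dimensions and positivity", {
  expect_error(network_spec("A", character(), gamma = -1, sigma = 1,
                            beta = 0, weights = matrix(0, 1, 1)),
               "strictly positive")
  expect_error(network_spec(c("A", "B"), "s", gamma = c(1, 1),
                            sigma = c(1, 1), beta = c(0, 0),
                            weights = matrix(0, 2, 2)),
               "n_species")
  expect_error(network_spec("A", character(), 1, 1, 0,
                            weights = matrix(NA_real_, 1, 1)), "finite")
})

test_that("network configs round-trip through JSON exactly", {
  for (id in th_models()) {
    m <- th_model(id)
    f <- withr::local_tempfile(fileext = ".json")
    write_network_spec(m, f)
    m2 <- read_network_spec(f)
    expect_identical(m2$species, m$species)
    expect_identical(m2$signals, m$signals)
    expect_identical(m2$gamma, m$gamma)
    expect_identical(m2$sigma, m$sigma)
    expect_identical(m2$beta, m$beta)
    expect_identical(m2$weights, m$weights)
    expect_identical(m2$swap, m$swap)
  }
  expect_error(read_network_spec(
    withr::local_tempfile(lines = '{"species": 3}', fileext = ".json")))
})
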