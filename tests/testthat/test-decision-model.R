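# The decision-model layer: marginal specifications, prior and conditional
# sampling (including the correlated bivariate blocks), the odds-ratio
# helper, the built-in net-benefit utility and the config round trip.

test_that("marginal and block specifications validate their parameters", {
  expect_error(marginal_spec("x", "normal", c(mean = 0)), "needs parameters")
  expect_error(marginal_spec("x", "normal", c(mean = 0, var = -1)),
               "variance")
  expect_error(marginal_spec("x", "beta", c(shape1 = 0, shape2 = 2)),
               "shapes")
  expect_identical(marginal_spec("x", "lognormal",
                                 c(mean = 0, var = 1))$transform, "log")
  expect_identical(marginal_spec("x", "logitnormal",
                                 c(mean = 0, var = 1))$transform, "logit")
  expect_error(correlated_block(c("a", "b"), c(0, 0),
                                matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  # block marginals must match the joint parameterisation
  expect_error(decision_model(
    options = c("A", "B"),
    variables = list(marginal_spec("a", "normal", c(mean = 0, var = 1)),
                     marginal_spec("b", "normal", c(mean = 5, var = 1))),
    utility = function(o, th, cst) th$a,
    blocks = list(correlated_block(c("a", "b"), c(0, 0),
                                   matrix(c(1, 0.5, 0.5, 1), 2)))),
    "does not match")
})

test_that("prior sampling reproduces the stated marginals and correlations", {
  m <- three_treatment_model()
  n <- 1e5
  th <- sample_prior(m, n, seed = 421)
  # N(30, 25) lifetime: mean within 3 SE, variance within 3 SE of S^2
  expect_lt(abs(mean(th$L) - 30), 3 * 5 / sqrt(n))
  expect_lt(abs(var(th$L) - 25), 3 * 25 * sqrt(2 / (n - 1)))
  # supports
  expect_true(all(th$Q_E > 0 & th$Q_E < 1))
  expect_true(all(th$OR_E_d2 > 0))
  expect_true(all(th$P_E_d1 > 0 & th$P_E_d1 < 1))
  # underlying-normal correlation of the odds-ratio block:
  # 0.02 / sqrt(0.11 * 0.06)
  rho <- 0.02 / sqrt(0.11 * 0.06)
  expect_lt(abs(cor(log(th$OR_E_d2), log(th$OR_E_d3)) - rho),
            3 * (1 - rho^2) / sqrt(n))
  # constant-family draws are exact
  mc <- decision_model(
    options = "A",
    variables = list(marginal_spec("lambda", "constant", c(value = 75000))),
    utility = function(o, th, cst) th$lambda)
  expect_identical(unique(sample_prior(mc, 50, seed = 1)$lambda), 75000)
})

test_that("conditional sampling matches the closed-form bivariate normal", {
  m <- three_treatment_model()
  n <- 4e4
  # fixing C_T_d3 at its mean 2e4: partner ~ N(1.5e4 + (100/500)(v - 2e4),
  # 300 - 100^2/500) = N(1.5e4, 280)
  th <- sample_conditional(m, "C_T_d3", 2e4, n, seed = 31)
  expect_identical(unique(th$C_T_d3), 2e4)
  expect_lt(abs(mean(th$C_T_d2) - 1.5e4), 3 * sqrt(280 / n))
  expect_lt(abs(var(th$C_T_d2) - 280), 3 * 280 * sqrt(2 / (n - 1)))
  # off-mean conditioning shifts the partner mean by the regression slope
  th2 <- sample_conditional(m, "C_T_d3", 2.1e4, n, seed = 32)
  expect_lt(abs(mean(th2$C_T_d2) - (1.5e4 + 0.2 * 1e3)), 3 * sqrt(280 / n))
  # conditioning on an unblocked variable leaves the others at their prior:
  # two-sample KS on L under prior vs conditional-on-Q_SE
  pri <- sample_prior(m, 1e4, seed = 33)
  cnd <- sample_conditional(m, "Q_SE", 0.7, 1e4, seed = 34)
  expect_gt(suppressWarnings(ks.test(pri$L, cnd$L)$p.value), 0.001)
  # support violations are domain errors
  expect_error(sample_conditional(m, "OR_E_d3", -1, 10), "support")
})

test_that("odds_to_prob is the correct inverse-odds map", {
  expect_equal(odds_to_prob(0.15, 1), 0.15)
  # direct arithmetic: 0.2231*(0.15/0.85)/(1 + 0.2231*(0.15/0.85))
  expect_equal(odds_to_prob(0.15, 0.2231), 0.03787926, tolerance = 1e-6)
  # round trip: recomputing the odds ratio from the result returns OR
  for (or in c(0.1, 0.2231, 5)) {
    p <- odds_to_prob(0.15, or)
    expect_equal((p / (1 - p)) / (0.15 / 0.85), or, tolerance = 1e-12)
  }
  expect_error(odds_to_prob(1.2, 2), "p_base")
  expect_error(odds_to_prob(0.5, -1), "odds_ratio")
})

test_that("the built-in net benefit matches hand-evaluated cases", {
  m <- three_treatment_model()
  base <- list(L = 30, Q_E = 0.6, Q_SE = 0.7, C_E = 2e5, C_SE = 1e5,
               C_T_d2 = 1.5e4, C_T_d3 = 2e4, P_E_d1 = 0.15, OR_E_d2 = 0.25,
               OR_E_d3 = 0.2, P_SE_d2 = 0.2, P_SE_d3 = 0.25)
  # standard of care with zero event probability: only the no-SE/no-event
  # term survives and there is no treatment cost -> lambda * L
  th0 <- base; th0$P_E_d1 <- 0
  expect_equal(net_benefit(m, "d1", th0), 75000 * 30)
  # point values: 0.15*(75000*30*0.8 - 2e5) + 0.85*(75000*30)
  expect_equal(net_benefit(m, "d1", base),
               0.15 * (75000 * 30 * 0.8 - 2e5) + 0.85 * 75000 * 30)
  expect_equal(net_benefit(m, "d1", base), 2152500)
  # independent term-by-term oracle for a costly treatment
  pe <- odds_to_prob(base$P_E_d1, base$OR_E_d2)
  manual <- with(base,
    P_SE_d2 * pe * (75000 * (L * (1 + Q_E) / 2 - Q_SE) - (C_SE + C_E)) +
    P_SE_d2 * (1 - pe) * (75000 * (L - Q_SE) - C_SE) +
    (1 - P_SE_d2) * pe * (75000 * L * (1 + Q_E) / 2 - C_E) +
    (1 - P_SE_d2) * (1 - pe) * 75000 * L - C_T_d2)
  expect_equal(net_benefit(m, "d2", base), manual)
  expect_error(net_benefit(m, "d9", base), "unknown option")
})

test_that("linearly entering variables support exact-mean plug-in", {
  # the multilinearity that justifies Rao-Blackwellisation: replacing a
  # linear variable by its exact mean leaves the MC mean unchanged within
  # 3 combined standard errors (common random numbers otherwise)
  m <- three_treatment_model()
  n <- 2e5
  th <- sample_prior(m, n, seed = 55)
  for (v in c("L", "C_E", "C_T_d2")) {
    full <- net_benefit(m, "d2", th)
    plugged <- th; plugged[[v]] <- m$plugin_means[[v]]
    plug <- net_benefit(m, "d2", plugged)
    se <- sd(full - plug) / sqrt(n)
    expect_lt(abs(mean(full) - mean(plug)), 3 * se + 1e-9)
  }
  # Q_E's quadrature mean agrees with a large-sample MC mean
  expect_lt(abs(m$plugin_means[["Q_E"]] -
                  mean(sample_prior(m, 2e5, seed = 56)$Q_E)),
            3 * 0.1 / sqrt(2e5))
})

test_that("models round-trip through the config file format", {
  m <- three_treatment_model()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, f)
  m2 <- read_model_config(f)
  expect_identical(sample_prior(m, 100, seed = 77),
                   sample_prior(m2, 100, seed = 77))
  expect_identical(net_benefit(m, "d3", as.list(sample_prior(m, 5, seed = 1))),
                   net_benefit(m2, "d3", as.list(sample_prior(m2, 5, seed = 1))))
  # user configs without a shipped utility must say so
  doc <- yaml::read_yaml(f)
  doc$utility <- "user"
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, f2)
  expect_error(read_model_config(f2), "utility")
  # samples export as plain CSV with variable-name headers
  csv <- withr::local_tempfile(fileext = ".csv")
  write_samples_csv(sample_prior(m, 10, seed = 9), csv)
  back <- read.csv(csv)
  expect_identical(names(back), names(m$variables))
  expect_equal(nrow(back), 10L)
})
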