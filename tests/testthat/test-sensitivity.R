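# Sensitivity measures: prior optimum, EVPI/EVPPI against closed forms,
# decision switching probability from closed-form marginal CDFs, and the
# common-random-number conditional-expectation curves.

test_that("the prior optimum maximises the expected utility", {
  # f_A = theta, f_B = -theta with theta ~ N(1, 1): means +1 / -1
  m <- toy_sign_model(theta_mean = 1)
  po <- prior_optimal(m, n = 2e4, seed = 41)
  expect_identical(po$optimal, "A")
  expect_lt(abs(po$means$mean[1] - 1), 3 / sqrt(2e4))
  expect_lt(abs(po$means$mean[2] + 1), 3 / sqrt(2e4))
  expect_identical(sum(tidy(po)$optimal), 1L)
  # a single-option model returns that option
  single <- decision_model("only",
                           list(marginal_spec("x", "normal",
                                              c(mean = 0, var = 1))),
                           utility = function(o, th, cst) th$x)
  expect_identical(prior_optimal(single, 100, seed = 1)$optimal, "only")
})

test_that("EVPI matches closed forms", {
  # identical utilities: zero exactly
  m0 <- decision_model(c("A", "B"),
                       list(marginal_spec("x", "normal",
                                          c(mean = 0, var = 1))),
                       utility = function(o, th, cst) th$x)
  expect_identical(evpi(m0, n = 1000, seed = 2)$estimate, 0)
  # antisymmetric toy: EVPI = E|theta| = sqrt(2/pi)
  m <- toy_sign_model()
  ev <- evpi(m, n = 5e5, seed = 43)
  expect_lt(abs(ev$estimate - sqrt(2 / pi)), 3 * ev$se)
  expect_gte(ev$estimate, 0)
})

test_that("EVPPI obeys its definitional limits", {
  # a variable the utilities never read carries no information value; what
  # remains is exactly the documented upward inner bias, E|mean of the
  # inner half-difference| ~ sqrt(2/pi) * sd / sqrt(n_inner), which must
  # bound the estimate and shrink as the inner sample grows
  m <- decision_model(
    options = c("A", "B"),
    variables = list(marginal_spec("x", "normal", c(mean = 0, var = 1)),
                     marginal_spec("junk", "normal", c(mean = 0, var = 1))),
    utility = function(o, th, cst)
      switch(o, A = th$x, B = -th$x))
  e0 <- evppi_nested(m, "junk", n_outer = 2000, n_inner = 64, seed = 44)
  expect_gte(e0$estimate, 0)
  expect_lt(e0$estimate, 2 * sqrt(2 / pi) / sqrt(64))
  e0b <- evppi_nested(m, "junk", n_outer = 2000, n_inner = 1024, seed = 44)
  expect_lt(e0b$estimate, e0$estimate / 2)
  # when the utilities depend on theta_j alone, EVPPI_j equals the EVPI
  ms <- toy_sign_model()
  ej <- evppi_nested(ms, "theta", n_outer = 2e4, n_inner = 2, seed = 45)
  ev <- evpi(ms, n = 2e4, seed = 45)
  expect_lt(abs(ej$estimate - ev$estimate),
            3 * sqrt(ej$se^2 + ev$se^2))
  # sandwich 0 <= EVPPI <= EVPI on the built-in model (reduced scale)
  mb <- three_treatment_model()
  eb <- evppi_nested(mb, "P_SE_d3", n_outer = 2^12, n_inner = 2^8,
                     seed = 46)
  evb <- evpi(mb, n = 2^15, seed = 47)
  expect_gte(eb$estimate, 0)
  expect_lt(eb$estimate, evb$estimate + 3 * sqrt(eb$se^2 + evb$se^2))
})

test_that("DSP integrates the marginal CDF over switching intervals", {
  m <- toy_unit_normal_model()
  # hand-built sets on a standard normal: tail masses beyond 3 and 1
  ts3 <- threshold_set("x", 3, c("d_a", "d_b"))
  ts1 <- threshold_set("x", 1, c("d_a", "d_b"))
  expect_equal(decision_switching_probability(m, "x", ts3, d_opt = "d_a"),
               pnorm(-3))
  expect_equal(round(decision_switching_probability(m, "x", ts3,
                                                    d_opt = "d_a"), 4),
               0.0013)
  expect_equal(decision_switching_probability(m, "x", ts1, d_opt = "d_a"),
               pnorm(-1))
  expect_equal(round(decision_switching_probability(m, "x", ts1,
                                                    d_opt = "d_a"), 4),
               0.1587)
  # empty set: the optimal option never switches
  ts0 <- threshold_set("x", numeric(), "d_a")
  expect_identical(decision_switching_probability(m, "x", ts0,
                                                  d_opt = "d_a"), 0)
  # DSP is a probability
  p <- decision_switching_probability(m, "x", ts1, d_opt = "d_b")
  expect_gte(p, 0); expect_lte(p, 1)
  # variable mismatch is an error
  expect_error(decision_switching_probability(
    three_treatment_model(), "Q_SE", ts1, d_opt = "d2"), "assembled")
})

test_that("DSP in transform space equals the natural-space integral", {
  # logit-space normal mass above a threshold vs numerical integration of
  # the logit-normal density in natural space
  m <- three_treatment_model()
  ts <- threshold_set("P_SE_d2", -0.7576, c("d2", "d1"), transform = "logit")
  dsp <- decision_switching_probability(m, "P_SE_d2", ts, d_opt = "d2")
  dens <- function(p) dnorm(qlogis(p), -1.4, sqrt(0.10)) / (p * (1 - p))
  nat <- integrate(dens, plogis(-0.7576), 1 - 1e-14, rel.tol = 1e-12)$value
  expect_equal(dsp, nat, tolerance = 1e-10)
})

test_that("conditional-expectation curves share noise across the grid", {
  m <- three_treatment_model()
  grid <- seq(0.4, 1.0, by = 0.15)
  cur <- conditional_expectation_curve(m, "Q_SE", grid, n = 2^10,
                                       plug_in = TRUE, seed = 48)
  # the costly option d2 is linear in Q_SE; with common random numbers the
  # estimated curve is exactly affine in the grid
  d2 <- cur[cur$option == "d2", ]
  fit <- lm(mean ~ theta, data = d2)
  expect_lt(max(abs(residuals(fit))), 1e-6 * diff(range(d2$mean)))
  # the cost-free option d1 ignores Q_SE entirely
  d1 <- cur[cur$option == "d1", ]
  expect_lt(diff(range(d1$mean)), 1e-9 * abs(mean(d1$mean)))
  expect_error(conditional_expectation_curve(m, "Q_E", c(-0.5, 0.5), n = 10),
               "support")
})

test_that("the grid oracle brackets a known root", {
  m <- toy_linear_model(a = 0.8, noise_sd = 0.5)
  o <- grid_root_oracle(m, "theta", "A", "B", lower = -1, upper = 2,
                        n_grid = 31, m = 2^12, seed = 49)
  expect_identical(nrow(o), 1L)
  expect_lt(abs(o$root - 0.8), 3 * o$se + 0.01)
})
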