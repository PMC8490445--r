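# Threshold-set orchestration: multi-root clustering, membership testing,
# assembly with interval labelling, and end-to-end recovery on a three-option
# toy with analytically placed roots.

test_that("independent runs recover both roots of a two-root toy", {
  # conditional difference theta^3 - theta: increasing crossings at -1 and
  # +1, repelling decreasing crossing at 0; marginal-drawn initialisations
  # straddle both basins
  m <- toy_cubic_model(noise_sd = 0.3)
  cfg <- sa_config(n_iter = 3000, schedule = step_schedule(0.1, 0.5),
                   sign = "auto")
  pr <- estimate_pairwise_roots(m, "theta", "A", "B", n_runs = 24,
                                config = cfg, seed = 2024)
  expect_false(pr$empty)
  expect_identical(pr$sign, 1)
  expect_identical(nrow(pr$clusters), 2L)
  expect_lt(abs(pr$clusters$estimate[1] + 1), 0.1)
  expect_lt(abs(pr$clusters$estimate[2] - 1), 0.1)
  # per-run tidy output matches the stored finals
  expect_equal(tidy(pr)$final, pr$finals)
})

test_that("membership tests saturate on dominated and dominating candidates", {
  m <- toy_three_option_model(noise_sd = 0.5)
  # at theta = 1 (root of d1,d2) the competitor d3 has mean -1 < 0: retained
  keep <- test_membership(m, "theta", 1.0, "d1", "d2", n = 4000, seed = 5)
  expect_true(keep$retained)
  expect_true(all(keep$p_values$p > 0.99))
  # at theta = 1.5 (root of d1,d3) the competitor d2 has mean +0.5: rejected
  drop <- test_membership(m, "theta", 1.5, "d1", "d3", n = 4000, seed = 6)
  expect_false(drop$retained)
  expect_true(all(drop$p_values$p < 1e-3))
  # Wilcoxon variant agrees on the clear-cut case
  dropw <- test_membership(m, "theta", 1.5, "d1", "d3", n = 4000,
                           family = "wilcoxon", seed = 7)
  expect_false(dropw$retained)
  # with two options there is no competitor: trivially retained
  two <- test_membership(toy_linear_model(), "theta", 0.5, "A", "B",
                         n = 100, seed = 8)
  expect_true(two$retained)
  expect_identical(nrow(two$p_values), 0L)
})

test_that("a full campaign recovers the analytic threshold set of the toy", {
  m <- toy_three_option_model(noise_sd = 0.5)
  camp <- threshold_campaign(m, "theta", n_runs = 12, n_iter = 2000,
                             n_test = 4000,
                             step_multipliers = c(theta = 2000), seed = 303)
  expect_identical(camp$prior$optimal, "d2")
  ts <- camp$results$theta$thresholds
  # K = {1, 2}: the (d1,d3) crossing at 1.5 is dominated by d2 and dropped
  expect_identical(length(ts$elements), 2L)
  expect_lt(abs(ts$elements[1] - 1), 0.08)
  expect_lt(abs(ts$elements[2] - 2), 0.08)
  expect_identical(ts$labels, c("d1", "d2", "d3"))
  td <- tidy(camp)
  expect_false(td$retained[td$d1 == "d1" & td$d2 == "d3"])
  # decision switching probability has the closed form 2 * pnorm(-0.5)
  expect_lt(abs(camp$results$theta$dsp - 2 * pnorm(-0.5)), 0.02)
  # cost accounting: one SA campaign per unordered pair
  expect_identical(names(camp$results$theta$roots),
                   c("d1,d2", "d1,d3", "d2,d3"))
})

test_that("pair order does not change the estimated root", {
  m <- toy_linear_model(a = 0.8, noise_sd = 0.5)
  cfg <- sa_config(n_iter = 1500, schedule = step_schedule(0.3, 0.5),
                   sign = "auto")
  ab <- estimate_pairwise_roots(m, "theta", "A", "B", n_runs = 8,
                                config = cfg, seed = 61)
  ba <- estimate_pairwise_roots(m, "theta", "B", "A", n_runs = 8,
                                config = cfg, seed = 62)
  expect_identical(ab$sign, 1)
  expect_identical(ba$sign, -1)  # mirrored regression, flipped recursion
  se <- sqrt(sd(ab$finals)^2 / 8 + sd(ba$finals)^2 / 8)
  expect_lt(abs(ab$clusters$estimate - ba$clusters$estimate), 3 * se)
})

test_that("an empty union yields a single interval at the prior optimum", {
  # one option dominates everywhere: the pairwise set is empty and the
  # constant conditionally optimal option must be the prior optimum
  dom <- decision_model(
    options = c("A", "B"),
    variables = list(marginal_spec("theta", "normal", c(mean = 0, var = 1)),
                     marginal_spec("eps", "normal", c(mean = 0, var = 0.25))),
    utility = function(o, th, cst)
      switch(o, A = 1 + th$eps, B = rep(0, length(th$eps))))
  cfg <- sa_config(n_iter = 1500, schedule = step_schedule(0.5, 0.5),
                   sign = +1)
  pr <- estimate_pairwise_roots(dom, "theta", "A", "B", n_runs = 6,
                                config = cfg, seed = 99)
  expect_true(pr$empty)
  ts <- assemble_threshold_set(dom, "theta", pr, n_label = 2000, seed = 100)
  expect_identical(length(ts$elements), 0L)
  expect_identical(ts$labels, "A")
  expect_identical(decision_switching_probability(dom, "theta", ts,
                                                  d_opt = "A"), 0)
})

test_that("hand-built threshold sets validate their shape", {
  expect_error(threshold_set("x", c(2, 1), c("a", "b", "a")), "increasing")
  expect_error(threshold_set("x", 1, c("a")), "label per interval")
  expect_warning(threshold_set("x", 1, c("a", "a")), "share")
  ts <- threshold_set("x", c(-1, 1), c("a", "b", "c"), transform = "logit")
  expect_equal(ts$elements_natural, plogis(c(-1, 1)))
  expect_identical(nrow(tidy(ts)), 3L)
})
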