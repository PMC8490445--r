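# The Robbins-Monro engine: the update rule, the unbiased pairwise
# difference estimator, convergence on analytic toys, Polyak-Ruppert
# averaging, sign determination and divergence detection.

test_that("the Robbins-Monro update solves a deterministic linear problem", {
  expect_equal(robbins_monro_step(1.0, 0.5, 0.4, +1), 0.8)
  expect_equal(robbins_monro_step(2.5, 0.1, 0, +1), 2.5)   # fixed point
  expect_equal(robbins_monro_step(1.0, 0.5, 0.4, -1), 1.2) # flipped
  # g(theta) = theta - 2, alpha_t = 1/t, start 10: converges to 2
  theta <- 10
  for (t in 1:1e5) theta <- robbins_monro_step(theta, 1 / t, theta - 2)
  expect_lt(abs(theta - 2), 1e-3)
})

test_that("the pairwise difference estimator is unbiased for every M", {
  m <- toy_linear_model(a = 0.5, noise_sd = 1)
  expect_error(pairwise_diff_estimate(m, "theta", "A", "A", 0), "differ")
  # identical utilities give exactly zero
  m0 <- decision_model(c("A", "B"),
                       list(marginal_spec("x", "normal",
                                          c(mean = 0, var = 1))),
                       utility = function(o, th, cst) th$x)
  expect_identical(pairwise_diff_estimate(m0, "x", "A", "B", 0.3, m = 50,
                                          seed = 1), 0)
  # averaging 2000 single-sample estimates equals one 2000-sample call
  # within 3 combined standard errors (E[g | theta = 1.2] = 0.7)
  singles <- vapply(1:2000, function(i)
    pairwise_diff_estimate(m, "theta", "A", "B", 1.2, m = 1,
                           seed = derive_seed(900, i)), 1)
  one <- pairwise_diff_estimate(m, "theta", "A", "B", 1.2, m = 2000,
                                seed = 901)
  se <- sd(singles) / sqrt(2000)
  expect_lt(abs(mean(singles) - one), 3 * sqrt(2) * se)
  expect_lt(abs(mean(singles) - 0.7), 3 * se)
})

test_that("run_sa converges in the noiseless limit and is seed-deterministic", {
  m <- toy_linear_model(a = 1.3, noise_sd = 1e-12)
  # the raw iterate converges essentially exactly without noise
  raw_cfg <- sa_config(n_iter = 3000, schedule = step_schedule(0.5, 0.6),
                       sign = +1, averaging = FALSE)
  tr_raw <- run_sa(m, "theta", "A", "B", raw_cfg, seed = 7)
  expect_lt(abs(tr_raw$final - 1.3), 1e-3)
  # the Polyak-Ruppert average carries a small diluted-transient offset
  cfg <- sa_config(n_iter = 3000, schedule = step_schedule(0.5, 0.5),
                   sign = +1)
  tr <- run_sa(m, "theta", "A", "B", cfg, seed = 7)
  expect_false(tr$diverged)
  expect_lt(abs(tr$final - 1.3), 5e-3)
  # Polyak-Ruppert identity: stored average is the exact running mean
  expect_equal(tr$averaged, cumsum(tr$raw) / seq_along(tr$raw))
  expect_equal(glance(tr)$final, tr$final)
  expect_equal(nrow(tidy(tr)), 3000L)
  # identical seeds give bit-identical traces
  tr2 <- run_sa(m, "theta", "A", "B", cfg, seed = 7)
  expect_identical(tr$raw, tr2$raw)
})

test_that("sign determination probes the crossing direction", {
  up <- toy_linear_model(a = 0.2, noise_sd = 0.3)
  dn <- toy_mirror_model(a = 0.2, noise_sd = 0.3)
  expect_identical(determine_sign(up, "theta", "A", "B", seed = 3), 1)
  expect_identical(determine_sign(dn, "theta", "A", "B", seed = 3), -1)
  # root far outside both probes: confidently one-signed at both ends
  far <- toy_linear_model(a = 25, noise_sd = 0.3)
  expect_identical(determine_sign(far, "theta", "A", "B", seed = 3),
                   "no-crossing")
})

test_that("divergence is detected for empty root sets but not at a root", {
  # conditional difference identically +1: the recursion drifts without
  # bound, so the across-run spread never shrinks
  drift <- decision_model(
    options = c("A", "B"),
    variables = list(marginal_spec("theta", "normal", c(mean = 0, var = 1)),
                     marginal_spec("eps", "normal", c(mean = 0, var = 0.25))),
    utility = function(o, th, cst)
      switch(o, A = 1 + th$eps, B = rep(0, length(th$eps))))
  cfg <- sa_config(n_iter = 2000, schedule = step_schedule(0.5, 0.5),
                   sign = +1)
  pr <- estimate_pairwise_roots(drift, "theta", "A", "B", n_runs = 6,
                                config = cfg, seed = 88)
  expect_true(pr$empty)
  expect_identical(nrow(pr$clusters), 0L)
  # raw iterates of each run drift downwards (noise flips the odd step)
  for (tr in pr$traces) {
    expect_gt(mean(diff(tr$raw[-1]) < 0), 0.8)
    expect_lt(tr$raw[length(tr$raw)], tr$raw[1] - 5)
  }
  # noiseless runs sitting at the root are converged, not empty
  at_root <- toy_linear_model(a = 0, noise_sd = 1e-12)
  cfg0 <- sa_config(n_iter = 500, schedule = step_schedule(0.1, 0.5),
                    sign = +1, init = 0)
  traces <- lapply(1:4, function(r)
    run_sa(at_root, "theta", "A", "B", cfg0, seed = r))
  expect_false(detect_divergence(traces))
  expect_error(detect_divergence(traces[1]), "length")
})

test_that("averaged iterates converge at the canonical 1/sqrt(t) rate", {
  # linear-Gaussian toy, 40 independent runs: the log-log slope of the
  # RMSE of the averaged iterate against t is -0.5 +/- 0.1
  m <- toy_linear_model(a = 0, noise_sd = 1, theta_mean = 0, theta_var = 1)
  cfg <- sa_config(n_iter = 4096, schedule = step_schedule(0.5, 0.5),
                   sign = +1)
  pr <- estimate_pairwise_roots(m, "theta", "A", "B", n_runs = 40,
                                config = cfg, seed = 414,
                                keep_traces = TRUE)
  cps <- 2^(8:12)
  rmse <- vapply(cps, function(t)
    sqrt(mean(vapply(pr$traces, function(tr) tr$averaged[t]^2, 1))), 1)
  slope <- coef(lm(log(rmse) ~ log(cps)))[2]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("slowly decaying steps without averaging are flagged", {
  m <- toy_linear_model()
  cfg <- sa_config(n_iter = 50, schedule = step_schedule(0.5, 0.5),
                   sign = +1, averaging = FALSE)
  expect_warning(run_sa(m, "theta", "A", "B", cfg, seed = 1),
                 "summable")
})
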