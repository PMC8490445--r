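# Small analytic toy models used across the suite.  Every toy has a known
# conditional-difference structure so expected roots, signs and sensitivity
# values come from closed form, independent of the estimators under test.

# Two options with E[f_A - f_B | theta] = theta - a (linear-Gaussian toy):
# f_A = theta + eps, f_B = a, eps ~ N(0, noise_sd^2).
toy_linear_model <- function(a = 0.5, noise_sd = 1, theta_mean = 0,
                             theta_var = 1) {
  decision_model(
    options = c("A", "B"),
    variables = list(
      marginal_spec("theta", "normal", c(mean = theta_mean, var = theta_var)),
      marginal_spec("eps", "normal", c(mean = 0, var = noise_sd^2))
    ),
    utility = function(option, th, cst)
      switch(option, A = th$theta + th$eps, B = rep(cst$a, length(th$eps))),
    constants = list(a = a)
  )
}

# Mirrored toy: E[f_A - f_B | theta] = a - theta (decreasing crossing).
toy_mirror_model <- function(a = 0.5, noise_sd = 1) {
  decision_model(
    options = c("A", "B"),
    variables = list(
      marginal_spec("theta", "normal", c(mean = 0, var = 1)),
      marginal_spec("eps", "normal", c(mean = 0, var = noise_sd^2))
    ),
    utility = function(option, th, cst)
      switch(option, A = -th$theta + th$eps, B = rep(-cst$a, length(th$eps))),
    constants = list(a = a)
  )
}

# Two-root toy: E[f_A - f_B | theta] = theta^3 - theta, increasing crossings
# at -1 and +1 (attracting under the standard recursion), decreasing at 0
# (repelling).  Marginal N(0, 1.44) straddles both basins while keeping the
# cubic's growth inside the stable-step region of the recursion.
toy_cubic_model <- function(noise_sd = 0.3) {
  decision_model(
    options = c("A", "B"),
    variables = list(
      marginal_spec("theta", "normal", c(mean = 0, var = 1.44)),
      marginal_spec("eps", "normal", c(mean = 0, var = noise_sd^2))
    ),
    utility = function(option, th, cst)
      switch(option, A = th$theta^3 - th$theta + th$eps,
             B = rep(0, length(th$eps)))
  )
}

# Three options with linear conditional differences and analytically placed
# roots: E[f_d1|th]=0, E[f_d2|th]=th-1, E[f_d3|th]=2 th-3.  Pairwise roots at
# 1 (d1,d2), 1.5 (d1,d3), 2 (d2,d3); the true threshold set is {1, 2} with
# optimal options d1 | d2 | d3 and the 1.5 candidate dominated by d2.  With
# theta ~ N(1.5, 1) the prior optimum is d2 and the decision switching
# probability is 2 * pnorm(-0.5).
toy_three_option_model <- function(noise_sd = 0.5) {
  decision_model(
    options = c("d1", "d2", "d3"),
    variables = list(
      marginal_spec("theta", "normal", c(mean = 1.5, var = 1)),
      marginal_spec("e1", "normal", c(mean = 0, var = noise_sd^2)),
      marginal_spec("e2", "normal", c(mean = 0, var = noise_sd^2)),
      marginal_spec("e3", "normal", c(mean = 0, var = noise_sd^2))
    ),
    utility = function(option, th, cst)
      switch(option,
             d1 = th$e1,
             d2 = th$theta - 1 + th$e2,
             d3 = 2 * th$theta - 3 + th$e3)
  )
}

# Antisymmetric pair f_A = theta, f_B = -theta on a single input: EVPI has
# the closed form E|theta| and EVPPI for that input equals the EVPI.
toy_sign_model <- function(theta_mean = 0) {
  decision_model(
    options = c("A", "B"),
    variables = list(
      marginal_spec("theta", "normal", c(mean = theta_mean, var = 1))
    ),
    utility = function(option, th, cst)
      switch(option, A = th$theta, B = -th$theta)
  )
}

# One-variable shell used to exercise DSP with hand-built threshold sets.
toy_unit_normal_model <- function() {
  decision_model(
    options = c("d_a", "d_b"),
    variables = list(
      marginal_spec("x", "normal", c(mean = 0, var = 1))
    ),
    utility = function(option, th, cst)
      switch(option, d_a = rep(1, length(th$x)), d_b = rep(0, length(th$x)))
  )
}
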