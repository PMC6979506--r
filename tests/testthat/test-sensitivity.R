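test_that("the vec-permutation matrix transposes vectorizations and is an involution pair", {
  expect_equal(vec_permutation(1, 4), diag(4))
  X <- matrix(1:4, 2, 2)
  expect_equal(drop(vec_permutation(2, 2) %*% as.vector(X)), as.vector(t(X)))
  X2 <- matrix(rnorm(12), 3, 4)
  expect_equal(drop(vec_permutation(3, 4) %*% as.vector(X2)), as.vector(t(X2)))
  expect_equal(vec_permutation(3, 4) %*% vec_permutation(4, 3), diag(12))
})

test_that("a zero perturbation map yields zero sensitivities", {
  cs <- random_sensitivity_case(3, seed = 2)
  pm <- perturbation_map(theta = c(1, 2), tau = 3)
  sens <- moment_sensitivity(cs$chain, cs$rewards, pm)
  expect_equal(sens$d_rho[[1]], matrix(0, 3, 2))
  expect_equal(sens$d_rho[[2]], matrix(0, 3, 2))
})

test_that("analytic moment and statistic sensitivities match finite differences", {
  # stage-classified kinds over random stage-structured models
  kinds <- c("mu_stage", "sigma", "G_comp", "f_mean_fixed_var",
             "f_var_fixed_mean", "f_linked")
  for (seed in 1:6) {
    cs <- random_sensitivity_case(sample(2:4, 1), seed = 100 + seed)
    for (kind in kinds) {
      expect_lt(fd_worst_error(cs, kind), 1e-5)
    }
  }
  # age-classified mortality map under Bernoulli rewards
  for (seed in 1:3) {
    cs <- random_sensitivity_case(4, seed = 200 + seed, profile = "age_like",
                                  fertility_model = "bernoulli")
    expect_lt(fd_worst_error(cs, "mu_age"), 1e-5)
    expect_lt(fd_worst_error(cs, "f_linked"), 1e-5)
  }
})

test_that("first-moment sensitivity does not depend on higher reward moments", {
  cs <- random_sensitivity_case(3, seed = 31)
  pm <- stage_classified_pmap(cs$decomp, "mu")
  d1 <- moment_sensitivity(cs$chain, cs$rewards, pm)$d_rho[[1]]
  # swap in fixed higher moments: same R1, different R2
  rw2 <- reward_moments(fertility_schedule(cs$fert$f1, "fixed"), tau = 3,
                        order = 2)
  d1b <- moment_sensitivity(cs$chain, rw2, pm)$d_rho[[1]]
  expect_equal(d1, d1b, tolerance = 1e-14)
})

test_that("Crow-index derivative satisfies the chain rule with the CV derivative", {
  cs <- random_sensitivity_case(4, seed = 41)
  pm <- stage_classified_pmap(cs$decomp, "sigma")
  sens <- statistic_sensitivity(moment_sensitivity(cs$chain, cs$rewards, pm))
  st <- lro_statistics(sens$moments)
  expect_equal(sens$d_stats$crow_i, 2 * st$cv * sens$d_stats$cv,
               tolerance = 1e-12)
})

test_that("elasticities behave as log-derivatives", {
  # for an output proportional to one parameter the elasticity is exactly 1
  theta <- c(2, 5)
  value <- 3 * theta[2]
  dvalue <- matrix(c(0, 3), 1, 2)
  expect_equal(elasticity(value, dvalue, theta), matrix(c(0, 1), 1, 2))
  # zero parameters give zero elasticity columns; nonpositive outputs NaN
  E <- elasticity(c(1, 0), matrix(1, 2, 3), c(1, 0, 2))
  expect_equal(E[, 2], c(0, 0))
  expect_true(all(is.nan(E[2, c(1, 3)])))
})

test_that("elasticity of mean LRO to fertility sums to one (degree-1 homogeneity)", {
  for (seed in c(3, 17)) {
    cs <- random_sensitivity_case(4, seed = seed)
    pm <- fertility_pmap(cs$fert, 4, "linked")
    sens <- moment_sensitivity(cs$chain, cs$rewards, pm)
    E <- elasticity(sens$moments$rho[[1]], sens$d_rho[[1]], pm$theta)
    expect_equal(rowSums(E), rep(1, 4), tolerance = 1e-10)
  }
  tsuga <- tsuga_model()
  rw <- reward_moments(tsuga$fertility, tau = 6, order = 2)
  pm <- fertility_pmap(tsuga$fertility, 6, "linked")
  sens <- moment_sensitivity(build_markov_chain(tsuga), rw, pm)
  E <- elasticity(sens$moments$rho[[1]], sens$d_rho[[1]], pm$theta)
  expect_equal(rowSums(E), rep(1, 6), tolerance = 1e-10)
  # positive elasticity to fertility in the reproductive classes
  expect_true(all(E[1, 3:6] > 0))
})

test_that("age-classified mortality map has the subdiagonal derivative structure", {
  mu <- c(0.2, 0.1, 0.3, 0.25)
  f <- c(0, 0.4, 0.5, 0.1)
  m <- age_classified_model(mu, f)
  pm <- age_classified_pmap(m, "mu")
  for (x in 1:3) {
    col <- matrix(pm$dU[, x], 4, 4)
    expect_equal(col[x + 1, x], -exp(-mu[x]))
    col[x + 1, x] <- 0
    expect_equal(col, matrix(0, 4, 4))
  }
  expect_equal(pm$dU[, 4], rep(0, 16))  # no survival out of the last age
})

test_that("human-like schedules show the expected sensitivity signs", {
  set.seed(77)
  omega <- 12
  mu <- 0.02 + 0.12 * ((1:omega) / omega)^2
  f <- 0.4 * exp(-((1:omega) - 6)^2 / 8)   # reproduction ends well before omega
  m <- age_classified_model(mu, fertility_schedule(f, "bernoulli"))
  rw <- reward_moments(m$fertility, tau = omega, order = 2)
  ch <- build_markov_chain(m)
  sens_mu <- statistic_sensitivity(
    moment_sensitivity(ch, rw, age_classified_pmap(m, "mu")))
  # increased mortality before the end of reproduction reduces mean LRO
  expect_true(all(sens_mu$d_stats$mean[1, 1:9] <= 0))
  sens_f <- statistic_sensitivity(
    moment_sensitivity(ch, rw, age_classified_pmap(m, "f")))
  # increased fertility raises mean LRO but lowers the opportunity for selection
  reproductive <- which(f > 0.01)
  expect_true(all(sens_f$d_stats$mean[1, reproductive] > 0))
  expect_true(all(sens_f$d_stats$crow_i[1, reproductive] < 0))
})

test_that("compensated growth directions preserve column sums and match the 2x2 closed form", {
  cs <- random_sensitivity_case(4, seed = 55)
  pm <- compensated_growth_pmap(cs$decomp)
  # dU direction = sigma_j * dG direction, so each dG column must sum to 0
  for (q in seq_len(ncol(pm$dU))) {
    j <- (q - 1) %/% 4 + 1
    dG <- matrix(pm$dU[, q], 4, 4) / cs$decomp$sigma[j]
    expect_lt(abs(sum(dG)), 1e-12)
  }
  # two stages: compensating g21 loads the whole change on g11
  G <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2)
  d <- decompose_stage_model(sweep(G, 2, c(0.9, 0.8), "*"), c(0.9, 0.8))
  pm2 <- compensated_growth_pmap(d)
  dG21 <- matrix(pm2$dU[, 2], 2, 2) / 0.9   # parameter g_21
  expect_equal(dG21[, 1], c(-0.7 / 0.7, 1))
  expect_equal(dG21[, 2], c(0, 0))
})

test_that("Tsuga elasticities reproduce the qualitative size-class pattern", {
  tsuga <- tsuga_model()
  fert <- tsuga$fertility
  rw <- reward_moments(fert, tau = 6, order = 2)
  ch <- build_markov_chain(tsuga)
  dec <- decompose_stage_model(tsuga$U)
  mom <- lro_moment_vectors(ch, rw)
  st <- lro_statistics(mom)

  sens_mu <- statistic_sensitivity(
    moment_sensitivity(ch, rw, stage_classified_pmap(dec, "mu")))
  E_mean <- elasticity(st$mean, sens_mu$d_stats$mean, dec$mu)
  E_var <- elasticity(st$variance, sens_mu$d_stats$variance, dec$mu)
  # elasticity of mean and variance of LRO to mortality negative in all classes
  expect_true(all(E_mean[1, ] < 0))
  expect_true(all(E_var[1, ] < 0))

  pmG <- compensated_growth_pmap(dec)
  sensG <- statistic_sensitivity(moment_sensitivity(ch, rw, pmG))
  EG <- elasticity(st$mean, sensG$d_stats$mean, pmG$theta)
  stasis <- (1:6 - 1) * 6 + 1:6
  # elasticity of mean LRO to stasis negative for classes 1-5, positive for 6
  expect_true(all(EG[1, stasis[1:5]] < 0))
  expect_gt(EG[1, stasis[6]], 0)
})

test_that("variance-fixed-mean fertility perturbations leave the mean untouched", {
  cs <- random_sensitivity_case(3, seed = 61)
  pm <- fertility_pmap(cs$fert, 3, "variance_fixed_mean")
  sens <- moment_sensitivity(cs$chain, cs$rewards, pm)
  expect_equal(sens$d_rho[[1]], matrix(0, 3, 3))
  expect_error(
    fertility_pmap(fertility_schedule(c(0.5, 0.5, 0.5), "bernoulli"), 3,
                   "variance_fixed_mean"),
    "not independent under Bernoulli")
  # orders beyond the map's support are refused, not silently zeroed
  rw3 <- reward_moments(cs$fert, tau = 3, order = 3)
  expect_error(moment_sensitivity(cs$chain, rw3, pm, order = 3),
               "perturbation map incomplete")
})
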