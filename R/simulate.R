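#' Simulate individual life trajectories and their reproductive output
#'
#' Individual-based Monte-Carlo companion to the closed-form results: each
#' individual starts in `start_stage`, draws a reproductive reward from its
#' current stage's fertility distribution at every time step (including the
#' dying step, unless the schedule requires parental survival), then moves
#' according to the corresponding column of the chain's transition matrix,
#' until absorption. Per-individual totals, lifespans, and the
#' path-conditional mean and variance of LRO (computed exactly from stage
#' visit counts, not by nested simulation) are recorded.
#'
#' Supported reward distributions: `bernoulli`, `poisson`, `fixed`, and
#' `empirical` with two raw moments, sampled as the two-point distribution
#' on \{0, f2/f1\} matching them.
#'
#' @param model an [lro_model()] with a fertility schedule.
#' @param fertility optional [fertility_schedule()] overriding the model's.
#' @param n number of individuals.
#' @param seed RNG seed (set for reproducibility; `NULL` leaves the RNG
#'   state alone).
#' @param start_stage starting stage for all individuals (default 1, birth).
#' @param max_steps safety cap on trajectory length.
#' @return object of class `trajectory_sample` with numeric vectors `lro`,
#'   `lifespan`, `path_mean`, `path_var` (each length n) plus `n`, `seed`,
#'   `start_stage`.
#' @export
#' @examples
#' m <- lro_model(matrix(0.5), fertility_schedule(0.4))
#' ts <- simulate_trajectories(m, n = 1000, seed = 1)
#' mean(ts$lro)
simulate_trajectories <- function(model, fertility = NULL, n, seed = NULL,
                                  start_stage = 1L, max_steps = 1e6L) {
  stopifnot(inherits(model, "lro_model"))
  fert <- if (!is.null(fertility)) fertility else model$fertility
  if (is.null(fert)) stop("a fertility schedule is required")
  if (fert$model == "empirical" && is.null(fert$f2)) {
    stop("cannot sample: supply a sampler or second moments")
  }
  if (!is.null(seed)) set.seed(seed)
  chain <- build_markov_chain(model)
  tau <- chain$tau
  s <- chain$s
  f1 <- fert$f1
  vf <- fertility_variance(fert)
  # two-point support for empirical rewards: {0, c} with P(c) = q
  if (fert$model == "empirical") {
    cc <- ifelse(f1 > 0, fert$f2 / f1, 0)
    qq <- ifelse(cc > 0, f1 / cc, 0)
    if (any(qq > 1 + 1e-12)) stop("cannot sample: moments admit no two-point distribution")
    qq <- pmin(qq, 1)
  }
  draw_reward <- function(stage, k) {
    switch(fert$model,
      bernoulli = stats::rbinom(k, 1L, f1[stage]),
      poisson = stats::rpois(k, f1[stage]),
      fixed = rep(f1[stage], k),
      empirical = cc[stage] * stats::rbinom(k, 1L, qq[stage])
    )
  }
  state <- rep.int(as.integer(start_stage), n)
  lro <- numeric(n)
  path_mean <- numeric(n)
  path_var <- numeric(n)
  lifespan <- integer(n)
  alive <- seq_len(n)
  rps <- fert$require_parental_survival
  step <- 0L
  while (length(alive) && step < max_steps) {
    step <- step + 1L
    st <- state[alive]
    dest <- integer(length(alive))
    reward <- numeric(length(alive))
    counted <- rep(TRUE, length(alive))
    for (j in unique(st)) {
      sel <- which(st == j)
      dest[sel] <- sample.int(s, length(sel), replace = TRUE, prob = chain$P[, j])
      reward[sel] <- draw_reward(j, length(sel))
    }
    if (rps) counted <- dest <= tau
    idx <- alive
    lro[idx] <- lro[idx] + ifelse(counted, reward, 0)
    path_mean[idx] <- path_mean[idx] + ifelse(counted, f1[st], 0)
    path_var[idx] <- path_var[idx] + ifelse(counted, vf[st], 0)
    lifespan[idx] <- lifespan[idx] + 1L
    state[idx] <- dest
    alive <- idx[dest <= tau]
  }
  if (length(alive)) stop("simulation exceeded max_steps before absorption")
  structure(
    list(lro = lro, lifespan = lifespan, path_mean = path_mean,
         path_var = path_var, n = n, seed = seed,
         start_stage = as.integer(start_stage)),
    class = "trajectory_sample"
  )
}

#' @export
print.trajectory_sample <- function(x, ...) {
  cat(sprintf("<trajectory_sample> n = %d from stage %d: mean LRO %.4g, var %.4g, mean lifespan %.4g\n",
              x$n, x$start_stage, mean(x$lro), stats::var(x$lro), mean(x$lifespan)))
  invisible(x)
}

#' Sample raw moments of LRO with Monte-Carlo standard errors
#'
#' @param sample a [simulate_trajectories()] result.
#' @param orders moment orders to report.
#' @return data frame with columns `order`, `moment`, `se`.
#' @export
sample_moments <- function(sample, orders = 1:3) {
  stopifnot(inherits(sample, "trajectory_sample"))
  res <- lapply(orders, function(k) {
    xk <- sample$lro^k
    data.frame(order = k, moment = mean(xk),
               se = stats::sd(xk) / sqrt(sample$n))
  })
  do.call(rbind, res)
}

#' Estimate the within/between-pathway variance partition from trajectories
#'
#' Between-pathway variance is estimated as the variance of the
#' path-conditional means (stage visit counts times stage mean fertility),
#' within-pathway variance as the mean of the path-conditional variances;
#' conditional on a path, the per-step rewards are independent, so both are
#' exact given the sampled paths.
#'
#' @param sample a [simulate_trajectories()] result.
#' @return list with `v_total`, `v_between`, `v_within`, `pct_between`,
#'   `pct_within`, and standard errors `se_between`, `se_within`.
#' @export
sample_partition <- function(sample) {
  stopifnot(inherits(sample, "trajectory_sample"))
  v_total <- stats::var(sample$lro)
  v_between <- stats::var(sample$path_mean)
  v_within <- mean(sample$path_var)
  n <- sample$n
  # SE of a sample variance via fourth central moment; SE of a mean directly
  m <- mean(sample$path_mean)
  mu4 <- mean((sample$path_mean - m)^4)
  se_between <- sqrt(pmax(mu4 - v_between^2, 0) / n)
  se_within <- stats::sd(sample$path_var) / sqrt(n)
  list(
    v_total = v_total, v_between = v_between, v_within = v_within,
    pct_between = 100 * v_between / v_total,
    pct_within = 100 * v_within / v_total,
    se_between = se_between, se_within = se_within
  )
}
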