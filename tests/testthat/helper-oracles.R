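# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: series summation instead of matrix inversion,
# enumeration over the lifetime distribution instead of the moment
# recursion, and central finite differences of the full rebuilt pipeline
# instead of the analytic derivative machinery.

# Fundamental matrix by truncated Neumann series sum_k U^k.
neumann_series <- function(U, tol = 1e-14, max_terms = 1e5) {
  acc <- diag(nrow(U))
  term <- diag(nrow(U))
  for (k in seq_len(max_terms)) {
    term <- term %*% U
    acc <- acc + term
    if (max(abs(term)) < tol) return(acc)
  }
  stop("Neumann series did not converge")
}

# Single transient stage with survival p: the lifespan T (number of
# transitions, including the dying one) is geometric, P(T = t) = p^(t-1)(1-p).
# Conditional on T, LRO is a sum of T iid per-step rewards. Enumerates T and
# accumulates raw moments 1-3 and the conditional-variance partition.
single_stage_oracle <- function(p, phi, model = c("bernoulli", "poisson", "fixed")) {
  model <- match.arg(model)
  t_max <- max(50, ceiling(-45 / log(max(p, 1e-12))))
  per_mean <- phi
  per_var <- switch(model, bernoulli = phi * (1 - phi), poisson = phi, fixed = 0)
  per_mu3 <- switch(model,
    bernoulli = phi * (1 - phi) * (1 - 2 * phi),
    poisson = phi,
    fixed = 0
  )
  m1 <- m2 <- m3 <- 0
  e_t <- e_t2 <- 0
  for (t in 1:t_max) {
    w <- p^(t - 1) * (1 - p)
    mu <- t * per_mean            # mean of a sum of t iid rewards
    v <- t * per_var
    mu3 <- t * per_mu3            # third central moment is additive for iid sums
    m1 <- m1 + w * mu
    m2 <- m2 + w * (v + mu^2)
    m3 <- m3 + w * (mu3 + 3 * mu * v + mu^3)
    e_t <- e_t + w * t
    e_t2 <- e_t2 + w * t^2
  }
  var_t <- e_t2 - e_t^2
  list(
    m1 = m1, m2 = m2, m3 = m3,
    mean = m1, variance = m2 - m1^2,
    v_between = per_mean^2 * var_t,   # Var(E[LRO | T])
    v_within = per_var * e_t          # E[Var(LRO | T)]
  )
}

# Statistics of LRO recomputed from scratch for a perturbed parameter
# vector; the workhorse of the finite-difference oracle. `kind` names the
# parameter set; `base` carries whatever the rebuild needs.
rebuild_outputs <- function(kind, theta, base) {
  fert <- base$fert
  U <- base$U
  if (kind == "mu_stage") {
    U <- sweep(base$G, 2L, exp(-theta), "*")
  } else if (kind == "sigma") {
    U <- sweep(base$G, 2L, theta, "*")
  } else if (kind == "mu_age") {
    omega <- length(theta)
    U <- matrix(0, omega, omega)
    if (omega > 1L) U[cbind(2:omega, 1:(omega - 1L))] <- exp(-theta[1:(omega - 1L)])
  } else if (kind == "G_comp") {
    G <- base$G
    q <- base$param_index
    j <- (q - 1L) %/% nrow(G) + 1L
    i <- (q - 1L) %% nrow(G) + 1L
    h <- theta[q] - base$G[i, j]
    newcol <- G[, j]
    if (G[i, j] < 1 - 1e-12) newcol <- newcol * (1 - h / (1 - G[i, j]))
    newcol[i] <- G[i, j] + h
    G[, j] <- newcol
    U <- sweep(G, 2L, base$sigma, "*")
  } else if (kind == "f_mean_fixed_var") {
    v <- fert$f2 - fert$f1^2
    fert <- fertility_schedule(theta, model = "empirical", f2 = v + theta^2,
                               require_parental_survival = fert$require_parental_survival)
  } else if (kind == "f_var_fixed_mean") {
    fert <- fertility_schedule(fert$f1, model = "empirical",
                               f2 = theta + fert$f1^2,
                               require_parental_survival = fert$require_parental_survival)
  } else if (kind == "f_linked") {
    fert <- fertility_schedule(theta, model = fert$model,
                               require_parental_survival = fert$require_parental_survival)
  } else {
    stop("unknown rebuild kind: ", kind)
  }
  model <- lro_model(U, fert)
  rw <- reward_moments(fert, tau = nrow(U), order = 2L)
  mom <- lro_moment_vectors(build_markov_chain(model), rw)
  st <- lro_statistics(mom)
  list(rho1 = mom$rho[[1L]], rho2 = mom$rho[[2L]],
       variance = st$variance, sd = st$sd, cv = st$cv, crow_i = st$crow_i)
}

# Finite differences of every output of rebuild_outputs with respect to
# theta: Richardson-extrapolated central differences,
# (4 D(h/2) - D(h)) / 3, with base step h ~ 2e-4. The larger base step keeps
# double-precision roundoff (eps |f| / h) far below the 1e-5 certification
# bar even for large-magnitude statistics such as Crow's index, and the
# extrapolation removes the O(h^2) truncation term that the larger step
# would otherwise introduce. Returns a list of tau x p matrices keyed by
# output name.
fd_pipeline <- function(kind, theta, base, h_scale = 2e-4) {
  p <- length(theta)
  if (is.null(base$param_index)) base$param_index <- 1L
  outs <- names(rebuild_outputs(kind, theta, base))
  grads <- NULL
  for (j in seq_len(p)) {
    bj <- base; bj$param_index <- j
    central <- function(h) {
      up <- theta; up[j] <- up[j] + h
      dn <- theta; dn[j] <- dn[j] - h
      fu <- rebuild_outputs(kind, up, bj)
      fd <- rebuild_outputs(kind, dn, bj)
      lapply(outs, function(nm) (fu[[nm]] - fd[[nm]]) / (2 * h))
    }
    # shrink the step if the perturbation leaves the feasible region
    # (probabilities above 1, negative compensated entries, ...)
    h <- h_scale * max(1, abs(theta[j]))
    d1 <- NULL
    for (try in 1:12) {
      d1 <- tryCatch(central(h), error = function(e) NULL)
      if (!is.null(d1)) break
      h <- h / 2
    }
    if (is.null(d1)) stop("could not find a feasible finite-difference step")
    d2 <- central(h / 2)
    col <- lapply(seq_along(outs), function(k) (4 * d2[[k]] - d1[[k]]) / 3)
    names(col) <- outs
    if (is.null(grads)) {
      grads <- lapply(col, function(x) matrix(NA_real_, length(x), p))
    }
    for (nm in outs) grads[[nm]][, j] <- col[[nm]]
  }
  grads
}

# Largest relative discrepancy with an absolute floor.
max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# One random model plus everything the sensitivity suite needs.
random_sensitivity_case <- function(tau, seed, profile = "stage_like",
                                    fertility_model = "poisson") {
  model <- generate_synthetic_model(tau, seed = seed, profile = profile,
                                    fertility_model = fertility_model)
  fert <- model$fertility
  chain <- build_markov_chain(model)
  rewards <- reward_moments(fert, tau = model$tau, order = 2L)
  list(model = model, fert = fert, chain = chain, rewards = rewards,
       decomp = if (profile == "stage_like") decompose_stage_model(model$U))
}

# Analytic statistic derivatives for a model/pmap pair, as a named list
# aligned with rebuild_outputs().
analytic_stat_derivs <- function(chain, rewards, pmap) {
  sens <- statistic_sensitivity(moment_sensitivity(chain, rewards, pmap, order = 2L))
  list(rho1 = sens$d_rho[[1L]], rho2 = sens$d_rho[[2L]],
       variance = sens$d_stats$variance, sd = sens$d_stats$sd,
       cv = sens$d_stats$cv, crow_i = sens$d_stats$crow_i)
}

# Runs the full FD comparison for one case and one perturbation kind;
# returns the worst relative error across all outputs.
fd_worst_error <- function(case, kind) {
  fert <- case$fert
  tau <- case$model$tau
  base <- list(U = case$model$U, fert = fert)
  if (!is.null(case$decomp)) {
    base$G <- case$decomp$G
    base$sigma <- case$decomp$sigma
  }
  emp <- function(f) {
    v <- fertility_variance(f)
    fertility_schedule(f$f1, model = "empirical", f2 = v + f$f1^2,
                       require_parental_survival = f$require_parental_survival)
  }
  if (kind == "mu_stage") {
    pmap <- stage_classified_pmap(case$decomp, "mu")
    theta <- case$decomp$mu
  } else if (kind == "sigma") {
    pmap <- stage_classified_pmap(case$decomp, "sigma")
    theta <- case$decomp$sigma
  } else if (kind == "mu_age") {
    pmap <- age_classified_pmap(case$model, "mu")
    theta <- attr(case$model, "schedule")$mu
  } else if (kind == "G_comp") {
    pmap <- compensated_growth_pmap(case$decomp)
    theta <- as.vector(case$decomp$G)
  } else if (kind == "f_mean_fixed_var") {
    pmap <- fertility_pmap(fert, tau, "mean_fixed_variance")
    theta <- fert$f1
    base$fert <- emp(fert)
  } else if (kind == "f_var_fixed_mean") {
    pmap <- fertility_pmap(fert, tau, "variance_fixed_mean")
    theta <- fertility_variance(fert)
    base$fert <- emp(fert)
  } else if (kind == "f_linked") {
    pmap <- fertility_pmap(fert, tau, "linked")
    theta <- fert$f1
  }
  ana <- analytic_stat_derivs(case$chain, case$rewards, pmap)
  fd <- fd_pipeline(kind, theta, base)
  max(vapply(names(ana), function(nm) max_rel_err(ana[[nm]], fd[[nm]]),
             numeric(1L)))
}
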