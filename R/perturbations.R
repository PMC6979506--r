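#' Perturbation maps for age-classified schedules
#'
#' For an age-classified model under Bernoulli reproduction, builds the
#' derivative structures for either the mortality hazards (`wrt = "mu"`) or
#' the age-specific fertility probabilities (`wrt = "f"`).
#'
#' Mortality: perturbing `mu[x]` changes only the entries of column x of `U`
#' (the survival `exp(-mu[x])`), so `d U[, x] / d mu[x] = -U[, x]`; the
#' reward matrices are unaffected. Fertility: `U` is unaffected and, because
#' all Bernoulli raw moments equal the mean, every `d vec R_i / d f^T` equals
#' the same 0/1 broadcasting matrix.
#'
#' @param model an [age_classified_model()] (carries its schedule), with a
#'   Bernoulli fertility schedule.
#' @param wrt `"mu"` or `"f"`.
#' @return a [perturbation_map()].
#' @export
age_classified_pmap <- function(model, wrt = c("mu", "f")) {
  wrt <- match.arg(wrt)
  stopifnot(inherits(model, "lro_model"))
  sched <- attr(model, "schedule")
  if (is.null(sched)) stop("model carries no age schedule; use age_classified_model()")
  if (is.null(model$fertility) || model$fertility$model != "bernoulli") {
    stop("age-classified perturbation maps assume Bernoulli fertility")
  }
  tau <- model$tau
  s <- tau + model$alpha
  if (wrt == "mu") {
    dU <- matrix(0, tau^2, tau)
    for (x in 1:tau) dU[(x - 1L) * tau + (1:tau), x] <- -model$U[, x]
    perturbation_map(theta = sched$mu, dU = dU, labels = paste0("mu_", 1:tau),
                     tau = tau, alpha = model$alpha, max_order = 3L)
  } else {
    B <- broadcast_fertility_derivative(tau, model$alpha,
                                        model$fertility$require_parental_survival)
    perturbation_map(theta = sched$f, dR = list(B, B, B),
                     labels = paste0("f_", 1:tau),
                     tau = tau, alpha = model$alpha, max_order = 3L)
  }
}

# d vec R / d f^T for R = 1_s (f^T | 0): column j is 1 on the vec positions
# of column j of R (all s destination rows), i.e. (Z^T (x) 1_s); with the
# parental-survival flag the absorbing-destination rows stay zero.
broadcast_fertility_derivative <- function(tau, alpha, require_parental_survival) {
  s <- tau + alpha
  B <- matrix(0, s^2, tau)
  rows <- if (require_parental_survival) 1:tau else 1:s
  for (j in 1:tau) B[(j - 1L) * s + rows, j] <- 1
  B
}

#' Perturbation maps for survival in stage-classified models
#'
#' Using the decomposition `U = G Sigma`, the derivative of `U` with respect
#' to stage survival is `d U[, j] / d sigma[j] = G[, j]`; with respect to the
#' stage mortality hazard (`sigma = exp(-mu)`) it is `-sigma[j] G[, j]`.
#' Rewards are unaffected.
#'
#' @param decomp a [decompose_stage_model()] result.
#' @param wrt `"sigma"` or `"mu"`.
#' @return a [perturbation_map()].
#' @export
stage_classified_pmap <- function(decomp, wrt = c("sigma", "mu")) {
  wrt <- match.arg(wrt)
  stopifnot(inherits(decomp, "stage_decomposition"))
  tau <- decomp$tau
  dU <- matrix(0, tau^2, tau)
  for (j in 1:tau) {
    dU[(j - 1L) * tau + (1:tau), j] <-
      if (wrt == "sigma") decomp$G[, j] else -decomp$sigma[j] * decomp$G[, j]
  }
  theta <- if (wrt == "sigma") decomp$sigma else decomp$mu
  perturbation_map(theta = theta, dU = dU,
                   labels = paste0(wrt, "_", 1:tau), tau = tau,
                   alpha = 1L, max_order = 3L)
}

#' Compensated perturbations of the conditional growth matrix
#'
#' The growth matrix `G` is column-stochastic, so an entry g_ij cannot be
#' perturbed alone: the other entries of column j must absorb the change.
#' This map perturbs each entry while reducing the remaining entries of its
#' column proportionally to their size, which keeps every column sum equal
#' to 1 to first order:
#' `d g_kj / d theta_ij = 1` for `k = i` and `-g_kj / (1 - g_ij)` otherwise.
#' The resulting direction is scaled by `sigma[j]` to act on `U = G Sigma`.
#'
#' The parameter vector is `vec(G)` (tau^2 entries, column-major). When the
#' perturbed entry itself equals 1, the rest of its column is zero and there
#' is nothing to compensate with; the direction is then the plain unit
#' perturbation (the proportional-compensation limit, since every would-be
#' compensating entry has weight 0).
#'
#' @param decomp a [decompose_stage_model()] result.
#' @return a [perturbation_map()] with `theta = vec(G)`.
#' @export
compensated_growth_pmap <- function(decomp) {
  stopifnot(inherits(decomp, "stage_decomposition"))
  tau <- decomp$tau
  G <- decomp$G
  dU <- matrix(0, tau^2, tau^2)
  labels <- character(tau^2)
  for (j in 1:tau) {
    for (i in 1:tau) {
      q <- (j - 1L) * tau + i
      dir <- if (G[i, j] >= 1 - 1e-12) rep(0, tau) else -G[, j] / (1 - G[i, j])
      dir[i] <- 1
      dU[(j - 1L) * tau + (1:tau), q] <- decomp$sigma[j] * dir
      labels[q] <- sprintf("g_%d%d", i, j)
    }
  }
  perturbation_map(theta = as.vector(G), dU = dU, labels = labels,
                   tau = tau, alpha = 1L, max_order = 3L)
}

#' Perturbation maps for the moments of stage-specific fertility
#'
#' Three views of fertility perturbation:
#' * `"mean_fixed_variance"` — theta is the mean fertility `f1`, with the
#'   per-stage variance held fixed, so the second raw moment co-varies as
#'   `d f2 = 2 f1 d f1`. Supports moment orders 1-2.
#' * `"variance_fixed_mean"` — theta is the per-stage variance `v`, with the
#'   mean held fixed: `d R1 = 0` and `d f2 = d v`. Supports orders 1-2.
#'   (Not available for Bernoulli fertility, whose moments are not
#'   independent.)
#' * `"linked"` — theta is the mean `f1` and the higher moments follow the
#'   parametric model (Poisson or Bernoulli), including order 3.
#'
#' The transition matrix is unaffected (`dU = 0`) in all modes.
#'
#' @param fert a [fertility_schedule()].
#' @param tau number of transient stages; `alpha` absorbing states.
#' @param mode one of the three modes above.
#' @param alpha number of absorbing states.
#' @return a [perturbation_map()].
#' @export
fertility_pmap <- function(fert, tau,
                           mode = c("mean_fixed_variance", "variance_fixed_mean",
                                    "linked"),
                           alpha = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(fert, "fertility_schedule"))
  if (length(fert$f1) != tau) stop("shape error: fertility length must equal tau")
  s <- tau + alpha
  B <- broadcast_fertility_derivative(tau, alpha, fert$require_parental_survival)
  f1 <- fert$f1
  if (mode == "mean_fixed_variance") {
    dR1 <- B
    dR2 <- sweep(B, 2L, 2 * f1, "*")
    perturbation_map(theta = f1, dR = list(dR1, dR2),
                     labels = paste0("f1_", 1:tau), tau = tau, alpha = alpha,
                     max_order = 2L)
  } else if (mode == "variance_fixed_mean") {
    if (fert$model == "bernoulli") {
      stop("moments not independent under Bernoulli")
    }
    v <- fertility_variance(fert)
    perturbation_map(theta = v, dR = list(NULL, B),
                     labels = paste0("v_", 1:tau), tau = tau, alpha = alpha,
                     max_order = 2L)
  } else {
    R1 <- rewards_from_fertility_vector(f1, s, fert$require_parental_survival)
    vR1 <- as.vector(R1)
    if (fert$model == "poisson") {
      dR1 <- B
      dR2 <- B + 2 * vR1 * B
      dR3 <- B + 6 * vR1 * B + 3 * vR1^2 * B
    } else if (fert$model == "bernoulli") {
      dR1 <- dR2 <- dR3 <- B
    } else {
      stop("linked mode requires a poisson or bernoulli fertility model")
    }
    perturbation_map(theta = f1, dR = list(dR1, dR2, dR3),
                     labels = paste0("f_", 1:tau), tau = tau, alpha = alpha,
                     max_order = 3L)
  }
}
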