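#' lrostats: statistics of lifetime reproductive output from matrix models
#'
#' Markov chains with rewards for age- and stage-classified matrix population
#' models: exact moments of lifetime reproductive output (LRO), variability
#' statistics including Crow's opportunity for selection, the within/between
#' pathway variance partition, and analytic sensitivity and elasticity of all
#' of these to mortality, transitions, and fertility moments.
#'
#' Stages are labelled 1..tau in all user-facing output; death is one (or
#' more) absorbing state(s) appended after the transient stages.
#'
#' @keywords internal
"_PACKAGE"

.SPECTRAL_TOL <- 1e-10

spectral_radius <- function(U) {
  if (nrow(U) == 1L) return(abs(U[1L, 1L]))
  max(Mod(eigen(U, only.values = TRUE)$values))
}

#' Construct a life-cycle model
#'
#' Bundles the transient transition matrix `U` (tau x tau, column j holds the
#' probabilities of moving from stage j to each stage over one time step) with
#' a fertility specification into a validated model object. The chain must be
#' absorbing: every individual eventually dies, i.e. the spectral radius of
#' `U` is strictly less than 1.
#'
#' @param U square numeric matrix of transition probabilities among transient
#'   (living) stages; entries in \[0, 1\], column sums at most 1.
#' @param fertility a [fertility_schedule()], or a numeric vector of
#'   stage-specific mean fertilities (converted with the Bernoulli model), or
#'   `NULL` for a purely survival-based model.
#' @param alpha number of absorbing states (default 1, death).
#' @param M optional `alpha x tau` matrix of absorption probabilities;
#'   required when `alpha > 1`, derived as `1 - colSums(U)` when `alpha = 1`.
#' @param stage_labels optional character vector of stage names.
#'
#' @return an object of class `lro_model`.
#' @export
#' @examples
#' m <- lro_model(matrix(0.5), fertility = fertility_schedule(0.3))
#' life_expectancy(m)
lro_model <- function(U, fertility = NULL, alpha = 1L, M = NULL,
                      stage_labels = NULL) {
  U <- as.matrix(U)
  if (nrow(U) != ncol(U)) stop("U must be square")
  if (!is.numeric(U) || anyNA(U)) stop("invalid transition matrix: non-numeric entries")
  tau <- nrow(U)
  if (any(U < 0) || any(U > 1)) stop("invalid transition matrix: entries outside [0, 1]")
  if (any(colSums(U) > 1 + 1e-12)) stop("invalid transition matrix: column sums > 1")
  if (spectral_radius(U) >= 1 - .SPECTRAL_TOL) stop("non-absorbing chain: spectral radius of U >= 1")
  alpha <- as.integer(alpha)
  if (alpha < 1L) stop("alpha must be at least 1")
  if (alpha > 1L) {
    if (is.null(M)) stop("M must be supplied when alpha > 1")
    M <- as.matrix(M)
    if (nrow(M) != alpha || ncol(M) != tau) stop("M must be alpha x tau")
    if (any(M < 0)) stop("invalid transition matrix: negative absorption probabilities")
    if (any(abs(colSums(U) + colSums(M) - 1) > 1e-8)) {
      stop("columns of rbind(U, M) must sum to 1")
    }
  }
  if (is.numeric(fertility) && is.null(dim(fertility))) {
    fertility <- fertility_schedule(fertility)
  }
  if (!is.null(fertility)) {
    stopifnot(inherits(fertility, "fertility_schedule"))
    if (length(fertility$f1) != tau) stop("fertility vector length must equal tau")
  }
  if (!is.null(stage_labels) && length(stage_labels) != tau) {
    stop("stage_labels length must equal tau")
  }
  structure(
    list(U = unname(U), tau = tau, alpha = alpha, M = M,
         fertility = fertility, stage_labels = stage_labels),
    class = "lro_model"
  )
}

#' @export
print.lro_model <- function(x, ...) {
  cat(sprintf("<lro_model> %d transient stage(s), %d absorbing state(s)\n",
              x$tau, x$alpha))
  if (!is.null(x$fertility)) {
    cat(sprintf("  fertility model: %s\n", x$fertility$model))
  }
  invisible(x)
}

#' Assemble the absorbing Markov chain for a life cycle
#'
#' Builds the full column-stochastic transition matrix
#' `P = rbind(cbind(U, 0), cbind(M, I))`, the mortality matrix `M`
#' (derived as `1 - colSums(U)` for a single absorbing state), the selection
#' matrix `Z = cbind(I, 0)` that picks out the transient states, and the
#' fundamental matrix `N = solve(I - U)`.
#'
#' @param model an [lro_model()].
#' @return an object of class `markov_chain` with elements `P`, `U`, `M`,
#'   `Z`, `N`, `tau`, `alpha`, `s`.
#' @export
#' @examples
#' ch <- build_markov_chain(lro_model(matrix(0.5)))
#' colSums(ch$P)
build_markov_chain <- function(model) {
  stopifnot(inherits(model, "lro_model"))
  tau <- model$tau
  alpha <- model$alpha
  s <- tau + alpha
  M <- if (alpha == 1L) {
    matrix(1 - colSums(model$U), nrow = 1L)
  } else {
    model$M
  }
  P <- rbind(
    cbind(model$U, matrix(0, tau, alpha)),
    cbind(M, diag(alpha))
  )
  Z <- cbind(diag(tau), matrix(0, tau, alpha))
  structure(
    list(P = P, U = model$U, M = M, Z = Z,
         N = fundamental_matrix(model),
         tau = tau, alpha = alpha, s = s,
         stage_labels = model$stage_labels),
    class = "markov_chain"
  )
}

#' @export
print.markov_chain <- function(x, ...) {
  cat(sprintf("<markov_chain> %d x %d, column-stochastic; tau = %d, alpha = %d\n",
              x$s, x$s, x$tau, x$alpha))
  invisible(x)
}

#' Fundamental matrix of the life cycle
#'
#' `N = solve(I - U)`; entry (i, j) is the expected number of time steps
#' spent in stage i by an individual currently in stage j, before death.
#' Computed by LU solves against the identity rather than by forming powers
#' of `U`.
#'
#' @param model an [lro_model()] or `markov_chain`, or a bare `U` matrix.
#' @return tau x tau numeric matrix.
#' @export
fundamental_matrix <- function(model) {
  U <- if (inherits(model, c("lro_model", "markov_chain"))) model$U else as.matrix(model)
  ImU <- diag(nrow(U)) - U
  N <- tryCatch(
    solve(ImU, diag(nrow(U))),
    error = function(e) stop("chain not absorbing within tolerance: ", conditionMessage(e))
  )
  if (kappa(ImU, exact = FALSE) > 1e14) {
    stop("chain not absorbing within tolerance: (I - U) is near-singular")
  }
  N
}

#' Life expectancy by starting stage
#'
#' Column sums of the fundamental matrix: expected remaining lifetime (in
#' time steps) for an individual in each stage.
#'
#' @inheritParams fundamental_matrix
#' @return numeric vector of length tau.
#' @export
life_expectancy <- function(model) {
  colSums(fundamental_matrix(model))
}

#' Build an age-classified model from mortality and fertility schedules
#'
#' Age-classified life cycles have survival probabilities
#' `p[x] = exp(-mu[x])` on the subdiagonal of `U` and zeros elsewhere: an
#' individual of age x either advances to age x + 1 or dies. By default the
#' last age class has no survival (the final column of `U` is zero, so death
#' is certain at the end of the schedule); with `open_ended = TRUE` the last
#' class is an open interval in which individuals remain with probability
#' `exp(-mu[omega])`.
#'
#' @param mu nonnegative vector of age-specific mortality hazards.
#' @param fertility age-specific mean fertility vector (same length as `mu`),
#'   or a [fertility_schedule()].
#' @param model fertility model used when `fertility` is a bare vector.
#' @param open_ended keep survivors in the final age class instead of
#'   imposing certain death at the end of the schedule.
#' @return an [lro_model()] carrying the schedule as attribute `"schedule"`
#'   (fields `mu`, `f`, `p`, `Y` where `Y` marks the nonzero structure of U).
#' @export
#' @examples
#' m <- age_classified_model(c(0.1, 0.2), c(0, 0.5))
#' m$U
age_classified_model <- function(mu, fertility, model = "bernoulli",
                                 open_ended = FALSE) {
  mu <- as.numeric(mu)
  if (any(mu < 0)) stop("mortality hazards must be nonnegative")
  fert <- if (inherits(fertility, "fertility_schedule")) fertility else
    fertility_schedule(fertility, model = model)
  omega <- length(mu)
  if (length(fert$f1) != omega) stop("ragged schedule: mu and fertility lengths differ")
  p <- exp(-mu)
  U <- matrix(0, omega, omega)
  if (omega > 1L) U[cbind(2:omega, 1:(omega - 1L))] <- p[1:(omega - 1L)]
  if (open_ended) {
    if (p[omega] >= 1 - .SPECTRAL_TOL) {
      stop("non-absorbing chain: open-ended final class with zero mortality")
    }
    U[omega, omega] <- p[omega]
  }
  out <- lro_model(U, fertility = fert)
  attr(out, "schedule") <- list(mu = mu, f = fert$f1, p = p, Y = (U > 0) * 1)
  out
}

#' Decompose a stage-classified transition matrix as U = G Sigma
#'
#' Factors `U` into a diagonal survival matrix `Sigma = diag(sigma)` and a
#' column-stochastic conditional transition ("growth") matrix `G`, with
#' `G[i, j] = U[i, j] / sigma[j]`. When `sigma` is not supplied it is
#' inferred as the column sums of `U` (the unique choice that makes `G`
#' column-stochastic). Stage mortality hazards are `mu = -log(sigma)`.
#'
#' For a stage j with `sigma[j] = 0` (and therefore a zero column of `U`),
#' `G[, j]` is set to the unit vector e_j; it is never reachable by a
#' surviving individual.
#'
#' @param U transient transition matrix.
#' @param sigma optional survival probability vector, entries in (0, 1\].
#' @return object of class `stage_decomposition` with `G`, `sigma`, `mu`, `U`.
#' @export
decompose_stage_model <- function(U, sigma = NULL) {
  U <- as.matrix(U)
  tau <- nrow(U)
  cs <- colSums(U)
  if (is.null(sigma)) sigma <- cs
  sigma <- as.numeric(sigma)
  if (length(sigma) != tau) stop("sigma length must equal tau")
  if (any(sigma < 0) || any(sigma > 1 + 1e-12)) stop("sigma entries must lie in [0, 1]")
  if (any(sigma == 0 & cs > 0)) {
    stop("inconsistent survival vector: sigma is zero where U has a nonzero column")
  }
  G <- U
  live <- sigma > 0
  G[, live] <- sweep(U[, live, drop = FALSE], 2L, sigma[live], "/")
  if (any(!live)) G[, !live] <- diag(tau)[, !live, drop = FALSE]
  if (any(abs(colSums(G) - 1) > 1e-8)) {
    stop("inconsistent survival vector: G is not column-stochastic")
  }
  structure(
    list(G = G, sigma = sigma, mu = -log(sigma), U = U, tau = tau),
    class = "stage_decomposition"
  )
}

#' @export
print.stage_decomposition <- function(x, ...) {
  cat(sprintf("<stage_decomposition> U = G Sigma, %d stages; sigma in [%.3g, %.3g]\n",
              x$tau, min(x$sigma), max(x$sigma)))
  invisible(x)
}
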