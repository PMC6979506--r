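#' Specify stage-specific fertility and its moments
#'
#' Describes per-time-step reproductive output by stage. The first moment
#' (mean fertility) `f1` is always required; higher moments come either from
#' a parametric assumption (`model`) or, for `model = "empirical"`, from the
#' supplied raw moments `f2` (and optionally `f3`).
#'
#' Models:
#' * `bernoulli` — at most one offspring per step; `f1` is the probability of
#'   reproducing, so all raw moments equal `f1`.
#' * `poisson` — offspring counts are Poisson with mean `f1`.
#' * `fixed` — every individual produces exactly `f1` offspring
#'   (zero within-stage variance); used to isolate between-pathway variance.
#' * `empirical` — raw moments supplied directly.
#'
#' @param f1 nonnegative vector of stage-specific mean fertility.
#' @param model one of `"bernoulli"`, `"poisson"`, `"fixed"`, `"empirical"`.
#' @param f2,f3 raw second/third moments per stage (empirical model only).
#' @param require_parental_survival if `TRUE`, no offspring are credited on
#'   the transition into death (the absorbing rows of the reward matrices are
#'   zeroed).
#' @return object of class `fertility_schedule`.
#' @export
fertility_schedule <- function(f1,
                               model = c("bernoulli", "poisson", "fixed", "empirical"),
                               f2 = NULL, f3 = NULL,
                               require_parental_survival = FALSE) {
  model <- match.arg(model)
  f1 <- as.numeric(f1)
  if (any(f1 < 0)) stop("invalid fertility: negative mean")
  if (model == "bernoulli" && any(f1 > 1)) {
    stop("Bernoulli requires probabilities: f1 entries must not exceed 1")
  }
  if (model == "empirical") {
    if (is.null(f2)) stop("empirical model requires the second raw moment f2")
    f2 <- as.numeric(f2)
    if (length(f2) != length(f1)) stop("f2 length must match f1")
    if (any(f2 < f1^2 - 1e-12)) stop("inconsistent moments: f2 < f1^2 (negative variance)")
    if (!is.null(f3)) {
      f3 <- as.numeric(f3)
      if (length(f3) != length(f1)) stop("f3 length must match f1")
    }
  } else if (!is.null(f2) || !is.null(f3)) {
    stop("f2/f3 are only accepted with model = \"empirical\"")
  }
  structure(
    list(f1 = f1, f2 = f2, f3 = f3, model = model,
         require_parental_survival = isTRUE(require_parental_survival)),
    class = "fertility_schedule"
  )
}

#' @export
print.fertility_schedule <- function(x, ...) {
  cat(sprintf("<fertility_schedule> model %s, %d stage(s), mean fertility in [%.3g, %.3g]%s\n",
              x$model, length(x$f1), min(x$f1), max(x$f1),
              if (x$require_parental_survival) ", parental survival required" else ""))
  invisible(x)
}

#' Stage-specific variance of per-step reproduction implied by a schedule
#' @param fert a [fertility_schedule()].
#' @return numeric vector of per-stage reward variances.
#' @export
fertility_variance <- function(fert) {
  switch(fert$model,
    bernoulli = fert$f1 * (1 - fert$f1),
    poisson = fert$f1,
    fixed = rep(0, length(fert$f1)),
    empirical = fert$f2 - fert$f1^2
  )
}

#' First-moment reward matrix from a stage-specific fertility vector
#'
#' Every row of `R1` equals the padded fertility vector `c(f1, rep(0, alpha))`:
#' the reward for a transition out of stage j is the fertility of stage j,
#' whatever the destination, and absorbed individuals accrue nothing. If
#' parental survival is required, the rows corresponding to absorbing
#' destinations are zeroed so that no reward is collected on the dying step.
#'
#' @param f1 stage-specific mean fertility (length tau).
#' @param s total number of states, tau + alpha.
#' @param require_parental_survival zero the absorbing-destination rows.
#' @return s x s matrix `R1`.
#' @export
rewards_from_fertility_vector <- function(f1, s, require_parental_survival = FALSE) {
  f1 <- as.numeric(f1)
  if (any(f1 < 0)) stop("invalid fertility: negative mean")
  tau <- length(f1)
  if (s <= tau) stop("s must exceed the number of transient stages")
  R1 <- matrix(rep(c(f1, rep(0, s - tau)), each = s), s, s)
  if (require_parental_survival) R1[(tau + 1L):s, ] <- 0
  R1
}

#' Higher reward moments under the Bernoulli model
#'
#' With at most one offspring per transition, every raw moment equals the
#' first: `R3 = R2 = R1`.
#' @param R1 first-moment reward matrix with entries in \[0, 1\].
#' @return list with `R2`, `R3`.
#' @export
bernoulli_moments <- function(R1) {
  if (any(R1 < 0) || any(R1 > 1)) stop("Bernoulli requires probabilities")
  list(R2 = R1, R3 = R1)
}

#' Higher reward moments under the Poisson model
#'
#' Raw Poisson moments: `R2 = R1 + R1^2` and `R3 = R1 + 3 R1^2 + R1^3`
#' (entrywise).
#' @param R1 nonnegative first-moment reward matrix.
#' @return list with `R2`, `R3`.
#' @export
poisson_moments <- function(R1) {
  if (any(R1 < 0)) stop("invalid fertility: negative mean")
  list(R2 = R1 + R1 * R1, R3 = R1 + 3 * R1 * R1 + R1 * R1 * R1)
}

#' Higher reward moments under fixed (degenerate) rewards
#'
#' Every individual produces exactly the mean: `R2 = R1^2`, `R3 = R1^3`
#' (entrywise), eliminating within-pathway fertility variance.
#' @param R1 nonnegative first-moment reward matrix.
#' @return list with `R2`, `R3`.
#' @export
fixed_moments <- function(R1) {
  if (any(R1 < 0)) stop("invalid fertility: negative mean")
  list(R2 = R1 * R1, R3 = R1 * R1 * R1)
}

transient_indices <- function(tau, s) {
  as.vector(outer(1:tau, (0:(tau - 1L)) * s, "+"))
}

#' Construct the reward-moment matrices for a life cycle
#'
#' Builds `R_1 ... R_m` (each s x s; the (i, j) entry of `R_k` is the k-th
#' raw moment of the reproductive reward on the transition j -> i) from a
#' fertility schedule, together with the transient submatrices
#' `Rtilde_k = Z R_k Z^T`.
#'
#' @param fert a [fertility_schedule()], or a list of raw s x s moment
#'   matrices supplied directly for transition-specific rewards.
#' @param tau number of transient stages.
#' @param alpha number of absorbing states.
#' @param order highest moment order m (default 3).
#' @return object of class `reward_moments` with elements `R` (list of
#'   matrices), `Rtilde`, `order`, `tau`, `alpha`, `s`, `model`.
#' @export
#' @examples
#' fert <- fertility_schedule(c(0, 2), model = "poisson")
#' rw <- reward_moments(fert, tau = 2)
#' rw$R[[2]]
reward_moments <- function(fert, tau, alpha = 1L, order = 3L) {
  s <- tau + alpha
  if (is.list(fert) && !inherits(fert, "fertility_schedule")) {
    R <- lapply(fert, function(x) {
      x <- as.matrix(x)
      if (!all(dim(x) == s)) stop("shape error: reward matrices must be s x s")
      if (any(x < 0)) stop("invalid fertility: negative reward moments")
      x
    })
    if (length(R) < 2L) stop("supply at least the first two moment matrices")
    for (k in 2:length(R)) {
      if (any(R[[k]] < R[[1L]]^k - 1e-9)) stop("inconsistent moments: Jensen violation")
    }
    model <- "matrix"
    rps <- FALSE
    order <- length(R)
  } else {
    stopifnot(inherits(fert, "fertility_schedule"))
    if (length(fert$f1) != tau) stop("shape error: fertility length must equal tau")
    if (order < 1L) stop("order must be at least 1")
    rps <- fert$require_parental_survival
    R1 <- rewards_from_fertility_vector(fert$f1, s, rps)
    hi <- switch(fert$model,
      bernoulli = bernoulli_moments(R1),
      poisson = poisson_moments(R1),
      fixed = fixed_moments(R1),
      empirical = {
        R2 <- rewards_from_fertility_vector(fert$f2, s, rps)
        R3 <- if (!is.null(fert$f3)) rewards_from_fertility_vector(fert$f3, s, rps)
        list(R2 = R2, R3 = R3)
      }
    )
    R <- list(R1, hi$R2, hi$R3)[seq_len(min(order, 3L))]
    if (order > 3L) {
      # extend parametric models to arbitrary order via per-stage raw moments
      R <- c(R, lapply(4:order, function(k) {
        fk <- raw_moment_by_model(fert, k)
        rewards_from_fertility_vector(fk, s, rps)
      }))
    }
    if (any(vapply(R, is.null, logical(1L)))) {
      stop("empirical schedule lacks the moments needed for the requested order")
    }
    model <- fert$model
  }
  Rtilde <- lapply(R, function(x) matrix(x[1:tau, 1:tau], tau, tau))
  structure(
    list(R = R, Rtilde = Rtilde, order = length(R), tau = tau, alpha = alpha,
         s = s, model = model, require_parental_survival = rps),
    class = "reward_moments"
  )
}

raw_moment_by_model <- function(fert, k) {
  f <- fert$f1
  switch(fert$model,
    bernoulli = f,
    fixed = f^k,
    poisson = vapply(f, function(lam) {
      # raw moment via Dobinski-style Stirling expansion
      sum(vapply(0:k, function(j) stirling2(k, j) * lam^j, numeric(1L)))
    }, numeric(1L)),
    stop("raw moments beyond order 3 require a parametric model")
  )
}

stirling2 <- function(n, k) {
  if (k == 0L) return(as.numeric(n == 0L))
  sum((-1)^(k - 0:k) * choose(k, 0:k) * (0:k)^n) / factorial(k)
}

#' Reward moments from a per-stage moment table
#'
#' Builds a `reward_moments` object from empirically measured raw moments of
#' per-step reproduction, one row per stage with columns `f1`, `f2` and
#' optionally `f3` (as from clutch-size data).
#'
#' @param moment_table data frame with columns `f1`, `f2`\[, `f3`\].
#' @param alpha number of absorbing states.
#' @param require_parental_survival see [fertility_schedule()].
#' @return a [reward_moments()] object.
#' @export
empirical_moments <- function(moment_table, alpha = 1L,
                              require_parental_survival = FALSE) {
  if (!all(c("f1", "f2") %in% names(moment_table))) {
    stop("moment table must contain columns f1 and f2")
  }
  fert <- fertility_schedule(
    moment_table$f1, model = "empirical",
    f2 = moment_table$f2, f3 = moment_table$f3,
    require_parental_survival = require_parental_survival
  )
  order <- if (is.null(fert$f3)) 2L else 3L
  reward_moments(fert, tau = length(fert$f1), alpha = alpha, order = order)
}

#' @export
print.reward_moments <- function(x, ...) {
  cat(sprintf("<reward_moments> model %s, orders 1..%d, %d x %d\n",
              x$model, x$order, x$s, x$s))
  invisible(x)
}
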