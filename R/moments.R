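#' Moments of lifetime reproductive output by starting stage
#'
#' Computes the moment vectors `rho_1 ... rho_m` of remaining LRO: the k-th
#' entry of `rho_k` is the k-th raw moment of the total offspring an
#' individual currently in that stage will produce before death. The
#' closed-form recursion is
#'
#' \deqn{\rho_m = N^T Z (P \circ R_m)^T 1 +
#'   \sum_{k=1}^{m-1} \binom{m}{k} N^T (U \circ \tilde R_{m-k})^T \rho_k}
#'
#' where `N` is the fundamental matrix; the direct term collects the reward
#' moments of the next transition (including the transition into death) and
#' the cross terms propagate lower-order moments along surviving transitions.
#' All applications of `N^T` are performed as LU linear solves against
#' `(I - U)^T`.
#'
#' @param chain a `markov_chain` from [build_markov_chain()] (or an
#'   [lro_model()], converted on the fly).
#' @param rewards a [reward_moments()] object.
#' @param order highest moment order m (defaults to the order carried by
#'   `rewards`).
#' @return object of class `lro_moments`: list with `rho` (list of numeric
#'   vectors, one per order), `order`, `tau`, `stage_labels`.
#' @export
#' @examples
#' m <- lro_model(matrix(0.5), fertility_schedule(0.4))
#' rw <- reward_moments(m$fertility, tau = 1)
#' lro_moment_vectors(build_markov_chain(m), rw)$rho[[1]]  # 0.4 / 0.5
lro_moment_vectors <- function(chain, rewards, order = rewards$order) {
  if (inherits(chain, "lro_model")) chain <- build_markov_chain(chain)
  stopifnot(inherits(chain, "markov_chain"), inherits(rewards, "reward_moments"))
  if (chain$s != rewards$s) stop("shape error: chain and rewards disagree on s")
  if (order > rewards$order) stop("rewards do not carry moments up to the requested order")
  tau <- chain$tau
  s <- chain$s
  P <- chain$P
  U <- chain$U
  ImUt <- t(diag(tau) - U)
  ones <- rep(1, s)
  rho <- vector("list", order)
  for (m in seq_len(order)) {
    direct <- (t(P * rewards$R[[m]]) %*% ones)[1:tau]
    rhs <- direct
    if (m > 1L) {
      for (k in 1:(m - 1L)) {
        rhs <- rhs + choose(m, k) *
          drop(t(U * rewards$Rtilde[[m - k]]) %*% rho[[k]])
      }
    }
    rho[[m]] <- drop(solve(ImUt, rhs))
  }
  structure(
    list(rho = rho, order = order, tau = tau, stage_labels = chain$stage_labels),
    class = "lro_moments"
  )
}

#' @export
print.lro_moments <- function(x, ...) {
  cat(sprintf("<lro_moments> orders 1..%d for %d stage(s); mean from stage 1: %.4g\n",
              x$order, x$tau, x$rho[[1L]][1L]))
  invisible(x)
}

#' Summary statistics of lifetime reproductive output
#'
#' Mean, variance, standard deviation, coefficient of variation and Crow's
#' opportunity for selection `I = V / mean^2 = CV^2`, one value per starting
#' stage. Where the mean is zero, CV and I are undefined and reported as
#' `NaN` rather than raising an error.
#'
#' @param moments an [lro_moment_vectors()] result of order at least 2.
#' @return data frame with columns `stage`, `mean`, `variance`, `sd`, `cv`,
#'   `crow_i`.
#' @export
lro_statistics <- function(moments) {
  stopifnot(inherits(moments, "lro_moments"))
  if (moments$order < 2L) stop("order >= 2 required for variance-based statistics")
  m1 <- moments$rho[[1L]]
  v <- moments$rho[[2L]] - m1^2
  v <- ifelse(v < 0 & v > -1e-10 * pmax(moments$rho[[2L]], 1), 0, v)
  if (any(v < 0)) stop("moment inconsistency: negative variance")
  sdv <- sqrt(v)
  cv <- ifelse(m1 > 0, sdv / m1, NaN)
  stage <- if (!is.null(moments$stage_labels)) moments$stage_labels else
    seq_len(moments$tau)
  data.frame(
    stage = stage, mean = m1, variance = v, sd = sdv, cv = cv,
    crow_i = cv^2, row.names = NULL
  )
}

#' Skewness of lifetime reproductive output
#'
#' Standardized third central moment per starting stage,
#' `(rho3 - 3 rho1 rho2 + 2 rho1^3) / sd^3`; `NaN` where the SD is zero.
#'
#' @param moments an [lro_moment_vectors()] result of order at least 3.
#' @return numeric vector of length tau.
#' @export
lro_skewness <- function(moments) {
  stopifnot(inherits(moments, "lro_moments"))
  if (moments$order < 3L) stop("order >= 3 required for skewness")
  m1 <- moments$rho[[1L]]
  m2 <- moments$rho[[2L]]
  m3 <- moments$rho[[3L]]
  v <- pmax(m2 - m1^2, 0)
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  ifelse(v > 0, mu3 / v^1.5, NaN)
}

#' Partition the variance in LRO within and between life-cycle pathways
#'
#' By the law of total variance, `V = V_within + V_between`: the
#' between-pathway component is the variance that would remain if every
#' individual produced exactly its stage's mean fertility at every step
#' (the fixed-reward model, which shares `rho_1` with the full model), and
#' the within-pathway component — stochastic per-step fertility along a given
#' path — is obtained by subtraction.
#'
#' @param model an [lro_model()] with a fertility schedule, or a
#'   `markov_chain`.
#' @param fertility optional [fertility_schedule()] overriding the model's.
#' @return object of class `variance_partition`: data frame with columns
#'   `stage`, `v_total`, `v_between`, `v_within`, `pct_between`, `pct_within`.
#' @export
#' @examples
#' m <- lro_model(matrix(0.5), fertility_schedule(0.4))
#' partition_variance(m)
partition_variance <- function(model, fertility = NULL) {
  if (inherits(model, "lro_model")) {
    fert <- if (!is.null(fertility)) fertility else model$fertility
    chain <- build_markov_chain(model)
  } else {
    stopifnot(inherits(model, "markov_chain"))
    fert <- fertility
    chain <- model
  }
  if (is.null(fert)) stop("a fertility schedule is required to partition variance")
  tau <- chain$tau
  rw_total <- reward_moments(fert, tau = tau, alpha = chain$alpha, order = 2L)
  fert_fixed <- fertility_schedule(
    fert$f1, model = "fixed",
    require_parental_survival = fert$require_parental_survival
  )
  rw_fixed <- reward_moments(fert_fixed, tau = tau, alpha = chain$alpha, order = 2L)
  st_total <- lro_statistics(lro_moment_vectors(chain, rw_total))
  st_fixed <- lro_statistics(lro_moment_vectors(chain, rw_fixed))
  v_total <- st_total$variance
  v_between <- st_fixed$variance
  v_within <- v_total - v_between
  bad <- v_within < -1e-10 * pmax(v_total, 1)
  if (any(bad)) stop("moment inconsistency: negative within-pathway variance")
  v_within <- pmax(v_within, 0)
  pct <- function(x) ifelse(v_total > 0, 100 * x / v_total, NaN)
  structure(
    data.frame(
      stage = st_total$stage, v_total = v_total, v_between = v_between,
      v_within = v_within, pct_between = pct(v_between),
      pct_within = pct(v_within), row.names = NULL
    ),
    class = c("variance_partition", "data.frame")
  )
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance in lifetime reproductive output, partitioned by pathway:\n")
  y <- x
  y$pct_between <- round(y$pct_between, 1)
  y$pct_within <- round(y$pct_within, 1)
  print.data.frame(y, ...)
  invisible(x)
}
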