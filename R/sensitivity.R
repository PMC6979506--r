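#' Vec-permutation (commutation) matrix
#'
#' The permutation matrix `K` of order (m, n) satisfying
#' `K %*% vec(X) == vec(t(X))` for every m x n matrix `X`.
#'
#' @param m,n matrix dimensions.
#' @return an mn x mn permutation matrix.
#' @export
#' @examples
#' X <- matrix(1:4, 2, 2)
#' all(vec_permutation(2, 2) %*% as.vector(X) == as.vector(t(X)))
vec_permutation <- function(m, n) {
  K <- matrix(0, m * n, m * n)
  i <- rep(1:m, times = n)
  j <- rep(1:n, each = m)
  K[cbind((i - 1L) * n + j, (j - 1L) * m + i)] <- 1
  K
}

# (v^T (x) I_tau) K_{tau,tau} B for B = d vec X / d theta^T (tau^2 x p):
# column q of the result is t(mat(B[, q])) %*% v, computed by reshaping.
.contract_left <- function(B, v) {
  tau <- length(v)
  p <- ncol(B)
  matrix(crossprod(v, matrix(B, tau, tau * p)), tau, p)
}

# (1_s^T (x) Z) K_{ss} A for A (s^2 x p): per column, colSums of mat(A[, q]),
# truncated to the transient stages.
.contract_colsums <- function(A, s, tau) {
  p <- ncol(A)
  matrix(colSums(matrix(A, s, s * p)), s, p)[1:tau, , drop = FALSE]
}

#' Bundle parameter derivatives of the life cycle into a perturbation map
#'
#' A perturbation map carries, for a parameter vector theta (length p), the
#' derivative matrices `dU = d vec U / d theta^T` (tau^2 x p) and
#' `dR[[i]] = d vec R_i / d theta^T` (s^2 x p), and optionally
#' `dP = d vec P / d theta^T`. With a single absorbing state `dP` is derived
#' from `dU` automatically (the death row absorbs whatever the columns of U
#' lose); with `alpha > 1` it must be supplied.
#'
#' Ready-made maps: [age_classified_pmap()], [stage_classified_pmap()],
#' [compensated_growth_pmap()], [fertility_pmap()].
#'
#' @param theta parameter values (length p).
#' @param dU tau^2 x p derivative of vec U; `NULL` means zero.
#' @param dR list of s^2 x p derivatives of vec R_i; `NULL` entries mean zero.
#' @param dP optional s^2 x p derivative of vec P.
#' @param labels optional parameter labels.
#' @param tau,alpha model dimensions.
#' @param max_order highest moment order whose derivative the map supports.
#' @return object of class `perturbation_map`.
#' @export
perturbation_map <- function(theta, dU = NULL, dR = list(), dP = NULL,
                             labels = NULL, tau, alpha = 1L,
                             max_order = 3L) {
  p <- length(theta)
  s <- tau + alpha
  if (is.null(dU)) dU <- matrix(0, tau^2, p)
  dU <- as.matrix(dU)
  if (nrow(dU) != tau^2 || ncol(dU) != p) stop("shape error: dU must be tau^2 x p")
  dR <- lapply(dR, function(x) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (nrow(x) != s^2 || ncol(x) != p) stop("shape error: dR blocks must be s^2 x p")
    x
  })
  if (!is.null(dP)) {
    dP <- as.matrix(dP)
    if (nrow(dP) != s^2 || ncol(dP) != p) stop("shape error: dP must be s^2 x p")
  }
  structure(
    list(theta = as.numeric(theta), dU = dU, dR = dR, dP = dP,
         labels = labels, tau = tau, alpha = alpha, s = s, p = p,
         max_order = max_order),
    class = "perturbation_map"
  )
}

#' @export
print.perturbation_map <- function(x, ...) {
  cat(sprintf("<perturbation_map> p = %d parameter(s)%s; tau = %d, alpha = %d\n",
              x$p, if (!is.null(x$labels)) paste0(" (", x$labels[1L],
                                                  if (x$p > 1L) ", ..." else "", ")") else "",
              x$tau, x$alpha))
  invisible(x)
}

# d vec P / d theta^T from d vec U / d theta^T, single absorbing state:
# the U block maps through unchanged and the death row receives minus the
# column sums of each dU direction.
dP_from_dU <- function(dU, tau) {
  p <- ncol(dU)
  s <- tau + 1L
  arr <- array(dU, c(tau, tau, p))
  out <- array(0, c(s, s, p))
  out[1:tau, 1:tau, ] <- arr
  out[s, 1:tau, ] <- -apply(arr, 3L, colSums)
  matrix(out, s * s, p)
}

#' Sensitivity of the LRO moment vectors to a parameter vector
#'
#' Differentiates the moment recursion: for each order m,
#' `d rho_m / d theta^T = N^T (V_m + sum_k choose(m,k) W_{k,m-k} + X_m)`,
#' built bottom-up since the cross terms `W` contain the lower-order
#' sensitivities. `V_m` carries the direct effect through `P` and `R_m`,
#' `W` the effect through surviving transitions and the transient reward
#' submatrices, and `X_m` the effect of `U` on the fundamental matrix.
#' Kronecker products with identity factors and the vec-permutation matrix
#' are applied implicitly by reshaping, so no s^2 x s^2 matrix is formed.
#'
#' @param chain a `markov_chain` (or [lro_model()]).
#' @param rewards a [reward_moments()] object.
#' @param pmap a [perturbation_map()].
#' @param order highest moment order to differentiate (default 2, enough for
#'   all variance-based statistics).
#' @return object of class `sensitivity_result` with `d_rho` (list of tau x p
#'   matrices), plus the `moments` used, `theta` and `labels`.
#' @export
moment_sensitivity <- function(chain, rewards, pmap, order = 2L) {
  if (inherits(chain, "lro_model")) chain <- build_markov_chain(chain)
  stopifnot(inherits(chain, "markov_chain"),
            inherits(rewards, "reward_moments"),
            inherits(pmap, "perturbation_map"))
  if (pmap$tau != chain$tau || pmap$alpha != chain$alpha) {
    stop("shape error: perturbation map does not match the chain")
  }
  if (order > pmap$max_order) {
    stop("perturbation map incomplete: reward derivatives available only up to order ",
         pmap$max_order)
  }
  if (order > rewards$order) stop("rewards do not carry moments up to the requested order")
  tau <- chain$tau
  s <- chain$s
  p <- pmap$p
  dP <- pmap$dP
  if (is.null(dP)) {
    if (chain$alpha != 1L) {
      stop("perturbation map incomplete: dP must be supplied when alpha > 1")
    }
    dP <- dP_from_dU(pmap$dU, tau)
  }
  moments <- lro_moment_vectors(chain, rewards, order = order)
  vecP <- as.vector(chain$P)
  vecU <- as.vector(chain$U)
  tidx <- transient_indices(tau, s)
  ImUt <- t(diag(tau) - chain$U)
  zero_s2 <- matrix(0, s^2, p)
  d_rho <- vector("list", order)
  for (m in seq_len(order)) {
    dRm <- if (length(pmap$dR) >= m && !is.null(pmap$dR[[m]])) pmap$dR[[m]] else zero_s2
    Am <- as.vector(rewards$R[[m]]) * dP + vecP * dRm
    Vm <- .contract_colsums(Am, s, tau)
    Xm <- .contract_left(pmap$dU, moments$rho[[m]])
    rhs <- Vm + Xm
    if (m > 1L) {
      for (k in 1:(m - 1L)) {
        j <- m - k
        dRj <- if (length(pmap$dR) >= j && !is.null(pmap$dR[[j]])) pmap$dR[[j]] else zero_s2
        dRtj <- dRj[tidx, , drop = FALSE]
        B <- as.vector(rewards$Rtilde[[j]]) * pmap$dU + vecU * dRtj
        Wkj <- .contract_left(B, moments$rho[[k]]) +
          t(chain$U * rewards$Rtilde[[j]]) %*% d_rho[[k]]
        rhs <- rhs + choose(m, k) * Wkj
      }
    }
    d_rho[[m]] <- solve(ImUt, rhs)
  }
  structure(
    list(d_rho = d_rho, order = order, moments = moments,
         theta = pmap$theta, labels = pmap$labels, tau = tau, p = p),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> d rho_1..%d / d theta^T (%d x %d)%s\n",
              x$order, x$tau, x$p,
              if (!is.null(x$d_stats)) "; statistic derivatives attached" else ""))
  invisible(x)
}

#' Sensitivity of the variability statistics of LRO
#'
#' From the moment sensitivities of orders 1 and 2, computes the derivative
#' matrices of the variance, standard deviation, coefficient of variation and
#' Crow's index:
#' `dV = d rho_2 - 2 D(rho_1) d rho_1`,
#' `dSD = D(SD)^-1 dV / 2`,
#' `dCV = D(rho_1)^-1 dSD - D(SD) D(rho_1)^-2 d rho_1`,
#' `dI = 2 D(CV) dCV`.
#' Rows where the SD (or the mean, for CV and I) is zero are `NaN`.
#'
#' @param sens a [moment_sensitivity()] result of order at least 2.
#' @return the same `sensitivity_result` with an added `d_stats` list holding
#'   tau x p matrices `mean`, `variance`, `sd`, `cv`, `crow_i`.
#' @export
statistic_sensitivity <- function(sens) {
  stopifnot(inherits(sens, "sensitivity_result"))
  if (sens$order < 2L) stop("order >= 2 required for statistic sensitivities")
  rho1 <- sens$moments$rho[[1L]]
  rho2 <- sens$moments$rho[[2L]]
  d1 <- sens$d_rho[[1L]]
  d2 <- sens$d_rho[[2L]]
  v <- pmax(rho2 - rho1^2, 0)
  sdv <- sqrt(v)
  dvar <- d2 - 2 * rho1 * d1
  safe_div <- function(M, denom) {
    out <- M / denom
    out[denom == 0, ] <- NaN
    out
  }
  dsd <- safe_div(dvar, 2 * sdv)
  dcv <- safe_div(dsd, rho1) - safe_div(sdv * d1, rho1^2)
  cv <- ifelse(rho1 > 0, sdv / rho1, NaN)
  dcrow <- 2 * cv * dcv
  sens$d_stats <- list(mean = d1, variance = dvar, sd = dsd, cv = dcv,
                       crow_i = dcrow)
  sens
}

#' Elasticity (proportional sensitivity) matrix
#'
#' `E[i, j] = (theta[j] / xi[i]) * d xi[i] / d theta[j]`: the proportional
#' change in output per proportional change in parameter. Defined only where
#' `xi > 0` (other rows are `NaN`) and for `theta >= 0`; columns with
#' `theta[j] == 0` are zero (the limit).
#'
#' @param value the output vector xi (length tau).
#' @param dvalue its derivative matrix, tau x p.
#' @param theta the parameter values (length p).
#' @return tau x p elasticity matrix.
#' @export
elasticity <- function(value, dvalue, theta) {
  dvalue <- as.matrix(dvalue)
  if (length(value) != nrow(dvalue) || length(theta) != ncol(dvalue)) {
    stop("shape error: value, dvalue and theta dimensions disagree")
  }
  if (any(theta < 0)) stop("elasticity requires theta >= 0")
  E <- sweep(dvalue, 2L, theta, "*") / value
  E[value <= 0 | !is.finite(value), ] <- NaN
  E[, theta == 0] <- 0
  E
}
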