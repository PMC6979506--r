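#' Read and write plain matrix CSV files
#'
#' Matrix files follow the common projection-matrix-database export
#' convention: comma-separated, period decimal, one matrix row per line, no
#' header.
#'
#' @param path file path.
#' @return `read_matrix_csv`: a numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' @param x numeric matrix to write.
#' @rdname read_matrix_csv
#' @export
write_matrix_csv <- function(x, path) {
  utils::write.table(format(x, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Build a life-cycle model from matU/matF files
#'
#' Reads a transient transition matrix `U` and (optionally) a fertility
#' matrix `F` from headerless CSV files and assembles an [lro_model()]. The
#' stage-specific mean fertility vector is taken as the column sums of `F`
#' (this supports offspring recruited into more than one stage). An optional
#' JSON sidecar may provide `stage_labels` and `alpha`.
#'
#' @param matU_path path to the U matrix CSV.
#' @param matF_path optional path to the F matrix CSV.
#' @param model fertility model for higher moments (see
#'   [fertility_schedule()]).
#' @param require_parental_survival see [fertility_schedule()].
#' @param sidecar optional path to a JSON file with fields `stage_labels`
#'   and/or `alpha`.
#' @return an [lro_model()].
#' @export
read_projection_matrices <- function(matU_path, matF_path = NULL,
                                     model = "poisson",
                                     require_parental_survival = FALSE,
                                     sidecar = NULL) {
  U <- read_matrix_csv(matU_path)
  if (nrow(U) != ncol(U)) stop("matU must be square")
  fert <- NULL
  if (!is.null(matF_path)) {
    F_ <- read_matrix_csv(matF_path)
    if (!all(dim(F_) == dim(U))) stop("matU and matF dimensions differ")
    if (any(F_ < 0)) stop("invalid fertility: negative entries in matF")
    fert <- fertility_schedule(colSums(F_), model = model,
                               require_parental_survival = require_parental_survival)
  }
  labels <- NULL
  alpha <- 1L
  if (!is.null(sidecar) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$stage_labels)) labels <- as.character(meta$stage_labels)
    if (!is.null(meta$alpha)) alpha <- as.integer(meta$alpha)
  }
  lro_model(U, fertility = fert, alpha = alpha, stage_labels = labels)
}

#' Read a life table and build an age-classified model
#'
#' Life-table CSVs have a header with columns `age`, `mu` (mortality hazard)
#' and `fx` (mean fertility), one row per age class.
#'
#' @param path life-table CSV path.
#' @return `read_life_table`: a data frame with columns `age`, `mu`, `fx`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lt <- utils::read.csv(path)
  need <- c("age", "mu", "fx")
  if (!all(need %in% names(lt))) {
    stop("life table must have columns age, mu, fx")
  }
  lt[need]
}

#' @param lt a life-table data frame as returned by `read_life_table`.
#' @param ... passed to [age_classified_model()].
#' @rdname read_life_table
#' @export
life_table_model <- function(lt, ...) {
  age_classified_model(lt$mu, lt$fx, ...)
}

#' The bundled Tsuga canadensis size-classified model
#'
#' A six-size-class matrix model for Canadian hemlock (diagonal stasis plus
#' subdiagonal growth; new recruits per individual per year as fertility of
#' size classes 3-6), shipped as matU/matF CSV fixtures. Fertility moments
#' default to the Poisson model, as appropriate for multi-offspring recruit
#' counts with no empirical higher moments.
#'
#' @param model fertility model (default `"poisson"`).
#' @param ... passed to [read_projection_matrices()].
#' @return an [lro_model()] with six stages.
#' @export
#' @examples
#' tsuga <- tsuga_model()
#' life_expectancy(tsuga)[1]
tsuga_model <- function(model = "poisson", ...) {
  read_projection_matrices(
    system.file("extdata", "tsuga_matU.csv", package = "lrostats", mustWork = TRUE),
    system.file("extdata", "tsuga_matF.csv", package = "lrostats", mustWork = TRUE),
    model = model, ...
  )
}

#' Generate a random valid life-cycle model
#'
#' Test-surface generator for property checks. Two profiles:
#' * `stage_like` — a column-stochastic growth matrix G drawn from flat
#'   Dirichlet columns, stage survival sigma ~ Uniform(0.2, 0.99), U = G
#'   diag(sigma) (spectral radius < 1 since every column sum is below 1),
#'   and mean fertility ~ Uniform(0.05, 0.95) in every stage (valid under
#'   both Bernoulli and Poisson rewards, and positive so that CV and Crow's
#'   index are defined from every starting stage).
#' * `age_like` — age-specific hazards mu ~ Uniform(0.05, 0.4) and a
#'   unimodal (Gaussian-window) fertility schedule peaking mid-life with
#'   maximum ~ Uniform(0.3, 0.9).
#'
#' @param tau number of transient stages.
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @param profile `"stage_like"` or `"age_like"`.
#' @param fertility_model model for higher fertility moments.
#' @return an [lro_model()].
#' @export
generate_synthetic_model <- function(tau, seed = NULL,
                                     profile = c("stage_like", "age_like"),
                                     fertility_model = "poisson") {
  profile <- match.arg(profile)
  if (!is.null(seed)) set.seed(seed)
  if (profile == "stage_like") {
    G <- matrix(stats::rgamma(tau * tau, shape = 1), tau, tau)
    G <- sweep(G, 2L, colSums(G), "/")
    sigma <- stats::runif(tau, 0.2, 0.99)
    U <- sweep(G, 2L, sigma, "*")
    f1 <- stats::runif(tau, 0.05, 0.95)
    lro_model(U, fertility_schedule(f1, model = fertility_model))
  } else {
    mu <- stats::runif(tau, 0.05, 0.4)
    mid <- (tau + 1) / 2
    f1 <- stats::runif(1L, 0.3, 0.9) *
      exp(-(seq_len(tau) - mid)^2 / (2 * max(tau / 4, 0.5)^2))
    age_classified_model(mu, fertility_schedule(f1, model = fertility_model))
  }
}
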