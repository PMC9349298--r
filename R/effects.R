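#' Random-walk precision structure on a time index
#'
#' Order-1 penalizes first differences; order-2 penalizes second differences
#' (interior rows of the structure matrix follow the (1, -4, 6, -4, 1)
#' pattern). The precision is `R / sigma^2` where `R = D'D` with `D` the
#' difference operator, so for order 2 the full conditional of an interior
#' state given the rest has mean
#' `(4(w[t-1] + w[t+1]) - (w[t-2] + w[t+2])) / 6` and variance `sigma^2/6`.
#' The structure matrix is rank `T - order`; its null space (the constant,
#' plus the linear trend for order 2) is returned so callers can impose
#' sum-to-zero style constraints.
#'
#' @param T number of time points.
#' @param order 1 or 2.
#' @param sigma conditional scale parameter (see above); default 1 returns
#'   the unscaled structure.
#' @return list of class `herd_rw`: `Q` (sparse, rank-deficient), `R`
#'   (structure matrix, sigma = 1), `rank`, `null` (orthonormal basis of the
#'   null space, T x order), `order`, `sigma`.
#' @export
rw_precision <- function(T, order = 2L, sigma = 1) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) abort("order must be 1 or 2")
  if (T < order + 1L) abort(paste0("T must be at least ", order + 1L, " for RW", order))
  if (sigma <= 0) abort("sigma must be > 0")
  D <- diff(diag(T), differences = order)
  R <- as(crossprod(Matrix::Matrix(D, sparse = TRUE)), "generalMatrix")
  nullsp <- cbind(rep(1, T))
  if (order == 2L) nullsp <- cbind(nullsp, seq_len(T) - (T + 1) / 2)
  nullsp <- qr.Q(qr(nullsp))
  structure(list(Q = forceSymmetric(R) / sigma^2, R = forceSymmetric(R),
                 rank = T - order, null = nullsp, order = order, sigma = sigma),
            class = "herd_rw")
}

#' Stationary AR(1) precision with unit marginal variance
#'
#' Tridiagonal precision of a stationary AR(1) process scaled so every
#' marginal variance is 1; the inverse has entries `rho_t^|i-j|`. The
#' process variance is controlled by an explicit standard-deviation
#' hyperparameter outside this structure, which keeps the PC prior on the
#' correlation interpretable.
#'
#' @param T series length (>= 1).
#' @param rho_t lag-one correlation, |rho_t| < 1.
#' @return sparse symmetric precision matrix (T x T).
#' @export
ar1_precision <- function(T, rho_t) {
  if (!is.finite(rho_t) || abs(rho_t) >= 1) abort("|rho_t| must be < 1")
  if (T < 1L) abort("T must be >= 1")
  if (T == 1L) return(Diagonal(1, x = 1))
  d <- c(1, rep(1 + rho_t^2, T - 2L), 1) / (1 - rho_t^2)
  off <- rep(-rho_t / (1 - rho_t^2), T - 1L)
  forceSymmetric(Matrix::bandSparse(T, k = c(0L, 1L),
                                    diagonals = list(d, off), symmetric = TRUE))
}

#' Separable space-time precision (AR1 in time x GMRF in space)
#'
#' Kronecker product `Q_ar1(T, rho_t) %x% Q_space`, so the covariance is the
#' Kronecker product of the AR(1) correlation and the spatial covariance:
#' the same vertex at lag h has covariance `rho_t^h` times its spatial
#' marginal variance.
#'
#' @param Q_space sparse SPD spatial precision (n x n).
#' @param rho_t AR(1) lag-one correlation.
#' @param T number of time points.
#' @param max_dim guard against accidental huge Kronecker products.
#' @return sparse symmetric precision (nT x nT), ordered space-fastest
#'   (vertex index varies within a time block).
#' @export
spacetime_precision <- function(Q_space, rho_t, T, max_dim = 5e4) {
  n <- nrow(Q_space)
  if (n * T > max_dim)
    abort(paste0("space-time dimension ", n * T, " exceeds cap ", max_dim))
  if (T == 1L) return(forceSymmetric(Q_space))
  forceSymmetric(ar1_precision(T, rho_t) %x% Q_space)
}

#' Intrinsic CAR (ICAR) precision from an adjacency matrix
#'
#' `Q = diag(m) - W` for a symmetric 0/1 adjacency `W` with neighbour counts
#' `m`. Under precision `Q/sigma^2` the full conditional of area c is
#' Gaussian around the mean of its neighbours with variance `sigma^2 / m_c`.
#' Row sums are zero: the constant vector (per connected component) spans
#' the null space, so a sum-to-zero constraint restores propriety.
#'
#' @param adjacency symmetric binary adjacency matrix (no self-loops).
#' @return list of class `herd_icar`: `Q` (structure matrix, sigma = 1),
#'   `m` neighbour counts, `null` (orthonormal constant basis).
#' @export
icar_precision <- function(adjacency) {
  W <- as(Matrix::Matrix(adjacency, sparse = TRUE), "generalMatrix")
  if (!Matrix::isSymmetric(W)) abort("adjacency must be symmetric")
  if (any(Matrix::diag(W) != 0)) abort("adjacency must have no self-loops")
  m <- Matrix::rowSums(W != 0)
  if (any(m == 0)) {
    isl <- which(m == 0)
    abort(paste0("island area(s) with zero neighbours: ",
                 paste(head(isl, 5L), collapse = ", "),
                 ". Connect them (e.g. nearest-neighbour edge) or drop them ",
                 "before smoothing."))
  }
  W01 <- W != 0
  Q <- Diagonal(nrow(W), x = m) - W01 * 1
  n <- nrow(W)
  structure(list(Q = forceSymmetric(Q), m = as.numeric(m),
                 null = matrix(1 / sqrt(n), n, 1L)),
            class = "herd_icar")
}

#' Read an adjacency matrix from a plain edge-list file
#'
#' Two-column whitespace/comma separated file of 1-based area indices; edges
#' are symmetrized.
#'
#' @param path file path.
#' @param n number of areas (defaults to the max index seen).
#' @export
read_adjacency <- function(path, n = NULL) {
  e <- as.matrix(readr::read_csv(path, col_names = c("i", "j"),
                                 col_types = "ii", progress = FALSE))
  if (is.null(n)) n <- max(e)
  sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]), x = 1,
               dims = c(n, n), use.last.ij = TRUE)
}

#' Sample a rank-deficient Gaussian structure under its constraints
#'
#' Draws from the Gaussian with precision `R / sigma^2` restricted to the
#' orthogonal complement of the null space (equivalently, conditioned on the
#' null-space contrasts being zero). Used by the synthetic-data generator
#' for RW and ICAR effects; sizes are small so a dense eigendecomposition is
#' used.
#'
#' @param R structure matrix (dense or sparse).
#' @param sigma scale.
#' @param n number of draws.
#' @return matrix (dim(R) x n) whose columns satisfy the constraints.
#' @export
constrained_sample <- function(R, sigma = 1, n = 1L) {
  Rd <- as.matrix(R)
  e <- eigen(Rd, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  V <- e$vectors[, pos, drop = FALSE]
  lam <- e$values[pos]
  z <- matrix(rnorm(sum(pos) * n), sum(pos), n)
  sigma * V %*% (z / sqrt(lam))
}
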