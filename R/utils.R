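# Internal numerical helpers shared across modules.

#' Minimum-norm least squares
#'
#' Solves `argmin ||X b - y||` via a Cholesky factorization of the normal
#' equations, falling back to an SVD pseudo-inverse (minimum-norm solution)
#' when the crossproduct is rank-deficient or badly conditioned.
#'
#' @param X design matrix (n x p), n >= 1.
#' @param y response vector or matrix with n rows.
#' @param cond_tol reciprocal-condition threshold below which the SVD
#'   fallback is used.
#' @return coefficient vector/matrix with p rows.
#' @keywords internal
#' @noRd
lstsq <- function(X, y, cond_tol = 1e-10) {
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  ok <- FALSE
  fit <- tryCatch({
    R <- chol(XtX)
    # cheap conditioning check on the Cholesky diagonal
    d <- diag(R)
    if (min(d) / max(d) > sqrt(cond_tol)) {
      ok <- TRUE
      backsolve(R, backsolve(R, Xty, transpose = TRUE))
    } else NULL
  }, error = function(e) NULL)
  if (ok && !is.null(fit)) return(fit)
  sv <- svd(XtX)
  pos <- sv$d > max(sv$d) * cond_tol
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], Xty)) / sv$d[pos]))
}

#' Symmetric positive-definite solve with pseudo-inverse fallback
#' @keywords internal
#' @noRd
spd_solve <- function(A, B, cond_tol = 1e-10, warn_singular = TRUE) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > max(ev) * cond_tol) {
    return(solve(A, B))
  }
  if (warn_singular) {
    warning("system is rank-deficient; using minimum-norm pseudo-inverse",
            call. = FALSE)
  }
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * cond_tol
  sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], B) / sv$d[pos])
}

#' Column z-scoring with a guard for constant columns
#' @keywords internal
#' @noRd
zscore_cols <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < tol] <- 1
  sweep(sweep(X, 2, mu, "-"), 2, sd_, "/")
}

#' Z-score a vector; error on zero variance
#' @keywords internal
#' @noRd
zscore_vec <- function(x, what = "signal", tol = 1e-12) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < tol) {
    stop(what, " has zero variance after preprocessing", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Circularly shift a vector by k samples (positive k delays the signal)
#' @keywords internal
#' @noRd
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Pearson correlation that rejects zero-variance inputs
#' @keywords internal
#' @noRd
pearson_strict <- function(x, y) {
  if (stats::sd(x) < 1e-14 || stats::sd(y) < 1e-14) {
    stop("Pearson correlation undefined: zero-variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

# small continued-fraction rational approximation p/q of a resampling ratio
rat_approx <- function(x, max_denom = 4096L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_denom) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r - a < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p = p1, q = q1)
}

#' Does a numeric equal an integer within tolerance?
#' @keywords internal
#' @noRd
is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol
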