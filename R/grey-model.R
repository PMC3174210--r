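#' First-order accumulative generation operation (1-AGO)
#'
#' The running cumulative sum of a series. For a non-negative input the
#' result is monotone non-decreasing (strictly increasing when the input is
#' strictly positive), which smooths the randomness of the original series
#' before the grey model is fitted.
#'
#' @param series Numeric vector, length >= 1.
#' @return Numeric vector of the same length; element k is the sum of the
#'   first k input values.
#' @examples
#' ago(c(1, 2, 3))  # 1 3 6
#' @export
ago <- function(series) {
  if (!is.numeric(series) || length(series) == 0L) {
    stop("`series` must be a non-empty numeric vector", call. = FALSE)
  }
  cumsum(as.numeric(series))
}

#' Discretized GM(2,1) least-squares system
#'
#' Builds the linear system whose least-squares solution gives the GM(2,1)
#' coefficients. With x0 the original series of length n and x1 its 1-AGO,
#' the background value is the adjacent-pair mean
#' z1(k) = (x1(k) + x1(k-1)) / 2, and for k = 2..n the discrete equation
#' reads x0(k) - x0(k-1) = -a1 * x0(k) - a2 * z1(k) + b. Hence the design
#' matrix rows are `[-x0(k), -z1(k), 1]` and the response is the first
#' difference of x0.
#'
#' @param series Numeric vector of length >= 4 (at least three equations for
#'   the three unknowns).
#' @return A list of class `gm21_system` with elements `B` ((n-1) x 3
#'   matrix) and `Y` (length n-1 response vector).
#' @export
build_gm21_system <- function(series) {
  if (!is.numeric(series)) {
    stop("`series` must be numeric", call. = FALSE)
  }
  x0 <- as.numeric(series)
  n <- length(x0)
  if (n < 4L) {
    stop(sprintf(
      "series too short for GM(2,1): length %d, minimum 4", n), call. = FALSE)
  }
  x1 <- cumsum(x0)
  z1 <- (x1[-1] + x1[-n]) / 2
  structure(list(B = cbind(-x0[-1], -z1, rep(1, n - 1L)), Y = diff(x0)),
            class = "gm21_system")
}

#' Fit the GM(2,1) grey model to a numeric series
#'
#' Solves the discretized system by minimum-norm least squares via singular
#' value decomposition; the orthogonal route avoids squaring the condition
#' number of the design matrix, which matters for near-constant
#' (homopolymer-like) series. When the system is rank deficient the
#' minimum-norm solution is returned and `degenerate` is set; a constant
#' series yields coefficients exactly (0, 0, 0) under this convention.
#'
#' @param series Strictly positive numeric vector, length >= 4 (a protein
#'   sequence encoding always satisfies positivity).
#' @return A list of class `grey_coefficients` with elements `a1`, `a2`
#'   (developing coefficients), `b` (influence coefficient), `degenerate`
#'   (logical), and `residual` (Euclidean norm of B %*% coef - Y).
#' @examples
#' fit_gm21(encode_sequence("ACDEFGHIKLMNPQRSTVWY"))
#' @export
fit_gm21 <- function(series) {
  if (!is.numeric(series)) {
    stop("`series` must be numeric", call. = FALSE)
  }
  if (any(series <= 0)) {
    stop("GM(2,1) requires a strictly positive series", call. = FALSE)
  }
  sys <- build_gm21_system(series)
  dec <- svd(sys$B)
  tol <- max(dim(sys$B)) * .Machine$double.eps * dec$d[1]
  rank <- sum(dec$d > tol)
  coef <- if (rank == 0L) {
    numeric(3)
  } else {
    u <- dec$u[, seq_len(rank), drop = FALSE]
    v <- dec$v[, seq_len(rank), drop = FALSE]
    drop(v %*% (crossprod(u, sys$Y) / dec$d[seq_len(rank)]))
  }
  structure(list(a1 = coef[1], a2 = coef[2], b = coef[3],
                 degenerate = rank < 3L,
                 residual = sqrt(sum((sys$B %*% coef - sys$Y)^2))),
            class = "grey_coefficients")
}

#' @export
print.grey_coefficients <- function(x, ...) {
  cat(sprintf("GM(2,1) coefficients: a1 = %.6g, a2 = %.6g, b = %.6g%s\n",
              x$a1, x$a2, x$b,
              if (x$degenerate) " (rank-deficient, minimum-norm)" else ""))
  invisible(x)
}

#' Grey-model feature triple of a series
#'
#' The absolute values (|a1|, |a2|, |b|) of the fitted GM(2,1) coefficients:
#' components 21-23 of the PseAAC vector.
#'
#' @inheritParams fit_gm21
#' @return Named numeric vector `c(abs_a1, abs_a2, abs_b)`, all >= 0.
#' @export
grey_features <- function(series) {
  fit <- fit_gm21(series)
  c(abs_a1 = abs(fit$a1), abs_a2 = abs(fit$a2), abs_b = abs(fit$b))
}
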