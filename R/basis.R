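#' Construct a Fourier basis on a time grid
#'
#' Builds the evaluation matrix of an odd number of Fourier basis
#' functions with fundamental frequency `omega = 2*pi/period`:
#' a constant column followed by `cos(k*omega*t), sin(k*omega*t)` pairs
#' for harmonics `k = 1..(n_basis-1)/2`.  On the full uniform
#' minute grid `0..period-1` the columns are exactly orthogonal
#' (`t(eval) %*% eval` diagonal: `period` for the constant, `period/2`
#' per harmonic column), which makes least-squares smoothing and
#' curve-level regression numerically clean.
#'
#' @param n_basis Odd integer >= 1; the default 9 (constant + 4 harmonic
#'   pairs) captures the major circadian trend of minute actigraphy.
#' @param period Period in minutes (default 1440 = 24 h).
#' @param grid Time points (minutes) at which to tabulate the basis;
#'   default the full minute grid `0..period-1`.
#' @return An object of class `fourier_basis`: a list with `n_basis`,
#'   `period`, `omega`, `grid` and the `length(grid) x n_basis`
#'   evaluation matrix `eval` (columns named `const`, `cos1`, `sin1`,
#'   ...).
#' @examples
#' b <- fourier_basis(9)
#' round(b$eval[1, ], 10)          # at t = 0: 1, cos terms 1, sin terms 0
#' @export
fourier_basis <- function(n_basis = 9L, period = 1440, grid = NULL) {
  n_basis <- as.integer(n_basis)
  if (length(n_basis) != 1 || is.na(n_basis) || n_basis < 1) {
    abort("n_basis must be a positive integer")
  }
  if (n_basis %% 2L == 0L) {
    abort("n_basis must be odd (constant plus complete sine/cosine pairs)")
  }
  if (!is.numeric(period) || length(period) != 1 || period <= 0) {
    abort("period must be a positive number")
  }
  if (is.null(grid)) grid <- seq_len(period) - 1
  structure(
    list(n_basis = n_basis, period = period, omega = 2 * pi / period,
         grid = as.numeric(grid),
         eval = fourier_eval(n_basis, 2 * pi / period, grid)),
    class = "fourier_basis"
  )
}

# evaluation matrix of the basis at arbitrary times
fourier_eval <- function(n_basis, omega, times) {
  times <- as.numeric(times)
  m <- matrix(1, nrow = length(times), ncol = n_basis)
  cn <- "const"
  if (n_basis > 1) {
    for (k in seq_len((n_basis - 1L) %/% 2L)) {
      m[, 2 * k]     <- cos(k * omega * times)
      m[, 2 * k + 1] <- sin(k * omega * times)
      cn <- c(cn, paste0("cos", k), paste0("sin", k))
    }
  }
  colnames(m) <- cn
  m
}

#' Evaluate a Fourier basis at new times
#'
#' @param basis A [fourier_basis()].
#' @param times Numeric times in minutes (any real values; the basis is
#'   periodic with period `basis$period`).
#' @return A `length(times) x n_basis` evaluation matrix.
#' @export
eval_basis <- function(basis, times) {
  stopifnot(inherits(basis, "fourier_basis"))
  fourier_eval(basis$n_basis, basis$omega, times)
}

#' @export
print.fourier_basis <- function(x, ...) {
  cat("<fourier_basis> ", x$n_basis, " functions (constant + ",
      (x$n_basis - 1) %/% 2, " harmonic pairs), period ", x$period,
      " min, tabulated on ", length(x$grid), " grid points\n", sep = "")
  invisible(x)
}
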