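#' Smooth circadian profiles with a Fourier basis
#'
#' Fits each subject's averaged profile by unweighted least squares in a
#' Fourier basis: the coefficients minimise the sum over the grid of
#' squared differences between the profile and the basis expansion (the
#' SMSSE criterion).  The solve uses a QR factorisation of the basis
#' evaluation matrix; the result equals the normal-equations solution
#' `solve(t(P) %*% P) %*% t(P) %*% y` to numerical precision.
#'
#' @param profiles A `tbl_profiles` (long tibble with `subject_id`,
#'   `minute`, `activity`); every subject must cover the same minute
#'   grid with finite values.
#' @param n_basis Odd number of Fourier basis functions (default 9).
#' @param period Period in minutes (default 1440).
#' @param basis Optional pre-built [fourier_basis()]; its grid must
#'   equal the profiles' minute grid.
#' @return A tibble of class `tbl_curves`: one row per subject with
#'   columns `subject_id` and coefficients `a1..a<n_basis>` (ordered
#'   constant, cos1, sin1, cos2, sin2, ...).  The basis is attached as
#'   the `basis` attribute.
#' @seealso [evaluate_curves()], [smoothed_profiles()], [smsse()]
#' @export
smooth_profiles <- function(profiles, n_basis = 9L, period = 1440,
                            basis = NULL) {
  Y <- profiles_matrix(profiles)
  grid <- attr(Y, "grid")
  if (is.null(basis)) {
    basis <- fourier_basis(n_basis, period, grid)
  } else {
    stopifnot(inherits(basis, "fourier_basis"))
    if (length(basis$grid) != length(grid) ||
        any(abs(basis$grid - grid) > 1e-9)) {
      abort("basis grid does not match the profiles' minute grid")
    }
  }
  qrP <- qr(basis$eval)
  if (qrP$rank < basis$n_basis) {
    abort("rank-deficient basis on this grid (duplicate grid points?)")
  }
  coefs <- t(qr.coef(qrP, t(Y)))    # N x n_basis
  out <- tibble::tibble(subject_id = rownames(Y))
  for (i in seq_len(basis$n_basis)) out[[paste0("a", i)]] <- coefs[, i]
  new_tbl_curves(out, basis)
}

new_tbl_curves <- function(x, basis) {
  structure(x, basis = basis,
            class = c("tbl_curves", class(tibble::tibble())))
}

# curves tibble -> N x n_basis coefficient matrix with subject rownames
curves_matrix <- function(curves) {
  basis <- attr(curves, "basis")
  if (is.null(basis)) abort("curves must carry a 'basis' attribute")
  cols <- paste0("a", seq_len(basis$n_basis))
  .assert_columns(curves, c("subject_id", cols), "curves_matrix()")
  m <- as.matrix(curves[cols])
  rownames(m) <- as.character(curves$subject_id)
  m
}

#' Evaluate smoothed circadian curves at chosen times
#'
#' @param curves A `tbl_curves` from [smooth_profiles()].
#' @param at Times in minutes (default: the basis grid).  The curves are
#'   periodic, so any real times are valid.
#' @return A long tibble with `subject_id`, `minute`, `activity`.
#' @export
evaluate_curves <- function(curves, at = NULL) {
  basis <- attr(curves, "basis")
  at <- at %||% basis$grid
  A <- curves_matrix(curves)
  vals <- A %*% t(eval_basis(basis, at))    # N x G
  tibble::tibble(
    subject_id = rep(rownames(A), each = length(at)),
    minute = rep(as.numeric(at), times = nrow(A)),
    activity = as.vector(t(vals))
  )
}

#' Smoothed fitted values of circadian profiles
#'
#' Convenience wrapper: fit the Fourier smoother and return the fitted
#' values on the profile grid (the least-squares projection of each
#' profile onto the basis span).
#'
#' @inheritParams smooth_profiles
#' @return A tibble like `profiles` (`subject_id`, `minute`, `activity`)
#'   containing the smoothed values.
#' @export
smoothed_profiles <- function(profiles, n_basis = 9L, period = 1440,
                              basis = NULL) {
  curves <- smooth_profiles(profiles, n_basis = n_basis, period = period,
                            basis = basis)
  evaluate_curves(curves)
}

#' Smoothing residual sum of squares per subject
#'
#' The least-squares smoothing criterion: for each subject, the sum over
#' grid minutes of squared differences between the raw profile and a
#' curve in the basis span (by default the fitted curve).
#'
#' @param profiles A `tbl_profiles`.
#' @param curves A `tbl_curves` on the same subjects; default the
#'   smoother's own fit.
#' @return A tibble with `subject_id` and `smsse`.
#' @export
smsse <- function(profiles, curves = NULL) {
  Y <- profiles_matrix(profiles)
  if (is.null(curves)) {
    curves <- smooth_profiles(profiles,
                              basis = fourier_basis(9L, 1440, attr(Y, "grid")))
  }
  basis <- attr(curves, "basis")
  A <- curves_matrix(curves)
  A <- A[rownames(Y), , drop = FALSE]
  fit <- A %*% t(eval_basis(basis, attr(Y, "grid")))
  tibble::tibble(subject_id = rownames(Y),
                 smsse = rowSums((Y - fit)^2))
}

#' Write curve coefficients as CSV
#'
#' @param curves A `tbl_curves`.
#' @param file Destination path.
#' @return `file`, invisibly.
#' @export
write_curves <- function(curves, file) {
  readr::write_csv(tibble::as_tibble(curves), file, progress = FALSE)
  invisible(file)
}
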