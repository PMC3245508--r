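#' Fit a function-on-scalar (functional linear) regression
#'
#' Regresses each subject's smoothed circadian activity curve on scalar
#' covariates: `Act_k(t) = Z_k beta(t) + eps_k(t)`, where `Z` is the
#' design matrix and each `beta_j(t)` is itself a curve.  The estimate
#' minimises the integrated squared error (LMSSE).  Because all curves
#' share one Fourier basis that is orthogonal on the evaluation grid,
#' the minimiser equals ordinary least squares applied column by column
#' to the `N x n_basis` coefficient matrix, and also equals pointwise
#' OLS at every grid minute (a tested contract, not an assumption).
#'
#' @param curves A `tbl_curves` from [smooth_profiles()].
#' @param covariates Covariate tibble; required unless `design` is
#'   given.
#' @param spec An [flm_spec()]; required unless `design` is given.
#' @param design Optionally a pre-built [build_design()] result; its
#'   subjects must all have curves.
#' @return An object of class `flm_fit` with components `coef`
#'   (`p x n_basis` functional-coefficient matrix, rows named by design
#'   column), `residual_coef` (`N x n_basis`), `A` (the input curve
#'   coefficients), `design`, `basis`, `subject_id`.  Methods:
#'   [tidy.flm_fit()], [glance.flm_fit()], [autoplot.flm_fit()],
#'   [group_mean_curve()], [pointwise_F()], [confidence_band()],
#'   [permutation_F_test()].
#' @export
fit_flm <- function(curves, covariates = NULL, spec = NULL, design = NULL) {
  basis <- attr(curves, "basis")
  if (is.null(basis)) abort("curves must come from smooth_profiles() (basis attribute)")
  if (is.null(design)) {
    if (is.null(covariates) || is.null(spec)) {
      abort("supply either `design` or both `covariates` and `spec`")
    }
    design <- build_design(covariates, spec,
                           subjects = as.character(curves$subject_id))
  }
  stopifnot(inherits(design, "flm_design"))
  A_all <- curves_matrix(curves)
  missing_curves <- setdiff(design$subject_id, rownames(A_all))
  if (length(missing_curves) > 0) {
    abort(paste0("design subjects without curves: ",
                 paste(head(missing_curves, 5), collapse = ", ")))
  }
  A <- A_all[design$subject_id, , drop = FALSE]
  Z <- design$Z
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    abort(paste0("singular design: collinear column(s) ",
                 paste(design$column_names[qrZ$pivot[seq(qrZ$rank + 1, ncol(Z))]],
                       collapse = ", ")))
  }
  B <- qr.coef(qrZ, A)                    # p x n_basis
  rownames(B) <- design$column_names
  E <- A - Z %*% B
  structure(list(coef = B, residual_coef = E, A = A, design = design,
                 basis = basis, subject_id = design$subject_id),
            class = "flm_fit")
}

#' @export
print.flm_fit <- function(x, ...) {
  cat("<flm_fit> N = ", nrow(x$A), " subjects, terms: ",
      paste(rownames(x$coef), collapse = ", "),
      "; basis: ", x$basis$n_basis, " Fourier functions, period ",
      x$basis$period, " min\n", sep = "")
  invisible(x)
}

#' Tidy the functional coefficients of an FLM fit
#'
#' @param x An `flm_fit`.
#' @param at Evaluation times in minutes (default: the basis grid, all
#'   1440 minutes).
#' @param ... Unused.
#' @return A tibble with `term`, `minute`, `estimate` — each functional
#'   coefficient curve evaluated on the grid.
#' @method tidy flm_fit
#' @export
tidy.flm_fit <- function(x, at = NULL, ...) {
  at <- at %||% x$basis$grid
  vals <- x$coef %*% t(eval_basis(x$basis, at))    # p x G
  tibble::tibble(
    term = rep(rownames(x$coef), each = length(at)),
    minute = rep(as.numeric(at), times = nrow(x$coef)),
    estimate = as.vector(t(vals))
  )
}

#' One-line summary of an FLM fit
#'
#' @param x An `flm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n` subjects, `p` design columns,
#'   `n_basis`, `df_residual` (= n - p), grid sums of squares `sse` and
#'   `sst` (around the mean curve), `r_squared = 1 - sse/sst`, and the
#'   design condition number `kappa`.
#' @method glance flm_fit
#' @export
glance.flm_fit <- function(x, ...) {
  G <- eval_basis(x$basis, x$basis$grid)
  act <- x$A %*% t(G)
  res <- x$residual_coef %*% t(G)
  ctr <- sweep(act, 2, colMeans(act))
  sse <- sum(res^2)
  sst <- sum(ctr^2)
  tibble::tibble(
    n = nrow(x$A), p = ncol(x$design$Z), n_basis = x$basis$n_basis,
    df_residual = nrow(x$A) - ncol(x$design$Z),
    sse = sse, sst = sst,
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
    kappa = kappa(x$design$Z, exact = TRUE)
  )
}

# contrast vector over design columns for a covariate combination:
# intercept = 1, binary/continuous terms taken from `combo`, interactions
# as products of their parents' values
combo_contrast <- function(fit, combo) {
  combo <- as.list(combo)
  terms <- fit$design$terms
  base_names <- names(purrr::keep(terms, ~ .x$kind != "interaction"))
  unknown <- setdiff(names(combo), base_names)
  if (length(unknown) > 0) {
    abort(paste0("unknown term(s) in combo: ", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(base_names, names(combo))
  if (length(missing) > 0) {
    abort(paste0("combo must cover all non-intercept base terms; missing: ",
                 paste(missing, collapse = ", ")))
  }
  vals <- c("(Intercept)" = 1)
  for (nm in names(terms)) {
    t <- terms[[nm]]
    vals[[nm]] <- if (t$kind == "interaction") {
      prod(unlist(vals[t$parents]))
    } else as.numeric(combo[[nm]])
  }
  vals[fit$design$column_names]
}

#' Reconstruct a group mean curve from an FLM fit
#'
#' Adds or subtracts the fitted functional coefficients according to a
#' covariate combination: e.g. with +1/-1 coded apnea and BMI terms and
#' their interaction, `combo = c(AHI = 1, BMI = 1)` yields
#' `beta_0(t) + beta_AHI(t) + beta_BMI(t) + beta_AHI:BMI(t)` (the
#' low/low group); interaction codes are derived as products of the
#' parent codes.
#'
#' @param fit An `flm_fit`.
#' @param combo Named vector/list giving the code (or continuous value)
#'   of every non-intercept base term.
#' @param at Evaluation times in minutes (default: full grid).
#' @return A tibble with `minute`, `activity`, plus the curve's basis
#'   coefficients in the `coefficients` attribute.
#' @export
group_mean_curve <- function(fit, combo, at = NULL) {
  stopifnot(inherits(fit, "flm_fit"))
  cvec <- combo_contrast(fit, combo)
  at <- at %||% fit$basis$grid
  coefs <- drop(cvec %*% fit$coef)
  vals <- drop(eval_basis(fit$basis, at) %*% coefs)
  structure(tibble::tibble(minute = as.numeric(at), activity = vals),
            coefficients = coefs)
}

#' Pointwise F statistic of an FLM fit
#'
#' At each time `t`, the ratio of the variance (divisor `N - 1`) of the
#' `N` design-predicted values `(Z %*% beta_hat)_k(t)` to the mean
#' (divisor `N`) squared residual.  Time points where both numerator
#' and denominator vanish return 0 with a warning.
#'
#' @param fit An `flm_fit` with at least 2 subjects.
#' @param at Evaluation times in minutes (default: full 1440-minute
#'   grid).
#' @return A tibble with `minute` and `statistic` (nonnegative).
#' @export
pointwise_F <- function(fit, at = NULL) {
  stopifnot(inherits(fit, "flm_fit"))
  N <- nrow(fit$A)
  if (N < 2) abort("pointwise_F() needs at least 2 subjects")
  at <- at %||% fit$basis$grid
  G <- t(eval_basis(fit$basis, at))                     # n_basis x G
  fitted <- (fit$design$Z %*% fit$coef) %*% G           # N x G
  resid <- fit$residual_coef %*% G                      # N x G
  num <- .colVars(fitted)
  den <- colSums(resid^2) / N
  f <- num / den
  zz <- which(den == 0)
  if (length(zz) > 0) {
    f[zz] <- ifelse(num[zz] == 0, 0, Inf)
    if (any(num[zz] == 0)) {
      warn(paste0("F(t) is 0/0 at ", sum(num[zz] == 0),
                  " time point(s); reported as 0"))
    }
  }
  tibble::tibble(minute = as.numeric(at), statistic = f)
}

# column-wise sample variance (divisor N - 1)
.colVars <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  colSums(sweep(m, 2, mu)^2) / (n - 1)
}

#' Pointwise confidence band for a group mean curve
#'
#' Normal-theory pointwise (not simultaneous) limits: at each minute,
#' `estimate +/- z * sqrt(sigma2(t) * c' (Z'Z)^{-1} c)`, where `c` is
#' the contrast vector of the covariate combination and `sigma2(t)` is
#' the residual-curve variance `sum_k eps_k(t)^2 / (N - p)`.
#'
#' @inheritParams group_mean_curve
#' @param level Coverage level in (0, 1); default 0.95.
#' @return A tibble with `minute`, `estimate`, `lower`, `upper`, `se`.
#' @export
confidence_band <- function(fit, combo, level = 0.95, at = NULL) {
  stopifnot(inherits(fit, "flm_fit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("level must be a single number in (0, 1)")
  }
  cvec <- combo_contrast(fit, combo)
  at <- at %||% fit$basis$grid
  N <- nrow(fit$A)
  p <- ncol(fit$design$Z)
  G <- t(eval_basis(fit$basis, at))
  est <- drop((cvec %*% fit$coef) %*% G)
  sigma2 <- colSums((fit$residual_coef %*% G)^2) / (N - p)
  ZtZinv <- chol2inv(chol(crossprod(fit$design$Z)))
  lever <- drop(cvec %*% ZtZinv %*% cvec)
  se <- sqrt(sigma2 * lever)
  z <- qnorm((1 + level) / 2)
  tibble::tibble(minute = as.numeric(at), estimate = est,
                 lower = est - z * se, upper = est + z * se, se = se)
}

#' Write betas / group means on the grid as CSV, and a JSON fit summary
#'
#' @param fit An `flm_fit`.
#' @param file Destination path.
#' @return `file`, invisibly.
#' @export
write_flm_curves <- function(fit, file) {
  wide <- tidy(fit) |>
    tidyr::pivot_wider(names_from = "term", values_from = "estimate")
  readr::write_csv(wide, file, progress = FALSE)
  invisible(file)
}

#' @rdname write_flm_curves
#' @export
write_flm_summary <- function(fit, file) {
  g <- glance(fit)
  out <- list(n = g$n, p = g$p, n_basis = g$n_basis,
              df_residual = g$df_residual, r_squared = g$r_squared,
              condition_number = g$kappa,
              columns = fit$design$column_names,
              dropped_subjects = fit$design$dropped)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
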