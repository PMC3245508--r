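#' Permutation test for differences in circadian activity patterns
#'
#' Builds the null distribution of the pointwise F statistic by randomly
#' rearranging the covariate assignment across subjects: for each
#' permutation the non-intercept rows of the design are shuffled jointly
#' (preserving the joint covariate distribution in multi-term models),
#' the model is refitted, and `F*(t)` recomputed.  Two summaries are
#' reported:
#'
#' * **global** — the proportion of permuted `max_t F*(t)` at or above
#'   the observed maximum (one conservative critical value for the whole
#'   curve), and
#' * **pointwise** — at each minute, the proportion of permuted `F*(t)`
#'   at or above the observed `F(t)` (a critical curve).
#'
#' p-values use the add-one estimator `(1 + b) / (n_perm + 1)`, so they
#' are strictly positive and valid; ties count against rejection.  In
#' models with several covariates the permutation tests the global null
#' that no covariate is associated with the activity pattern; it cannot
#' isolate one covariate among many.
#'
#' @param fit An `flm_fit` with at least one non-intercept column and
#'   `N >= 4` subjects.
#' @param n_perm Number of permutations (default 1000).  A warning is
#'   issued when `n_perm < 20 / alpha`, where the empirical (1 - alpha)
#'   quantile is unstable.
#' @param alpha Significance level for critical values and reported
#'   intervals (default 0.05).
#' @param seed Integer seed; mandatory, consumed via a local RNG scope
#'   (the caller's RNG state is untouched).
#' @param at Evaluation grid in minutes (default: full 1440-minute
#'   grid).
#' @return An object of class `flm_perm`: list with `observed` (tibble
#'   `minute`, `statistic`), `global_p`, `global_critical`, `pointwise`
#'   (tibble `minute`, `statistic`, `critical`, `p_value`),
#'   `intervals_global` and `intervals_pointwise` (see
#'   [significant_intervals()]), `perm_max` (the permuted max-F values),
#'   `n_perm`, `alpha`, `seed`.
#' @export
permutation_F_test <- function(fit, n_perm = 1000L, alpha = 0.05, seed,
                               at = NULL) {
  stopifnot(inherits(fit, "flm_fit"))
  if (missing(seed)) abort("seed is mandatory (reproducibility contract)")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1) abort("n_perm must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort("alpha must be in (0,1)")
  Z <- fit$design$Z
  N <- nrow(Z)
  p <- ncol(Z)
  if (p < 2) abort("design needs at least one non-intercept column")
  if (N < 4) abort("permutation test needs N >= 4 subjects")
  binary_cols <- Z[, -1, drop = FALSE]
  if (all(binary_cols %in% c(-1, 1)) &&
      any(apply(binary_cols, 2, function(cc) length(unique(cc)) < 2))) {
    abort("all subjects are in one group; nothing to permute")
  }
  if (n_perm < 20 / alpha) {
    warn(paste0("n_perm = ", n_perm, " is small for alpha = ", alpha,
                "; the empirical critical value is unstable"))
  }
  at <- at %||% fit$basis$grid
  G <- t(eval_basis(fit$basis, at))          # n_basis x G
  A <- fit$A
  act_vals <- A %*% G                        # N x G, fixed across permutations

  f_of <- function(Zp) {
    B <- qr.coef(qr(Zp), A)
    fitted <- (Zp %*% B) %*% G
    num <- .colVars(fitted)
    den <- colSums((act_vals - fitted)^2) / N
    f <- num / den
    f[den == 0] <- ifelse(num[den == 0] == 0, 0, Inf)
    f
  }

  f_obs <- f_of(Z)
  max_obs <- max(f_obs)
  perm_max <- numeric(n_perm)
  ge_point <- numeric(length(at))
  perm_F <- matrix(0, nrow = n_perm, ncol = length(at))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(N)
      Zp <- Z
      Zp[, -1] <- Z[idx, -1, drop = FALSE]
      fb <- f_of(Zp)
      perm_F[b, ] <- fb
      perm_max[b] <- max(fb)
      ge_point <- ge_point + (fb >= f_obs)
    }
  })
  global_p <- (1 + sum(perm_max >= max_obs)) / (n_perm + 1)
  pointwise_p <- (1 + ge_point) / (n_perm + 1)
  global_critical <- unname(quantile(perm_max, 1 - alpha, names = FALSE))
  pointwise_critical <- apply(perm_F, 2, quantile, probs = 1 - alpha,
                              names = FALSE)
  observed <- tibble::tibble(minute = as.numeric(at), statistic = f_obs)
  structure(list(
    observed = observed,
    global_p = global_p,
    global_critical = global_critical,
    pointwise = tibble::tibble(minute = as.numeric(at), statistic = f_obs,
                               critical = pointwise_critical,
                               p_value = pointwise_p),
    intervals_global = significant_intervals(observed, global_critical),
    intervals_pointwise = significant_intervals(observed, pointwise_critical),
    perm_max = perm_max,
    n_perm = n_perm, alpha = alpha, seed = seed
  ), class = "flm_perm")
}

#' @export
print.flm_perm <- function(x, ...) {
  cat("<flm_perm> ", x$n_perm, " permutations, alpha = ", x$alpha,
      ", seed = ", x$seed, "\n", sep = "")
  cat("  global p = ", format(x$global_p, digits = 4),
      " (critical max-F = ", format(x$global_critical, digits = 4), ")\n",
      sep = "")
  iv <- x$intervals_global
  if (nrow(iv) > 0) {
    cat("  globally significant: ",
        paste(iv$label, collapse = ", "), "\n", sep = "")
  } else {
    cat("  no globally significant intervals\n")
  }
  invisible(x)
}

#' @rdname permutation_F_test
#' @param x An `flm_perm`.
#' @param ... Unused.
#' @method tidy flm_perm
#' @export
tidy.flm_perm <- function(x, ...) {
  dplyr::mutate(x$pointwise,
                significant_global = .data$statistic > x$global_critical,
                significant_pointwise = .data$statistic > .data$critical)
}

#' @rdname permutation_F_test
#' @method glance flm_perm
#' @export
glance.flm_perm <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, alpha = x$alpha, seed = x$seed,
                 global_p = x$global_p, global_critical = x$global_critical,
                 max_F = max(x$observed$statistic),
                 n_intervals_global = nrow(x$intervals_global))
}

#' Time intervals where F(t) exceeds a critical threshold
#'
#' Finds maximal runs of grid minutes with `statistic > threshold` and
#' reports them as half-open minute intervals `[start, end)`.  When the
#' grid covers a full period and the run wraps across midnight, the two
#' edge runs are merged into a single interval whose `end` is smaller
#' than its `start` (it crosses 00:00).
#'
#' @param observed A tibble with `minute` and `statistic` (e.g.
#'   `$observed` of an [permutation_F_test()] result), or a numeric
#'   vector of F values on `0..1439`.
#' @param threshold A single critical value, or a vector/curve (tibble
#'   with `minute`, `critical` or `statistic`) on the same grid.
#' @return A tibble with `start`, `end` (minutes) and `label`
#'   ("HH:MM-HH:MM").
#' @export
significant_intervals <- function(observed, threshold) {
  if (is.numeric(observed)) {
    observed <- tibble::tibble(minute = seq_along(observed) - 1,
                               statistic = observed)
  }
  .assert_columns(observed, c("minute", "statistic"), "significant_intervals()")
  f <- observed$statistic
  minute <- observed$minute
  if (is.data.frame(threshold)) {
    tc <- if ("critical" %in% names(threshold)) "critical" else "statistic"
    if (nrow(threshold) != length(f) ||
        any(abs(threshold$minute - minute) > 1e-9)) {
      abort("threshold curve grid does not match the observed grid")
    }
    thr <- threshold[[tc]]
  } else {
    thr <- threshold
    if (!length(thr) %in% c(1L, length(f))) {
      abort("threshold must be scalar or match the observed grid")
    }
  }
  above <- f > thr
  if (!any(above)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0),
                          label = character(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  step <- if (length(minute) > 1) minute[2] - minute[1] else 1
  iv <- tibble::tibble(start = minute[starts[runs]],
                       end = minute[ends[runs]] + step)
  full_period <- length(minute) > 1 &&
    abs((minute[length(minute)] + step) - (minute[1] + 1440)) < 1e-9
  if (full_period && nrow(iv) > 1 && above[1] && above[length(above)]) {
    # wrap across midnight: merge last run into the first
    iv$end[nrow(iv)] <- iv$end[1]
    iv <- iv[-1, , drop = FALSE]
  }
  iv$label <- paste0(minute_to_hhmm(iv$start), "-", minute_to_hhmm(iv$end))
  iv
}

#' Write a permutation-test result as JSON
#'
#' @param perm An `flm_perm`.
#' @param file Destination path.
#' @return `file`, invisibly.
#' @export
write_perm_json <- function(perm, file) {
  iv <- function(tbl) {
    purrr::pmap(tbl, function(start, end, label) {
      list(start_minute = start, end_minute = end, clock = label)
    })
  }
  out <- list(
    n_perm = perm$n_perm, alpha = perm$alpha, seed = perm$seed,
    global_p = perm$global_p, global_critical = perm$global_critical,
    max_F = max(perm$observed$statistic),
    intervals_global = iv(perm$intervals_global),
    intervals_pointwise = iv(perm$intervals_pointwise)
  )
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
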