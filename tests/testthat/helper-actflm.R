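# Fixtures built in code: no data files.

# epochs for given per-subject count vectors, contiguous minutes from `start`
make_epochs <- function(counts, start = "2024-01-01 00:00:00") {
  start <- as.POSIXct(start, tz = "UTC")
  rows <- purrr::imap(counts, function(y, id) {
    tibble::tibble(subject_id = id,
                   timestamp = start + 60 * (seq_along(y) - 1),
                   count = y)
  })
  as_epochs(dplyr::bind_rows(rows))
}

# random epoch collection with optional gaps (gaps = dropped rows)
random_epochs <- function(n_subjects = 3, n_minutes = 120, gap_prob = 0.1,
                          seed = 1) {
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_subjects), function(k) {
      y <- round(runif(n_minutes, 0, 500), 1)
      keep <- runif(n_minutes) > gap_prob
      keep[c(1, n_minutes)] <- TRUE   # keep the span endpoints
      tibble::tibble(
        subject_id = sprintf("R%02d", k),
        timestamp = as.POSIXct("2024-01-01", tz = "UTC") + 60 * (which(keep) - 1),
        count = y[keep])
    })
    as_epochs(dplyr::bind_rows(rows))
  })
}

# profiles tibble with one random 1440-minute profile per subject
random_profiles <- function(n_subjects = 4, seed = 1, grid = 0:1439) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject_id = rep(sprintf("P%02d", seq_len(n_subjects)), each = length(grid)),
      minute = rep(grid, n_subjects),
      activity = pmax(0, rnorm(n_subjects * length(grid), 200, 80)))
  })
}

# curves tibble with random coefficients drawn directly in the basis span
random_curves <- function(n_subjects = 12, n_basis = 9, seed = 1) {
  basis <- fourier_basis(n_basis, 1440)
  withr::with_seed(seed, {
    out <- tibble::tibble(subject_id = sprintf("C%02d", seq_len(n_subjects)))
    out$a1 <- rnorm(n_subjects, 300, 60)
    for (i in 2:n_basis) out[[paste0("a", i)]] <- rnorm(n_subjects, 0, 30)
    actflm:::new_tbl_curves(out, basis)
  })
}

# constant-curve fixture at given levels (one flat curve per subject)
constant_curves <- function(levels, ids = sprintf("K%02d", seq_along(levels)),
                            n_basis = 9) {
  basis <- fourier_basis(n_basis, 1440)
  out <- tibble::tibble(subject_id = ids, a1 = as.numeric(levels))
  for (i in 2:n_basis) out[[paste0("a", i)]] <- 0
  actflm:::new_tbl_curves(out, basis)
}

# the printed 8-subject example: per-subject average activities and groups
worked_example <- function() {
  list(
    low = c(370, 397, 482, 421),     # low apnea, code +1
    high = c(78, 76, 80, 76),        # high apnea, code -1
    ids = sprintf("W%d", 1:8),
    covariates = tibble::tibble(subject_id = sprintf("W%d", 1:8),
                                AHI = c(rep(2, 4), rep(40, 4)))
  )
}

worked_example_fit <- function() {
  ex <- worked_example()
  curves <- constant_curves(c(ex$low, ex$high), ids = ex$ids)
  fit_flm(curves, ex$covariates,
          flm_spec(flm_binary("AHI", threshold = "median")))
}

# independent pointwise-OLS oracle: beta_j(t) by .lm.fit minute by minute
pointwise_ols_oracle <- function(Z, act_vals) {
  p <- ncol(Z)
  vapply(seq_len(ncol(act_vals)),
         function(j) .lm.fit(Z, act_vals[, j])$coefficients,
         numeric(p))                      # p x G
}

# naive subject-loop evaluation of the pointwise F statistic
naive_F_oracle <- function(Z, beta_vals, act_vals) {
  N <- nrow(Z)
  G <- ncol(act_vals)
  f <- numeric(G)
  for (j in seq_len(G)) {
    fitted <- numeric(N)
    for (k in seq_len(N)) fitted[k] <- sum(Z[k, ] * beta_vals[, j])
    num <- var(fitted)
    den <- sum((act_vals[, j] - fitted)^2) / N
    f[j] <- num / den
  }
  f
}
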