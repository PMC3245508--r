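#' Parametric circadian curve (cosinor-style)
#'
#' Describes a smooth 24-hour curve `mesor + amplitude *
#' cos(2*pi*(t - acrophase)/period)` plus optional extra harmonics, used
#' for the baseline mean and the covariate effect curves of the
#' synthetic cohort generator.
#'
#' @param mesor Midline level (counts/min for baseline curves; an effect
#'   curve's mesor is a constant activity shift).
#' @param amplitude Half peak-to-trough range (counts/min).
#' @param acrophase Peak time in minutes after midnight (default 900 =
#'   15:00, a typical afternoon activity peak).
#' @param harmonics Optional list of extra components, each
#'   `list(k = harmonic number, amplitude = , acrophase = minutes)`.
#' @param period Period in minutes (default 1440).
#' @return An object of class `circadian_curve`.
#' @examples
#' mu <- circadian_curve(mesor = 250, amplitude = 150, acrophase = 900)
#' head(eval_circadian(mu, 0:5))
#' @export
circadian_curve <- function(mesor, amplitude = 0, acrophase = 900,
                            harmonics = NULL, period = 1440) {
  stopifnot(is.numeric(mesor), is.numeric(amplitude), is.numeric(acrophase))
  structure(list(mesor = mesor, amplitude = amplitude, acrophase = acrophase,
                 harmonics = harmonics, period = period),
            class = "circadian_curve")
}

#' @rdname circadian_curve
#' @param curve A `circadian_curve`.
#' @param times Minutes at which to evaluate.
#' @return For `eval_circadian()`: numeric vector of curve values.
#' @export
eval_circadian <- function(curve, times = 0:1439) {
  stopifnot(inherits(curve, "circadian_curve"))
  w <- 2 * pi / curve$period
  v <- curve$mesor + curve$amplitude * cos(w * (times - curve$acrophase))
  for (h in curve$harmonics %||% list()) {
    v <- v + h$amplitude * cos(h$k * w * (times - h$acrophase))
  }
  v
}

#' Declare a synthetic covariate effect
#'
#' `effect_binary()` attaches an effect curve `delta(t)` to a balanced
#' +1/-1 covariate (subject `k` contributes `code_k * delta(t)`);
#' `effect_continuous()` attaches it to a continuous covariate whose
#' values span `range` (contribution `x_k * delta(t)`).  Covariate
#' codes/values are deterministic functions of the cohort size
#' (alternating codes, evenly spaced values) so the truth bundle is
#' identical across simulation seeds.
#'
#' @param curve A [circadian_curve()] effect `delta(t)`.
#' @param range For `effect_continuous()`: length-2 numeric range of the
#'   covariate values.
#' @return An effect declaration for [cohort_spec()].
#' @export
effect_binary <- function(curve) {
  stopifnot(inherits(curve, "circadian_curve"))
  structure(list(kind = "binary", curve = curve), class = "cohort_effect")
}

#' @rdname effect_binary
#' @export
effect_continuous <- function(curve, range = c(0, 1)) {
  stopifnot(inherits(curve, "circadian_curve"),
            is.numeric(range), length(range) == 2, range[1] < range[2])
  structure(list(kind = "continuous", curve = curve, range = range),
            class = "cohort_effect")
}

#' Specify a synthetic actigraphy cohort
#'
#' Defines the data-generating model
#' `y_k(t) = max(0, mu(t) + sum_c x_kc * delta_c(t) + s_k(t) + noise)`
#' per minute and day, where `mu` is the baseline circadian mean,
#' `delta_c` are covariate effect curves, `s_k` is a smooth subject-level
#' random curve drawn in the 9-term Fourier span (so the default
#' smoother is unbiased for it), and the minute noise is either Gaussian
#' (truncated at 0 with the mean) or Poisson-like
#' (variance = mean x dispersion).
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param n_days Days recorded per subject, starting midnight Monday
#'   (default 5 weekdays).
#' @param baseline A [circadian_curve()] for `mu(t)`.
#' @param effects Named list of [effect_binary()] /
#'   [effect_continuous()] declarations; names become covariate names.
#' @param subject_sd Pointwise SD (counts/min) of the smooth
#'   subject-level random curve (its 9 Fourier coefficients are iid
#'   normal, scaled so the curve's stationary SD equals `subject_sd`).
#' @param minute_noise_sd SD of the Gaussian minute noise (ignored for
#'   Poisson-like noise).
#' @param noise `"gaussian"` (truncated at 0) or `"poisson"`
#'   (variance = mean x `dispersion`).
#' @param dispersion Dispersion of the Poisson-like family.
#' @param rough_sd Optional SD of an out-of-span high-frequency
#'   component (harmonic 12) added to subject curves, to probe smoother
#'   robustness; default 0 (off).
#' @param start_date Calendar date of the first midnight; must be a
#'   Monday (default 2024-01-01).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_days = 5L,
                        baseline = circadian_curve(250, 150, 900),
                        effects = list(),
                        subject_sd = 30, minute_noise_sd = 60,
                        noise = c("gaussian", "poisson"), dispersion = 5,
                        rough_sd = 0,
                        start_date = as.Date("2024-01-01")) {
  noise <- rlang::arg_match(noise)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 4) abort("n_subjects must be >= 4")
  if (length(effects) > 0 &&
      (is.null(names(effects)) || any(names(effects) == ""))) {
    abort("effects must be a named list (names become covariate names)")
  }
  if (!all(vapply(effects, inherits, logical(1), "cohort_effect"))) {
    abort("each effect must come from effect_binary()/effect_continuous()")
  }
  if (.wday_mon1(start_date) != 1L) abort("start_date must be a Monday")
  spec <- structure(
    list(n_subjects = n_subjects, n_days = as.integer(n_days),
         baseline = baseline, effects = effects,
         subject_sd = subject_sd, minute_noise_sd = minute_noise_sd,
         noise = noise, dispersion = dispersion, rough_sd = rough_sd,
         start_date = start_date),
    class = "cohort_spec")
  .check_cohort_spec(spec)
  spec
}

# deterministic covariate codes / values (identical across seeds)
.cohort_codes <- function(spec) {
  n <- spec$n_subjects
  out <- list()
  for (nm in names(spec$effects)) {
    e <- spec$effects[[nm]]
    out[[nm]] <- if (e$kind == "binary") {
      rep_len(c(1, -1), n)
    } else {
      seq(e$range[1], e$range[2], length.out = n)
    }
  }
  out
}

# worst-case mean must stay nonnegative before noise truncation
.check_cohort_spec <- function(spec) {
  t <- 0:1439
  mu <- eval_circadian(spec$baseline, t)
  worst <- mu
  codes <- .cohort_codes(spec)
  for (nm in names(spec$effects)) {
    d <- eval_circadian(spec$effects[[nm]]$curve, t)
    worst <- worst - max(abs(codes[[nm]])) * abs(d)
  }
  if (min(worst) < 0) {
    abort(paste0("invalid cohort_spec: baseline minus worst-case effects dips to ",
                 round(min(worst), 2), " < 0"))
  }
  invisible(spec)
}

.subject_ids <- function(n) sprintf("S%03d", seq_len(n))

#' True group mean curve implied by a cohort specification
#'
#' `mu(t) + sum_c combo_c * delta_c(t)` on the minute grid — the
#' pre-truncation truth against which pipeline estimates are compared.
#'
#' @param spec A [cohort_spec()].
#' @param combo Named vector/list with one code (or continuous value)
#'   per declared effect; an empty combo (or 0 codes) returns `mu(t)`.
#' @return A tibble with `minute` (0--1439) and `activity`.
#' @export
true_group_curve <- function(spec, combo = list()) {
  stopifnot(inherits(spec, "cohort_spec"))
  combo <- as.list(combo)
  unknown <- setdiff(names(combo), names(spec$effects))
  if (length(unknown) > 0) {
    abort(paste0("unknown covariate(s) in combo: ",
                 paste(unknown, collapse = ", ")))
  }
  t <- 0:1439
  v <- eval_circadian(spec$baseline, t)
  for (nm in names(combo)) {
    v <- v + as.numeric(combo[[nm]]) * eval_circadian(spec$effects[[nm]]$curve, t)
  }
  tibble::tibble(minute = t, activity = v)
}

#' Simulate a synthetic actigraphy cohort
#'
#' Generates minute-epoch recordings, the covariate table, and a truth
#' bundle for end-to-end pipeline validation.  The truth bundle (mean
#' curve, effect curves, covariate codes) is a deterministic function of
#' the spec; the seed drives only subject curves and minute noise.
#'
#' Binary covariates are emitted in the covariate table as severity
#' scores in \{0, 1\} (0 for subjects with code +1, 1 for code -1), so
#' the canonical [flm_binary()] threshold of 0.5 reproduces the true
#' codes; continuous covariates are emitted as their values.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (mandatory; local RNG scope).
#' @return A list of class `actflm_cohort`:
#'   * `epochs` — a `tbl_epochs` (no missing minutes),
#'   * `covariates` — tibble `subject_id` + one column per effect,
#'   * `truth` — list with `mu` (1440 vector), `effects` (named list of
#'     1440 vectors), `codes` (tibble of true per-subject codes/values),
#'     `subject_coefs` (the random subject-curve Fourier coefficients)
#'     and `spec`.
#' @export
simulate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed)) abort("seed is mandatory")
  .check_cohort_spec(spec)
  n <- spec$n_subjects
  t <- 0:1439
  mu <- eval_circadian(spec$baseline, t)
  codes <- .cohort_codes(spec)
  deltas <- lapply(spec$effects, function(e) eval_circadian(e$curve, t))
  ids <- .subject_ids(n)

  # per-subject pre-noise mean: mu + sum_c code * delta  (n x 1440)
  mean_mat <- matrix(mu, nrow = n, ncol = 1440, byrow = TRUE)
  for (nm in names(deltas)) {
    mean_mat <- mean_mat + outer(codes[[nm]], deltas[[nm]])
  }

  n_basis <- 9L
  basis_eval <- fourier_eval(n_basis, 2 * pi / 1440, t)
  counts <- withr::with_seed(seed, {
    subj_coefs <- matrix(rnorm(n * n_basis, sd = spec$subject_sd / sqrt(5)),
                         nrow = n)
    subj_curves <- subj_coefs %*% t(basis_eval)
    if (spec$rough_sd > 0) {
      rough <- matrix(rnorm(n * 2, sd = spec$rough_sd / sqrt(2)), nrow = n)
      w <- 2 * pi / 1440
      subj_curves <- subj_curves +
        rough %*% rbind(cos(12 * w * t), sin(12 * w * t))
    }
    day_mean <- mean_mat + subj_curves                    # n x 1440
    total <- n * spec$n_days * 1440L
    # minutes vary fastest, then days, then subjects
    m_full <- rep(seq_len(n), each = spec$n_days * 1440L) # subject index
    mm <- day_mean[cbind(m_full, rep(rep(t + 1L, times = spec$n_days), n))]
    y <- if (spec$noise == "gaussian") {
      pmax(0, mm + rnorm(total, sd = spec$minute_noise_sd))
    } else {
      d <- spec$dispersion
      d * rpois(total, lambda = pmax(mm, 0) / d)
    }
    attr(y, "subject_coefs") <- subj_coefs
    y
  })
  subj_coefs <- attr(counts, "subject_coefs")
  attr(counts, "subject_coefs") <- NULL

  start <- as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC")
  ts_one <- start + 60 * seq_len(spec$n_days * 1440L) - 60
  epochs <- new_tbl_epochs(
    tibble::tibble(
      subject_id = rep(ids, each = spec$n_days * 1440L),
      timestamp = rep(ts_one, times = n),
      count = as.numeric(counts),
      missing = FALSE
    ), 60L)

  covariates <- tibble::tibble(subject_id = ids)
  truth_codes <- tibble::tibble(subject_id = ids)
  for (nm in names(spec$effects)) {
    e <- spec$effects[[nm]]
    truth_codes[[nm]] <- codes[[nm]]
    covariates[[nm]] <- if (e$kind == "binary") {
      ifelse(codes[[nm]] > 0, 0, 1)
    } else codes[[nm]]
  }

  structure(list(
    epochs = epochs,
    covariates = covariates,
    truth = list(mu = mu, effects = deltas, codes = truth_codes,
                 subject_coefs = subj_coefs, spec = spec)
  ), class = "actflm_cohort")
}

#' Default model specification for a simulated cohort
#'
#' Maps the cohort's effects onto [flm_spec()] terms: binary effects
#' become [flm_binary()] terms with the canonical 0.5 threshold on the
#' emitted \{0, 1\} severity score, continuous effects become
#' [flm_continuous()] terms.
#'
#' @param spec A [cohort_spec()].
#' @return An [flm_spec()].
#' @export
cohort_model_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  terms <- purrr::imap(spec$effects, function(e, nm) {
    if (e$kind == "binary") flm_binary(nm, threshold = 0.5)
    else flm_continuous(nm)
  })
  do.call(flm_spec, unname(terms))
}

#' @export
print.actflm_cohort <- function(x, ...) {
  sp <- x$truth$spec
  cat("<actflm_cohort> ", sp$n_subjects, " subjects x ", sp$n_days,
      " days x 1440 min; effects: ",
      if (length(sp$effects)) paste(names(sp$effects), collapse = ", ") else "none",
      "; noise: ", sp$noise, "\n", sep = "")
  invisible(x)
}
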