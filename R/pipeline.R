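#' Default pipeline configuration
#'
#' All tunables of the end-to-end run with their defaults: weekday
#' selection (Mon--Fri), minimum usable days (3), Fourier smoothing
#' (9 basis functions, 1440-minute period), model terms, permutation
#' settings (1000 permutations, alpha 0.05) and output toggles.
#'
#' @return A named list; edit and pass to [run_pipeline()].
#' @export
default_config <- function() {
  list(
    epochs = NULL,            # path to epoch CSV/TSV
    covariates = NULL,        # path to covariate CSV/TSV
    days = c("Mon", "Tue", "Wed", "Thu", "Fri"),
    min_days = 3,
    partial = "drop",
    missing = "ignore",
    n_basis = 9,
    period = 1440,
    model = list(             # list of term descriptions
      list(kind = "binary", covariate = "AHI", threshold = "median")
    ),
    n_perm = 1000,
    alpha = 0.05,
    seed = NULL,              # mandatory when n_perm > 0
    out_dir = "actflm-results",
    plots = TRUE
  )
}

# term-description list -> flm_spec
config_model_spec <- function(model) {
  terms <- purrr::map(model, function(m) {
    kind <- m$kind %||% "binary"
    switch(kind,
      binary = flm_binary(m$covariate, threshold = m$threshold %||% "median",
                          name = m$name %||% m$covariate),
      continuous = flm_continuous(m$covariate,
                                  center = isTRUE(m$center),
                                  scale = isTRUE(m$scale),
                                  name = m$name %||% m$covariate),
      interaction = do.call(flm_interaction,
                            c(as.list(unlist(m$parents)),
                              list(name = m$name %||% NULL))),
      abort(paste0("unknown model term kind: ", kind))
    )
  })
  do.call(flm_spec, terms)
}

#' Run the full actigraphy FLM pipeline
#'
#' Reads epochs and covariates, builds per-subject circadian profiles,
#' smooths them, fits the functional linear model, runs the permutation
#' F test, and writes results (profiles CSV, coefficient CSV, beta
#' curves CSV, fit JSON, permutation JSON, figures, run log) to the
#' output directory.  Identical configuration and seed give identical
#' JSON/CSV results.
#'
#' @param config A configuration list (see [default_config()]) or a
#'   path to a YAML file with the same fields.
#' @return Invisibly, a list with `profiles`, `curves`, `fit`, `perm`
#'   and the output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_config(), config)
  if (is.null(cfg$epochs) || is.null(cfg$covariates)) {
    abort("config must name 'epochs' and 'covariates' input files")
  }
  for (f in c(cfg$epochs, cfg$covariates)) {
    if (!file.exists(f)) abort(paste0("input file not found: ", f))
  }
  if (cfg$n_perm > 0 && is.null(cfg$seed)) {
    abort("config must set 'seed' when permutation testing is enabled")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(cfg$out_dir, "run.log")
  logi <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_file, append = TRUE)
    inform(msg)
  }
  unlink(log_file)

  logi("stage: read (", cfg$epochs, ", ", cfg$covariates, ")")
  epochs <- read_epochs(cfg$epochs)
  covariates <- read_covariates(cfg$covariates)
  logi("  ", length(unique(epochs$subject_id)), " subjects with epochs; ",
       nrow(covariates), " covariate rows")

  logi("stage: profiles (days ", paste(cfg$days, collapse = ","),
       ", min_days ", cfg$min_days, ")")
  profiles <- withCallingHandlers(
    daily_profiles(epochs, days = cfg$days, min_days = cfg$min_days,
                   partial = cfg$partial, missing = cfg$missing),
    warning = function(w) {
      cat("  ", conditionMessage(w), "\n", file = log_file, append = TRUE)
      invokeRestart("muffleWarning")
    })
  n_prof <- length(unique(profiles$subject_id))
  logi("  ", n_prof, " subjects retained with usable profiles")

  logi("stage: smooth (n_basis ", cfg$n_basis, ", period ", cfg$period, ")")
  curves <- smooth_profiles(profiles, n_basis = cfg$n_basis, period = cfg$period)

  logi("stage: fit")
  spec <- config_model_spec(cfg$model)
  fit <- fit_flm(curves, covariates, spec)
  logi("  N = ", nrow(fit$A), " subjects in model (",
       length(fit$design$dropped), " dropped for missing covariates)")

  perm <- NULL
  if (cfg$n_perm > 0) {
    logi("stage: permtest (n_perm ", cfg$n_perm, ", alpha ", cfg$alpha,
         ", seed ", cfg$seed, ")")
    perm <- permutation_F_test(fit, n_perm = cfg$n_perm, alpha = cfg$alpha,
                               seed = cfg$seed)
    logi("  global p = ", format(perm$global_p, digits = 4))
  }

  paths <- list(
    profiles = file.path(cfg$out_dir, "profiles.csv"),
    coefficients = file.path(cfg$out_dir, "coefficients.csv"),
    betas = file.path(cfg$out_dir, "beta_curves.csv"),
    fit = file.path(cfg$out_dir, "fit.json"),
    log = log_file
  )
  write_profiles(profiles, paths$profiles)
  write_curves(curves, paths$coefficients)
  write_flm_curves(fit, paths$betas)
  write_flm_summary(fit, paths$fit)
  if (!is.null(perm)) {
    paths$permutation <- file.path(cfg$out_dir, "permutation.json")
    write_perm_json(perm, paths$permutation)
  }
  if (isTRUE(cfg$plots)) {
    paths$figure <- file.path(cfg$out_dir, "flm.pdf")
    plot_flm(fit, perm, file = paths$figure)
  }
  logi("done: results in ", cfg$out_dir)
  invisible(list(profiles = profiles, curves = curves, fit = fit,
                 perm = perm, paths = paths))
}
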