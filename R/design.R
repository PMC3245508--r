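#' Dichotomise a covariate into +1 / -1 codes
#'
#' Codes values below the threshold as `+1` and values at or above it as
#' `-1` — the "low disease burden = +1" convention, so that adding the
#' corresponding functional coefficient to the mean curve gives the
#' low group and subtracting it gives the high group.
#'
#' @param x Numeric vector with no missing values (complete-case
#'   filtering happens upstream in [build_design()]).
#' @param threshold Finite cut point; values exactly at the threshold
#'   code `-1`.
#' @return Integer vector of `+1` / `-1`.
#' @examples
#' encode_binary(c(9, 11), 10.8)   # +1, -1
#' encode_binary(34, 30)           # -1 (obese)
#' @export
encode_binary <- function(x, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold)) {
    abort("threshold must be a single finite number")
  }
  if (anyNA(x)) abort("encode_binary() requires complete input (no NA)")
  ifelse(x < threshold, 1L, -1L)
}

#' Model terms for a functional linear model
#'
#' These helpers declare the columns of the design matrix (besides the
#' intercept, which is always present and listed first).
#'
#' * `flm_binary()` — a covariate dichotomised at `threshold` into
#'   +1 (below) / -1 (at or above); `threshold = "median"` uses the
#'   complete-case median computed by [build_design()].
#' * `flm_continuous()` — a covariate used as-is (optionally centred /
#'   standardised).
#' * `flm_interaction()` — elementwise product of previously declared
#'   terms.
#'
#' @param covariate Covariate column name in the covariate table.
#' @param threshold Numeric cut point or `"median"`.
#' @param center,scale Centre (subtract mean) / standardise (divide by
#'   SD) a continuous covariate, using complete-case statistics.
#' @param name Column name in the design matrix (default: the covariate
#'   name, or the parent names joined by `:` for interactions).
#' @param ... For `flm_interaction()`: names of previously declared
#'   terms.
#' @return A term object for [flm_spec()].
#' @examples
#' flm_spec(flm_binary("AHI"), flm_binary("BMI", threshold = 30),
#'          flm_interaction("AHI", "BMI"))
#' @export
flm_binary <- function(covariate, threshold = "median", name = covariate) {
  if (!(identical(threshold, "median") ||
        (is.numeric(threshold) && length(threshold) == 1 && is.finite(threshold)))) {
    abort("threshold must be a finite number or \"median\"")
  }
  structure(list(kind = "binary", name = name, covariate = covariate,
                 threshold = threshold),
            class = "flm_term")
}

#' @rdname flm_binary
#' @export
flm_continuous <- function(covariate, center = FALSE, scale = FALSE,
                           name = covariate) {
  structure(list(kind = "continuous", name = name, covariate = covariate,
                 center = center, scale = scale),
            class = "flm_term")
}

#' @rdname flm_binary
#' @export
flm_interaction <- function(..., name = NULL) {
  parents <- unlist(list(...), use.names = FALSE)
  if (length(parents) < 2) abort("an interaction needs at least two parent terms")
  structure(list(kind = "interaction",
                 name = name %||% paste(parents, collapse = ":"),
                 parents = parents),
            class = "flm_term")
}

#' Assemble a functional-linear-model specification
#'
#' Collects [flm_binary()]/[flm_continuous()]/[flm_interaction()] terms
#' into an ordered model specification.  The intercept is implicit and
#' always first; interactions must reference terms declared before them.
#'
#' @param ... Term objects.
#' @return An object of class `flm_spec`.
#' @export
flm_spec <- function(...) {
  terms <- list(...)
  if (!all(vapply(terms, inherits, logical(1), "flm_term"))) {
    abort("all arguments must be flm_binary()/flm_continuous()/flm_interaction() terms")
  }
  nm <- vapply(terms, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("duplicate term names in flm_spec()")
  if ("(Intercept)" %in% nm) abort("the intercept is implicit; do not declare it")
  seen <- character(0)
  for (t in terms) {
    if (t$kind == "interaction") {
      bad <- setdiff(t$parents, seen)
      if (length(bad) > 0) {
        abort(paste0("interaction '", t$name,
                     "' references undeclared term(s): ",
                     paste(bad, collapse = ", ")))
      }
    }
    seen <- c(seen, t$name)
  }
  structure(list(terms = terms), class = "flm_spec")
}

#' Build the design matrix for a functional linear model
#'
#' Applies complete-case filtering on the referenced covariates, resolves
#' `"median"` thresholds on the retained subjects, encodes binary terms
#' as +1/-1, and forms interaction columns as elementwise products of
#' their parents.
#'
#' @param covariates Covariate tibble (see [read_covariates()]).
#' @param spec An [flm_spec()].
#' @param subjects Optional character vector: restrict to these subjects
#'   (e.g. the subjects with usable actigraphy) before complete-case
#'   filtering, mirroring per-model analysis subsets.
#' @return An object of class `flm_design`: list with the `N x p` matrix
#'   `Z` (column 1 all ones), `subject_id`, `column_names`, resolved
#'   term metadata (`terms`, with numeric thresholds filled in), and the
#'   ids dropped by filtering (`dropped`).
#' @export
build_design <- function(covariates, spec, subjects = NULL) {
  stopifnot(inherits(spec, "flm_spec"))
  .assert_columns(covariates, "subject_id", "build_design()")
  cv <- tibble::as_tibble(covariates)
  cv$subject_id <- as.character(cv$subject_id)
  if (!is.null(subjects)) {
    cv <- cv[cv$subject_id %in% as.character(subjects), , drop = FALSE]
  }
  base_terms <- purrr::keep(spec$terms, ~ .x$kind != "interaction")
  refd <- unique(vapply(base_terms, `[[`, character(1), "covariate"))
  .assert_columns(cv, refd, "build_design()")
  kept <- complete_cases(cv, refd)
  dropped <- setdiff(cv$subject_id, kept$subject_id)
  n <- nrow(kept)

  cols <- list("(Intercept)" = rep(1, n))
  resolved <- list()
  for (t in spec$terms) {
    if (t$kind == "binary") {
      thr <- if (identical(t$threshold, "median")) {
        median(kept[[t$covariate]])
      } else t$threshold
      col <- as.numeric(encode_binary(kept[[t$covariate]], thr))
      if (n > 0 && length(unique(col)) < 2) {
        abort(paste0("binary term '", t$name,
                     "' is constant (all subjects on one side of ", thr, ")"))
      }
      t$threshold <- thr
    } else if (t$kind == "continuous") {
      col <- kept[[t$covariate]]
      if (isTRUE(t$center)) col <- col - mean(col)
      if (isTRUE(t$scale)) col <- col / sd(col)
    } else {
      col <- Reduce(`*`, cols[t$parents])
    }
    cols[[t$name]] <- col
    resolved[[t$name]] <- t
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- kept$subject_id
  if (n <= ncol(Z)) {
    abort(paste0("design has N = ", n, " subjects for p = ", ncol(Z),
                 " columns; need N > p"))
  }
  structure(list(Z = Z, subject_id = kept$subject_id,
                 column_names = colnames(Z), terms = resolved,
                 dropped = dropped),
            class = "flm_design")
}

#' @export
print.flm_design <- function(x, ...) {
  cat("<flm_design> ", nrow(x$Z), " subjects x ", ncol(x$Z), " columns: ",
      paste(x$column_names, collapse = ", "), "\n", sep = "")
  if (length(x$dropped) > 0) {
    cat("  dropped (incomplete covariates): ", length(x$dropped), "\n", sep = "")
  }
  invisible(x)
}

#' @method as_tibble flm_design
#' @export
as_tibble.flm_design <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$Z))
  out <- dplyr::bind_cols(tibble::tibble(subject_id = x$subject_id), out)
  out
}
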