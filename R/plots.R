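# clock-time x axis shared by all figures
.scale_x_clock <- function() {
  ggplot2::scale_x_continuous(
    breaks = seq(0, 1440, by = 240),
    labels = c("00:00", "04:00", "08:00", "12:00", "16:00", "20:00", "24:00"),
    limits = c(0, 1440), expand = c(0.01, 0)
  )
}

# enumerate display combos: all +/-1 combinations of binary terms crossed
# with display quantiles (10/50/90%) of continuous terms (binning is for
# display only; inference never bins)
.display_combos <- function(fit) {
  terms <- purrr::keep(fit$design$terms, ~ .x$kind != "interaction")
  if (length(terms) == 0) return(list())
  lv <- lapply(names(terms), function(nm) {
    t <- terms[[nm]]
    if (t$kind == "binary") {
      setNames(c(1, -1), paste0(nm, c(" low", " high")))
    } else {
      Zcol <- fit$design$Z[, nm]
      q <- quantile(Zcol, c(0.1, 0.5, 0.9), names = FALSE)
      setNames(q, paste0(nm, " = ", signif(q, 3)))
    }
  })
  names(lv) <- names(terms)
  grid <- expand.grid(lapply(lv, seq_along))
  combos <- list()
  for (i in seq_len(nrow(grid))) {
    combo <- purrr::imap(lv, function(v, nm) unname(v[grid[i, nm]]))
    label <- paste(purrr::imap_chr(lv, function(v, nm) names(v)[grid[i, nm]]),
                   collapse = ", ")
    combos[[label]] <- combo
  }
  combos
}

#' Plot fitted circadian activity patterns
#'
#' Panel-(a)-style figure: individual smoothed curves as thin grey
#' lines, group mean curves thick and coloured (one per combination of
#' the binary terms; continuous terms shown at their 10/50/90% display
#' quantiles), optionally with shaded pointwise confidence bands, on a
#' midnight-to-midnight clock axis.
#'
#' @param object An `flm_fit`.
#' @param bands Draw pointwise confidence bands (default TRUE).
#' @param level Band level (default 0.95).
#' @param step Plot the curves every `step` minutes (default 5; purely a
#'   display thinning).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flm_fit
#' @export
autoplot.flm_fit <- function(object, bands = TRUE, level = 0.95, step = 5, ...) {
  at <- seq(0, 1439, by = step)
  G <- eval_basis(object$basis, at)
  indiv <- tibble::tibble(
    subject_id = rep(object$subject_id, each = length(at)),
    minute = rep(at, times = nrow(object$A)),
    activity = as.vector(t(object$A %*% t(G)))
  )
  p <- ggplot2::ggplot(indiv, ggplot2::aes(x = .data$minute, y = .data$activity)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       colour = "grey70", linewidth = 0.3)
  combos <- .display_combos(object)
  if (length(combos) > 0) {
    means <- purrr::imap(combos, function(combo, label) {
      dplyr::mutate(group_mean_curve(object, combo, at = at), group = label)
    }) |> dplyr::bind_rows()
    if (bands) {
      bb <- purrr::imap(combos, function(combo, label) {
        dplyr::mutate(confidence_band(object, combo, level = level, at = at),
                      group = label)
      }) |> dplyr::bind_rows()
      p <- p + ggplot2::geom_ribbon(
        data = bb,
        ggplot2::aes(x = .data$minute, ymin = .data$lower, ymax = .data$upper,
                     fill = .data$group),
        alpha = 0.2, inherit.aes = FALSE)
    }
    p <- p + ggplot2::geom_line(
      data = means,
      ggplot2::aes(colour = .data$group), linewidth = 1.1)
  } else {
    overall <- group_mean_curve(object, list(), at = at)
    p <- p + ggplot2::geom_line(data = overall, colour = "black", linewidth = 1.1)
  }
  p + .scale_x_clock() +
    ggplot2::labs(x = "Time of day", y = "Activity (counts/min)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot the permutation F-test result
#'
#' Panel-(b)-style figure: observed F(t) as a solid curve, the global
#' max-F critical value as a dashed line and the pointwise critical
#' curve dotted, at the test's alpha.
#'
#' @param object An `flm_perm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flm_perm
#' @export
autoplot.flm_perm <- function(object, ...) {
  ggplot2::ggplot(object$pointwise, ggplot2::aes(x = .data$minute)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$statistic), colour = "red") +
    ggplot2::geom_hline(yintercept = object$global_critical,
                        linetype = "dashed", colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$critical),
                       linetype = "dotted", colour = "blue") +
    .scale_x_clock() +
    ggplot2::labs(x = "Time of day", y = "F(t)",
                  subtitle = paste0("global p = ", signif(object$global_p, 3),
                                    " (", object$n_perm, " permutations, alpha = ",
                                    object$alpha, ")")) +
    ggplot2::theme_minimal()
}

#' Two-panel FLM figure (patterns + F test)
#'
#' Combines [autoplot.flm_fit()] (estimated activity patterns with
#' bands) and [autoplot.flm_perm()] (F-test result); written to `file`
#' if given.
#'
#' @param fit An `flm_fit`.
#' @param perm Optionally the matching `flm_perm`; when `NULL` only the
#'   pattern panel is produced.
#' @param file Optional output path (e.g. `.pdf` or `.png`);
#'   `ggplot2::ggsave()` dimensions 9 x 8 in.
#' @param ... Passed to [autoplot.flm_fit()].
#' @return The combined plot (patchwork if installed, else a list of
#'   ggplots), invisibly when written to file.
#' @export
plot_flm <- function(fit, perm = NULL, file = NULL, ...) {
  pa <- autoplot.flm_fit(fit, ...)
  out <- if (is.null(perm)) {
    pa
  } else if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(pa, autoplot.flm_perm(perm), ncol = 1)
  } else {
    list(patterns = pa, f_test = autoplot.flm_perm(perm))
  }
  if (!is.null(file)) {
    if (is.list(out) && !inherits(out, "ggplot")) {
      ggplot2::ggsave(file, out$patterns, width = 9, height = 4)
    } else {
      ggplot2::ggsave(file, out, width = 9, height = 8)
    }
    return(invisible(out))
  }
  out
}

#' Plot raw profiles with their smoothed curves
#'
#' @param profiles A `tbl_profiles`.
#' @param curves Optional matching `tbl_curves`; drawn as red lines over
#'   the raw minute averages.
#' @param subjects Optional subset of subject ids to show.
#' @return A ggplot object, facetted by subject.
#' @export
plot_profiles <- function(profiles, curves = NULL, subjects = NULL) {
  pf <- tibble::as_tibble(profiles)
  if (!is.null(subjects)) pf <- pf[pf$subject_id %in% subjects, ]
  p <- ggplot2::ggplot(pf, ggplot2::aes(x = .data$minute, y = .data$activity)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.4) +
    ggplot2::facet_wrap(~subject_id) +
    .scale_x_clock() +
    ggplot2::labs(x = "Time of day", y = "Activity (counts/min)") +
    ggplot2::theme_minimal()
  if (!is.null(curves)) {
    sm <- evaluate_curves(curves)
    if (!is.null(subjects)) sm <- sm[sm$subject_id %in% subjects, ]
    p <- p + ggplot2::geom_line(data = sm, colour = "red", linewidth = 0.6)
  }
  p
}
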