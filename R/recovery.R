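# Spike-in recovery statistics: a known number of tumor cells is spiked into
# whole blood, processed to slides, and counted back; recovery percentages,
# per-line summaries, the pooled identified-vs-spiked regression, and
# single-digit detection tallies quantify how much of the spike the platform
# finds.

#' Percent recovery of a spike-in experiment
#'
#' `100 * n_identified / n_spiked`, at full precision (display rounding is a
#' separate concern; see [single_digit_summary()] which floors for its
#' printed percent).
#'
#' @param n_identified,n_spiked Non-negative counts (vectorised).
#'   `n_identified` may exceed `n_spiked` (contaminants can inflate the
#'   count).
#'
#' @return Percent recovery.
#' @export
percent_recovery <- function(n_identified, n_spiked) {
  if (any(n_spiked == 0)) {
    abort("percent recovery is undefined for n_spiked = 0",
          class = "ctcscan_config_error")
  }
  stopifnot(all(n_identified >= 0), all(n_spiked > 0))
  100 * n_identified / n_spiked
}

#' Per-line and pooled recovery summary
#'
#' For a table of spike-in experiments grouped by cell line: per-line mean
#' and sample standard deviation (n - 1 denominator) of percent recovery,
#' the grand mean both as the unweighted mean of line means and as the
#' pooled mean over all experiments, and the pooled ordinary-least-squares
#' regression of identified on spiked counts (when the design permits one).
#'
#' @param experiments Tibble with columns `line`, `n_spiked`,
#'   `n_identified`.
#'
#' @return A `recovery_summary` object; see [tidy.recovery_summary()] and
#'   [glance.recovery_summary()].
#' @export
summarize_lines <- function(experiments) {
  stopifnot(all(c("line", "n_spiked", "n_identified") %in%
                names(experiments)))
  experiments <- dplyr::mutate(
    experiments,
    recovery_pct = percent_recovery(.data$n_identified, .data$n_spiked))
  per_line <- experiments |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_recovery_pct = mean(.data$recovery_pct),
      sd_recovery_pct = ifelse(dplyr::n() > 1, sd(.data$recovery_pct), 0),
      degenerate_sd = dplyr::n() < 2,
      .groups = "drop")
  fit <- if (length(unique(experiments$n_spiked)) >= 2) {
    fit_regression(experiments)
  } else {
    NULL
  }
  structure(list(
    per_line = per_line,
    grand_mean_of_line_means = mean(per_line$mean_recovery_pct),
    pooled_mean = mean(experiments$recovery_pct),
    n_experiments = nrow(experiments),
    experiments = experiments,
    fit = fit
  ), class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf(
    "<recovery_summary> %d experiments, %d lines\n", x$n_experiments,
    nrow(x$per_line)))
  cat(sprintf("  grand mean of line means %.1f%%, pooled mean %.1f%%\n",
              x$grand_mean_of_line_means, x$pooled_mean))
  if (!is.null(x$fit)) {
    g <- glance(x$fit)
    cat(sprintf("  identified ~ spiked: slope %.4f, intercept %.3f, R^2 %.4f\n",
                g$slope, g$intercept, g$r_squared))
  }
  invisible(x)
}

#' @describeIn summarize_lines Per-line recovery table.
#' @param x A `recovery_summary`.
#' @param ... Unused.
#' @method tidy recovery_summary
#' @export
tidy.recovery_summary <- function(x, ...) x$per_line

#' @describeIn summarize_lines One-row overall summary (grand means and, if
#'   fitted, regression slope/intercept/R-squared).
#' @method glance recovery_summary
#' @export
glance.recovery_summary <- function(x, ...) {
  out <- tibble::tibble(
    n_experiments = x$n_experiments,
    n_lines = nrow(x$per_line),
    grand_mean_of_line_means = x$grand_mean_of_line_means,
    pooled_mean = x$pooled_mean)
  if (!is.null(x$fit)) {
    out <- dplyr::bind_cols(out, glance(x$fit)[, c("slope", "intercept",
                                                   "r_squared")])
  }
  out
}

#' @describeIn summarize_lines Scatter of identified vs spiked counts by
#'   line, with the pooled regression line.
#' @param object A `recovery_summary`.
#' @method autoplot recovery_summary
#' @export
autoplot.recovery_summary <- function(object, ...) {
  g <- ggplot2::ggplot(object$experiments,
                       ggplot2::aes(x = .data$n_spiked,
                                    y = .data$n_identified,
                                    colour = .data$line)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_point(size = 2)
  if (!is.null(object$fit)) {
    gf <- glance(object$fit)
    g <- g + ggplot2::geom_abline(slope = gf$slope,
                                  intercept = gf$intercept)
  }
  g + ggplot2::labs(x = "cells spiked in", y = "cells identified",
                    title = "Spike-in recovery") +
    ggplot2::theme_minimal()
}

#' Ordinary least squares of identified on spiked counts
#'
#' @param experiments Tibble with `n_spiked` and `n_identified`; at least
#'   two distinct spiked counts are required.
#'
#' @return A `spike_fit` object wrapping the [stats::lm()] fit; see
#'   [tidy.spike_fit()] and [glance.spike_fit()].
#' @export
fit_regression <- function(experiments) {
  if (length(unique(experiments$n_spiked)) < 2) {
    abort("regression needs at least two distinct spiked counts",
          class = "ctcscan_config_error")
  }
  model <- lm(n_identified ~ n_spiked, data = experiments)
  structure(list(model = model, data = experiments), class = "spike_fit")
}

#' @export
print.spike_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<spike_fit> n = %d: identified = %.4f * spiked + %.4f (R^2 %.4f)\n",
    g$n, g$slope, g$intercept, g$r_squared))
  invisible(x)
}

#' @describeIn fit_regression Coefficient table.
#' @param x A `spike_fit`.
#' @param ... Unused.
#' @method tidy spike_fit
#' @export
tidy.spike_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(s[, "Estimate"]),
                 std_error = unname(s[, "Std. Error"]))
}

#' @describeIn fit_regression One-row fit summary.
#' @method glance spike_fit
#' @export
glance.spike_fit <- function(x, ...) {
  cf <- coef(x$model)
  tibble::tibble(slope = unname(cf["n_spiked"]),
                 intercept = unname(cf["(Intercept)"]),
                 r_squared = summary(x$model)$r.squared,
                 n = nrow(x$data))
}

#' @describeIn fit_regression Scatter with the fitted line.
#' @param object A `spike_fit`.
#' @method autoplot spike_fit
#' @export
autoplot.spike_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n_spiked,
                                            y = .data$n_identified)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = g$slope, intercept = g$intercept) +
    ggplot2::labs(x = "cells spiked in", y = "cells identified") +
    ggplot2::theme_minimal()
}

#' Simulate a binomial spike-in study
#'
#' Each experiment spikes a uniform-integer count in `[n_min, n_max]` and
#' identifies each spiked cell independently with probability `p`
#' (`n_identified ~ Binomial(n_spiked, p)`). The defaults mirror a study of
#' 20 experiments (4 cell lines, 5 replicates) spiking on the order of one
#' hundred cells (70 to 210), with a per-cell identification probability
#' equal to the observed mean recovery of 90.5%.
#'
#' @param p Per-cell identification probability.
#' @param n_min,n_max Spike-count range (inclusive).
#' @param n_experiments Number of experiments.
#' @param seed Integer seed.
#' @param lines Optional character vector recycled over experiments as the
#'   `line` column.
#'
#' @return Tibble `experiment`, `line`, `n_spiked`, `n_identified`.
#' @export
simulate_spikein <- function(p = 0.905, n_min = 70, n_max = 210,
                             n_experiments = 20, seed = 1L,
                             lines = c("A549", "LNCaP", "PC3", "MCF7")) {
  stopifnot(p >= 0, p <= 1, n_min >= 1, n_max >= n_min, n_experiments >= 1)
  withr::local_seed(seed)
  n_spiked <- n_min + floor(runif(n_experiments) * (n_max - n_min + 1))
  n_spiked <- pmin(n_spiked, n_max)  # guard the runif(.) == 1 edge
  tibble::tibble(
    experiment = seq_len(n_experiments),
    line = rep(lines, length.out = n_experiments),
    n_spiked = as.integer(n_spiked),
    n_identified = rbinom(n_experiments, n_spiked, p))
}

#' Tally single-digit spike-in detection
#'
#' Categorises each experiment by `n_identified - n_spiked`: full recovery
#' (0), one missed (-1), two missed (-2), over-count (> 0, e.g. contaminant
#' cells), and anything else. The printed percent identified is floored to
#' an integer, with the full-precision value alongside.
#'
#' @param experiments Tibble with `n_spiked` and `n_identified`.
#'
#' @return One-row tibble: `n_experiments`, `n_full`, `n_minus1`,
#'   `n_minus2`, `n_over`, `n_other`, `total_spiked`, `total_identified`,
#'   `percent_identified`, `percent_identified_display`.
#' @export
single_digit_summary <- function(experiments) {
  if (nrow(experiments) == 0 || sum(experiments$n_spiked) == 0) {
    abort("percent identified is undefined without spiked cells",
          class = "ctcscan_config_error")
  }
  d <- experiments$n_identified - experiments$n_spiked
  total_spiked <- sum(experiments$n_spiked)
  total_identified <- sum(experiments$n_identified)
  pct <- 100 * total_identified / total_spiked
  tibble::tibble(
    n_experiments = nrow(experiments),
    n_full = sum(d == 0),
    n_minus1 = sum(d == -1),
    n_minus2 = sum(d == -2),
    n_over = sum(d > 0),
    n_other = sum(d < -2),
    total_spiked = total_spiked,
    total_identified = total_identified,
    percent_identified = pct,
    percent_identified_display = floor(pct))
}
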