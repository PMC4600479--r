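#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a source estimate
#'
#' One row per (vertex, sample) with the estimated current density.
#'
#' @param x a `source_estimate`.
#' @param ... unused.
#' @return A tibble with columns `vertex`, `sample`, `current`.
#' @export
tidy.source_estimate <- function(x, ...) {
  tibble::tibble(
    vertex = rep(seq_len(nrow(x$J)), times = ncol(x$J)),
    sample = rep(seq_len(ncol(x$J)), each = nrow(x$J)),
    current = as.numeric(x$J))
}

#' One-row summary of a source estimate
#'
#' @param x a `source_estimate`.
#' @param ... unused.
#' @return A tibble with the method, problem size, peak current and
#'   solver convergence (cMEM only).
#' @export
glance.source_estimate <- function(x, ...) {
  conv <- if (!is.null(x$diagnostics) && nrow(x$diagnostics) > 0) {
    mean(x$diagnostics$converged)
  } else NA_real_
  tibble::tibble(
    method = x$method,
    n_sources = nrow(x$J),
    n_samples = ncol(x$J),
    peak_abs_current = max(abs(x$J)),
    lambda = if (!is.null(x$lambda)) x$lambda else NA_real_,
    converged_frac = conv)
}

#' Tidy a parcellation
#'
#' @param x a `parcellation`.
#' @param ... unused.
#' @return A tibble with `vertex`, `parcel`, `is_seed`.
#' @export
tidy.parcellation <- function(x, ...) {
  tibble::tibble(
    vertex = seq_along(x$parcel),
    parcel = x$parcel,
    is_seed = seq_along(x$parcel) %in% x$seeds)
}

#' @export
glance.parcellation <- function(x, ...) {
  sizes <- table(x$parcel)
  tibble::tibble(K = x$K, scale = x$scale,
                 min_size = min(sizes), median_size = median(sizes),
                 max_size = max(sizes))
}

#' Plot a spike waveform
#'
#' @param spike a [gamma_spike()] result.
#' @return A ggplot.
#' @export
plot_spike <- function(spike) {
  df <- tibble::tibble(t = spike$t * 1000, w = spike$w)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$w)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = spike$t[spike$peak_index] * 1000,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (ms)", y = "normalized amplitude",
                  title = "Simulated interictal spike") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of study metrics by method and modality
#'
#' @param object a [run_study()] tibble.
#' @param metric one of `"auc"`, `"sd_mm"`, `"se"`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.memfusion_study <- function(object, metric = "auc", ...) {
  plot_study_metric(object, metric)
}

#' @rdname autoplot.memfusion_study
#' @param results study results tibble.
#' @export
plot_study_metric <- function(results, metric = "auc") {
  metric <- match.arg(metric, c("auc", "sd_mm", "se"))
  lab <- c(auc = "AUC", sd_mm = "spatial dispersion (mm)",
           se = "shape error")[metric]
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$method, y = .data[[metric]],
                               fill = .data$modality)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = lab, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of paired AUC values from the conductivity-ratio experiment
#'
#' @param rbs_results a [run_rbs_experiment()] tibble.
#' @return A ggplot (x: incorrect-Rbs AUC, y: correct-Rbs AUC).
#' @export
plot_rbs_pairs <- function(rbs_results) {
  ggplot2::ggplot(rbs_results,
                  ggplot2::aes(x = .data$auc_incorrect,
                               y = .data$auc_correct,
                               colour = .data$modality)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "AUC, incorrect Rbs", y = "AUC, correct Rbs",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
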