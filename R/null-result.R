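#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result> %s / %s on '%s'%s\n", x$index, x$algorithm,
              x$dataset_id,
              if (!is.na(x$guild)) paste0(" [", x$guild, "]") else ""))
  cat(sprintf("  observed %.4f | null %.4f +/- %.4f (n_sim %d)\n",
              x$observed, mean(x$null_values), sd(x$null_values), x$n_sim))
  cat(sprintf("  p_low %.4g, p_high %.4g%s -> %s (%s-tailed, alpha %.3g)\n",
              x$p_low, x$p_high,
              if (x$tails == "two") sprintf(", p_two %.4g", x$p_two) else "",
              x$outcome, x$tails, x$alpha))
  invisible(x)
}

#' Tidy a null-model result
#'
#' @param x A `null_result` from [run_binary_null()] or [run_quant_null()].
#' @param ... Unused.
#' @return A one-row tibble: dataset/level/guild labels, model type,
#'   algorithm, index, observed value, tail probabilities, outcome, `n_sim`
#'   and `alpha` — the outcome-record schema consumed by
#'   [tabulate_outcomes()] and the meta-GLMs.
#' @export
tidy.null_result <- function(x, ...) {
  tibble::tibble(
    dataset_id = x$dataset_id, level = x$level, guild = x$guild,
    model_type = x$model_type, algorithm = x$algorithm, index = x$index,
    observed = x$observed, p_low = x$p_low, p_high = x$p_high,
    p_two = if (x$tails == "two") x$p_two else NA_real_,
    outcome = x$outcome, n_sim = x$n_sim, alpha = x$alpha
  )
}

#' @rdname tidy.null_result
#' @export
glance.null_result <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, null_mean = mean(x$null_values),
    null_sd = sd(x$null_values), p_low = x$p_low, p_high = x$p_high,
    outcome = x$outcome, n_sim = x$n_sim
  )
}

#' Plot a null distribution against the observed index
#'
#' Histogram of the simulated null index values with the observed value
#' marked; the subtitle reports the tail probabilities and outcome.
#'
#' @param object A `null_result`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_result <- function(object, bins = 40, ...) {
  df <- tibble::tibble(null = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      title = sprintf("%s under %s — %s", object$index, object$algorithm,
                      object$dataset_id),
      subtitle = sprintf("observed %.4g; p_low %.3g, p_high %.3g; outcome: %s",
                         object$observed, object$p_low, object$p_high,
                         object$outcome),
      x = "null index value", y = "count"
    ) +
    ggplot2::theme_minimal()
}
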