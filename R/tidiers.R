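# broom-style accessors and ggplot2 views of the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a summarized expression result
#'
#' One row per probe set x array, with the mean level, raw and backscaled
#' fold changes and the reported expression value.
#'
#' @param x An `rdn_expression` from [run_rdn()] / [summarize_probesets()].
#' @param ... Unused.
#' @return A tibble with columns `probeset_id`, `array`, `omega`, `alpha`,
#'   `alpha_backscaled`, `expression`.
#' @method tidy rdn_expression
#' @export
tidy.rdn_expression <- function(x, ...) {
  long <- function(m, name) {
    tibble::tibble(probeset_id = rep(rownames(m), times = ncol(m)),
                   array = rep(colnames(m), each = nrow(m)),
                   value = as.vector(m)) |>
      stats::setNames(c("probeset_id", "array", name))
  }
  out <- long(x$alpha, "alpha")
  out$alpha_backscaled <- as.vector(x$alpha_backscaled)
  out$omega <- rep(unname(x$omega), times = ncol(x$alpha))
  out$expression <- as.vector(x$expression)
  out[c("probeset_id", "array", "omega", "alpha", "alpha_backscaled",
        "expression")]
}

#' @rdname tidy.rdn_expression
#' @method glance rdn_expression
#' @export
glance.rdn_expression <- function(x, ...) {
  tibble::tibble(
    n_probesets = nrow(x$expression),
    n_arrays = ncol(x$expression),
    n_probes_removed = nrow(x$removed_probes),
    output = x$output,
    optical_background = if (!is.null(x$reference)) x$reference$o else NA_real_,
    median_background = if (!is.null(x$reference)) {
      stats::median(x$reference$b)
    } else NA_real_
  )
}

#' Tidy a reference decomposition
#'
#' @param x An `rdn_reference`.
#' @param ... Unused.
#' @return A tibble with one row per probe: `s`, `o`, `b`, `x` components
#'   and the background-only flag.
#' @method tidy rdn_reference
#' @export
tidy.rdn_reference <- function(x, ...) {
  tibble::tibble(s = x$s, o = x$o, b = x$b, x = x$x,
                 background_only = x$background_only)
}

#' Tidy a per-array difference fit
#'
#' @param x An `rdn_arrayfit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `block`,
#'   `estimate`): the optical difference, hybridization knot weights and
#'   amplification coefficients.
#' @method tidy rdn_arrayfit
#' @export
tidy.rdn_arrayfit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(block = "optical", term = "d", estimate = x$d),
    tibble::tibble(block = "hyb_background",
                   term = paste0("phi_b", seq_along(x$phi_b)),
                   estimate = x$phi_b),
    tibble::tibble(block = "hyb_foreground",
                   term = paste0("phi_f", seq_along(x$phi_f)),
                   estimate = x$phi_f),
    tibble::tibble(block = "amplification",
                   term = paste0("a_", DINUCLEOTIDES), estimate = x$a)
  )
}

#' Plot fold changes against mean level
#'
#' MA-style view of the summarized output: per probe set, the reported fold
#' change on each array against the probe-set mean level, backscaled and raw
#' values distinguished by colour.
#'
#' @param object An `rdn_expression`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rdn_expression
#' @export
autoplot.rdn_expression <- function(object, ...) {
  td <- tidy(object)
  td_long <- tidyr::pivot_longer(td, c("alpha", "alpha_backscaled"),
                                 names_to = "kind", values_to = "fold_change")
  ggplot2::ggplot(td_long,
                  ggplot2::aes(x = .data$omega, y = .data$fold_change,
                               colour = .data$kind)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::labs(x = "probe-set mean level (log2)",
                  y = "fold change vs mean (log2)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an estimated location-effect field
#'
#' Heatmap of the smoothed log2 location effect of one array over the probe
#' grid.
#'
#' @param object An `rdn_location_field`.
#' @param arrays The [rdn_arrayset()] the field was estimated from (for the
#'   probe coordinates).
#' @param array Column index of the array to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rdn_location_field
#' @export
autoplot.rdn_location_field <- function(object, arrays, array = 1L, ...) {
  ann <- arrays$annotation
  df <- tibble::tibble(x = ann$x, y = ann$y, lambda = object$lambda[, array])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$lambda)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "grid column", y = "grid row",
                  fill = "location\neffect (log2)") +
    ggplot2::theme_minimal()
}
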