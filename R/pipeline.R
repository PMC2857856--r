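# Full pipeline: reference construction and decomposition, per-array
# technical-difference correction, quantile + location + quantile
# normalization, and background-weighted summarization.

#' Pipeline configuration
#'
#' All tunables of the normalization pipeline with their defaults. The stage
#' toggles reproduce the ablated variants (quantile-only, quantile+location,
#' quantile+hybridization, ...): a disabled stage is exactly the identity
#' map for that stage.
#'
#' @param optical,hyb,amp,location,quantile Stage toggles.
#' @param eta Background-fit asymmetry factor (10; 1 = symmetric).
#' @param n_knots,degree Hybridization-model spline controls (5, cubic).
#' @param filter_size Median box filter side (9).
#' @param huber_c Huber tuning constant (1.345, 95 percent Gaussian efficiency).
#' @param weight_cutoff,outlier_fraction,probe_floor Outlier-probe rule.
#' @param output `"backscaled"` (default), `"raw"` (no backscaling) or
#'   `"accuracy"` (symmetric background fit `eta = 1` and no backscaling,
#'   for bias-sensitive downstream use).
#' @param backscale_aggregate `"median"` or `"mean"` probe-background
#'   aggregation for backscaling.
#' @param include_optical Include the optical floor inside the summarization
#'   model (default TRUE).
#' @param sweeps Block-coordinate sweeps in the per-array difference fit.
#' @param bg_target `"min"` or `"median"` background fit target.
#' @return A `rdn_config` list.
#' @export
rdn_config <- function(optical = TRUE, hyb = TRUE, amp = TRUE,
                       location = TRUE, quantile = TRUE,
                       eta = 10, n_knots = 5L, degree = 3L,
                       filter_size = 9L, huber_c = 1.345,
                       weight_cutoff = 0.9, outlier_fraction = 1 / 3,
                       probe_floor = 5L,
                       output = c("backscaled", "raw", "accuracy"),
                       backscale_aggregate = c("median", "mean"),
                       include_optical = TRUE, sweeps = 3L,
                       bg_target = c("min", "median")) {
  cfg <- as.list(environment())
  cfg$output <- match.arg(output)
  cfg$backscale_aggregate <- match.arg(backscale_aggregate)
  cfg$bg_target <- match.arg(bg_target)
  if (cfg$output == "accuracy") cfg$eta <- 1
  structure(cfg, class = "rdn_config")
}

#' Run the full normalization and summarization pipeline
#'
#' Steps: (1a) median reference pseudo-array; (1b) reference background fit
#' and decomposition into optical / non-specific binding / true signal;
#' (2a) per-array robust fit and removal of optical, hybridization and
#' amplification differences; (2b) quantile normalization, array-location
#' correction, quantile normalization again (quantile normalization is
#' idempotent, so bracketing the location step costs nothing); (3)
#' background-weighted Huber summarization with outlier-probe removal and
#' (by default) backscaled fold changes. Arrays are fitted independently in
#' step 2a. The pipeline is deterministic given input and configuration.
#'
#' @param arrays An [rdn_arrayset()] with at least two arrays.
#' @param config An [rdn_config()].
#' @param diagnostics Optional directory; per-stage diagnostic TSVs are
#'   written there when given.
#' @param verbose Print one progress line per stage.
#' @return An `rdn_expression` (see [summarize_probesets()]) with extra
#'   fields `reference` (`rdn_reference`), `array_fits` (list of
#'   `rdn_arrayfit`), `location_field` and `config`.
#' @export
run_rdn <- function(arrays, config = rdn_config(), diagnostics = NULL,
                    verbose = FALSE) {
  stopifnot(inherits(arrays, "rdn_arrayset"), inherits(config, "rdn_config"))
  if (ncol(arrays$signals) < 2) stop("at least two arrays are required.")
  say <- function(...) if (verbose) message(sprintf(...))

  ## step 1: reference and components
  say("step 1a: building median reference over %d arrays", ncol(arrays$signals))
  s_ref <- build_reference(arrays)
  designs <- rdn_designs(arrays$annotation, n_knots = config$n_knots,
                         degree = config$degree)
  say("step 1b: fitting reference background (eta = %g)", config$eta)
  bg <- fit_background(arrays, eta = config$eta, target = config$bg_target,
                       n_knots = config$n_knots, degree = config$degree,
                       huber_c = config$huber_c, design = designs$hyb)
  ref <- decompose_reference(s_ref, bg$o_ref, bg$bg_hat)
  ref$background_fit <- bg

  ## step 2a: per-array difference correction
  steps <- c(optical = config$optical, hyb = config$hyb, amp = config$amp)
  fits <- NULL
  work <- arrays
  if (any(steps)) {
    fits <- vector("list", ncol(arrays$signals))
    names(fits) <- colnames(arrays$signals)
    for (i in seq_len(ncol(arrays$signals))) {
      fit <- fit_array_difference(arrays$signals[, i], ref, designs,
                                  steps = steps, huber_c = config$huber_c,
                                  sweeps = config$sweeps)
      work$signals[, i] <- apply_difference_correction(arrays$signals[, i],
                                                       fit, ref)
      fits[[i]] <- fit
      say("step 2a [%s]: d = %.2f, loss = %.1f, %d iterations",
          colnames(arrays$signals)[i], fit$d, fit$loss, fit$iterations)
    }
  } else {
    say("step 2a: disabled")
  }

  ## step 2b: quantile - location - quantile
  field <- NULL
  if (config$quantile) {
    say("step 2b: quantile normalization")
    work <- quantile_to_reference(work)
  }
  if (config$location) {
    say("step 2b: array-location correction (%dx%d median box filter)",
        config$filter_size, config$filter_size)
    field <- estimate_location_field(work, ref$o, size = config$filter_size)
    work <- apply_location_correction(work, field, ref$o)
    if (config$quantile) work <- quantile_to_reference(work)
  }

  ## step 3: summarization
  say("step 3: summarizing %d probe sets",
      length(unique(arrays$annotation$probeset_id)))
  out_mode <- if (config$output == "backscaled") "backscaled" else "raw"
  expr <- summarize_probesets(
    work, ref, output = out_mode,
    backscale_aggregate = config$backscale_aggregate,
    huber_c = config$huber_c, include_optical = config$include_optical,
    probe_floor = config$probe_floor, weight_cutoff = config$weight_cutoff,
    outlier_fraction = config$outlier_fraction)
  expr$reference <- ref
  expr$array_fits <- fits
  expr$location_field <- field
  expr$config <- config

  if (!is.null(diagnostics)) {
    dir.create(diagnostics, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tibble::tibble(
      probe_id = arrays$annotation$probe_id, s_ref = ref$s, o_ref = ref$o,
      b_ref = ref$b, x_ref = ref$x, background_only = ref$background_only),
      file.path(diagnostics, "reference_components.tsv"), progress = FALSE)
    if (!is.null(fits)) {
      readr::write_tsv(tibble::tibble(
        array = names(fits),
        d = vapply(fits, `[[`, numeric(1), "d"),
        loss = vapply(fits, `[[`, numeric(1), "loss"),
        iterations = vapply(fits, `[[`, numeric(1), "iterations")),
        file.path(diagnostics, "array_fits.tsv"), progress = FALSE)
    }
    if (!is.null(field)) {
      lam <- tibble::as_tibble(field$lambda)
      lam <- dplyr::bind_cols(
        tibble::tibble(probe_id = arrays$annotation$probe_id), lam)
      readr::write_tsv(lam, file.path(diagnostics, "location_field.tsv"),
                       progress = FALSE)
    }
    readr::write_tsv(expr$removed_probes,
                     file.path(diagnostics, "removed_probes.tsv"),
                     progress = FALSE)
  }
  expr
}
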