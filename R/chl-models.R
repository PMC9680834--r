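#' Linear CI-to-chlorophyll models
#'
#' A `chl_model` maps a Cyanobacteria Index value to near-surface
#' chlorophyll-a by `chl = slope * ci + intercept`. Two published
#' parameterizations ship with the package:
#'
#' * `chl_t16()`: slope 4050 (+/- 271), intercept 20 (+/- 3) ug/L, tuned on
#'   above-water radiometry from eutrophic-to-hypereutrophic Florida lakes.
#'   Its 20 ug/L intercept reflects a background of non-cyanobacteria
#'   chlorophyll in those lakes, so it should not be applied below roughly
#'   its own minimum detection level (~20 ug/L).
#' * `chl_bs()`: slope 6620 (+/- 646), intercept -3.1 (+/- 5.2) ug/L, the
#'   bootstrap-recalibrated relationship for CI_cyano over a wide range of
#'   lake trophic states. Its intercept is not meaningfully different from
#'   zero.
#'
#' The +/- values are carried as symmetric 95% coefficient bounds in
#' `slope_ci95` / `intercept_ci95`.
#'
#' @param slope Chlorophyll per CI unit (ug/L); must be finite and positive.
#' @param intercept Chlorophyll at CI = 0 (ug/L).
#' @param slope_ci95,intercept_ci95 Optional length-2 `(low, high)` bounds.
#' @param name Label used in printing and reports.
#' @return An object of class `chl_model`.
#' @seealso [apply_chl_model()], [bootstrap_fit()] which produces a fitted
#'   model of the same shape.
#' @export
chl_model <- function(slope, intercept, slope_ci95 = NULL,
                      intercept_ci95 = NULL, name = "custom") {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  if (slope <= 0) stop("chl_model: slope must be positive")
  check_bounds <- function(b, what) {
    if (is.null(b)) return(NULL)
    stopifnot(is.numeric(b), length(b) == 2L)
    if (b[1] > b[2]) stop("chl_model: ", what, " bounds must be (low, high)")
    as.numeric(b)
  }
  structure(list(slope = slope, intercept = intercept,
                 slope_ci95 = check_bounds(slope_ci95, "slope"),
                 intercept_ci95 = check_bounds(intercept_ci95, "intercept"),
                 name = name),
            class = "chl_model")
}

#' @rdname chl_model
#' @export
chl_t16 <- function() {
  chl_model(4050, 20, slope_ci95 = c(4050 - 271, 4050 + 271),
            intercept_ci95 = c(20 - 3, 20 + 3), name = "Chl_T16")
}

#' @rdname chl_model
#' @export
chl_bs <- function() {
  chl_model(6620, -3.1, slope_ci95 = c(6620 - 646, 6620 + 646),
            intercept_ci95 = c(-3.1 - 5.2, -3.1 + 5.2), name = "Chl_BS")
}

#' @export
print.chl_model <- function(x, ...) {
  cat(sprintf("<chl_model> %s: chl = %g * CI + %g ug/L\n",
              x$name, x$slope, x$intercept))
  if (!is.null(x$slope_ci95)) {
    cat(sprintf("  slope 95%%: [%g, %g]", x$slope_ci95[1], x$slope_ci95[2]))
    if (!is.null(x$intercept_ci95)) {
      cat(sprintf("  intercept 95%%: [%g, %g]",
                  x$intercept_ci95[1], x$intercept_ci95[2]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Convert CI values to chlorophyll-a
#'
#' Applies a linear [chl_model] to CI (or CI_cyano) values. Retrievals that
#' come out negative are removed rather than clamped: they are returned as
#' `NA` and counted in the `"n_negative_removed"` attribute, since a
#' negative concentration has no physical meaning and near-zero retrievals
#' are already at the edge of the model's validity.
#'
#' @param ci_value Numeric vector of CI values (`NA` propagates).
#' @param model A [chl_model]; defaults to [chl_bs()].
#' @return Numeric vector of chlorophyll-a (ug/L) with `NA` where the
#'   retrieval was negative (or the input `NA`); attribute
#'   `"n_negative_removed"` holds the count of removed negatives.
#' @examples
#' apply_chl_model(0.01, chl_bs())        # 63.1
#' apply_chl_model(0, chl_t16())          # 20
#' apply_chl_model(0.0001, chl_bs())      # NA: negative retrieval removed
#' @export
apply_chl_model <- function(ci_value, model = chl_bs()) {
  stopifnot(inherits(model, "chl_model"), is.numeric(ci_value))
  if (any(is.infinite(ci_value))) {
    stop("apply_chl_model: CI values must be finite")
  }
  chl <- model$slope * ci_value + model$intercept
  neg <- !is.na(chl) & chl < 0
  chl[neg] <- NA_real_
  structure(chl, n_negative_removed = sum(neg))
}
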