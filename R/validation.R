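#' Log-domain multiplicative bias and absolute error
#'
#' Chlorophyll spans four orders of magnitude with strongly heteroskedastic,
#' non-Gaussian errors, so validation uses geometric-mean metrics computed
#' in log10 space and converted back to dimensionless multiplicative
#' factors rather than mean-square statistics:
#' \deqn{bias_{log} = 10^{\,\mathrm{mean}(\log_{10} M_i - \log_{10} O_i)}}
#' \deqn{MAE_{log} = 10^{\,\mathrm{mean}|\log_{10} M_i - \log_{10} O_i|}}
#' where `M` are modeled (satellite) and `O` observed (in situ) values. A
#' bias of 1.3 means the model runs 1.3x (30%) high on average; a bias
#' below 1 is a negative bias. MAE is never below 1; an MAE of 1.2 means
#' 20% relative misfit in either direction.
#'
#' @param modeled,observed Positive numeric vectors of equal length (ug/L).
#' @return A single dimensionless factor.
#' @examples
#' o <- c(2, 15, 60, 300)
#' bias_log(1.3 * o, o)  # 1.3
#' mae_log(1.2 * o, o)   # 1.2
#' @export
bias_log <- function(modeled, observed) {
  d <- log_diffs(modeled, observed, "bias_log")
  10^mean(d)
}

#' @rdname bias_log
#' @export
mae_log <- function(modeled, observed) {
  d <- log_diffs(modeled, observed, "mae_log")
  10^mean(abs(d))
}

log_diffs <- function(modeled, observed, fn) {
  if (length(modeled) != length(observed)) {
    stop(fn, ": modeled and observed lengths differ (",
         length(modeled), " vs ", length(observed), ")")
  }
  if (length(modeled) == 0L) stop(fn, ": empty input")
  bad <- which(!is.finite(modeled) | modeled <= 0 |
                 !is.finite(observed) | observed <= 0)
  if (length(bad) > 0L) {
    stop(fn, ": non-positive or non-finite value at index ", bad[1L])
  }
  log10(modeled) - log10(observed)
}

#' Trophic-state categories
#'
#' Names and chlorophyll boundaries (ug/L) of the four lake trophic
#' categories used for classification: oligotrophic/mesotrophic below 7,
#' eutrophic 7--30, low hypereutrophic 30--90, high hypereutrophic above
#' 90. Intervals are left-closed/right-open, so a boundary value belongs to
#' the higher category (7 is eutrophic, 30 and 90 hypereutrophic).
#' @export
TROPHIC_LEVELS <- c("oligo_meso", "eutrophic", "low_hyper", "high_hyper")

#' Assign lake trophic category from chlorophyll-a
#'
#' @param chl Non-negative numeric vector of chlorophyll-a (ug/L); `NA`
#'   propagates.
#' @param breaks Increasing category boundaries, default `c(7, 30, 90)`.
#' @return Factor with levels [TROPHIC_LEVELS].
#' @examples
#' trophic_category(c(2, 15, 50, 95))
#' @export
trophic_category <- function(chl, breaks = c(7, 30, 90)) {
  stopifnot(is.numeric(chl), length(breaks) == 3L, !is.unsorted(breaks))
  if (any(chl < 0, na.rm = TRUE)) {
    stop("trophic_category: negative chlorophyll at index ",
         which(chl < 0)[1L])
  }
  cut(chl, breaks = c(0, breaks, Inf), labels = TROPHIC_LEVELS,
      right = FALSE, include.lowest = TRUE)
}

#' Trophic-state confusion matrix
#'
#' Cross-tabulates observed versus predicted trophic category and reports
#' both raw counts and row percentages (each observed-category row
#' normalized to 100%), the standard view for asking how often the
#' satellite retrieval lands an in situ sample in the right trophic bin.
#' Pairs whose prediction was removed (NA, e.g. a negative retrieval) are
#' excluded from the matrix and counted in `n_removed`.
#'
#' @param predicted,observed Positive chlorophyll vectors of equal length
#'   (ug/L), or factors already produced by [trophic_category()].
#' @param breaks Category boundaries passed to [trophic_category()].
#' @return An object of class `trophic_confusion`: list with `counts`
#'   (4x4 integer matrix, rows = observed, cols = predicted), `percent`
#'   (row-normalized; rows with no observations are `NA`, not 0/0), `n`,
#'   and `n_removed`.
#' @export
trophic_confusion <- function(predicted, observed, breaks = c(7, 30, 90)) {
  to_cat <- function(v) {
    if (is.factor(v)) factor(v, levels = TROPHIC_LEVELS) else
      trophic_category(v, breaks)
  }
  p <- to_cat(predicted); o <- to_cat(observed)
  if (length(p) != length(o)) {
    stop("trophic_confusion: predicted and observed lengths differ")
  }
  keep <- !is.na(p) & !is.na(o)
  counts <- table(observed = o[keep], predicted = p[keep])
  counts <- unclass(counts)
  rs <- rowSums(counts)
  percent <- 100 * sweep(counts, 1L, ifelse(rs == 0, NA_real_, rs), "/")
  structure(list(counts = counts, percent = percent,
                 n = sum(counts), n_removed = sum(!keep & !is.na(o))),
            class = "trophic_confusion")
}

#' @export
print.trophic_confusion <- function(x, digits = 0, ...) {
  cat("<trophic_confusion> n =", x$n)
  if (x$n_removed > 0L) cat(" (", x$n_removed, "pairs removed )")
  cat("\nrow percentages (observed x predicted):\n")
  print(round(x$percent, digits))
  invisible(x)
}

#' Pooled classification accuracy over selected categories
#'
#' Fraction (as a percentage) of pairs whose observed category is in
#' `levels` and whose predicted category is also in `levels` — e.g. pooling
#' the two hypereutrophic rows answers "when the lake was hypereutrophic,
#' how often did the retrieval say hypereutrophic (of either degree)?".
#'
#' @param cm A [trophic_confusion()].
#' @param levels Character subset of [TROPHIC_LEVELS] to pool.
#' @return List with `percent`, `n_correct`, `n_observed`.
#' @export
pooled_accuracy <- function(cm, levels = c("low_hyper", "high_hyper")) {
  stopifnot(inherits(cm, "trophic_confusion"),
            all(levels %in% TROPHIC_LEVELS))
  sub <- cm$counts[levels, , drop = FALSE]
  n_obs <- sum(sub)
  n_cor <- sum(sub[, levels, drop = FALSE])
  list(percent = 100 * n_cor / n_obs, n_correct = n_cor,
       n_observed = n_obs)
}

default_strata <- function() {
  tibble::tibble(
    stratum = c("all", "0-700", "20-700", TROPHIC_LEVELS),
    lower = c(0, 0, 20, 0, 7, 30, 90),
    upper = c(Inf, 700, 700, 7, 30, 90, Inf)
  )
}

#' Stratified log-domain performance report
#'
#' Computes `n`, [bias_log()] and [mae_log()] within chlorophyll strata
#' defined on the *observed* values, mirroring the usual summary layout:
#' an all-data row, broad 0--700 and high-range 20--700 rows, and the four
#' trophic categories. Strata are left-closed/right-open. Rows may overlap
#' (the 0--700 and 20--700 rows do), so per-row `n` need not sum to the
#' total. Pairs with removed (NA) predictions are excluded and counted in
#' the `"n_removed"` attribute; empty strata report `n = 0` with `NA`
#' metrics.
#'
#' @param predicted,observed Positive chlorophyll vectors of equal length
#'   (ug/L); `predicted` may contain `NA` for removed retrievals.
#' @param strata Data frame with columns `stratum`, `lower`, `upper`
#'   (ug/L); default mirrors the standard report.
#' @return Tibble with columns `stratum`, `lower`, `upper`, `n`,
#'   `bias_log`, `mae_log`.
#' @export
stratified_report <- function(predicted, observed,
                              strata = default_strata()) {
  if (length(predicted) != length(observed)) {
    stop("stratified_report: predicted and observed lengths differ")
  }
  strata <- tibble::as_tibble(strata)
  stopifnot(all(c("stratum", "lower", "upper") %in% names(strata)))
  keep <- !is.na(predicted)
  n_removed <- sum(!keep)
  p <- predicted[keep]; o <- observed[keep]
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    inb <- o >= strata$lower[i] & o < strata$upper[i]
    if (!any(inb)) {
      tibble::tibble(stratum = strata$stratum[i], lower = strata$lower[i],
                     upper = strata$upper[i], n = 0L,
                     bias_log = NA_real_, mae_log = NA_real_)
    } else {
      tibble::tibble(stratum = strata$stratum[i], lower = strata$lower[i],
                     upper = strata$upper[i], n = sum(inb),
                     bias_log = bias_log(p[inb], o[inb]),
                     mae_log = mae_log(p[inb], o[inb]))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "n_removed") <- n_removed
  out
}
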