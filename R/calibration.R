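#' Split match-ups into training and evaluation sets
#'
#' Uniform random split without replacement. The training set receives
#' `floor(train_fraction * N)` pairs (so 1738 match-ups at the default 80%
#' fraction give 1390 training and 348 evaluation points) and the
#' evaluation set the remainder. The split is purely random — no
#' stratification by region or concentration — and fully determined by
#' `seed`.
#'
#' @param pairs Data frame of match-up pairs (see [match_same_day()]); any
#'   data frame with at least 5 rows is accepted.
#' @param train_fraction Proportion assigned to training, in (0, 1).
#' @param seed Integer seed controlling the split.
#' @return A list of class `split_result` with `training`, `evaluation`
#'   (disjoint tibbles whose union is the input) and `seed`.
#' @export
split_matchups <- function(pairs, train_fraction = 0.8, seed = 1L) {
  pairs <- tibble::as_tibble(pairs)
  n <- nrow(pairs)
  if (n < 5L) stop("split_matchups: need at least 5 pairs, got ", n)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("split_matchups: train_fraction must be in (0, 1)")
  }
  n_train <- floor(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  structure(list(training = pairs[sort(idx), , drop = FALSE],
                 evaluation = pairs[setdiff(seq_len(n), idx), ,
                                    drop = FALSE],
                 seed = seed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result>", nrow(x$training), "training /",
      nrow(x$evaluation), "evaluation pairs (seed", x$seed, ")\n")
  invisible(x)
}

#' Bootstrap recalibration of the linear CI-to-chlorophyll model
#'
#' Nonparametric (pair-resampling) bootstrap of the ordinary least squares
#' fit `chl_insitu = slope * ci_cyano + intercept` on untransformed values.
#' Each of `n_iter` iterations draws `nrow(training)` pairs with
#' replacement and refits; the reported coefficients are the means over
#' iterations and the 95% confidence bounds are the 2.5th/97.5th
#' percentiles of the bootstrap coefficient distribution (type-7
#' quantiles). Symmetric normal-approximation intervals
#' (mean +/- 1.96 * sd of the draws) are stored alongside for comparison,
#' since published coefficient uncertainties are often printed as symmetric
#' +/- values.
#'
#' Resampling and refitting across many data subsets reduces the risk of
#' overfitting a single draw of the data and yields coefficient confidence
#' intervals without distributional assumptions — valuable here because
#' chlorophyll residuals are strongly heteroskedastic. A resample whose CI
#' values are all identical has no defined slope; such degenerate draws are
#' redrawn (and counted in `n_redraws`), and more than 10% redraws is an
#' error because it signals near-degenerate training data.
#'
#' @param training Data frame with columns `ci_cyano` and `chl_insitu`, at
#'   least 3 rows with non-identical `ci_cyano`.
#' @param n_iter Number of bootstrap iterations (default 1500).
#' @param seed Integer seed; the same (data, n_iter, seed) reproduces the
#'   fit exactly.
#' @return An object of class `bootstrap_fit`: list with `slope_mean`,
#'   `intercept_mean`, `slope_draws`, `intercept_draws` (length `n_iter`),
#'   `slope_ci95`, `intercept_ci95` (percentile bounds), `slope_ci95_normal`,
#'   `intercept_ci95_normal`, `n_iter`, `n_train`, `n_redraws`, `seed`.
#' @seealso [as_chl_model()] to use the fit for prediction,
#'   [predict_with_bounds()] for prediction-spread envelopes.
#' @export
bootstrap_fit <- function(training, n_iter = 1500L, seed = 1L) {
  training <- tibble::as_tibble(training)
  stopifnot(all(c("ci_cyano", "chl_insitu") %in% names(training)))
  x <- as.numeric(training$ci_cyano)
  y <- as.numeric(training$chl_insitu)
  n <- length(x)
  if (n < 3L) stop("bootstrap_fit: need at least 3 training pairs")
  if (length(unique(x)) < 2L) {
    stop("bootstrap_fit: ci_cyano values are all identical")
  }
  if (anyNA(x) || anyNA(y)) stop("bootstrap_fit: NA in training pairs")
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("bootstrap_fit: n_iter must be >= 1")

  # slope/intercept of OLS per resample, vectorized over iterations
  ols_rows <- function(idx_mat) {
    X <- matrix(x[idx_mat], nrow(idx_mat))
    Y <- matrix(y[idx_mat], nrow(idx_mat))
    mx <- rowMeans(X); my <- rowMeans(Y)
    vx <- rowMeans(X * X) - mx * mx
    slope <- (rowMeans(X * Y) - mx * my) / vx
    list(slope = slope, intercept = my - slope * mx, varx = vx)
  }

  res <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_iter, replace = TRUE), n_iter, n)
    fit <- ols_rows(idx)
    eps <- 1e-30
    n_redraws <- 0L
    bad <- which(!is.finite(fit$slope) | fit$varx <= eps)
    while (length(bad) > 0L) {
      n_redraws <- n_redraws + length(bad)
      if (n_redraws >= 0.1 * n_iter) {
        stop("bootstrap_fit: >=10% of resamples had zero CI variance; ",
             "training data are near-degenerate")
      }
      idx2 <- matrix(sample.int(n, n * length(bad), replace = TRUE),
                     length(bad), n)
      fit2 <- ols_rows(idx2)
      fit$slope[bad] <- fit2$slope
      fit$intercept[bad] <- fit2$intercept
      fit$varx[bad] <- fit2$varx
      bad <- bad[!is.finite(fit2$slope) | fit2$varx <= eps]
    }
    list(fit = fit, n_redraws = n_redraws)
  })
  slope_draws <- res$fit$slope
  intercept_draws <- res$fit$intercept
  if (res$n_redraws > 0L) {
    message("bootstrap_fit: redrew ", res$n_redraws,
            " degenerate resample(s)")
  }
  normal_ci <- function(d) mean(d) + c(-1, 1) * 1.959964 * stats::sd(d)
  structure(list(
    slope_mean = mean(slope_draws),
    intercept_mean = mean(intercept_draws),
    slope_draws = slope_draws,
    intercept_draws = intercept_draws,
    slope_ci95 = unname(stats::quantile(slope_draws, c(0.025, 0.975))),
    intercept_ci95 = unname(stats::quantile(intercept_draws,
                                            c(0.025, 0.975))),
    slope_ci95_normal = if (n_iter > 1L) normal_ci(slope_draws),
    intercept_ci95_normal = if (n_iter > 1L) normal_ci(intercept_draws),
    n_iter = n_iter, n_train = n, n_redraws = res$n_redraws,
    seed = seed), class = "bootstrap_fit")
}

#' @export
print.bootstrap_fit <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap_fit> chl = %.4g * CI_cyano + %.4g ",
                     "(%d iterations, n = %d)\n"),
              x$slope_mean, x$intercept_mean, x$n_iter, x$n_train))
  cat(sprintf("  slope     95%% percentile [%.4g, %.4g]",
              x$slope_ci95[1], x$slope_ci95[2]))
  if (!is.null(x$slope_ci95_normal)) {
    cat(sprintf("  normal approx [%.4g, %.4g]",
                x$slope_ci95_normal[1], x$slope_ci95_normal[2]))
  }
  cat("\n")
  cat(sprintf("  intercept 95%% percentile [%.4g, %.4g]",
              x$intercept_ci95[1], x$intercept_ci95[2]))
  if (!is.null(x$intercept_ci95_normal)) {
    cat(sprintf("  normal approx [%.4g, %.4g]",
                x$intercept_ci95_normal[1], x$intercept_ci95_normal[2]))
  }
  cat("\n")
  if (x$n_redraws > 0L) cat("  redraws:", x$n_redraws, "\n")
  invisible(x)
}

#' Convert a bootstrap fit to a chlorophyll model
#'
#' @param fit A [bootstrap_fit].
#' @param name Model label.
#' @return A [chl_model] with the bootstrap mean coefficients and
#'   percentile 95% bounds.
#' @export
as_chl_model <- function(fit, name = "bootstrap") {
  stopifnot(inherits(fit, "bootstrap_fit"))
  chl_model(fit$slope_mean, fit$intercept_mean,
            slope_ci95 = fit$slope_ci95,
            intercept_ci95 = fit$intercept_ci95, name = name)
}

#' Predict chlorophyll with coefficient-bound spread
#'
#' Central prediction from the mean bootstrap coefficients plus the spread
#' of predictions obtainable from the full range of coefficients inside
#' their 95% confidence bounds: for each CI value the envelope is the
#' min/max of `slope * ci + intercept` over the four corner combinations of
#' the slope and intercept bounds. Because the slope term scales with CI,
#' the envelope widens as predicted chlorophyll grows. Negative central
#' predictions are removed (returned `NA`) as in [apply_chl_model()]; the
#' envelope bounds are reported as computed.
#'
#' @param fit A [bootstrap_fit], or a [chl_model] carrying both coefficient
#'   bounds.
#' @param ci_values Numeric vector of CI_cyano values.
#' @return Tibble with columns `ci`, `chl`, `low`, `high` (ug/L).
#' @examples
#' m <- chl_model(6620, -3.1, c(5974, 7266), c(-8.3, 2.1))
#' predict_with_bounds(m, 0.01)  # 63.1 [51.44, 74.76]
#' @export
predict_with_bounds <- function(fit, ci_values) {
  if (inherits(fit, "bootstrap_fit")) fit <- as_chl_model(fit)
  stopifnot(inherits(fit, "chl_model"), is.numeric(ci_values))
  if (is.null(fit$slope_ci95) || is.null(fit$intercept_ci95)) {
    stop("predict_with_bounds: model lacks coefficient bounds")
  }
  corners <- expand.grid(s = fit$slope_ci95, b = fit$intercept_ci95)
  pred <- outer(ci_values, corners$s) +
    matrix(corners$b, length(ci_values), nrow(corners), byrow = TRUE)
  tibble::tibble(
    ci = ci_values,
    chl = as.numeric(apply_chl_model(ci_values, fit)),
    low = apply(pred, 1L, min),
    high = apply(pred, 1L, max)
  )
}
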