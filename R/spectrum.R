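#' Construct a Rayleigh-corrected reflectance spectrum
#'
#' A `lake_spectrum` holds one pixel's (or station's) unitless
#' Rayleigh-corrected top-of-atmosphere reflectance \eqn{\rho_s(\lambda)} at
#' the canonical MERIS band centers, plus the boolean contamination flags
#' that upstream Level-2 processing attaches to a pixel. The flags are
#' consumed as inputs here: any `TRUE` flag marks the spectrum unusable for
#' index computation.
#'
#' @param rho_s Numeric vector of reflectances. Either length 11 in
#'   [MERIS_BANDS] order, or named `rho_s_413`, ..., `rho_s_885` (any
#'   subset; absent bands are treated as missing). `NA` marks a missing
#'   band.
#' @param flags Named logical vector or list with any of `cloud`,
#'   `mixed_pixel`, `adjacency`, `snow_ice`; unset flags default to `FALSE`.
#' @return An object of class `lake_spectrum`: a list with `wavelengths`
#'   (integer, nm), `rho_s` (numeric, unitless, `NA` = missing) and `flags`
#'   (named logical of length 4).
#' @examples
#' s <- lake_spectrum(c(rho_s_620 = 0.015, rho_s_665 = 0.020,
#'                      rho_s_681 = 0.012, rho_s_709 = 0.022))
#' compute_ci(s)
#' @export
lake_spectrum <- function(rho_s, flags = NULL) {
  stopifnot(is.numeric(rho_s))
  full <- rep(NA_real_, length(MERIS_BANDS))
  names(full) <- paste0("rho_s_", MERIS_BANDS)
  if (is.null(names(rho_s))) {
    if (length(rho_s) != length(MERIS_BANDS)) {
      stop("unnamed `rho_s` must have length ", length(MERIS_BANDS),
           " (one value per canonical band)")
    }
    full[] <- rho_s
  } else {
    bad <- setdiff(names(rho_s), names(full))
    if (length(bad) > 0L) {
      stop("unknown band column(s): ", paste(bad, collapse = ", "),
           "; bands must be among the canonical nominal wavelengths ",
           paste(MERIS_BANDS, collapse = ", "), " nm")
    }
    full[names(rho_s)] <- rho_s
  }
  if (any(is.infinite(full))) stop("reflectance values must be finite or NA")
  fl <- stats::setNames(rep(FALSE, length(FLAG_NAMES)), FLAG_NAMES)
  if (!is.null(flags)) {
    flags <- unlist(flags)
    bad <- setdiff(names(flags), FLAG_NAMES)
    if (length(bad) > 0L) stop("unknown flag(s): ", paste(bad, collapse = ", "))
    fl[names(flags)] <- as.logical(flags)
  }
  structure(list(wavelengths = MERIS_BANDS, rho_s = full, flags = fl),
            class = "lake_spectrum")
}

#' @export
print.lake_spectrum <- function(x, ...) {
  cat("<lake_spectrum>\n")
  print(round(x$rho_s, 6))
  if (any(x$flags)) {
    cat("flags set:", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  }
  invisible(x)
}

band_value <- function(s, nm, context = "spectral_shape") {
  key <- paste0("rho_s_", nm)
  if (!key %in% names(s$rho_s)) {
    stop(context, ": ", nm, " nm is not a canonical band")
  }
  v <- s$rho_s[[key]]
  if (is.na(v)) stop(context, ": band ", nm, " nm is missing")
  v
}

#' Derivative spectral shape (line height) at a band triplet
#'
#' Computes the spectral shape
#' \deqn{SS(\lambda) = \rho_s(\lambda) - \rho_s(\lambda^-) +
#'   [\rho_s(\lambda^-) - \rho_s(\lambda^+)]
#'   \frac{\lambda - \lambda^-}{\lambda^+ - \lambda^-},}
#' the height of \eqn{\rho_s} at the center band above (positive) or below
#' (negative) the straight baseline through the two flanking bands. The
#' baseline subtraction removes any linear trend, so SS responds to spectral
#' curvature only: it is invariant to adding a constant across the triplet
#' and scales linearly with the spectrum.
#'
#' @param s A [lake_spectrum].
#' @param center,lower,upper Nominal band centers \eqn{\lambda},
#'   \eqn{\lambda^-}, \eqn{\lambda^+} in nm; must be canonical bands with
#'   `lower < center < upper` and non-missing reflectance.
#' @return The unitless SS value.
#' @seealso [compute_ci()] for the CI decision tree built on SS(681) and
#'   SS(665).
#' @examples
#' s <- lake_spectrum(c(rho_s_665 = 0.020, rho_s_681 = 0.025,
#'                      rho_s_709 = 0.018))
#' spectral_shape(s, 681, 665, 709)
#' @export
spectral_shape <- function(s, center, lower, upper) {
  stopifnot(inherits(s, "lake_spectrum"))
  for (nm in c(center, lower, upper)) {
    if (!nm %in% MERIS_BANDS) {
      stop("spectral_shape: ", nm,
           " nm is not in the canonical band set (",
           paste(MERIS_BANDS, collapse = ", "), ")")
    }
  }
  if (!(lower < center && center < upper)) {
    stop("spectral_shape: bands must satisfy lower < center < upper, got (",
         lower, ", ", center, ", ", upper, ")")
  }
  r  <- band_value(s, center)
  rm_ <- band_value(s, lower)
  rp <- band_value(s, upper)
  r - rm_ + (rm_ - rp) * (center - lower) / (upper - lower)
}

# Vectorized SS(681) and SS(665) from the four red/NIR bands; the workhorse
# shared by compute_ci methods and the scene generator.
ss_pair <- function(r620, r665, r681, r709) {
  list(
    ss681 = r681 - r665 + (r665 - r709) * (681 - 665) / (709 - 665),
    ss665 = r665 - r620 + (r620 - r681) * (665 - 620) / (681 - 620)
  )
}

ci_detection <- function(ci, ss665) {
  ifelse(ci > 0 & ss665 > 0, "cyano",
         ifelse(ci > 0, "noncyano", "nondetect"))
}

#' Cyanobacteria Index and bloom-type decision
#'
#' Evaluates the line-height Cyanobacteria Index CI = -SS(681) together with
#' SS(665) and classifies the spectrum. A positive CI (reflectance at 681 nm
#' depressed below its baseline) indicates a bloom; the sign of SS(665) then
#' attributes it: phycocyanin absorption in cyanobacteria depresses
#' \eqn{\rho_s(620)} and raises the curvature around 665 nm, so a positive
#' SS(665) marks a cyanobacteria-dominated bloom (`cyano`, with `ci_cyano`
#' set) while SS(665) <= 0 marks some other bloom type (`noncyano`).
#' CI <= 0 is a non-detection. Ties are broken away from detection: CI
#' exactly 0 is `nondetect`, and SS(665) exactly 0 with CI > 0 is
#' `noncyano`.
#'
#' SS(681) uses the band triplet (665, 681, 709) nm and SS(665) the triplet
#' (620, 665, 681) nm; all four bands must be present. A spectrum with any
#' contamination flag set yields the distinct outcome `masked` (not
#' `nondetect`), so composites and match-ups can treat flagged pixels
#' separately from clear-water non-detections.
#'
#' @param x A [lake_spectrum], or a data frame of spectra with columns
#'   `rho_s_620`, `rho_s_665`, `rho_s_681`, `rho_s_709` (other band columns
#'   optional) and optional logical flag columns `cloud`, `mixed_pixel`,
#'   `adjacency`, `snow_ice`.
#' @param ... Unused.
#' @return For a single spectrum, a `ci_result`: list with `ss665`, `ss681`,
#'   `ci`, `detection` (one of `"cyano"`, `"noncyano"`, `"nondetect"`,
#'   `"masked"`) and `ci_cyano` (`NA` unless `detection == "cyano"`). For a
#'   data frame, a [tibble::tibble] with those five columns, one row per
#'   input row (`ss665`, `ss681`, `ci` are `NA` for masked rows).
#' @examples
#' compute_ci(lake_spectrum(c(rho_s_620 = 0.015, rho_s_665 = 0.020,
#'                            rho_s_681 = 0.012, rho_s_709 = 0.022)))
#' @export
compute_ci <- function(x, ...) UseMethod("compute_ci")

#' @rdname compute_ci
#' @export
compute_ci.lake_spectrum <- function(x, ...) {
  if (any(x$flags)) {
    return(structure(list(ss665 = NA_real_, ss681 = NA_real_, ci = NA_real_,
                          detection = "masked", ci_cyano = NA_real_),
                     class = "ci_result"))
  }
  ss681 <- spectral_shape(x, 681, 665, 709)
  ss665 <- spectral_shape(x, 665, 620, 681)
  ci <- -ss681
  detection <- ci_detection(ci, ss665)
  structure(list(ss665 = ss665, ss681 = ss681, ci = ci,
                 detection = detection,
                 ci_cyano = if (detection == "cyano") ci else NA_real_),
            class = "ci_result")
}

#' @rdname compute_ci
#' @export
compute_ci.data.frame <- function(x, ...) {
  need <- paste0("rho_s_", c(620, 665, 681, 709))
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("compute_ci: missing band column(s): ", paste(miss, collapse = ", "))
  }
  masked <- rep(FALSE, nrow(x))
  for (f in intersect(FLAG_NAMES, names(x))) {
    masked <- masked | (!is.na(x[[f]]) & as.logical(x[[f]]))
  }
  bad <- !masked & !stats::complete.cases(x[need])
  if (any(bad)) {
    stop("compute_ci: unmasked row(s) with missing bands: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  ss <- ss_pair(x$rho_s_620, x$rho_s_665, x$rho_s_681, x$rho_s_709)
  ci <- -ss$ss681
  detection <- ifelse(masked, "masked", ci_detection(ci, ss$ss665))
  out <- tibble::tibble(
    ss665 = ifelse(masked, NA_real_, ss$ss665),
    ss681 = ifelse(masked, NA_real_, ss$ss681),
    ci = ifelse(masked, NA_real_, ci),
    detection = detection,
    ci_cyano = ifelse(detection == "cyano", ci, NA_real_)
  )
  for (col in intersect(c("station_id", "date"), names(x))) {
    out[[col]] <- x[[col]]
  }
  out
}

#' @export
print.ci_result <- function(x, ...) {
  cat("<ci_result> detection:", x$detection, "\n")
  if (x$detection != "masked") {
    cat(sprintf("  SS(665) = %+.7f  SS(681) = %+.7f  CI = %+.7f\n",
                x$ss665, x$ss681, x$ci))
  }
  if (!is.na(x$ci_cyano)) cat(sprintf("  CI_cyano = %.7f\n", x$ci_cyano))
  invisible(x)
}

#' Normalize a spectrum by its trapezoidal integral
#'
#' Divides \eqn{\rho_s(\lambda)} by its integrated value over the
#' 400--754 nm range, computed with the trapezoidal rule over the bands
#' actually measured in that window (413--754 nm; there is no measurement at
#' 400 nm, and the 885 nm band lies outside the window). The result has
#' units of nm\eqn{^{-1}} and is invariant to scaling of the input, which
#' isolates spectral shape from amplitude when comparing optically different
#' lakes.
#'
#' @param s A [lake_spectrum] with all bands from 413 through 754 nm present.
#' @return A `lake_spectrum` whose `rho_s` holds the normalized values
#'   (nm^-1; the 885 nm band, if present, is scaled by the same integral),
#'   with the integral stored in attribute `"integral"`.
#' @examples
#' s <- lake_spectrum(rep(0.02, 11))
#' normalize_spectrum(s)$rho_s[["rho_s_560"]]  # 1/341
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "lake_spectrum"))
  in_window <- MERIS_BANDS >= 400 & MERIS_BANDS <= 754
  lam <- MERIS_BANDS[in_window]
  vals <- s$rho_s[paste0("rho_s_", lam)]
  if (anyNA(vals)) {
    stop("normalize_spectrum: bands ",
         paste(lam[is.na(vals)], collapse = ", "),
         " nm missing; all bands in [400, 754] nm are required")
  }
  integral <- pracma::trapz(as.numeric(lam), as.numeric(vals))
  if (!is.finite(integral) || integral <= 0) {
    stop("normalize_spectrum: non-positive integral (", integral, ")")
  }
  out <- s
  out$rho_s <- s$rho_s / integral
  attr(out, "integral") <- integral
  out
}
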