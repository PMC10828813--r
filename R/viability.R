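#' Construct a stress-survival (CFU/OD) viability curve
#'
#' Viable-cell density is expressed as colony-forming units per OD600 unit
#' at each sampling time; the pre-stress time point (t = 0) is the
#' normalization reference.
#'
#' @param time_h Nondecreasing sampling times starting at 0 h.
#' @param cfu_per_od Positive CFU/OD values, same length.
#' @param stressor,strain,condition Optional metadata labels.
#' @return An object of class `viability_curve`.
#' @export
viability_curve <- function(time_h, cfu_per_od, stressor = NA_character_,
                            strain = NA_character_, condition = NA_character_) {
  time_h <- as.numeric(time_h)
  cfu_per_od <- as.numeric(cfu_per_od)
  if (length(time_h) != length(cfu_per_od) || length(time_h) < 1) {
    stop("`time_h` and `cfu_per_od` must be non-empty and of equal length")
  }
  if (time_h[1] != 0) stop("first time point must be 0 h (the pre-stress reference)")
  if (any(diff(time_h) < 0)) stop("`time_h` must be nondecreasing")
  if (any(!is.finite(cfu_per_od)) || any(cfu_per_od <= 0)) {
    stop("`cfu_per_od` must be finite and > 0")
  }
  structure(list(time_h = time_h, cfu_per_od = cfu_per_od,
                 stressor = stressor, strain = strain, condition = condition),
            class = "viability_curve")
}

#' @export
print.viability_curve <- function(x, ...) {
  cat(sprintf("<viability_curve> %d points over %g h%s\n",
              length(x$time_h), max(x$time_h),
              if (!is.na(x$stressor)) paste0(", stressor: ", x$stressor) else ""))
  invisible(x)
}

#' Relative viability normalized to the pre-stress time point
#'
#' The viability at 0 h is set to 1; every later value is
#' `cfu_per_od(t) / cfu_per_od(0)`. Invariant under rescaling all counts by
#' a positive constant.
#'
#' @param curve A [viability_curve()].
#' @return Tibble with `time_h` and `rel_viability` (first value exactly 1).
#' @export
relative_viability <- function(curve) {
  stopifnot(inherits(curve, "viability_curve"))
  if (curve$cfu_per_od[1] <= 0) stop("normalization error: zero initial count")
  tibble::tibble(time_h = curve$time_h,
                 rel_viability = curve$cfu_per_od / curve$cfu_per_od[1])
}

#' Exponential death rate of a survival curve
#'
#' OLS slope of ln(relative viability) versus time; the negative slope is
#' reported as a positive death rate (1/h). A nondecreasing curve yields a
#' rate <= 0, flagged with a warning rather than an error.
#'
#' @param curve A [viability_curve()].
#' @param window Optional length-2 time range (hours) restricting the fit.
#' @return List with `rate` (1/h), `r_squared`, `n_points`, `flagged`.
#' @export
death_rate <- function(curve, window = NULL) {
  rv <- relative_viability(curve)
  keep <- rv$rel_viability > 0
  if (!is.null(window)) {
    keep <- keep & rv$time_h >= window[1] & rv$time_h <= window[2]
  }
  if (sum(keep) < 3) stop("need >= 3 positive points in the fit window")
  f <- loglin_fit(rv$time_h[keep], log(rv$rel_viability[keep]))
  rate <- -f$slope
  flagged <- rate <= 0
  if (flagged) warning("nondecreasing counts: death rate <= 0")
  list(rate = rate, r_squared = f$r2, n_points = sum(keep), flagged = flagged)
}

#' Percent viability loss at a given time
#'
#' `100 * (1 - relative viability at t)`, with log-linear interpolation
#' between the bracketing sampled points (matching exponential-death
#' kinetics). `t` must lie within the observed time range.
#'
#' @param curve A [viability_curve()].
#' @param t Time (hours), scalar or vector, inside the observed range.
#' @return Percentage(s) in \[0, 100\] (negative values are possible if the
#'   culture grew).
#' @export
percent_loss <- function(curve, t) {
  rv <- relative_viability(curve)
  if (any(t < min(rv$time_h)) || any(t > max(rv$time_h))) {
    stop(sprintf("extrapolation error: t must lie within [%g, %g] h",
                 min(rv$time_h), max(rv$time_h)))
  }
  lv <- stats::approx(rv$time_h, log(rv$rel_viability), xout = t,
                      ties = "ordered")$y
  100 * (1 - exp(lv))
}

#' Read a viability curve from CSV (+ optional YAML sidecar)
#'
#' The CSV must have columns `time_h` and `cfu_per_od`; a YAML sidecar may
#' carry `stressor`, `strain`, `condition`.
#'
#' @param path CSV path.
#' @param sidecar Optional YAML metadata path.
#' @return A [viability_curve()].
#' @export
read_viability_curve <- function(path, sidecar = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_h", "cfu_per_od") %in% names(df))) {
    stop("viability CSV must have columns `time_h` and `cfu_per_od`")
  }
  meta <- list()
  sidecar <- sidecar %||% {
    cand <- sub("\\.csv$", ".yaml", path)
    if (file.exists(cand) && cand != path) cand else NULL
  }
  if (!is.null(sidecar)) meta <- yaml::read_yaml(sidecar)
  viability_curve(df$time_h, df$cfu_per_od,
                  stressor = meta$stressor %||% NA_character_,
                  strain = meta$strain %||% NA_character_,
                  condition = meta$condition %||% NA_character_)
}
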