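#' Construct an OD600 growth curve
#'
#' @param time_h Strictly increasing sampling times, hours.
#' @param od600 Positive optical densities (600 nm), same length as `time_h`
#'   (at least 3 points).
#' @param strain,condition Optional metadata labels.
#' @param t_transition Optional shift time (hours) for nutrient-downshift
#'   curves: the moment cells enter the post-shift medium.
#' @param od_ini Optional OD600 measured immediately after the transition
#'   (used by [lag_time()]; it is a measured datum, never estimated).
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(time_h, od600, strain = NA_character_,
                         condition = NA_character_, t_transition = NULL,
                         od_ini = NULL) {
  time_h <- as.numeric(time_h)
  od600 <- as.numeric(od600)
  if (length(time_h) != length(od600) || length(time_h) < 3) {
    stop("need >= 3 (time, OD) points of equal length")
  }
  if (any(diff(time_h) <= 0)) stop("`time_h` must be strictly increasing")
  if (any(!is.finite(od600)) || any(od600 <= 0)) stop("`od600` must be positive")
  structure(
    list(time_h = time_h, od600 = od600,
         strain = strain, condition = condition,
         t_transition = if (is.null(t_transition) || is.na(t_transition)) NULL
                        else as.numeric(t_transition),
         od_ini = od_ini),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %d points, t = [%g, %g] h%s\n",
              length(x$time_h), min(x$time_h), max(x$time_h),
              if (!is.null(x$t_transition))
                sprintf(", shift at %g h", x$t_transition) else ""))
  invisible(x)
}

# Log-linear OLS of ln(OD) on time; r^2 defined as 0 for constant response.
loglin_fit <- function(t, ln_od) {
  fit <- stats::lm(ln_od ~ t)
  ss_tot <- sum((ln_od - mean(ln_od))^2)
  r2 <- if (ss_tot <= 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r2 = r2, residuals = unname(stats::residuals(fit)))
}

#' Fit an exponential growth rate from the exponential phase
#'
#' Ordinary least squares of ln(OD600) on time, restricted to the points
#' inside the OD window (default 0.05-0.5, the usual exponential-phase
#' range). The slope is the growth rate lambda in 1/h (natural log
#' convention).
#'
#' @param curve A [growth_curve()].
#' @param od_window Length-2 numeric, inclusive OD600 bounds of the points
#'   used for fitting.
#' @return An object of class `growth_fit`: `lambda` (1/h),
#'   `ln_od_intercept` (ln OD at t = 0 of the fitted line), `window`
#'   (integer indices used), `r_squared`, `n_points`.
#' @export
fit_growth_rate <- function(curve, od_window = c(0.05, 0.5)) {
  stopifnot(inherits(curve, "growth_curve"), length(od_window) == 2)
  idx <- which(curve$od600 >= od_window[1] & curve$od600 <= od_window[2])
  if (length(idx) < 3) {
    stop(sprintf("insufficient data: %d point(s) within OD window [%g, %g]; need >= 3",
                 length(idx), od_window[1], od_window[2]))
  }
  f <- loglin_fit(curve$time_h[idx], log(curve$od600[idx]))
  structure(
    list(lambda = f$slope, ln_od_intercept = f$intercept, window = idx,
         r_squared = f$r2, n_points = length(idx)),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> lambda = %.4g /h (n = %d, r^2 = %.5f)\n",
              x$lambda, x$n_points, x$r_squared))
  invisible(x)
}

#' Locate the post-shift exponential range of a downshift curve
#'
#' Finds the exponential range of the post-shift part of a nutrient-downshift
#' curve, deterministically. A candidate window is the longest contiguous
#' trailing run of post-shift points whose log-linear fit reaches
#' `r2_min`, found by shrinking from the earliest post-shift point. Because a
#' long exponential tail dominates the total variance, such a window can
#' still carry a few lag-phase points at its head without dropping below
#' `r2_min`; these are then trimmed: leading points whose absolute residual
#' exceeds `max(3 * RMSE of the window's later half, 1e-8)` are removed one
#' at a time. On noiseless piecewise (lag, then exponential) curves the
#' result is exactly the exponential range.
#'
#' @param curve A [growth_curve()] with `t_transition` set.
#' @param r2_min Minimum r-squared of the log-linear fit (default 0.995).
#' @param min_points Minimum window size (default 4).
#' @return Integer vector of point indices (into the curve) of the selected
#'   window.
#' @export
select_postshift_window <- function(curve, r2_min = 0.995, min_points = 4) {
  stopifnot(inherits(curve, "growth_curve"))
  if (is.null(curve$t_transition)) {
    stop("curve has no `t_transition`; not a downshift curve")
  }
  post <- which(curve$time_h >= curve$t_transition)
  if (length(post) < min_points) {
    stop(sprintf("need >= %d post-shift points, found %d", min_points, length(post)))
  }
  found <- NULL
  for (s in seq_len(length(post) - min_points + 1)) {
    idx <- post[s:length(post)]
    f <- loglin_fit(curve$time_h[idx], log(curve$od600[idx]))
    if (f$r2 >= r2_min) { found <- idx; break }
  }
  if (is.null(found)) {
    stop(sprintf("window-search error: no trailing post-shift window reaches r^2 >= %g; consider lowering `r2_min`",
                 r2_min))
  }
  repeat {
    if (length(found) <= min_points) break
    f <- loglin_fit(curve$time_h[found], log(curve$od600[found]))
    later <- f$residuals[seq(ceiling(length(found) / 2) + 1, length(found))]
    tol <- max(3 * sqrt(mean(later^2)), 1e-8)
    if (abs(f$residuals[1]) > tol) found <- found[-1] else break
  }
  found
}

#' Extract a nutrient-downshift lag time by back-extrapolation
#'
#' Fits the post-shift exponential F(t) = exp(a + lambda t) on the given
#' window and back-extrapolates it to the OD measured immediately after the
#' transition: the growth-resumption time solves F(T_resume) = OD_ini, i.e.
#' `T_resume = (ln OD_ini - a) / lambda`, and the lag is
#' `T_lag = T_resume - T_transition` (the classical geometric lag). Negative
#' computed lags (possible under noise) are clamped to 0 with a flag.
#'
#' @param curve A [growth_curve()] with `t_transition` set.
#' @param od_ini OD600 measured immediately after the transition (a datum,
#'   not inferred from the fit). Defaults to the curve's `od_ini` field.
#' @param window Integer indices of the post-shift exponential range;
#'   defaults to [select_postshift_window()].
#' @param r2_min Passed to the window search when `window` is NULL.
#' @return An object of class `lag_result`: `fit` (the post-shift
#'   `growth_fit`), `od_ini`, `t_transition`, `t_resume`, `t_lag`, `clamped`.
#' @export
lag_time <- function(curve, od_ini = NULL, window = NULL, r2_min = 0.995) {
  stopifnot(inherits(curve, "growth_curve"))
  if (is.null(curve$t_transition)) stop("curve has no `t_transition`")
  od_ini <- od_ini %||% curve$od_ini
  if (is.null(od_ini) || !is.finite(od_ini) || od_ini <= 0) {
    stop("`od_ini` (OD measured at the transition) must be supplied and positive")
  }
  window <- window %||% select_postshift_window(curve, r2_min = r2_min)
  f <- loglin_fit(curve$time_h[window], log(curve$od600[window]))
  if (f$slope <= 0) {
    stop("no-growth error: post-shift window has nonpositive growth rate")
  }
  fit <- structure(
    list(lambda = f$slope, ln_od_intercept = f$intercept, window = window,
         r_squared = f$r2, n_points = length(window)),
    class = "growth_fit"
  )
  t_resume <- (log(od_ini) - f$intercept) / f$slope
  t_lag <- t_resume - curve$t_transition
  clamped <- t_lag < 0
  if (clamped) t_lag <- 0
  structure(
    list(fit = fit, od_ini = od_ini, t_transition = curve$t_transition,
         t_resume = t_resume, t_lag = t_lag, clamped = clamped),
    class = "lag_result"
  )
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("<lag_result> T_lag = %.3f h (T_resume = %.3f h, lambda_post = %.3g /h)%s\n",
              x$t_lag, x$t_resume, x$fit$lambda,
              if (x$clamped) " [clamped from negative]" else ""))
  invisible(x)
}

#' Group summary of fitted growth rates
#'
#' Fits each curve with [fit_growth_rate()] and reports per-group mean and SD
#' of lambda. Curves whose fit fails are annotated per curve; a group is
#' dropped (with a warning) only if every curve in it fails.
#'
#' @param curves List of [growth_curve()] objects.
#' @param groups Character vector, one group label per curve. Defaults to
#'   each curve's `strain|condition`.
#' @param od_window Passed to [fit_growth_rate()].
#' @return Tibble with `group`, `mean_lambda`, `sd_lambda`, `n_curves`,
#'   `n_failed`. Per-curve fits (or error messages) are attached as the
#'   `"fits"` attribute.
#' @export
growth_rate_summary <- function(curves, groups = NULL, od_window = c(0.05, 0.5)) {
  stopifnot(length(curves) > 0)
  groups <- groups %||% vapply(curves, function(cv)
    paste(cv$strain %||% "", cv$condition %||% "", sep = "|"), character(1))
  if (length(groups) != length(curves)) stop("one group label per curve required")
  fits <- lapply(curves, function(cv) {
    tryCatch(fit_growth_rate(cv, od_window = od_window),
             error = function(e) conditionMessage(e))
  })
  lambda <- vapply(fits, function(f)
    if (inherits(f, "growth_fit")) f$lambda else NA_real_, numeric(1))
  out <- lapply(unique(groups), function(g) {
    l <- lambda[groups == g]
    ok <- l[!is.na(l)]
    if (length(ok) == 0) {
      warning("group '", g, "' dropped: all growth-rate fits failed")
      return(NULL)
    }
    tibble::tibble(group = g, mean_lambda = mean(ok),
                   sd_lambda = if (length(ok) > 1) stats::sd(ok) else 0,
                   n_curves = length(l), n_failed = sum(is.na(l)))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "fits") <- fits
  res
}

#' Read a growth curve from CSV (+ optional YAML sidecar)
#'
#' The CSV must have columns `time_h` and `od600`. A YAML sidecar (same path
#' with extension `.yaml`, or given explicitly) may carry `t_transition`,
#' `od_ini`, `strain` and `condition`.
#'
#' @param path CSV path.
#' @param sidecar Optional YAML metadata path.
#' @return A [growth_curve()].
#' @export
read_growth_curve <- function(path, sidecar = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_h", "od600") %in% names(df))) {
    stop("growth curve CSV must have columns `time_h` and `od600`")
  }
  meta <- list()
  sidecar <- sidecar %||% {
    cand <- sub("\\.csv$", ".yaml", path)
    if (file.exists(cand) && cand != path) cand else NULL
  }
  if (!is.null(sidecar)) meta <- yaml::read_yaml(sidecar)
  growth_curve(df$time_h, df$od600,
               strain = meta$strain %||% NA_character_,
               condition = meta$condition %||% NA_character_,
               t_transition = meta$t_transition,
               od_ini = meta$od_ini)
}
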