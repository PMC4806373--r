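#' Segment a sigmoidal penetration curve into lag / linear / plateau phases
#'
#' Finite-dose penetration curves are sigmoidal: a hold-up (lag) phase while
#' the membrane charges, a long quasi-linear phase at the maximal rate, and
#' a plateau as the system approaches sorption equilibrium. The linear
#' window is found by scanning every contiguous window of at least
#' `min_points` observations and keeping the longest (in time span) whose
#' ordinary-least-squares fit reaches `R2 >= r2_threshold`; ties are broken
#' toward the earlier window. Windows with zero ordinate variance carry no
#' rate information and are excluded.
#'
#' @param series data.frame with columns `time_h` and `Mt_per_A_g_m2`
#'   (e.g. from [cumulative_penetrated()]).
#' @param r2_threshold Minimum R^2 for a window to count as linear.
#' @param min_points Minimum observations per window (>= 4).
#' @return An object of class `phase_segmentation`: list with `linear_window`
#'   (`c(t_a, t_b)` h), `lag_window`, `plateau_window`, `idx` (rows of the
#'   linear window), `r2`, `n_windows_scanned`, `best_r2`.
#' @export
segment_phases <- function(series, r2_threshold = 0.995, min_points = 4L) {
  series <- check_series(series)
  n <- nrow(series)
  if (n < 8L) {
    stop("segmentation needs >= 8 observations spanning past the inflection",
         call. = FALSE)
  }
  if (min_points < 4L) stop("min_points must be >= 4", call. = FALSE)
  t <- series$time_h; y <- series$Mt_per_A_g_m2
  best <- best_linear_window(t, y, r2_threshold, min_points)
  if (is.null(best$window)) {
    stop("segmentation failed: no window of >= ", min_points,
         " points reaches R^2 >= ", r2_threshold,
         " (best R^2 scanned: ", format(best$best_r2, digits = 4), ")",
         call. = FALSE)
  }
  b <- best$window
  structure(list(linear_window = c(b$t_a, b$t_b),
                 lag_window = c(t[1], b$t_a),
                 plateau_window = c(b$t_b, t[n]),
                 idx = b$i:b$j, r2 = b$r2,
                 n_windows_scanned = best$scanned, best_r2 = best$best_r2),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<phase_segmentation> lag [%g, %g] | linear [%g, %g] ",
                     "(%d pts, R^2 = %.5f) | plateau [%g, %g] h\n"),
              x$lag_window[1], x$lag_window[2],
              x$linear_window[1], x$linear_window[2], length(x$idx), x$r2,
              x$plateau_window[1], x$plateau_window[2]))
  invisible(x)
}

#' Fit the linear penetration phase
#'
#' Ordinary least squares of `M_t/A` on time over the linear window. The
#' slope is the maximal penetration rate `Jmax` (g m^-2 h^-1) and the
#' x-axis intercept `-intercept/slope` is the hold-up time: the period
#' before solute reaches the receiver.
#'
#' @param series data.frame with `time_h`, `Mt_per_A_g_m2`.
#' @param segmentation A [segment_phases()] result, or `NULL` to fit all
#'   points.
#' @param dc_series Optional data.frame `time_h`, `dc_mg_per_L` used to
#'   evaluate the concentration gradient at the window midpoint.
#' @return An object of class `penetration_summary`: `Jmax_g_m2_h`,
#'   `hold_up_time_h` (NA when the slope is not positive), `r2`,
#'   `linear_window`, `n`, `dc_mid_mg_per_L` (NA unless `dc_series` given),
#'   `P_m_s` (NA unless `dc_series` given).
#' @export
fit_linear_phase <- function(series, segmentation = NULL, dc_series = NULL) {
  series <- check_series(series)
  idx <- if (is.null(segmentation)) seq_len(nrow(series)) else {
    stopifnot(inherits(segmentation, "phase_segmentation"))
    segmentation$idx
  }
  if (length(idx) < 4L) {
    stop("linear window must contain >= 4 observations", call. = FALSE)
  }
  t <- series$time_h[idx]; y <- series$Mt_per_A_g_m2[idx]
  f <- ols_fit(t, y)
  jmax <- f$slope; holdup <- NA_real_
  if (jmax > 0) {
    holdup <- -f$intercept / f$slope
    if (holdup < 0) holdup <- 0
  } else {
    warning("non-positive linear-phase slope; Jmax clipped at 0 and ",
            "hold-up time undefined")
    jmax <- 0
  }
  win <- c(t[1], t[length(t)])
  dc_mid <- NA_real_; P <- NA_real_
  if (!is.null(dc_series)) {
    dc_mid <- stats::approx(dc_series$time_h, dc_series$dc_mg_per_L,
                            xout = mean(win), rule = 2)$y
    if (jmax > 0 && is.finite(dc_mid) && dc_mid > 0) {
      P <- penetration_coefficient(jmax, dc_mid)
    }
  }
  structure(list(Jmax_g_m2_h = jmax, hold_up_time_h = holdup,
                 r2 = if (is.na(f$r2)) 1 else f$r2,
                 linear_window = win, n = length(idx),
                 dc_mid_mg_per_L = dc_mid, P_m_s = P),
            class = "penetration_summary")
}

#' @export
print.penetration_summary <- function(x, ...) {
  cat(sprintf(paste0("<penetration_summary> Jmax = %.4g g m^-2 h^-1, ",
                     "hold-up = %s h, R^2 = %.4f, window [%g, %g] h (n = %d)\n"),
              x$Jmax_g_m2_h,
              if (is.na(x$hold_up_time_h)) "undefined" else {
                format(x$hold_up_time_h, digits = 4)
              },
              x$r2, x$linear_window[1], x$linear_window[2], x$n))
  if (!is.na(x$P_m_s)) {
    cat(sprintf("  P = %.3g m/s at dc(mid) = %.4g mg/L\n",
                x$P_m_s, x$dc_mid_mg_per_L))
  }
  invisible(x)
}

#' Penetration coefficient (permeance)
#'
#' `P = J / dc`, converted from per-hour to per-second. A flux in
#' g m^-2 h^-1 divided by a concentration in mg/L (= g/m^3) is m/h, so
#' `P = (J/dc)/3600` m/s exactly, with no other factors.
#'
#' @param J_g_m2_h Penetration rate, g m^-2 h^-1.
#' @param dc_mg_L Driving concentration gradient, mg/L.
#' @return `P` in m/s.
#' @export
penetration_coefficient <- function(J_g_m2_h, dc_mg_L) {
  num_scalar(J_g_m2_h, "J_g_m2_h")
  num_scalar(dc_mg_L, "dc_mg_L")
  if (dc_mg_L <= 0) {
    stop("penetration coefficient undefined for dc <= 0", call. = FALSE)
  }
  (J_g_m2_h / dc_mg_L) / 3600
}

#' Dose-response regression of Jmax on initial donor concentration
#'
#' Least-squares fit through the origin of `Jmax = slope * C_d0` (zero dose
#' forces zero flux), with R^2 computed against the through-origin model
#' (`1 - SSres / sum(J^2)`). The slope (g m^-2 h^-1 per mg/L, i.e. m/h)
#' divided by 3600 is the penetration coefficient in m/s.
#'
#' @param C_d0_mg_L Initial donor concentrations, mg/L.
#' @param Jmax_g_m2_h Matching maximal penetration rates.
#' @return An object of class `dose_response_fit`: `slope_m_h`, `r2`, `n`,
#'   `P_m_s`.
#' @export
dose_response_fit <- function(C_d0_mg_L, Jmax_g_m2_h) {
  stopifnot(is.numeric(C_d0_mg_L), is.numeric(Jmax_g_m2_h),
            length(C_d0_mg_L) == length(Jmax_g_m2_h),
            length(C_d0_mg_L) >= 1L)
  if (any(C_d0_mg_L <= 0)) {
    stop("dose-response fit requires positive concentrations", call. = FALSE)
  }
  sxx <- sum(C_d0_mg_L^2)
  if (sxx == 0) stop("dose-response fit error: all-zero doses", call. = FALSE)
  slope <- sum(C_d0_mg_L * Jmax_g_m2_h) / sxx
  ss_tot <- sum(Jmax_g_m2_h^2)
  ss_res <- sum((Jmax_g_m2_h - slope * C_d0_mg_L)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope_m_h = slope, r2 = r2, n = length(C_d0_mg_L),
                 P_m_s = slope / 3600),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("<dose_response_fit> J = %.4g x C_d0 (R^2 = %.3f, ",
                     "n = %d); P = %.3g m/s\n"),
              x$slope_m_h, x$r2, x$n, x$P_m_s))
  invisible(x)
}

#' Per-temperature-segment penetration rates and fold-changes
#'
#' Under a temperature-programmed run, each constant-temperature period is
#' fitted independently (`M_t/A` vs time, OLS) and the penetration rate of
#' each period is its slope. Fold-changes are ratios of consecutive segment
#' slopes, plus the overall first-to-last fold.
#'
#' Within each segment the fit is restricted to the segment's own linear
#' sub-window (longest window of `>= min_points` points reaching
#' `r2_threshold`, as in [segment_phases()]): the first segment of a cold
#' start contains the hold-up phase, and regressing through it would
#' understate that segment's penetration rate and inflate every fold. When
#' no sub-window reaches the threshold the whole segment is fitted and the
#' segment is flagged (`lag_excluded = FALSE`).
#'
#' @param series data.frame with `time_h`, `Mt_per_A_g_m2`.
#' @param program A [temperature_program()].
#' @param min_points Minimum observations per segment (segments with fewer
#'   are skipped with a warning).
#' @param r2_threshold Threshold for the per-segment linear sub-window.
#' @return List with `segments` (data.frame `t_start_h`, `t_end_h`,
#'   `temperature_C`, `n`, `J_g_m2_h`, `r2`, `lag_excluded`), `folds`
#'   (consecutive slope ratios, NA when a denominator slope is not
#'   positive) and `overall_fold` (last vs first segment).
#' @export
temperature_segment_fit <- function(series, program, min_points = 3L,
                                    r2_threshold = 0.995) {
  series <- check_series(series)
  stopifnot(inherits(program, "temperature_program"))
  segs <- lapply(seq_len(nrow(program)), function(s) {
    t0 <- program$t_start_h[s]; t1 <- program$t_end_h[s]
    idx <- which(series$time_h >= t0 - 1e-9 & series$time_h <= t1 + 1e-9)
    if (length(idx) < min_points) {
      warning("temperature segment [", t0, ", ", t1, "] h has ",
              length(idx), " < ", min_points, " observations; skipped")
      return(NULL)
    }
    tt <- series$time_h[idx]; yy <- series$Mt_per_A_g_m2[idx]
    bw <- best_linear_window(tt, yy, r2_threshold, min_points)
    lag_excluded <- !is.null(bw$window)
    use <- if (lag_excluded) bw$window$i:bw$window$j else seq_along(tt)
    f <- ols_fit(tt[use], yy[use])
    data.frame(t_start_h = t0, t_end_h = t1,
               temperature_C = program$temperature_C[s],
               n = length(use), J_g_m2_h = f$slope,
               r2 = if (is.na(f$r2)) 1 else f$r2,
               lag_excluded = lag_excluded)
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) < 1L) {
    stop("no temperature segment has enough observations", call. = FALSE)
  }
  folds <- rep(NA_real_, max(nrow(segs) - 1L, 0L))
  if (nrow(segs) > 1L) {
    for (s in seq_len(nrow(segs) - 1L)) {
      if (segs$J_g_m2_h[s] > 0) {
        folds[s] <- segs$J_g_m2_h[s + 1L] / segs$J_g_m2_h[s]
      }
    }
  }
  overall <- if (nrow(segs) > 1L && segs$J_g_m2_h[1] > 0) {
    segs$J_g_m2_h[nrow(segs)] / segs$J_g_m2_h[1]
  } else NA_real_
  list(segments = segs, folds = folds, overall_fold = overall)
}

# internal: longest contiguous window (in time span) of >= min_points whose
# OLS fit reaches r2_threshold; ties broken toward the earlier window.
# Flat windows (zero ordinate variance) are skipped.
best_linear_window <- function(t, y, r2_threshold, min_points) {
  n <- length(t)
  best <- NULL; best_r2_any <- -Inf; scanned <- 0L
  if (n >= min_points) {
    for (i in seq_len(n - min_points + 1L)) {
      for (j in seq(i + min_points - 1L, n)) {
        scanned <- scanned + 1L
        f <- ols_fit(t[i:j], y[i:j])
        if (is.na(f$r2)) next
        if (f$r2 > best_r2_any) best_r2_any <- f$r2
        if (f$r2 >= r2_threshold) {
          span <- t[j] - t[i]
          if (is.null(best) || span > best$span + 1e-12 ||
              (abs(span - best$span) <= 1e-12 && t[i] < best$t_a)) {
            best <- list(i = i, j = j, span = span, t_a = t[i], t_b = t[j],
                         r2 = f$r2)
          }
        }
      }
    }
  }
  list(window = best, best_r2 = best_r2_any, scanned = scanned)
}

# internal: fast simple OLS with R^2; r2 is NA when the ordinate has zero
# variance (a flat window carries no rate information)
ols_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  if (sxx == 0) stop("degenerate window: zero time variance", call. = FALSE)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  r2 <- if (syy > 0) {
    res <- y - intercept - slope * x
    1 - sum(res^2) / syy
  } else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2)
}

# internal: validate a (time, Mt/A) series
check_series <- function(series) {
  series <- as.data.frame(series)
  if (!all(c("time_h", "Mt_per_A_g_m2") %in% names(series))) {
    stop("series must have columns time_h and Mt_per_A_g_m2", call. = FALSE)
  }
  if (anyDuplicated(series$time_h)) {
    stop("duplicate times in series", call. = FALSE)
  }
  series[order(series$time_h), c("time_h", "Mt_per_A_g_m2")]
}
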