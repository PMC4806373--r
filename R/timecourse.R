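#' Diffusion-cell time course
#'
#' Sampled donor/receiver concentrations with the evolving cell volumes and
#' the cumulative sampling-loss ledgers. At each record, the mass in a cell
#' is `c * V` (mg) and the mass removed by all aliquots up to and including
#' that time is the cumulative loss; volumes are post-sampling.
#'
#' @param records data.frame with columns `time_h`, `c_d_mg_per_L`,
#'   `c_r_mg_per_L`, `V_d_L`, `V_r_L`, `cum_loss_d_mg`, `cum_loss_r_mg`.
#' @param C_d0_mg_L Initial donor concentration, mg/L.
#' @param M_0_mg Total dose, mg (defaults to `C_d0 * V_d` at the first
#'   record).
#' @param membrane Optional [membrane_spec()] carried as metadata.
#' @return An object of class `time_course` (a data.frame with attributes
#'   `C_d0_mg_L`, `M_0_mg`, `membrane`).
#' @export
time_course <- function(records, C_d0_mg_L = NULL, M_0_mg = NULL,
                        membrane = NULL) {
  need <- c("time_h", "c_d_mg_per_L", "c_r_mg_per_L", "V_d_L", "V_r_L",
            "cum_loss_d_mg", "cum_loss_r_mg")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("time_course records missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[need]
  rownames(records) <- NULL
  bad_time <- which(diff(records$time_h) <= 0)
  if (length(bad_time) > 0) {
    stop("times must be strictly increasing (violated at row ",
         bad_time[1] + 1L, ")", call. = FALSE)
  }
  for (col in c("c_d_mg_per_L", "c_r_mg_per_L")) {
    bad <- which(records[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative concentration in ", col, " at row ", bad[1],
           call. = FALSE)
    }
  }
  for (col in c("V_d_L", "V_r_L")) {
    if (any(records[[col]] <= 0)) stop(col, " must be positive", call. = FALSE)
    if (any(diff(records[[col]]) > 1e-12)) {
      stop(col, " must be non-increasing (aliquots are not replaced)",
           call. = FALSE)
    }
  }
  for (col in c("cum_loss_d_mg", "cum_loss_r_mg")) {
    if (any(records[[col]] < 0) || any(diff(records[[col]]) < -1e-12)) {
      stop(col, " must be nonnegative and non-decreasing", call. = FALSE)
    }
  }
  if (is.null(C_d0_mg_L)) C_d0_mg_L <- records$c_d_mg_per_L[1]
  if (is.null(M_0_mg)) M_0_mg <- C_d0_mg_L * records$V_d_L[1]
  structure(records, class = c("time_course", "data.frame"),
            C_d0_mg_L = C_d0_mg_L, M_0_mg = M_0_mg, membrane = membrane)
}

#' @export
print.time_course <- function(x, ...) {
  cat("<time_course> ", nrow(x), " samples over ",
      format(x$time_h[nrow(x)]), " h; C_d0 = ",
      format(attr(x, "C_d0_mg_L")), " mg/L, M_0 = ",
      format(attr(x, "M_0_mg")), " mg\n", sep = "")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... ", nrow(x) - 4L, " more rows\n", sep = "")
  invisible(x)
}

#' Loss-corrected cumulative penetrated mass
#'
#' The receiver-side cumulative penetrated mass at each sampling time is
#' `M_t = c_r * V_r + cum_loss_r` (mg): what is in the receiver now plus
#' everything previously removed from it by sampling. Reported per membrane
#' area (`M_t / A`, g/m^2) and relative to the dose (`M_t / M_0`, %).
#'
#' @param tc A [time_course()].
#' @param area_m2 Membrane area, m^2 (defaults to the membrane metadata).
#' @return data.frame with `time_h`, `M_t_mg`, `Mt_per_A_g_m2`,
#'   `Mt_per_M0_pct`.
#' @export
cumulative_penetrated <- function(tc, area_m2 = NULL) {
  stopifnot(inherits(tc, "time_course"))
  if (is.null(area_m2)) {
    mem <- attr(tc, "membrane")
    if (is.null(mem)) stop("area_m2 is required when the time course has no ",
                           "membrane metadata", call. = FALSE)
    area_m2 <- mem$area_m2
  }
  num_scalar(area_m2, "area_m2", positive = TRUE)
  M_0 <- attr(tc, "M_0_mg")
  M_t <- tc$c_r_mg_per_L * tc$V_r_L + tc$cum_loss_r_mg
  ratio <- if (!is.null(M_0) && M_0 > 0) 100 * M_t / M_0 else {
    rep(NA_real_, length(M_t))
  }
  data.frame(time_h = tc$time_h, M_t_mg = M_t,
             Mt_per_A_g_m2 = (M_t / 1000) / area_m2,
             Mt_per_M0_pct = ratio)
}

#' Donor-receiver concentration gradient
#'
#' `dc(t) = c_d(t) - c_r(t)` and, when a linear window is supplied, the fold
#' decrease of the gradient from the first record to the end of the linear
#' window.
#'
#' @param tc A [time_course()].
#' @param linear_window Optional numeric `c(t_a, t_b)` (h); the fold is
#'   `dc(first) / dc(t_b)`, reported only when the denominator is positive.
#' @return List with `series` (data.frame `time_h`, `dc_mg_per_L`) and
#'   `fold_decrease` (NA when unavailable).
#' @export
concentration_gradient <- function(tc, linear_window = NULL) {
  stopifnot(inherits(tc, "time_course"))
  dc <- tc$c_d_mg_per_L - tc$c_r_mg_per_L
  fold <- NA_real_
  t_end <- if (is.null(linear_window)) tc$time_h[length(tc$time_h)] else {
    linear_window[2]
  }
  dc_end <- stats::approx(tc$time_h, dc, xout = t_end, rule = 2)$y
  if (is.finite(dc_end) && dc_end > 0) fold <- dc[1] / dc_end
  list(series = data.frame(time_h = tc$time_h, dc_mg_per_L = dc),
       fold_decrease = fold)
}
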