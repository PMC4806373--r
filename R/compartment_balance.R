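#' Invert a solution time course into compartment amounts
#'
#' The membrane load at each time is what the mass balance leaves over:
#' `M_cuticle = M_0 - (c_d V_d + cum_loss_d) - (c_r V_r + cum_loss_r)`.
#' Fast interfacial sorption ties the membrane face touching each solution
#' to that solution: in the forward orientation
#' `M_EW = Kd_EW * c_d * m_EW` and `M_CL = Kd_CL * c_r * m_CL` (masses in
#' kg); in the reverse orientation (inner side faces the donor) the roles
#' of `c_d` and `c_r` swap. The cuticle proper takes the remainder
#' `M_CP = M_cuticle - M_EW - M_CL`. The remainder is never
#' clamped: negative `M_CP` early in a run is the model's diagnostic that
#' interfacial equilibrium has not yet been reached, and is expected before
#' roughly the end of the lag phase. `Kd_CP` plays no role here — only the
#' two boundary interfaces are equilibrium-tied.
#'
#' @param tc A [time_course()] with `M_0` metadata.
#' @param membrane A [membrane_spec()] with `Kd_EW` and `Kd_CL` set.
#' @param tol Fraction of `M_0` by which `M_cuticle` may go negative
#'   (measurement noise makes small negative loads unavoidable early in a
#'   run) before the input is declared mass-balance-corrupt.
#' @return An object of class `compartment_series`: data.frame with
#'   `time_h`, `M_cuticle_mg`, `M_EW_mg`, `M_CP_mg`, `M_CL_mg` and densities
#'   `rho_EW_mg_kg`, `rho_CP_mg_kg`, `rho_CL_mg_kg` (NA for absent
#'   compartments), with the membrane attached as an attribute.
#' @export
invert_compartments <- function(tc, membrane, tol = 0.05) {
  stopifnot(inherits(tc, "time_course"), inherits(membrane, "membrane_spec"))
  M_0 <- attr(tc, "M_0_mg")
  if (is.null(M_0)) stop("time course has no M_0 metadata", call. = FALSE)
  m_kg <- component_masses(membrane) * 1e-6
  M_cut <- M_0 - (tc$c_d_mg_per_L * tc$V_d_L + tc$cum_loss_d_mg) -
    (tc$c_r_mg_per_L * tc$V_r_L + tc$cum_loss_r_mg)
  bad <- which(M_cut < -tol * max(M_0, .Machine$double.eps))
  if (length(bad) > 0) {
    stop("mass-balance violation: negative membrane load at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (min ", format(min(M_cut), digits = 6), " mg); input corrupt?",
         call. = FALSE)
  }
  if (membrane$orientation == "reverse") {
    M_EW <- membrane$Kd_EW * tc$c_r_mg_per_L * m_kg[["m_EW"]]
    M_CL <- membrane$Kd_CL * tc$c_d_mg_per_L * m_kg[["m_CL"]]
  } else {
    M_EW <- membrane$Kd_EW * tc$c_d_mg_per_L * m_kg[["m_EW"]]
    M_CL <- membrane$Kd_CL * tc$c_r_mg_per_L * m_kg[["m_CL"]]
  }
  M_CP <- M_cut - M_EW - M_CL
  dens <- function(M, m) if (m > 0) M / m else rep(NA_real_, length(M))
  cs <- data.frame(time_h = tc$time_h, M_cuticle_mg = M_cut,
                   M_EW_mg = M_EW, M_CP_mg = M_CP, M_CL_mg = M_CL,
                   rho_EW_mg_kg = dens(M_EW, m_kg[["m_EW"]]),
                   rho_CP_mg_kg = dens(M_CP, m_kg[["m_CP"]]),
                   rho_CL_mg_kg = dens(M_CL, m_kg[["m_CL"]]))
  structure(cs, class = c("compartment_series", "data.frame"),
            membrane = membrane, M_0_mg = M_0)
}

#' Compartment densities (mg solute per kg compartment)
#'
#' `rho_X(t) = M_X(t) / m_X` with the compartment dry mass in kg. A
#' compartment with zero mass (e.g. EW of a dewaxed membrane) is omitted
#' with a warning rather than an error.
#'
#' @param cs A [invert_compartments()] result.
#' @param membrane A [membrane_spec()] (defaults to the one attached to
#'   `cs`).
#' @return data.frame `time_h` plus one `rho_X_mg_kg` column per
#'   non-empty compartment.
#' @export
compartment_densities <- function(cs, membrane = NULL) {
  stopifnot(inherits(cs, "compartment_series"))
  if (is.null(membrane)) membrane <- attr(cs, "membrane")
  stopifnot(inherits(membrane, "membrane_spec"))
  m_kg <- component_masses(membrane) * 1e-6
  out <- data.frame(time_h = cs$time_h)
  for (x in c("EW", "CP", "CL")) {
    m <- m_kg[[paste0("m_", x)]]
    if (m > 0) {
      out[[paste0("rho_", x, "_mg_kg")]] <- cs[[paste0("M_", x, "_mg")]] / m
    } else {
      warning("compartment ", x, " has zero mass; density omitted")
    }
  }
  out
}

#' Four-interface flux decomposition of a penetration run
#'
#' Differentiates the mass-balance series to recover the interfacial
#' penetration rates of the donor | EW | CP | CL | receiver chain:
#' `J1 = -(1/A) d(M_d + cum_loss_d)/dt` (what leaves the donor),
#' `J4 = (1/A) d(M_r + cum_loss_r)/dt` (what reaches the receiver),
#' `J2 = J1 - (1/A) dM_EW/dt` and `J3 = J4 + (1/A) dM_CL/dt`.
#' Central differences on the interior, one-sided at the endpoints (which
#' are flagged). Optionally a 3-point running median is applied to the mass
#' series first for noisy data.
#'
#' @param cs A [invert_compartments()] result on the same grid as `tc`.
#' @param tc The matching [time_course()].
#' @param area_m2 Membrane area, m^2 (defaults to membrane metadata).
#' @param median_filter Apply a 3-point median filter before
#'   differentiating (default off).
#' @return An object of class `flux_series`: data.frame `time_h`,
#'   `J1_g_m2_h` .. `J4_g_m2_h`, `endpoint` (logical flag for one-sided
#'   stencils).
#' @export
flux_decomposition <- function(cs, tc, area_m2 = NULL, median_filter = FALSE) {
  stopifnot(inherits(cs, "compartment_series"), inherits(tc, "time_course"))
  if (nrow(cs) != nrow(tc) || any(abs(cs$time_h - tc$time_h) > 1e-9)) {
    stop("compartment series and time course are on different grids",
         call. = FALSE)
  }
  if (nrow(tc) < 3L) stop("flux decomposition needs >= 3 time points",
                          call. = FALSE)
  if (anyDuplicated(tc$time_h)) stop("duplicate times", call. = FALSE)
  if (is.null(area_m2)) {
    mem <- attr(cs, "membrane")
    if (is.null(mem)) stop("area_m2 required", call. = FALSE)
    area_m2 <- mem$area_m2
  }
  num_scalar(area_m2, "area_m2", positive = TRUE)
  filt <- function(x) if (median_filter) stats::runmed(x, 3) else x
  t <- tc$time_h
  M_d <- filt(tc$c_d_mg_per_L * tc$V_d_L + tc$cum_loss_d_mg)
  M_r <- filt(tc$c_r_mg_per_L * tc$V_r_L + tc$cum_loss_r_mg)
  M_EW <- filt(cs$M_EW_mg)
  M_CL <- filt(cs$M_CL_mg)
  conv <- 1 / (1000 * area_m2)          # mg/h -> g m^-2 h^-1
  J1 <- -fd_deriv(t, M_d) * conv
  J4 <- fd_deriv(t, M_r) * conv
  J2 <- J1 - fd_deriv(t, M_EW) * conv
  J3 <- J4 + fd_deriv(t, M_CL) * conv
  n <- length(t)
  structure(data.frame(time_h = t, J1_g_m2_h = J1, J2_g_m2_h = J2,
                       J3_g_m2_h = J3, J4_g_m2_h = J4,
                       endpoint = seq_len(n) %in% c(1L, n)),
            class = c("flux_series", "data.frame"))
}

#' Report the flux ordering over a window
#'
#' Checks the interior-point ordering `J2 > J3 > J4` expected while the
#' membrane charges (lag + linear phases of a forward run).
#'
#' @param fs A [flux_decomposition()] result.
#' @param window Numeric `c(t0, t1)` h; only interior (non-endpoint) rows
#'   inside it are checked.
#' @return List with `fraction_ordered` (share of checked rows satisfying
#'   `J2 > J3 > J4`), `n_checked`, and `all_ordered`.
#' @export
flux_ordering <- function(fs, window) {
  stopifnot(inherits(fs, "flux_series"), length(window) == 2L)
  idx <- which(!fs$endpoint & fs$time_h >= window[1] - 1e-9 &
                 fs$time_h <= window[2] + 1e-9)
  if (length(idx) == 0) {
    return(list(fraction_ordered = NA_real_, n_checked = 0L,
                all_ordered = NA))
  }
  ok <- fs$J2_g_m2_h[idx] > fs$J3_g_m2_h[idx] &
    fs$J3_g_m2_h[idx] > fs$J4_g_m2_h[idx]
  list(fraction_ordered = mean(ok), n_checked = length(idx),
       all_ordered = all(ok))
}

# internal: derivative by central differences (non-uniform grid aware),
# one-sided at the two endpoints
fd_deriv <- function(t, y) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}
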