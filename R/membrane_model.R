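#' Cuticular membrane specification
#'
#' Describes one isolated cuticular membrane (CM) as three stacked
#' compartments: epicuticular waxes (EW, outermost), cuticle proper (CP,
#' intracuticular waxes + cutin) and cuticular layer (CL, cutan +
#' polysaccharides, innermost). Sorption in each compartment is linear with
#' partition coefficient `Kd_X` (L/kg), so a compartment of dry mass `m_X`
#' exposed to solution concentration `c` holds `Kd_X * c * m_X` (mg, with
#' `m_X` in kg) at equilibrium.
#'
#' The default `area_m2` is the constant printed alongside the per-area
#' penetration equations of the motivating diffusion-cell study
#' (7.85e-2 m^2). That constant is geometrically inconsistent with the same
#' study's 1 mm sampling hole, and neither reading is consistent with the
#' study's own flux magnitudes; `area_m2` is therefore an ordinary field and
#' the shipped presets use a self-consistent value (see the package
#' vignette).
#'
#' @param area_m2 Membrane area exposed to solution, m^2.
#' @param mass_total_mg Dry membrane mass, mg.
#' @param f_EW,f_CP,f_CL Compartment mass fractions; must sum to 1.
#' @param Kd_EW,Kd_CP,Kd_CL Linear sorption partition coefficients, L/kg.
#' @param orientation `"forward"` (morphological outer side faces the donor)
#'   or `"reverse"`.
#' @return An object of class `membrane_spec`.
#' @seealso [component_masses()], [effective_cp_partition()],
#'   [equilibrium_state()]
#' @export
membrane_spec <- function(area_m2 = 7.85e-2,
                          mass_total_mg = 12,
                          f_EW = 0.062, f_CP = 0.648, f_CL = 0.290,
                          Kd_EW = 48880, Kd_CP = 67582.06, Kd_CL = 7090,
                          orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  num_scalar(area_m2, "area_m2", positive = TRUE)
  num_scalar(mass_total_mg, "mass_total_mg")
  for (nm in c("f_EW", "f_CP", "f_CL", "Kd_EW", "Kd_CP", "Kd_CL")) {
    num_scalar(get(nm), nm)
  }
  if (mass_total_mg < 0) stop("mass_total_mg must be nonnegative", call. = FALSE)
  fr <- c(f_EW, f_CP, f_CL)
  if (any(fr < 0)) stop("mass fractions must be nonnegative", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("compartment mass fractions must sum to 1 (got ",
         format(sum(fr), digits = 12), ")", call. = FALSE)
  }
  if (any(c(Kd_EW, Kd_CP, Kd_CL) < 0)) {
    stop("partition coefficients must be nonnegative", call. = FALSE)
  }
  structure(list(area_m2 = area_m2, mass_total_mg = mass_total_mg,
                 f_EW = f_EW, f_CP = f_CP, f_CL = f_CL,
                 Kd_EW = Kd_EW, Kd_CP = Kd_CP, Kd_CL = Kd_CL,
                 orientation = orientation),
            class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat("<membrane_spec> ", format(x$mass_total_mg), " mg over ",
      format(x$area_m2), " m^2, orientation ", x$orientation, "\n", sep = "")
  m <- component_masses(x)
  cat(sprintf("  EW %g mg (Kd %g) | CP %g mg (Kd %g) | CL %g mg (Kd %g) L/kg\n",
              m[["m_EW"]], x$Kd_EW, m[["m_CP"]], x$Kd_CP, m[["m_CL"]], x$Kd_CL))
  invisible(x)
}

#' Solute specification
#'
#' @param name Solute label, e.g. `"PHE"` (phenanthrene), `"PYR"` (pyrene) or
#'   `"TCP"` (2,4,6-trichlorophenol).
#' @param detection_limit_mg_L Optional analytical detection limit, mg/L;
#'   observed concentrations below it are reported as 0 by the synthetic
#'   observation model.
#' @return An object of class `solute_spec`.
#' @export
solute_spec <- function(name = "PHE", detection_limit_mg_L = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(detection_limit_mg_L)) {
    num_scalar(detection_limit_mg_L, "detection_limit_mg_L")
    if (detection_limit_mg_L < 0) {
      stop("detection_limit_mg_L must be nonnegative", call. = FALSE)
    }
  }
  structure(list(name = name, detection_limit_mg_L = detection_limit_mg_L),
            class = "solute_spec")
}

#' Diffusion half-cell specification
#'
#' Two glass half-cells separated by the mounted membrane; the donor starts
#' at concentration `C_d0_mg_L`, the receiver at 0. The total dose is
#' `M_0 = C_d0 * V_donor0` (mg).
#'
#' @param V_donor0_L,V_receiver0_L Initial solution volumes, L.
#' @param C_d0_mg_L Initial donor concentration, mg/L.
#' @return An object of class `diffusion_cell_spec` with an `M_0_mg` field.
#' @export
diffusion_cell_spec <- function(V_donor0_L = 0.15, V_receiver0_L = 0.15,
                                C_d0_mg_L = 0.34) {
  num_scalar(V_donor0_L, "V_donor0_L", positive = TRUE)
  num_scalar(V_receiver0_L, "V_receiver0_L", positive = TRUE)
  num_scalar(C_d0_mg_L, "C_d0_mg_L")
  if (C_d0_mg_L < 0) stop("C_d0_mg_L must be nonnegative", call. = FALSE)
  structure(list(V_donor0_L = V_donor0_L, V_receiver0_L = V_receiver0_L,
                 C_d0_mg_L = C_d0_mg_L,
                 M_0_mg = C_d0_mg_L * V_donor0_L),
            class = "diffusion_cell_spec")
}

#' Interfacial transport parameters
#'
#' First-order exchange conductances for the four interfaces of the
#' donor | EW | CP | CL | receiver chain. The net mass flow across an
#' interface is `k * (a_up - a_down)` (mg/h) where `a` is the
#' solution-scale activity of a pool: the concentration (mg/L) for the two
#' solutions, and `density / Kd` (i.e. `M_X / (Kd_X * m_X)`) for a
#' compartment. The conductances `k` therefore carry units of L/h, and net
#' flow vanishes exactly at the Kd-consistent sorption equilibrium.
#'
#' All four conductances are scaled by `Q10^((T - T_ref)/10)` under a
#' temperature program. The default Q10 of 1.92 makes a 15 to 35 degree C
#' step multiply rates by 1.92^2 = 3.69, the midpoint of the 3.0-4.4-fold
#' range reported for cuticular penetration.
#'
#' @param k_d_ew,k_ew_cp,k_cp_cl,k_cl_r Interface conductances, L/h.
#' @param T_ref_C Reference temperature, degrees C, at which the
#'   conductances are stated.
#' @param Q10 Fold-change of all conductances per 10 degrees C.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(k_d_ew, k_ew_cp, k_cp_cl, k_cl_r,
                             T_ref_C = 25, Q10 = 1.92) {
  ks <- c(k_d_ew = k_d_ew, k_ew_cp = k_ew_cp, k_cp_cl = k_cp_cl,
          k_cl_r = k_cl_r)
  for (i in seq_along(ks)) num_scalar(ks[[i]], names(ks)[i])
  if (any(ks < 0)) stop("rate coefficients must be nonnegative", call. = FALSE)
  num_scalar(T_ref_C, "T_ref_C")
  num_scalar(Q10, "Q10", positive = TRUE)
  structure(list(k_d_ew = k_d_ew, k_ew_cp = k_ew_cp, k_cp_cl = k_cp_cl,
                 k_cl_r = k_cl_r, T_ref_C = T_ref_C, Q10 = Q10),
            class = "transport_params")
}

#' Temperature program
#'
#' Piecewise-constant temperature as contiguous `[t_start, t_end)` segments
#' covering the simulation horizon.
#'
#' @param t_start_h,t_end_h,temperature_C Equal-length numeric vectors of
#'   segment bounds (h) and temperatures (degrees C).
#' @return An object of class `temperature_program` (a data.frame).
#' @export
temperature_program <- function(t_start_h, t_end_h, temperature_C) {
  stopifnot(length(t_start_h) == length(t_end_h),
            length(t_end_h) == length(temperature_C),
            length(t_start_h) >= 1L)
  if (any(t_end_h <= t_start_h)) {
    stop("temperature segments must have t_end_h > t_start_h", call. = FALSE)
  }
  o <- order(t_start_h)
  t_start_h <- t_start_h[o]; t_end_h <- t_end_h[o]
  temperature_C <- temperature_C[o]
  if (length(t_start_h) > 1L &&
      any(abs(t_start_h[-1] - t_end_h[-length(t_end_h)]) > 1e-9)) {
    stop("temperature segments must be contiguous and non-overlapping",
         call. = FALSE)
  }
  structure(data.frame(t_start_h = t_start_h, t_end_h = t_end_h,
                       temperature_C = temperature_C),
            class = c("temperature_program", "data.frame"))
}

#' Constant-temperature program
#'
#' @param temperature_C Temperature, degrees C.
#' @param horizon_h Program end time, h.
#' @return A single-segment [temperature_program()].
#' @export
constant_temperature <- function(temperature_C = 25, horizon_h = 360) {
  temperature_program(0, horizon_h, temperature_C)
}

#' Aliquot sampling schedule
#'
#' Times at which a small solution aliquot is withdrawn (and quenched for
#' HPLC analysis, not volume-replaced) from a cell. Cell volumes shrink and
#' the removed mass is tracked in that cell's cumulative loss ledger.
#'
#' @param time_h Sampling times, h.
#' @param cell `"donor"` or `"receiver"` per sampling event (recycled).
#' @param aliquot_L Aliquot volume, L, per event (recycled; default 0.4 mL).
#' @param aliquot_range_L Permitted aliquot range (default 0.3-0.5 mL).
#' @return An object of class `sampling_schedule` (a data.frame).
#' @export
sampling_schedule <- function(time_h, cell, aliquot_L = 4e-4,
                              aliquot_range_L = c(3e-4, 5e-4)) {
  stopifnot(is.numeric(time_h), length(time_h) >= 1L)
  cell <- rep_len(as.character(cell), length(time_h))
  aliquot_L <- rep_len(aliquot_L, length(time_h))
  if (!all(cell %in% c("donor", "receiver"))) {
    stop("cell must be 'donor' or 'receiver'", call. = FALSE)
  }
  if (any(time_h < 0)) stop("sampling times must be nonnegative", call. = FALSE)
  if (any(aliquot_L < aliquot_range_L[1] - 1e-12) ||
      any(aliquot_L > aliquot_range_L[2] + 1e-12)) {
    stop("aliquot volumes outside the configured range [",
         aliquot_range_L[1], ", ", aliquot_range_L[2], "] L", call. = FALSE)
  }
  df <- data.frame(time_h = time_h, cell = cell, aliquot_L = aliquot_L)
  df <- df[order(df$time_h, df$cell), , drop = FALSE]
  for (cl in c("donor", "receiver")) {
    tt <- df$time_h[df$cell == cl]
    if (anyDuplicated(tt)) {
      stop("sampling times must be strictly increasing per cell", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("sampling_schedule", "data.frame"))
}

#' Default both-cell sampling schedule
#'
#' Samples both donor and receiver at 0, 12, 24 h and then every 24 h to
#' `horizon_h`, with 0.4 mL aliquots — a plausible reconstruction of
#' "periodic 0.3-0.5 mL" sampling over a two-week diffusion-cell run.
#'
#' @param horizon_h Last sampling time, h.
#' @param by_h Spacing of the regular part of the schedule, h.
#' @param aliquot_L Aliquot volume, L.
#' @return A [sampling_schedule()] covering both cells.
#' @export
default_schedule <- function(horizon_h = 360, by_h = 24, aliquot_L = 4e-4) {
  tt <- sort(unique(c(0, 12, seq(by_h, horizon_h, by = by_h))))
  sampling_schedule(time_h = rep(tt, each = 2L),
                    cell = rep(c("donor", "receiver"), times = length(tt)),
                    aliquot_L = aliquot_L)
}

#' Dry masses of the three cuticular compartments
#'
#' @param membrane A [membrane_spec()].
#' @return Named numeric vector `c(m_EW, m_CP, m_CL)` in mg, summing to
#'   `mass_total_mg` exactly.
#' @examples
#' component_masses(membrane_spec())  # 0.744 7.776 3.480 for a 12 mg CM
#' @export
component_masses <- function(membrane) {
  stopifnot(inherits(membrane, "membrane_spec"))
  m <- membrane$mass_total_mg * c(m_EW = membrane$f_EW,
                                  m_CP = membrane$f_CP,
                                  m_CL = membrane$f_CL)
  # force exact additivity against rounding in f_X
  m[["m_CL"]] <- membrane$mass_total_mg - m[["m_EW"]] - m[["m_CP"]]
  m
}

#' Close the cuticle-proper partition coefficient by mass balance
#'
#' Sorption isotherms are measured on whole membranes, and literature
#' surrogates exist for EW and CL only. The CP coefficient is obtained by
#' requiring the mass-weighted mean of the compartment coefficients to equal
#' the whole-membrane `Kd`:
#' `Kd_CP = (Kd_membrane*m_total - Kd_EW*m_EW - Kd_CL*m_CL) / m_CP`.
#'
#' @param Kd_membrane Whole-membrane partition coefficient, L/kg.
#' @param membrane A [membrane_spec()] supplying masses and `Kd_EW`, `Kd_CL`.
#' @return `Kd_CP` in L/kg.
#' @export
effective_cp_partition <- function(Kd_membrane, membrane) {
  stopifnot(inherits(membrane, "membrane_spec"))
  num_scalar(Kd_membrane, "Kd_membrane", positive = TRUE)
  m <- component_masses(membrane)
  if (m[["m_CP"]] <= 0) {
    stop("Kd_CP is undefined for a membrane with no cuticle proper (f_CP = 0)",
         call. = FALSE)
  }
  kd <- (Kd_membrane * membrane$mass_total_mg -
           membrane$Kd_EW * m[["m_EW"]] -
           membrane$Kd_CL * m[["m_CL"]]) / m[["m_CP"]]
  if (kd < 0) {
    stop("inconsistent constants: implied Kd_CP is negative (",
         format(kd, digits = 6), " L/kg)", call. = FALSE)
  }
  kd
}

#' Closed-system sorption equilibrium
#'
#' Long-time limit of a sealed two-cell system (no sampling losses): all five
#' pools share one solution-scale activity, so
#' `c_eq = M_0 / (V_d + V_r + sum(Kd_X * m_X))` with compartment masses in
#' kg, and each compartment holds `Kd_X * c_eq * m_X` mg.
#'
#' @param cell A [diffusion_cell_spec()].
#' @param membrane A [membrane_spec()].
#' @return List with `c_eq_mg_L`, named compartment masses `M_EW_mg`,
#'   `M_CP_mg`, `M_CL_mg`, solution masses, and `membrane_fraction` of the
#'   dose held by the membrane.
#' @export
equilibrium_state <- function(cell, membrane) {
  stopifnot(inherits(cell, "diffusion_cell_spec"),
            inherits(membrane, "membrane_spec"))
  m_kg <- component_masses(membrane) * 1e-6
  cap <- c(membrane$Kd_EW, membrane$Kd_CP, membrane$Kd_CL) * m_kg  # L
  denom <- cell$V_donor0_L + cell$V_receiver0_L + sum(cap)
  c_eq <- cell$M_0_mg / denom
  M_comp <- cap * c_eq
  list(c_eq_mg_L = c_eq,
       M_EW_mg = M_comp[[1]], M_CP_mg = M_comp[[2]], M_CL_mg = M_comp[[3]],
       M_donor_mg = c_eq * cell$V_donor0_L,
       M_receiver_mg = c_eq * cell$V_receiver0_L,
       membrane_fraction = if (cell$M_0_mg > 0) sum(M_comp) / cell$M_0_mg else 0)
}

# internal: scalar numeric validation
num_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a finite numeric scalar", call. = FALSE)
  }
  if (positive && x <= 0) stop(name, " must be > 0", call. = FALSE)
  invisible(x)
}
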