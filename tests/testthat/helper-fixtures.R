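# Shared fixtures: the reference green-pepper membrane and small helpers.

paper_membrane <- function(area_m2 = 7.85e-2, ...) {
  membrane_spec(area_m2 = area_m2, ...)
}

# independently derived constants used across tests (hand arithmetic,
# written out so the oracle is visible)
KD_CP_GP <- (48880 * 12 - 48880 * 0.744 - 7090 * 3.48) / 7.776  # 67582.06 L/kg

# a tiny exactly-known time course: straight-line receiver accumulation
# M_t/A = slope * (t - t0) after a flat lag, constant volumes, no losses
line_timecourse <- function(times, slope_g_m2_h, t0_h, area_m2,
                            C_d0 = 0.4, V = 0.15) {
  Mt_A <- pmax(0, slope_g_m2_h * (times - t0_h))
  c_r <- Mt_A * area_m2 * 1000 / V   # mg/L so that c_r*V/1000/A reproduces it
  time_course(data.frame(time_h = times, c_d_mg_per_L = C_d0,
                         c_r_mg_per_L = c_r, V_d_L = V, V_r_L = V,
                         cum_loss_d_mg = 0, cum_loss_r_mg = 0),
              C_d0_mg_L = C_d0)
}

quick_scenario <- function(preset = "green_pepper", cv = 0, seed = 1, ...) {
  make_scenario(preset, list(cv = cv, dt_h = 6, ...), seed = seed)
}

# bare column data, without time_course metadata attributes
tc_columns <- function(tc) {
  df <- as.data.frame(tc)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  class(df) <- "data.frame"
  df
}

# first time at which the decomposed receiver flux is detectably positive:
# during a detection-censored hold-up phase J3 = J4 = 0 exactly, so the
# strict J2 > J3 > J4 ordering is assessed from signal onset
ordering_window <- function(fs, t_end) {
  on <- fs$time_h[!fs$endpoint & fs$J4_g_m2_h > 0]
  c(min(on), t_end)
}
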