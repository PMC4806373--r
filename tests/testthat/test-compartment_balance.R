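worked_tc <- function() {
  time_course(data.frame(time_h = c(0, 50),
                         c_d_mg_per_L = c(0.4, 0.2),
                         c_r_mg_per_L = c(0, 0.05),
                         V_d_L = 0.15, V_r_L = 0.15,
                         cum_loss_d_mg = 0, cum_loss_r_mg = 0),
              C_d0_mg_L = 0.4, M_0_mg = 0.06)
}

test_that("mass-balance inversion reproduces the worked example", {
  cs <- invert_compartments(worked_tc(), paper_membrane())
  # oracle, each term spelled out:
  #   M_cuticle = 0.06 - 0.2*0.15 - 0.05*0.15            = 0.0225 mg
  #   M_EW      = 48880 * 0.2  * 0.744e-6                = 7.2733e-3 mg
  #   M_CL      = 7090  * 0.05 * 3.48e-6                 = 1.2337e-3 mg
  expect_equal(cs$M_cuticle_mg[2], 0.0225, tolerance = 1e-12)
  expect_equal(cs$M_EW_mg[2], 48880 * 0.2 * 0.744e-6, tolerance = 1e-12)
  expect_equal(cs$M_EW_mg[2], 0.00727, tolerance = 1e-3)
  expect_equal(cs$M_CL_mg[2], 7090 * 0.05 * 3.48e-6, tolerance = 1e-12)
  expect_equal(cs$M_CL_mg[2], 0.00123, tolerance = 3e-3)
  expect_equal(cs$M_CP_mg[2], 0.0225 - 48880 * 0.2 * 0.744e-6 -
                 7090 * 0.05 * 3.48e-6, tolerance = 1e-12)
  expect_equal(cs$M_CP_mg[2], 0.01399, tolerance = 1e-3)
})

test_that("empty solutions put the whole dose into the CP remainder", {
  tc <- time_course(data.frame(time_h = c(0, 10), c_d_mg_per_L = 0,
                               c_r_mg_per_L = 0, V_d_L = 0.15, V_r_L = 0.15,
                               cum_loss_d_mg = 0, cum_loss_r_mg = 0),
                    C_d0_mg_L = 0, M_0_mg = 0.06)
  cs <- invert_compartments(tc, paper_membrane())
  expect_equal(cs$M_cuticle_mg, c(0.06, 0.06))
  expect_equal(cs$M_EW_mg, c(0, 0))
  expect_equal(cs$M_CL_mg, c(0, 0))
  expect_equal(cs$M_CP_mg, c(0.06, 0.06))
})

test_that("the construction identity holds to machine precision", {
  set.seed(42)
  for (i in 1:20) {
    n <- 10L
    tc <- time_course(data.frame(
      time_h = cumsum(runif(n, 1, 20)),
      c_d_mg_per_L = 0.4 * exp(-seq_len(n) / 8),
      c_r_mg_per_L = 0.2 * (1 - exp(-seq_len(n) / 5)),
      V_d_L = 0.15 - 4e-4 * seq_len(n),
      V_r_L = 0.15 - 4e-4 * seq_len(n),
      cum_loss_d_mg = cumsum(rep(1e-4, n)),
      cum_loss_r_mg = cumsum(rep(5e-5, n))),
      C_d0_mg_L = 0.4, M_0_mg = 0.06)
    cs <- invert_compartments(tc, paper_membrane())
    expect_lt(max(abs(cs$M_EW_mg + cs$M_CP_mg + cs$M_CL_mg -
                        cs$M_cuticle_mg)), 1e-15)
  }
})

test_that("corrupted inputs violating the mass balance are rejected", {
  tc <- time_course(data.frame(time_h = c(0, 10), c_d_mg_per_L = 0.4,
                               c_r_mg_per_L = 0.4, V_d_L = 0.15, V_r_L = 0.15,
                               cum_loss_d_mg = 0, cum_loss_r_mg = 0),
                    C_d0_mg_L = 0.4, M_0_mg = 0.06)  # 0.12 mg in solution
  expect_error(invert_compartments(tc, paper_membrane()),
               "mass-balance violation")
})

test_that("densities equal Kd times the adjacent concentration at the
          equilibrated interfaces", {
  cs <- invert_compartments(worked_tc(), paper_membrane())
  d <- compartment_densities(cs)
  # oracle: rho_EW = M_EW/m_EW = Kd_EW * c_d
  expect_equal(d$rho_EW_mg_kg[2], 48880 * 0.2, tolerance = 1e-12)
  expect_equal(d$rho_EW_mg_kg[2], 0.00727 / 7.44e-7, tolerance = 1e-3)
  expect_equal(d$rho_CL_mg_kg[2], 7090 * 0.05, tolerance = 1e-12)

  # equilibrium state input: densities proportional to Kd
  mem <- membrane_spec(Kd_CP = KD_CP_GP)
  eq <- equilibrium_state(diffusion_cell_spec(C_d0_mg_L = 0.4), mem)
  tc_eq <- time_course(data.frame(time_h = c(0, 1),
                                  c_d_mg_per_L = eq$c_eq_mg_L,
                                  c_r_mg_per_L = eq$c_eq_mg_L,
                                  V_d_L = 0.15, V_r_L = 0.15,
                                  cum_loss_d_mg = 0, cum_loss_r_mg = 0),
                       C_d0_mg_L = 0.4, M_0_mg = 0.06)
  cs_eq <- invert_compartments(tc_eq, mem)
  d_eq <- compartment_densities(cs_eq)
  expect_equal(d_eq$rho_EW_mg_kg[1] / d_eq$rho_CL_mg_kg[1], 48880 / 7090,
               tolerance = 1e-9)
  expect_equal(d_eq$rho_CP_mg_kg[1] / d_eq$rho_CL_mg_kg[1],
               KD_CP_GP / 7090, tolerance = 1e-9)

  # dewaxed membranes omit the EW density with a warning, not an error
  dmem <- membrane_spec(mass_total_mg = 11.256, f_EW = 0,
                        f_CP = 7.776 / 11.256, f_CL = 3.48 / 11.256)
  cs_d <- invert_compartments(worked_tc(), dmem)
  expect_warning(dd <- compartment_densities(cs_d), "EW")
  expect_false("rho_EW_mg_kg" %in% names(dd))
})

test_that("steady transport gives equal fluxes at all four interfaces", {
  # linear rise in both solutions' bookkeeping with constant compartments
  n <- 9L; t <- seq(0, 80, by = 10)
  tc <- time_course(data.frame(time_h = t,
                               c_d_mg_per_L = 0.4 - 0.001 * t,
                               c_r_mg_per_L = 0.001 * t * (0.15 / 0.15),
                               V_d_L = 0.15, V_r_L = 0.15,
                               cum_loss_d_mg = 0, cum_loss_r_mg = 0),
                    C_d0_mg_L = 0.4, M_0_mg = 0.06)
  mem <- paper_membrane()
  cs <- invert_compartments(tc, mem)
  # overwrite compartment columns with constants: pure steady state
  cs$M_EW_mg <- rep(0.005, n); cs$M_CL_mg <- rep(0.001, n)
  fs <- flux_decomposition(cs, tc, area_m2 = 7.85e-2)
  inner <- !fs$endpoint
  expect_equal(fs$J1_g_m2_h[inner], fs$J2_g_m2_h[inner], tolerance = 1e-12)
  expect_equal(fs$J2_g_m2_h[inner], fs$J3_g_m2_h[inner], tolerance = 1e-12)
  expect_equal(fs$J3_g_m2_h[inner], fs$J4_g_m2_h[inner], tolerance = 1e-12)
})

test_that("finite-difference fluxes match the simulator's instantaneous
          fluxes under dense output", {
  # fast boundary exchange so the inversion's equilibrium assumption holds
  mem <- membrane_spec(area_m2 = 7.85e-6, Kd_CP = KD_CP_GP)
  kap <- 3.5e-3
  tr <- transport_params(100 * kap, 0.12 * kap, kap, 100 * kap)
  cell <- diffusion_cell_spec(C_d0_mg_L = 0.34)
  sim <- simulate_finite_dose(cell, mem, tr, horizon_h = 360, dt_h = 0.5)
  g <- sim$grid
  tc <- time_course(g[, c("time_h", "c_d_mg_per_L", "c_r_mg_per_L",
                          "V_d_L", "V_r_L", "cum_loss_d_mg",
                          "cum_loss_r_mg")],
                    C_d0_mg_L = 0.34, M_0_mg = cell$M_0_mg)
  cs <- invert_compartments(tc, mem)
  fs <- flux_decomposition(cs, tc, 7.85e-6)
  # compare after the fast boundary-layer transient, away from endpoints
  sel <- which(!fs$endpoint & g$time_h >= 24)
  for (j in c("J1_g_m2_h", "J2_g_m2_h", "J3_g_m2_h", "J4_g_m2_h")) {
    rel <- abs(fs[[j]][sel] - g[[j]][sel]) / abs(g[[j]][sel])
    expect_lt(max(rel), 0.02)
  }
})

test_that("inversion recovers simulated EW and CL loads under fast
          boundary exchange", {
  sc <- quick_scenario()
  kap <- 3.544801e-3
  tr <- transport_params(100 * kap, 0.12 * kap, kap, 100 * kap)
  sim <- simulate_finite_dose(sc$cell, sc$membrane, tr,
                              schedule = sc$schedule, horizon_h = 360,
                              dt_h = 6)
  cs <- invert_compartments(sim$timecourse, sc$membrane)
  gi <- match(cs$time_h, sim$grid$time_h)
  sel <- cs$time_h >= 24
  for (x in c("EW", "CL")) {
    est <- cs[[paste0("M_", x, "_mg")]][sel]
    tru <- sim$grid[[paste0("M_", x, "_mg")]][gi][sel]
    expect_lt(max(abs(est - tru) / tru), 0.05)
  }
})

test_that("interior fluxes obey J2 > J3 > J4 while the membrane charges", {
  sc <- quick_scenario()
  ex <- synthesize_experiment(sc)
  s <- analyze_timecourse(ex$observed, sc$membrane$area_m2)
  cs <- invert_compartments(ex$observed, sc$membrane)
  fs <- flux_decomposition(cs, ex$observed, sc$membrane$area_m2)
  ord <- flux_ordering(fs, ordering_window(fs, s$linear_window[2]))
  expect_gt(ord$n_checked, 5)
  expect_true(ord$all_ordered)
})

test_that("duplicate times are rejected by the flux decomposition", {
  tc <- worked_tc()
  cs <- invert_compartments(tc, paper_membrane())
  cs2 <- rbind(cs, cs[2, ]); tc2 <- rbind(tc, tc[2, ])
  attr(cs2, "membrane") <- paper_membrane()
  class(cs2) <- class(cs); class(tc2) <- class(tc)
  expect_error(flux_decomposition(cs2, tc2, 1), "different grids|duplicate")
})

test_that("dewaxing enhances membrane accumulation at matched times", {
  int <- synthesize_experiment(quick_scenario("green_pepper"))$observed
  dew <- synthesize_experiment(quick_scenario("green_pepper_dewaxed"))$observed
  sc_i <- quick_scenario("green_pepper")
  sc_d <- quick_scenario("green_pepper_dewaxed")
  cs_i <- invert_compartments(int, sc_i$membrane)
  cs_d <- invert_compartments(dew, sc_d$membrane)
  sel <- cs_i$time_h > 0
  expect_true(all(cs_d$M_cuticle_mg[sel] > cs_i$M_cuticle_mg[sel]))
})

test_that("reverse penetration loads the waxes far less than forward", {
  fw <- quick_scenario("green_pepper")
  rv <- quick_scenario("reverse")
  cs_f <- invert_compartments(synthesize_experiment(fw)$observed,
                              fw$membrane)
  cs_r <- invert_compartments(synthesize_experiment(rv)$observed,
                              rv$membrane)
  sel <- cs_f$time_h > 24
  expect_true(all(cs_r$M_EW_mg[sel] < cs_f$M_EW_mg[sel]))
})
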