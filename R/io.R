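#' Read a diffusion-cell time course from CSV
#'
#' Expects the package's tidy dialect: header
#' `time_h,c_d_mg_per_L,c_r_mg_per_L,V_d_L,V_r_L,cum_loss_d_mg,cum_loss_r_mg`,
#' UTF-8, period decimal separator. Validation failures name the offending
#' row.
#'
#' @param path CSV file path.
#' @param C_d0_mg_L,M_0_mg Optional metadata; defaults are taken from the
#'   first record (`C_d0 = c_d[1]`, `M_0 = c_d[1] * V_d[1]`).
#' @param membrane Optional [membrane_spec()] metadata.
#' @return A [time_course()].
#' @seealso [write_timecourse()] — the pair round-trips bit-exactly on
#'   canonicalized files.
#' @export
read_timecourse <- function(path, C_d0_mg_L = NULL, M_0_mg = NULL,
                            membrane = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "numeric", check.names = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("time_h", "c_d_mg_per_L", "c_r_mg_per_L", "V_d_L", "V_r_L",
            "cum_loss_d_mg", "cum_loss_r_mg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         " (unit suffixes are part of the dialect)", call. = FALSE)
  }
  time_course(df, C_d0_mg_L = C_d0_mg_L, M_0_mg = M_0_mg,
              membrane = membrane)
}

#' Write a time course in the canonical CSV dialect
#'
#' Numbers are written with `%.17g` so that read/write round-trips are
#' bit-exact.
#'
#' @param tc A [time_course()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  cols <- c("time_h", "c_d_mg_per_L", "c_r_mg_per_L", "V_d_L", "V_r_L",
            "cum_loss_d_mg", "cum_loss_r_mg")
  lines <- c(paste(cols, collapse = ","),
             apply(as.data.frame(tc)[cols], 1L, function(r) {
               paste(vapply(r, fmt_num, character(1)), collapse = ",")
             }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a simulation, compartment or flux series as tidy CSV
#'
#' One observation per row: `time_h, cell_or_compartment, quantity, value,
#' units`, in deterministic column and row order.
#'
#' @param x A `simulation_result`, `compartment_series` or `flux_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_tidy_csv <- function(x, path) {
  df <- tidy_records(x)
  lines <- c("time_h,cell_or_compartment,quantity,value,units",
             sprintf("%s,%s,%s,%s,%s", vapply(df$time_h, fmt_num, ""),
                     df$cell_or_compartment, df$quantity,
                     vapply(df$value, fmt_num, ""), df$units))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# internal: long-format records for export_tidy_csv
tidy_records <- function(x) {
  long <- function(time, where, quantity, value, units) {
    data.frame(time_h = time, cell_or_compartment = where,
               quantity = quantity, value = value, units = units)
  }
  if (inherits(x, "simulation_result")) {
    g <- x$grid
    specs <- list(
      c("c_d_mg_per_L", "donor", "concentration", "mg/L"),
      c("c_r_mg_per_L", "receiver", "concentration", "mg/L"),
      c("M_EW_mg", "EW", "amount", "mg"),
      c("M_CP_mg", "CP", "amount", "mg"),
      c("M_CL_mg", "CL", "amount", "mg"),
      c("J1_g_m2_h", "interface_1", "flux", "g/m2/h"),
      c("J2_g_m2_h", "interface_2", "flux", "g/m2/h"),
      c("J3_g_m2_h", "interface_3", "flux", "g/m2/h"),
      c("J4_g_m2_h", "interface_4", "flux", "g/m2/h"),
      c("V_d_L", "donor", "volume", "L"),
      c("V_r_L", "receiver", "volume", "L"),
      c("cum_loss_d_mg", "donor", "cumulative_loss", "mg"),
      c("cum_loss_r_mg", "receiver", "cumulative_loss", "mg"))
    do.call(rbind, lapply(specs, function(s) {
      long(g$time_h, s[2], s[3], g[[s[1]]], s[4])
    }))
  } else if (inherits(x, "compartment_series")) {
    specs <- list(c("M_cuticle_mg", "cuticle", "amount", "mg"),
                  c("M_EW_mg", "EW", "amount", "mg"),
                  c("M_CP_mg", "CP", "amount", "mg"),
                  c("M_CL_mg", "CL", "amount", "mg"),
                  c("rho_EW_mg_kg", "EW", "density", "mg/kg"),
                  c("rho_CP_mg_kg", "CP", "density", "mg/kg"),
                  c("rho_CL_mg_kg", "CL", "density", "mg/kg"))
    do.call(rbind, lapply(specs, function(s) {
      long(x$time_h, s[2], s[3], x[[s[1]]], s[4])
    }))
  } else if (inherits(x, "flux_series")) {
    do.call(rbind, lapply(1:4, function(i) {
      long(x$time_h, paste0("interface_", i), "flux",
           x[[paste0("J", i, "_g_m2_h")]], "g/m2/h")
    }))
  } else {
    stop("no tidy export for class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
}

#' Serialize / restore a scenario
#'
#' JSON round-trips exactly: `write -> read -> write` is byte-identical.
#'
#' @param scenario A [make_scenario()] result.
#' @param path Output path.
#' @return For `write_scenario`, `path` invisibly; for `read_scenario`, the
#'   restored `scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  ser <- list(
    preset = scenario$preset,
    membrane = unclass(scenario$membrane),
    cell = unclass(scenario$cell),
    solute = unclass(scenario$solute),
    transport = unclass(scenario$transport),
    schedule = as.data.frame(scenario$schedule),
    program = as.data.frame(scenario$program),
    noise = unclass(scenario$noise),
    horizon_h = scenario$horizon_h, dt_h = scenario$dt_h,
    seed = scenario$seed,
    has_competitors = !is.null(scenario$competitors))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  mem <- do.call(membrane_spec, ser$membrane[setdiff(names(ser$membrane),
                                                     character(0))])
  sc <- structure(list(
    preset = ser$preset,
    membrane = mem,
    cell = diffusion_cell_spec(ser$cell$V_donor0_L, ser$cell$V_receiver0_L,
                               ser$cell$C_d0_mg_L),
    solute = solute_spec(ser$solute$name, ser$solute$detection_limit_mg_L),
    transport = transport_params(ser$transport$k_d_ew, ser$transport$k_ew_cp,
                                 ser$transport$k_cp_cl, ser$transport$k_cl_r,
                                 ser$transport$T_ref_C, ser$transport$Q10),
    schedule = sampling_schedule(ser$schedule$time_h, ser$schedule$cell,
                                 ser$schedule$aliquot_L),
    program = temperature_program(ser$program$t_start_h, ser$program$t_end_h,
                                  ser$program$temperature_C),
    noise = noise_model(ser$noise$cv, ser$noise$detection_floor_mg_L),
    competitors = NULL,
    horizon_h = ser$horizon_h, dt_h = ser$dt_h,
    seed = as.integer(ser$seed)), class = "scenario")
  if (isTRUE(ser$has_competitors)) {
    # competitor blocks are preset-defined; rebuild from the preset
    sc$competitors <- make_scenario(ser$preset, seed = sc$seed)$competitors
  }
  sc
}

#' Write an analysis summary as JSON with provenance
#'
#' @param summary A `penetration_summary`, `dose_response_fit` or plain
#'   list.
#' @param path Output path.
#' @param inputs Character vector of input file paths to hash into the
#'   provenance block.
#' @param config Optional configuration list echoed into the document.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, inputs = character(0),
                               config = NULL, seed = NULL) {
  doc <- list(summary = strip_attrs(summary),
              provenance = manifest_block(inputs, config, seed))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

# internal: provenance block (input hashes, package version, seed, config)
manifest_block <- function(inputs = character(0), config = NULL,
                           seed = NULL) {
  hashes <- if (length(inputs) > 0) {
    h <- tools::md5sum(inputs)
    as.list(stats::setNames(unname(h), basename(names(h))))
  } else NULL
  list(package = "cuticleflux",
       version = as.character(utils::packageVersion("cuticleflux")),
       input_md5 = hashes, seed = seed, config = config)
}

# internal: drop attributes/classes that don't serialize cleanly
strip_attrs <- function(x) {
  if (inherits(x, "penetration_summary")) {
    x$segmentation <- NULL
  }
  if (is.list(x)) {
    out <- lapply(unclass(x), function(el) {
      if (is.data.frame(el)) el else if (is.list(el)) strip_attrs(el) else el
    })
    return(out)
  }
  x
}

# internal: shortest decimal representation that survives read-back
fmt_num <- function(x) {
  if (is.na(x)) return("NA")
  s <- sprintf("%.15g", x)
  if (as.numeric(s) == x) return(s)
  sprintf("%.17g", x)
}
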