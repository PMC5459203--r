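# End-to-end orchestration: fixture generation, the full analysis pipeline
# (ensemble -> sorption -> kinetics -> capture model -> D_intra) and the
# JSON analysis report.

#' Write a complete synthetic fixture directory
#'
#' Generates, under one directory, every input the pipeline consumes:
#' a species config, a calibration dilution series, depletion isotherms for
#' both carrier types, loading traces across the solvent/pH series, a
#' loading-trace series over a decade of particle concentrations for the
#' capture-model fit, and the pipeline config that ties them together.
#' Deterministic for a fixed seed.
#'
#' @param dir destination directory (created if needed).
#' @param seed integer seed for all measurement noise.
#' @param noise_frac multiplicative measurement noise fraction.
#' @return The path of the written pipeline config, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, noise_frac = 0.02) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  p <- function(...) file.path(dir, ...)

  species <- list(
    list(name = "MIL-100(Fe)", radius_nm = 26.5, density_g_cm3 = 0.98,
         s_bet_m2_g = 2004),
    list(name = "MIL-101(Cr)", radius_nm = 9.45, density_g_cm3 = 0.62,
         s_bet_m2_g = 3205))
  yaml::write_yaml(species, p("species.yaml"))

  # calibration dilution series, linear with a small positive intercept
  cal_c <- c(5, 10, 25, 50, 100, 250, 500, 1000, 1500)
  cal <- with_seed(seed + 1L, data.frame(
    conc_ug_ml = cal_c,
    absorbance = 0.021 * cal_c + 0.05 +
      stats::rnorm(length(cal_c), 0, 0.01)))
  utils::write.csv(cal, p("calibration.csv"), row.names = FALSE)

  design <- c(5, 10, 20, 50, 100, 200, 400, 700, 1000, 1500)
  iso <- list(
    `MIL-100(Fe)` = list(p_max = 649.4, k_d = 4.4, file = "isotherm_mil100.csv"),
    `MIL-101(Cr)` = list(p_max = 413.5, k_d = 11.7, file = "isotherm_mil101.csv"))
  for (i in seq_along(iso)) {
    d <- gen_isotherm(iso[[i]]$p_max, iso[[i]]$k_d, design,
                      noise_model(noise_frac, 0, seed + 10L + i),
                      replicates = 3L)
    utils::write.csv(as.data.frame(d), p(iso[[i]]$file), row.names = FALSE)
  }

  # loading traces: water + pH series; rates as measured on the bench
  # (1e-3 1/s), flat traces above pH 7
  conditions <- data.frame(
    label = c("water", "ph4.1", "ph5.1", "ph6.2", "ph7.1", "ph7.4", "ph8.4"),
    ph = c(NA, 4.1, 5.1, 6.2, 7.1, 7.4, 8.4),
    solvent = c("water", rep("HBG", 6)),
    rate = c(13e-3, 10e-3, 10e-3, 6e-3, 0, 0, 0),
    offset = c(0.2, 0.65, 0.7, 0.86, 1, 1, 1))
  for (i in seq_len(nrow(conditions))) {
    tr <- gen_trace(conditions$rate[i], conditions$offset[i],
                    baseline_s = 60, duration_s = 500,
                    noise = noise_model(0.01, 0, seed + 20L + i),
                    ph = conditions$ph[i], solvent = conditions$solvent[i])
    write_trace_csv(tr, p(paste0("trace_", conditions$label[i], ".csv")))
  }

  # capture series: decay rate 1/(A/c + tau0) over a decade of c_NP
  a_true <- 0.3; tau0_true <- 60
  c_nps <- c(0.001, 0.002, 0.004, 0.01, 0.02)      # mg/cm^3
  for (i in seq_along(c_nps)) {
    tau <- a_true / c_nps[i] + tau0_true
    tr <- gen_trace(1 / tau, offset = 0.15, baseline_s = 60,
                    duration_s = max(500, 4 * tau),
                    noise = noise_model(0.01, 0, seed + 40L + i),
                    ph = 5.1, solvent = "HBG")
    write_trace_csv(tr, p(sprintf("trace_cnp_%g.csv", c_nps[i])))
  }

  # TEM diameters for both species
  utils::write.csv(
    data.frame(diameter_nm = gen_sizes(49.9, 0.31, 5000, seed + 60L)),
    p("diameters_mil100.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(diameter_nm = gen_sizes(17.8, 0.34, 5000, seed + 61L)),
    p("diameters_mil101.csv"), row.names = FALSE)

  config <- list(
    m_guest = 412.3,
    d_ex = 3.9e-10,
    density_eff_mg_cm3 = 2,
    species_config = "species.yaml",
    isotherms = lapply(names(iso), function(nm)
      list(species = nm, file = iso[[nm]]$file)),
    traces = lapply(seq_len(nrow(conditions)), function(i)
      list(file = paste0("trace_", conditions$label[i], ".csv"),
           label = conditions$label[i])),
    capture_series = lapply(seq_along(c_nps), function(i)
      list(file = sprintf("trace_cnp_%g.csv", c_nps[i]),
           c_np_mg_cm3 = c_nps[i])),
    capture_species = "MIL-100(Fe)",
    seed = seed)
  cfg_path <- p("pipeline.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}

#' Run the full analysis pipeline
#'
#' Executes the analysis end to end from a YAML config: particle-ensemble
#' summaries for each species, Langmuir fits and payload summaries for each
#' isotherm, per-condition first-order decay fits, the capture-model fit of
#' loading time versus particle concentration, and the intraparticle
#' diffusion-constant estimate. Deterministic given fixed inputs.
#'
#' @param config_path path to the pipeline YAML (as written by
#'   [make_fixtures()]); file paths inside are relative to its directory.
#' @return A `mof_report` list with components `species`, `langmuir`,
#'   `payload`, `decay_fits`, `capture`, `d_intra`, `provenance`.
#' @export
#' @examples
#' \donttest{
#' cfg <- make_fixtures(file.path(tempdir(), "fx"), seed = 1)
#' rep <- run_pipeline(cfg)
#' rep$capture$tau0
#' }
run_pipeline <- function(config_path) {
  if (!file.exists(config_path))
    stop_input("pipeline config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  if (length(cfg) == 0) stop_input("pipeline config is empty: ", config_path)
  root <- dirname(config_path)
  rp <- function(f) file.path(root, f)
  for (f in c("m_guest", "species_config"))
    if (is.null(cfg[[f]])) stop_input("pipeline config missing '", f, "'")

  species <- read_species_config(rp(cfg$species_config))

  langmuir <- list(); payload <- list()
  for (entry in cfg$isotherms %||% list()) {
    iso <- read_isotherm_csv(rp(entry$file))
    fit <- fit_langmuir(iso, m_guest = cfg$m_guest)
    langmuir[[entry$species]] <- fit
    if (isTRUE(fit$converged) && entry$species %in% names(species))
      payload[[entry$species]] <- payload_summary(fit, species[[entry$species]])
  }

  decay_fits <- list()
  for (entry in cfg$traces %||% list()) {
    tr <- normalize_trace(read_trace_csv(rp(entry$file)))
    decay_fits[[entry$label %||% entry$file]] <- fit_exponential(tr)
  }

  capture <- NULL; d_intra <- NULL
  cs <- cfg$capture_series %||% list()
  if (length(cs) >= 3) {
    c_np <- vapply(cs, `[[`, numeric(1), "c_np_mg_cm3")
    fits <- lapply(cs, function(e)
      fit_exponential(normalize_trace(read_trace_csv(rp(e$file)))))
    ok <- vapply(fits, function(f) isTRUE(f$detected), logical(1))
    if (sum(ok) >= 3) {
      tau <- vapply(fits[ok], `[[`, numeric(1), "tau")
      se  <- vapply(fits[ok], function(f) f$se_rate / f$rate^2, numeric(1))
      capture <- fit_capture_model(c_np[ok], tau,
                                   se_tau = if (all(is.finite(se))) se)
      sp_name <- cfg$capture_species %||% names(species)[1]
      if (capture$tau0 > 0 && sp_name %in% names(species))
        d_intra <- list(
          species = sp_name,
          radius_nm = species[[sp_name]]$radius_nm,
          tau0_s = capture$tau0,
          d_intra_m2_s = d_intra_estimate(species[[sp_name]]$radius_nm,
                                          capture$tau0))
    }
  }

  inputs <- unlist(c(
    cfg$species_config,
    lapply(cfg$isotherms %||% list(), `[[`, "file"),
    lapply(cfg$traces %||% list(), `[[`, "file"),
    lapply(cs, `[[`, "file")))
  hashes <- tools::md5sum(vapply(inputs, rp, character(1)))
  names(hashes) <- inputs

  structure(
    list(species = species, langmuir = langmuir, payload = payload,
         decay_fits = decay_fits, capture = capture, d_intra = d_intra,
         provenance = list(
           config = normalizePath(config_path),
           input_md5 = as.list(hashes),
           seed = cfg$seed,
           package_version = as.character(utils::packageVersion("mofkinetics")))),
    class = "mof_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an analysis report to JSON
#'
#' Units are spelled out in the field names; running the pipeline twice on
#' identical inputs yields byte-identical files (no timestamps).
#'
#' @param report a `mof_report` from [run_pipeline()].
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "mof_species"))
      return(unclass(x))
    if (inherits(x, c("mof_langmuir_fit", "mof_payload_summary",
                      "mof_decay_fit", "mof_capture_fit")))
      return(unclass(x))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read back a serialized analysis report
#'
#' @param path JSON path written by [write_report_json()].
#' @return A plain nested list mirroring the report structure.
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) stop_input("report not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.mof_report <- function(x, ...) {
  cat("<mof_report>\n")
  cat("  species:", paste(names(x$species), collapse = ", "), "\n")
  for (nm in names(x$langmuir)) {
    f <- x$langmuir[[nm]]
    if (isTRUE(f$converged))
      cat(sprintf("  %s: P_max = %.4g ug/mg, K_D = %.3g ug/mL (%.3g uM)\n",
                  nm, f$p_max, f$k_d_mass, f$k_d_molar))
  }
  det <- vapply(x$decay_fits, function(f) isTRUE(f$detected), logical(1))
  cat(sprintf("  decay fits: %d/%d conditions with detectable loading\n",
              sum(det), length(det)))
  if (!is.null(x$capture))
    cat(sprintf("  capture model: A = %.3g s*mg/cm^3, tau0 = %.3g s\n",
                x$capture$prefactor_a, x$capture$tau0))
  if (!is.null(x$d_intra))
    cat(sprintf("  D_intra(%s) = %.3g m^2/s\n",
                x$d_intra$species, x$d_intra$d_intra_m2_s))
  invisible(x)
}
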