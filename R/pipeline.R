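#' Default end-to-end pipeline configuration
#'
#' All tunables of [run_pipeline()] in one place.  Unknown keys are
#' rejected by the schema check, so typos fail loudly.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 20260101,
    out_dir = "pipeline_out",
    pk_study = list(design = "both"),
    pk_fit = list(method = "fo", n_starts = 1,
                  fix = c("Km", "sigma_add"), compute_rse = TRUE),
    exposure = list(doses = default_dose_ladder(), cycle_length = 504,
                    noael_auc = 193),
    xenograft = list(arms = c(0, 2.5, 25), n_per_arm = 10),
    pd_fit = list(method = "fo", n_starts = 1, compute_rse = TRUE),
    translation = list(human_doses = c(360, 750, 900), n_weekly_doses = 3,
                       stasis_day = 21),
    mouse_weight = 0.02
  )
}

.check_config <- function(config, schema = default_config(), path = "") {
  bad <- setdiff(names(config), names(schema))
  if (length(bad)) {
    stop("unknown config key(s): ",
         paste0(path, bad, collapse = ", "))
  }
  for (nm in names(config)) {
    if (is.list(schema[[nm]]) && !is.null(names(schema[[nm]]))) {
      .check_config(config[[nm]], schema[[nm]], paste0(path, nm, "$"))
    }
  }
  utils::modifyList(schema, config)
}

.log_stage <- function(...) message("[pipeline] ", sprintf(...))

#' Run the full translational analysis pipeline
#'
#' Executes the analysis chain end-to-end on synthetic data: generate a
#' monkey PK study, fit the population PK model, scale the estimates to
#' human and mouse, build the human exposure / receptor-occupancy table,
#' generate a xenograft study, fit the tumor model, and evaluate
#' tumor stasis under AUC-matched mouse regimens of the proposed clinical
#' doses.  All randomness flows from `config$seed`; rerunning with the
#' same config is byte-identical.  Artifacts (datasets, fit reports as
#' JSON, and the three report tables as CSV) are written under
#' `config$out_dir`.
#'
#' @param config A (possibly partial) configuration; merged over
#'   [default_config()] after schema validation.
#' @return Invisibly, a list with the fit results, the exposure table and
#'   the stasis table, plus `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- .check_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage <- "generate PK study"
  result <- tryCatch({
    .log_stage("seed %d; writing to %s", cfg$seed, cfg$out_dir)
    truth <- human_default_params()
    d1 <- generate_monkey_pk_study(truth, design = monkey_single_dose_design())
    if (cfg$pk_study$design == "both") {
      d2 <- generate_monkey_pk_study(truth,
                                     design = monkey_repeat_dose_design())
      d2$ID <- d2$ID + max(d1$ID)
      pk_data <- rbind(d1, d2)
    } else pk_data <- d1
    write_dataset(pk_data, file.path(cfg$out_dir, "monkey_pk.csv"))

    stage <- "fit PK model"
    .log_stage("fitting PK model (%s)", cfg$pk_fit$method)
    pk_fit <- fit_pk(pk_data, method = cfg$pk_fit$method,
                     n_starts = cfg$pk_fit$n_starts, fix = cfg$pk_fit$fix,
                     compute_rse = cfg$pk_fit$compute_rse)

    stage <- "allometric scaling"
    human <- pk_fit$estimates
    mouse <- scale_params(human, cfg$mouse_weight)
    tab1 <- data.frame(
      parameter = c("CL", "V1", "Q", "V2", "Vmax", "Km"),
      unit = c("L/h", "L", "L/h", "L", "mg/h", "mg/L"),
      estimate_human = unlist(human[c("CL", "V1", "Q", "V2", "Vmax", "Km")]),
      scaled_mouse = unlist(mouse[c("CL", "V1", "Q", "V2", "Vmax", "Km")]))
    rse <- pk_fit$rse_percent
    tab1$rse_percent <- rse[match(tab1$parameter, names(rse))]
    utils::write.csv(tab1, file.path(cfg$out_dir, "pk_parameters.csv"),
                     row.names = FALSE)

    stage <- "exposure table"
    .log_stage("building exposure table over %d doses",
               length(cfg$exposure$doses))
    ref <- reference_exposure(noael_auc = cfg$exposure$noael_auc)
    expo <- exposure_table(human, doses = cfg$exposure$doses,
                           cycle_length = cfg$exposure$cycle_length,
                           ref = ref)
    utils::write.csv(format_exposure_table(expo),
                     file.path(cfg$out_dir, "exposure_table.csv"),
                     row.names = FALSE)

    stage <- "generate xenograft study"
    pd_truth <- pd_params()
    xeno <- generate_xenograft_study(pd_truth, mouse,
                                     arms = cfg$xenograft$arms,
                                     n_per_arm = cfg$xenograft$n_per_arm,
                                     mouse_weight = cfg$mouse_weight)
    write_dataset(xeno, file.path(cfg$out_dir, "xenograft.csv"))

    stage <- "fit tumor model"
    .log_stage("fitting tumor model (%s)", cfg$pd_fit$method)
    pd_fit <- fit_pd(xeno, mouse, method = cfg$pd_fit$method,
                     n_starts = cfg$pd_fit$n_starts,
                     compute_rse = cfg$pd_fit$compute_rse)
    est <- pd_fit$estimates
    tab2 <- data.frame(
      parameter = c("Base", "KG", "KD", "Kio", "EC50", "EC50_KD", "lam"),
      unit = c("mm3", "mm3/h", "1/h", "1/h", "mg/L", "mg/L", "1/week"),
      estimate = unlist(est[c("Base", "KG", "KD", "Kio", "EC50", "EC50_KD",
                              "lam")]))
    rse2 <- pd_fit$rse_percent
    tab2$rse_percent <- rse2[match(tab2$parameter, names(rse2))]
    utils::write.csv(tab2, file.path(cfg$out_dir, "pd_parameters.csv"),
                     row.names = FALSE)

    stage <- "dose translation"
    .log_stage("AUC-matched translation of %s mg",
               paste(cfg$translation$human_doses, collapse = "/"))
    stasis <- lapply(cfg$translation$human_doses, function(hd) {
      m <- auc_matched_mouse_dose(hd, cfg$translation$n_weekly_doses,
                                  human = human, mouse = mouse)
      reg <- weekly_regimen(m$weekly_dose_mg, cfg$translation$n_weekly_doses)
      tc <- simulate_tumor(est, mouse, reg,
                           times = seq(0, cfg$translation$stasis_day * 24,
                                       by = 6))
      s <- stasis_metric(tc, cfg$translation$stasis_day)
      data.frame(human_dose_mg = hd,
                 mouse_weekly_mg_per_kg = m$weekly_dose_mg_per_kg,
                 matched_auc_g_h_L = m$target_auc,
                 volume_ratio = s$ratio,
                 classification = s$classification)
    })
    stasis <- do.call(rbind, stasis)
    utils::write.csv(stasis, file.path(cfg$out_dir, "stasis_table.csv"),
                     row.names = FALSE)

    fits <- list(
      pk = list(estimates = unclass(human)[1:7],
                omega_cv = as.list(unclass(pk_fit$omega)),
                sigma_prop = pk_fit$residual$proportional_sd,
                objective = pk_fit$objective,
                convergence = pk_fit$convergence),
      pd = list(estimates = unclass(est)[1:9],
                omega_cv = as.list(unclass(pd_fit$omega)),
                sigma_prop = pd_fit$residual$proportional_sd,
                objective = pd_fit$objective,
                convergence = pd_fit$convergence),
      seed = cfg$seed)
    jsonlite::write_json(fits, file.path(cfg$out_dir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA)
    list(pk_fit = pk_fit, pd_fit = pd_fit, exposure = expo,
         stasis = stasis, out_dir = cfg$out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  .log_stage("done")
  invisible(result)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [default_config()] keys.
#' @return The merged, validated configuration.
#' @export
read_config <- function(path) {
  .check_config(yaml::read_yaml(path))
}
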