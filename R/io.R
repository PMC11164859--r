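#' Read a drug config (JSON)
#'
#' Fields mirror the published drug-parameter table:
#' `molecular_weight_g_mol`, `pka`, `solubility_mg_ml`, `log_p`,
#' `binding_protein`, `intestinal_permeability_cm_min`, `fu`,
#' `km_cyp2c19_uM`, `kcat_cyp2c19_per_min`, `renal_clearance_ml_min_kg`;
#' optional `name`, `fu_literature_range`, `blood_plasma_ratio`, `kery`.
#' Unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return A [drug_parameters()] object.
#' @export
read_drug_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("molecular_weight_g_mol", "pka", "solubility_mg_ml",
                "log_p", "binding_protein",
                "intestinal_permeability_cm_min", "fu", "km_cyp2c19_uM",
                "kcat_cyp2c19_per_min", "renal_clearance_ml_min_kg")
  optional <- c("name", "fu_literature_range", "blood_plasma_ratio", "kery",
                "ka_ap")
  .check_keys(cfg, required, optional, "drug config")
  drug_parameters(
    molecular_weight = cfg$molecular_weight_g_mol, pka = cfg$pka,
    log_p = cfg$log_p, solubility = cfg$solubility_mg_ml, fu = cfg$fu,
    binding_protein = cfg$binding_protein,
    intestinal_permeability = cfg$intestinal_permeability_cm_min,
    km_cyp2c19 = cfg$km_cyp2c19_uM,
    kcat_cyp2c19 = cfg$kcat_cyp2c19_per_min,
    renal_clearance = cfg$renal_clearance_ml_min_kg,
    blood_plasma_ratio = cfg$blood_plasma_ratio,
    kery = if (is.null(cfg$kery)) 1 else cfg$kery,
    ka_ap = cfg$ka_ap)
}

.check_keys <- function(cfg, required, optional, what) {
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    stop(sprintf("%s: missing required field(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(cfg), c(required, optional))
  if (length(unknown))
    stop(sprintf("%s: unknown field(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  invisible(cfg)
}

#' Read a physiology/disease config (JSON)
#'
#' Fields: `body_weight_kg`, `sex`, `age_yr` and optional `disease`
#' (`{"kind": ..., "severity": ..., "overrides": {...}}`). Unknown keys
#' are rejected.
#'
#' @param path Path to a JSON file.
#' @return A `physiology_set`.
#' @export
read_physiology_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  .check_keys(cfg, character(0),
              c("body_weight_kg", "sex", "age_yr", "disease"),
              "physiology config")
  phys <- reference_adult(
    body_weight = if (is.null(cfg$body_weight_kg)) 73 else cfg$body_weight_kg,
    sex = if (is.null(cfg$sex)) "male" else cfg$sex,
    age = if (is.null(cfg$age_yr)) 30 else cfg$age_yr)
  if (!is.null(cfg$disease)) {
    .check_keys(cfg$disease, c("kind", "severity"), "overrides",
                "disease config")
    ov <- if (is.null(cfg$disease$overrides)) list()
          else as.list(cfg$disease$overrides)
    phys <- apply_disease(phys, disease_spec(cfg$disease$kind,
                                             cfg$disease$severity, ov))
  }
  phys
}

#' Read a dosing-regimen config (JSON)
#'
#' Fields: `route`, `dose_mg`; optional `n_doses`, `interval_h`,
#' `infusion_duration_h`. Unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return A [dose_regimen()].
#' @export
read_regimen_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  .check_keys(cfg, c("route", "dose_mg"),
              c("n_doses", "interval_h", "infusion_duration_h"),
              "regimen config")
  dose_regimen(cfg$route, cfg$dose_mg,
               n_doses = if (is.null(cfg$n_doses)) 1L else cfg$n_doses,
               interval = if (is.null(cfg$interval_h)) 24 else cfg$interval_h,
               infusion_duration = if (is.null(cfg$infusion_duration_h)) 0
                                   else cfg$infusion_duration_h)
}

#' Write / read a concentration-time profile CSV
#'
#' Comma-separated, dot decimal, header `time_h,conc_ug_per_ml`
#' (plus any extra columns), UTF-8, 15 significant digits — lossless
#' round-trip up to float formatting.
#'
#' @param profile data.frame with at least `time_h`, `conc_ug_per_ml`.
#' @param path Output path.
#' @return `path`, invisibly (writer); the data.frame (reader).
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(all(c("time_h", "conc_ug_per_ml") %in% names(profile)))
  num <- vapply(profile, is.numeric, logical(1))
  profile[num] <- lapply(profile[num], signif, digits = 15)
  utils::write.csv(profile, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("time_h", "conc_ug_per_ml") %in% names(out)))
    stop("profile CSV needs columns time_h, conc_ug_per_ml", call. = FALSE)
  out
}

#' Run configuration for workflow commands
#'
#' @param drug_config_path,physiology_config_path,regimen_config_path
#'   Paths to the JSON configs; must exist at load time (regimen optional
#'   for `generate-data`/`reproduce-paper`).
#' @param output_dir Directory for artifacts; created if absent.
#' @param seed Integer seed recorded in every manifest and feeding every
#'   stochastic step.
#' @param population Optional [population_spec()] for the `population`
#'   command.
#' @param disease Optional [disease_spec()] applied on top of the
#'   physiology config.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` object.
#' @export
run_config <- function(drug_config_path, physiology_config_path = NULL,
                       regimen_config_path = NULL, output_dir = tempdir(),
                       seed = 1L, population = NULL, disease = NULL,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  for (p in c(drug_config_path, physiology_config_path,
              regimen_config_path))
    if (!is.null(p) && !file.exists(p))
      stop("config path does not exist: ", p, call. = FALSE)
  structure(list(drug_config_path = drug_config_path,
                 physiology_config_path = physiology_config_path,
                 regimen_config_path = regimen_config_path,
                 output_dir = output_dir, seed = as.integer(seed),
                 population = population, disease = disease,
                 log_level = log_level),
            class = "run_config")
}

.manifest <- function(config, command, files) {
  list(command = command,
       package_version = as.character(utils::packageVersion("brvpbpk")),
       seed = config$seed,
       inputs = lapply(
         Filter(Negate(is.null),
                list(drug = config$drug_config_path,
                     physiology = config$physiology_config_path,
                     regimen = config$regimen_config_path)),
         function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
       outputs = files,
       timestamp = format(Sys.time(), tz = "UTC"))
}

.log <- function(config, ...) {
  if (config$log_level != "quiet") message(sprintf(...))
  invisible(NULL)
}

#' Run an end-to-end workflow command
#'
#' Commands: `simulate` (one profile CSV), `population` (VPC band CSV),
#' `nca` (PK parameter JSON for the simulated profile),
#' `evaluate` (observed-vs-predicted table CSV from two profile CSVs of
#' PK values), `generate-data` (synthetic observed CSV + manifest) and
#' `reproduce-paper` (calibrates the healthy model, runs healthy IV/oral
#' and Child-Pugh simulations, NCA, and writes the evaluation table
#' against the shipped clinical reference values). Each command writes a
#' `manifest.json` (inputs hash, seed, package version); partial outputs
#' are removed on failure.
#'
#' @param config A [run_config()].
#' @param command One of the commands above.
#' @return Invisible list of artifact paths.
#' @export
run_workflow <- function(config,
                         command = c("simulate", "population", "nca",
                                     "evaluate", "generate-data",
                                     "reproduce-paper")) {
  stopifnot(inherits(config, "run_config"))
  command <- match.arg(command)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  out <- function(f) file.path(config$output_dir, f)
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("workflow '%s' failed: %s", command, conditionMessage(e)),
         call. = FALSE)
  }
  res <- tryCatch({
    drug <- read_drug_config(config$drug_config_path)
    phys <- if (!is.null(config$physiology_config_path))
      read_physiology_config(config$physiology_config_path)
    else reference_adult()
    if (!is.null(config$disease)) phys <- apply_disease(phys, config$disease)
    amount <- calibrate_hepatic_activity(drug, reference_adult())

    if (command == "simulate") {
      regimen <- read_regimen_config(config$regimen_config_path)
      sim <- suppressWarnings(
        simulate_pbpk(drug, phys, regimen, cyp2c19_amount = amount))
      written <- c(written, out("profile.csv"))
      write_profile_csv(profile_frame(sim), out("profile.csv"))
      .log(config, "simulate: wrote %s", out("profile.csv"))
      list(profile = out("profile.csv"))
    } else if (command == "population") {
      regimen <- read_regimen_config(config$regimen_config_path)
      spec <- if (is.null(config$population))
        population_spec(100, seed = config$seed) else config$population
      pop <- sample_population(spec, phys)
      sims <- simulate_population(drug, pop, regimen,
                                  cyp2c19_amount = amount)
      vpc <- vpc_summary(sims)
      written <- c(written, out("vpc.csv"))
      utils::write.csv(vpc, out("vpc.csv"), row.names = FALSE)
      .log(config, "population: n=%d, wrote %s", spec$n, out("vpc.csv"))
      list(vpc = out("vpc.csv"))
    } else if (command == "nca") {
      regimen <- read_regimen_config(config$regimen_config_path)
      sim <- suppressWarnings(
        simulate_pbpk(drug, phys, regimen, cyp2c19_amount = amount))
      pk <- nca(profile_frame(sim),
                dose = regimen$dose_amount * regimen$n_doses,
                body_weight = phys$body_weight, route = regimen$route)
      written <- c(written, out("pk.json"))
      jsonlite::write_json(unclass(pk), out("pk.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      list(pk = out("pk.json"))
    } else if (command == "evaluate") {
      ref <- clinical_reference_values("all")
      obs <- data.frame(label = paste(ref$label, sep = "_"),
                        parameter = ref$parameter, value = ref$observed)
      pre <- data.frame(label = obs$label, parameter = ref$parameter,
                        value = ref$predicted)
      ev <- evaluation_table(obs, pre)
      written <- c(written, out("evaluation.csv"), out("evaluation_summary.csv"))
      utils::write.csv(ev$table, out("evaluation.csv"), row.names = FALSE)
      utils::write.csv(ev$summary, out("evaluation_summary.csv"),
                       row.names = FALSE)
      list(evaluation = out("evaluation.csv"),
           summary = out("evaluation_summary.csv"))
    } else if (command == "generate-data") {
      design <- bundled_designs()$healthy_oral_low
      design$seed <- config$seed
      datum <- generate_observed(design, drug, phys,
                                 cyp2c19_amount = amount)
      written <- c(written, out("observed.csv"))
      utils::write.csv(datum, out("observed.csv"), row.names = FALSE)
      list(observed = out("observed.csv"))
    } else {  # reproduce-paper
      rp <- reproduce_evaluation(drug, amount, config$output_dir,
                                 seed = config$seed)
      rp$paths
    }
  }, error = on_fail)
  files <- unlist(res)
  manifest <- .manifest(config, command, as.list(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(res, manifest = out("manifest.json")))
}

#' Reproduce the published model-evaluation workflow
#'
#' Chains the published workflow on this implementation: calibrate the
#' healthy model against the literature clearance, simulate healthy
#' 100 mg IV and oral doses plus Child-Pugh A/B/C oral 100 mg and CKD
#' oral 200 mg, run NCA on every profile, and evaluate this model's
#' predictions against the shipped clinical observed values (ratio,
#' two-fold flag, per-parameter AFE).
#'
#' @param drug A [drug_parameters()] object.
#' @param cyp2c19_amount Calibrated CYP2C19 amount (umol); calibrated
#'   here when `NULL`.
#' @param output_dir Optional directory; when given, CSV artifacts are
#'   written there.
#' @param seed Seed recorded with the outputs (the chain is
#'   deterministic).
#' @return List with `predicted` (per scenario/parameter NCA values),
#'   `evaluation` (vs the shipped observed values) and file paths when
#'   `output_dir` is set.
#' @export
reproduce_evaluation <- function(drug = brivaracetam(),
                                 cyp2c19_amount = NULL, output_dir = NULL,
                                 seed = 1L) {
  healthy <- reference_adult()
  if (is.null(cyp2c19_amount))
    cyp2c19_amount <- calibrate_hepatic_activity(drug, healthy)
  scen <- list(
    iv_100 = list(phys = healthy, route = "iv_bolus", dose = 100),
    oral_10_s21 = list(phys = healthy, route = "oral", dose = 10),
    oral_100_s21 = list(phys = healthy, route = "oral", dose = 100),
    cp_a_100 = list(phys = .physiology_for_population("CP_A"),
                    route = "oral", dose = 100),
    cp_b_100 = list(phys = .physiology_for_population("CP_B"),
                    route = "oral", dose = 100),
    cp_c_100 = list(phys = .physiology_for_population("CP_C"),
                    route = "oral", dose = 100),
    ckd_moderate_200 = list(phys = .physiology_for_population("CKD_moderate"),
                            route = "oral", dose = 200),
    ckd_severe_200 = list(phys = .physiology_for_population("CKD_severe"),
                          route = "oral", dose = 200))
  # clinical-style schedule; 5- and 10-min samples cover the IV
  # distribution phase
  sampling <- c(5 / 60, 10 / 60, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8,
                12, 16, 24, 36, 48, 60, 72)
  pred <- do.call(rbind, lapply(names(scen), function(nm) {
    s <- scen[[nm]]
    sim <- suppressWarnings(
      simulate_pbpk(drug, s$phys, dose_regimen(s$route, s$dose),
                    duration = 72, cyp2c19_amount = cyp2c19_amount,
                    extra_times = sampling))
    prof <- profile_frame(sim)
    prof <- prof[prof$time_h %in% sampling, ]
    pk <- nca(prof, dose = s$dose, body_weight = s$phys$body_weight,
              route = s$route)
    # clearance on the L/h scale of the published evaluation tables
    data.frame(label = nm,
               parameter = c("cmax", "auc_0_inf", "cl"),
               value = c(pk$cmax, pk$auc_0_inf, pk$clearance_L_h))
  }))
  ref <- clinical_reference_values("all")
  keys_pred <- paste(pred$label, pred$parameter)
  ref <- ref[paste(ref$label, ref$parameter) %in% keys_pred, ]
  obs <- data.frame(label = ref$label, parameter = ref$parameter,
                    value = ref$observed)
  pre <- pred[match(paste(ref$label, ref$parameter), keys_pred), ]
  ev <- evaluation_table(obs, pre[, c("label", "parameter", "value")])
  out <- list(predicted = pred, evaluation = ev, seed = seed,
              cyp2c19_amount = as.numeric(cyp2c19_amount))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(predicted = file.path(output_dir, "predicted_pk.csv"),
               evaluation = file.path(output_dir, "evaluation.csv"),
               summary = file.path(output_dir, "evaluation_summary.csv"))
    utils::write.csv(pred, paths[["predicted"]], row.names = FALSE)
    utils::write.csv(ev$table, paths[["evaluation"]], row.names = FALSE)
    utils::write.csv(ev$summary, paths[["summary"]], row.names = FALSE)
    out$paths <- as.list(paths)
  }
  out
}
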