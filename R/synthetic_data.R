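#' Synthetic clinical study design
#'
#' Describes a pseudo-observed study: population, arm doses, sampling
#' schedule and the multiplicative lognormal residual error emulating
#' digitization plus assay noise.
#'
#' @param label Free-text study label.
#' @param population One of `"healthy"`, `"CP_A"`, `"CP_B"`, `"CP_C"`,
#'   `"CKD_moderate"`, `"CKD_severe"`.
#' @param n_subjects Subjects per dose arm (>= 1).
#' @param route `"iv_bolus"` or `"oral"`.
#' @param doses Vector of positive dose amounts (mg), one arm per dose.
#' @param sampling_times Strictly increasing sampling times (h).
#' @param residual_cv Residual (within-sample) lognormal CV, >= 0.
#' @param iiv Named list of between-subject CVs forwarded to
#'   [population_spec()] `variability`; all-zero gives identical
#'   subjects.
#' @param seed Integer seed.
#' @return A `study_design` object.
#' @export
study_design <- function(label, population = "healthy", n_subjects = 12L,
                         route = c("oral", "iv_bolus"), doses,
                         sampling_times = c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6,
                                            8, 12, 16, 24, 36, 48, 72),
                         residual_cv = 0.2,
                         iiv = list(flows = 0.1, volumes = 0.1,
                                    enzyme = 0.3, gfr = 0.1),
                         seed = 1L) {
  route <- match.arg(route)
  if (!population %in% .disease_labels)
    stop("unknown population: ", population, call. = FALSE)
  if (n_subjects < 1) stop("'n_subjects' must be >= 1", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be > 0 mg", call. = FALSE)
  if (any(diff(sampling_times) <= 0) || any(sampling_times < 0))
    stop("sampling_times must be non-negative and strictly increasing",
         call. = FALSE)
  if (residual_cv < 0) stop("'residual_cv' must be >= 0", call. = FALSE)
  structure(list(label = label, population = population,
                 n_subjects = as.integer(n_subjects), route = route,
                 doses = doses, sampling_times = sampling_times,
                 residual_cv = residual_cv, iiv = iiv,
                 seed = as.integer(seed)),
            class = "study_design")
}

.physiology_for_population <- function(population, base = reference_adult()) {
  switch(population,
         healthy = base,
         CP_A = apply_disease(base, disease_spec("cirrhosis", "CP_A")),
         CP_B = apply_disease(base, disease_spec("cirrhosis", "CP_B")),
         CP_C = apply_disease(base, disease_spec("cirrhosis", "CP_C")),
         CKD_moderate = apply_disease(base, disease_spec("ckd", "moderate")),
         CKD_severe = apply_disease(base, disease_spec("ckd", "severe")),
         stop("unknown population: ", population, call. = FALSE))
}

#' Generate pseudo-observed concentration-time profiles
#'
#' Stands in for digitized clinical profiles: for every dose arm it
#' samples `n_subjects` physiologies (at the design's between-subject
#' CVs) from the design's population, simulates each subject, samples
#' the profile at the design's schedule and multiplies each sample by a
#' median-1 lognormal residual (CV = `residual_cv`). Values below the
#' lower limit of quantification are censored to `NA`.
#'
#' @param design A [study_design()].
#' @param drug A [drug_parameters()] object.
#' @param base_phys Healthy template physiology the design's population
#'   transformation starts from.
#' @param cyp2c19_amount Calibrated hepatic CYP2C19 amount (umol).
#' @param lloq Lower limit of quantification (ug/ml); default 0.01.
#' @param duration Simulation length (h); defaults to the last sampling
#'   time.
#' @return data.frame with columns `subject_id`, `dose_mg`, `time_h`,
#'   `conc_ug_per_ml` (NA where censored); the design is attached as
#'   attribute `design`.
#' @export
generate_observed <- function(design, drug, base_phys = reference_adult(),
                              cyp2c19_amount = 1, lloq = 0.01,
                              duration = max(design$sampling_times)) {
  stopifnot(inherits(design, "study_design"),
            inherits(drug, "drug_parameters"))
  pop_base <- .physiology_for_population(design$population, base_phys)
  rows <- list()
  sdlog <- sqrt(log(1 + design$residual_cv^2))
  for (di in seq_along(design$doses)) {
    dose <- design$doses[di]
    spec <- population_spec(design$n_subjects,
                            weight_range = c(70, 80),
                            variability = design$iiv,
                            seed = design$seed + 1000L * di)
    pop <- sample_population(spec, pop_base)
    regimen <- dose_regimen(design$route, dose)
    for (si in seq_along(pop)) {
      sim <- suppressWarnings(
        simulate_pbpk(drug, pop[[si]], regimen, duration,
                      cyp2c19_amount = cyp2c19_amount,
                      extra_times = design$sampling_times))
      conc <- stats::approx(sim$time, sim$conc,
                            xout = design$sampling_times)$y
      set.seed(design$seed + 1000L * di + si)
      noise <- if (design$residual_cv > 0)
        exp(stats::rnorm(length(conc), 0, sdlog)) else 1
      conc <- conc * noise
      conc[conc < lloq] <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("d%g_s%02d", dose, si),
        dose_mg = dose,
        time_h = design$sampling_times,
        conc_ug_per_ml = conc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}

#' Ready-made study designs mirroring the published evaluation studies
#'
#' The bundled set covers: a healthy 100 mg IV bolus study; healthy oral
#' once-daily studies at 10, 50, 75, 100 and 200 mg; a healthy oral
#' dose-escalation arm set (10, 20, 40, 80, 150, 300, 600, 1000,
#' 1400 mg); Child-Pugh A/B/C oral 100 mg; and CKD (moderate and severe)
#' oral 200 mg. Sampling 0-72 h.
#'
#' @return Named list of `study_design` objects.
#' @export
bundled_designs <- function() {
  list(
    healthy_iv_100 = study_design("healthy IV 100 mg", "healthy",
                                  n_subjects = 25L, route = "iv_bolus",
                                  doses = 100, seed = 101L,
                                  # bolus studies draw the first sample at
                                  # 5 min, during the distribution phase
                                  sampling_times = c(5 / 60, 10 / 60, 0.25,
                                                     0.5, 1, 1.5, 2, 3, 4, 6,
                                                     8, 12, 16, 24, 36, 48,
                                                     72)),
    healthy_oral_low = study_design("healthy oral 10-100 mg", "healthy",
                                    n_subjects = 25L, route = "oral",
                                    doses = c(10, 50, 75, 100), seed = 102L),
    healthy_oral_200 = study_design("healthy oral 200 mg", "healthy",
                                    n_subjects = 14L, route = "oral",
                                    doses = 200, seed = 103L),
    healthy_oral_escalation = study_design(
      "healthy oral dose escalation", "healthy", n_subjects = 35L,
      route = "oral",
      doses = c(10, 20, 40, 80, 150, 300, 600, 1000, 1400), seed = 104L),
    cirrhosis_cp_a = study_design("CP-A oral 100 mg", "CP_A",
                                  n_subjects = 9L, doses = 100, seed = 105L),
    cirrhosis_cp_b = study_design("CP-B oral 100 mg", "CP_B",
                                  n_subjects = 9L, doses = 100, seed = 106L),
    cirrhosis_cp_c = study_design("CP-C oral 100 mg", "CP_C",
                                  n_subjects = 8L, doses = 100, seed = 107L),
    ckd_moderate = study_design("CKD moderate oral 200 mg", "CKD_moderate",
                                n_subjects = 9L, doses = 200, seed = 108L),
    ckd_severe = study_design("CKD severe oral 200 mg", "CKD_severe",
                              n_subjects = 9L, doses = 200, seed = 109L))
}
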