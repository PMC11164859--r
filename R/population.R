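#' Virtual population specification
#'
#' @param n Number of individuals (>= 1).
#' @param age_range,weight_range Two-element numeric intervals (years, kg).
#' @param sex_ratio Fraction of males in (0, 1).
#' @param variability Named list of lognormal coefficients of variation
#'   applied as median-preserving multiplicative perturbations. Recognized
#'   names: `flows`, `volumes`, `enzyme`, `gfr`. CVs must be >= 0.
#' @param seed Integer seed; sampling is fully reproducible.
#' @return A `population_spec` object.
#' @export
population_spec <- function(n, age_range = c(18, 55),
                            weight_range = c(70, 80), sex_ratio = 0.5,
                            variability = list(flows = 0.10, volumes = 0.10,
                                               enzyme = 0.35, gfr = 0.10),
                            seed = 1L) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  for (r in list(age_range, weight_range))
    if (length(r) != 2L || r[2L] <= r[1L])
      stop("ranges must be non-degenerate intervals", call. = FALSE)
  bad <- setdiff(names(variability), c("flows", "volumes", "enzyme", "gfr"))
  if (length(bad)) stop("unknown variability component(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(unlist(variability) < 0)) stop("CVs must be >= 0", call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("'sex_ratio' must lie in [0, 1]", call. = FALSE)
  structure(list(n = as.integer(n), age_range = age_range,
                 weight_range = weight_range, sex_ratio = sex_ratio,
                 variability = variability, seed = as.integer(seed)),
            class = "population_spec")
}

# median-preserving lognormal multiplier(s)
.lognormal_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog))
}

#' Sample a virtual population of physiologies
#'
#' Draws `spec$n` individuals: weight uniform over the weight range, age
#' uniform over the age range, sex Bernoulli at `sex_ratio`; organ
#' volumes and flows scale linearly with weight (via
#' [reference_adult()]), then receive independent median-preserving
#' lognormal perturbations at the configured CVs (flows renormalized only
#' through the stored cardiac-output sum, which is recomputed, so the
#' flow-balance invariants hold by construction). The hepatic enzyme
#' scale and GFR get their own lognormal factors.
#'
#' @param spec A [population_spec()].
#' @param base Template `physiology_set`; disease labels are preserved,
#'   i.e. you may sample a Child-Pugh or CKD population from a
#'   transformed base.
#' @return List of `physiology_set` objects, with per-individual
#'   `enzyme_mult` retained in each element.
#' @export
sample_population <- function(spec, base = reference_adult()) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(base, "physiology_set"))
  cv <- function(nm) if (is.null(spec$variability[[nm]])) 0
                     else spec$variability[[nm]]
  set.seed(spec$seed)
  weights <- stats::runif(spec$n, spec$weight_range[1L], spec$weight_range[2L])
  ages <- stats::runif(spec$n, spec$age_range[1L], spec$age_range[2L])
  sexes <- ifelse(stats::runif(spec$n) < spec$sex_ratio, "male", "female")
  out <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    w <- weights[i] / base$body_weight
    phys <- base
    phys$body_weight <- weights[i]
    phys$organ_volumes <- base$organ_volumes * w *
      .lognormal_mult(length(base$organ_volumes), cv("volumes"))
    q <- base$organ_blood_flows * w *
      .lognormal_mult(length(base$organ_blood_flows), cv("flows"))
    phys$organ_blood_flows <- q
    phys$cardiac_output <- sum(q)
    phys$liver_total_flow <- q[["liver"]] + q[["gut"]] + q[["spleen"]]
    phys$hepatic_enzyme_scale <- base$hepatic_enzyme_scale *
      .lognormal_mult(1, cv("enzyme"))
    phys$gfr <- base$gfr * .lognormal_mult(1, cv("gfr"))
    phys$sex <- sexes[i]
    phys$age <- ages[i]
    phys$enzyme_mult <- phys$hepatic_enzyme_scale / base$hepatic_enzyme_scale
    validate_physiology(phys)
    out[[i]] <- phys
  }
  out
}

#' Simulate a virtual population on a common time grid
#'
#' @param drug,regimen,duration,cyp2c19_amount,dt,... Passed to
#'   [simulate_pbpk()] for each individual.
#' @param population List of `physiology_set` objects (from
#'   [sample_population()]).
#' @return List of `pbpk_sim` objects sharing one time grid.
#' @export
simulate_population <- function(drug, population, regimen, duration = 72,
                                cyp2c19_amount = 1, dt = 0.1, ...) {
  lapply(population, function(phys)
    suppressWarnings(
      simulate_pbpk(drug, phys, regimen, duration,
                    cyp2c19_amount = cyp2c19_amount, dt = dt, ...)))
}

#' Visual-predictive-check summary bands
#'
#' Pointwise arithmetic mean, empirical 5th and 95th percentiles
#' (type-7 linear interpolation between order statistics, the common
#' plotting convention), minimum and maximum over a set of simulated
#' profiles sharing a time grid.
#'
#' @param profiles Non-empty list of `pbpk_sim` objects (or data.frames
#'   with `time_h`/`conc_ug_per_ml`) on identical grids.
#' @return A `vpc_summary` data.frame: `time_h`, `mean`, `p5`, `p95`,
#'   `min`, `max` (ug/ml).
#' @export
vpc_summary <- function(profiles) {
  if (!length(profiles)) stop("empty profile list", call. = FALSE)
  as_prof <- function(p) if (inherits(p, "pbpk_sim")) profile_frame(p) else p
  profs <- lapply(profiles, as_prof)
  t0 <- profs[[1L]]$time_h
  for (p in profs)
    if (length(p$time_h) != length(t0) || any(p$time_h != t0))
      stop("profiles must share one time grid", call. = FALSE)
  cm <- vapply(profs, function(p) p$conc_ug_per_ml,
               numeric(length(t0)))
  cm <- matrix(cm, nrow = length(t0))
  qs <- t(apply(cm, 1L, stats::quantile, probs = c(0.05, 0.95),
                type = 7, names = FALSE))
  out <- data.frame(time_h = t0,
                    mean = rowMeans(cm),
                    p5 = qs[, 1L], p95 = qs[, 2L],
                    min = apply(cm, 1L, min),
                    max = apply(cm, 1L, max))
  class(out) <- c("vpc_summary", "data.frame")
  out
}
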