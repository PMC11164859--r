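test_that("noise-free single subject equals the deterministic simulation", {
  amt <- fixture_cyp_amount()
  design <- study_design("noise-free", "healthy", n_subjects = 1L,
                         route = "oral", doses = 100,
                         residual_cv = 0,
                         iiv = list(flows = 0, volumes = 0, enzyme = 0,
                                    gfr = 0),
                         seed = 3L)
  obs <- generate_observed(design, fixture_drug(), cyp2c19_amount = amt)
  # weight is sampled uniformly in [70, 80]; rebuild that individual
  spec <- population_spec(1, weight_range = c(70, 80),
                          variability = design$iiv, seed = design$seed + 1000L)
  indiv <- sample_population(spec)[[1]]
  sim <- suppressWarnings(
    simulate_pbpk(fixture_drug(), indiv, dose_regimen("oral", 100),
                  duration = max(design$sampling_times),
                  cyp2c19_amount = amt,
                  extra_times = design$sampling_times))
  expected <- approx(sim$time, sim$conc, design$sampling_times)$y
  expected[expected < 0.01] <- NA
  expect_equal(obs$conc_ug_per_ml, expected, tolerance = 1e-10)
})

test_that("generation is seed-reproducible", {
  amt <- fixture_cyp_amount()
  design <- study_design("repro", "healthy", n_subjects = 3L,
                         route = "oral", doses = 50, seed = 9L,
                         sampling_times = c(0.5, 1, 2, 4, 8, 12, 24))
  a <- generate_observed(design, fixture_drug(), cyp2c19_amount = amt)
  b <- generate_observed(design, fixture_drug(), cyp2c19_amount = amt)
  expect_identical(a, b)
})

test_that("residual CV is recovered empirically at n = 100", {
  amt <- fixture_cyp_amount()
  # between-subject variability off so the spread is purely residual
  design <- study_design("cv-recovery", "healthy", n_subjects = 100L,
                         route = "oral", doses = 100,
                         sampling_times = c(2, 4, 8),
                         residual_cv = 0.2,
                         iiv = list(flows = 0, volumes = 0, enzyme = 0,
                                    gfr = 0),
                         seed = 17L)
  # identical weights remove the last between-subject difference
  obs <- generate_observed(design, fixture_drug(),
                           cyp2c19_amount = amt)
  at4 <- obs$conc_ug_per_ml[obs$time_h == 4]
  # subjects share physiology up to sampled weight; normalize per-subject
  # deterministic signal out using the noise-free design
  nf <- design; nf$residual_cv <- 0
  base <- generate_observed(nf, fixture_drug(), cyp2c19_amount = amt)
  ratio <- at4 / base$conc_ug_per_ml[base$time_h == 4]
  cv <- sd(ratio) / mean(ratio)
  expect_gt(cv, 0.15); expect_lt(cv, 0.25)
})

test_that("bundled designs mirror the published study set and validate", {
  designs <- bundled_designs()
  expect_true(any(vapply(designs, function(d)
    identical(d$doses, c(10, 20, 40, 80, 150, 300, 600, 1000, 1400)),
    logical(1))))
  ckd <- designs[grepl("ckd", names(designs))]
  expect_true(all(vapply(ckd, function(d)
    identical(d$doses, 200) && d$route == "oral", logical(1))))
  expect_true(any(vapply(designs, function(d)
    d$route == "iv_bolus" && identical(d$doses, 100), logical(1))))
  for (d in designs) {
    expect_s3_class(d, "study_design")
    expect_true(all(diff(d$sampling_times) > 0))
    expect_gte(d$residual_cv, 0)
  }
})

test_that("self-evaluation loop on noise-free data gives AFE of 1", {
  amt <- fixture_cyp_amount()
  design <- study_design("self-eval", "healthy", n_subjects = 1L,
                         route = "oral", doses = c(50, 100),
                         residual_cv = 0,
                         iiv = list(flows = 0, volumes = 0, enzyme = 0,
                                    gfr = 0),
                         seed = 23L)
  obs <- generate_observed(design, fixture_drug(), cyp2c19_amount = amt,
                           lloq = 0)
  rows <- list()
  for (dose in design$doses) {
    sub <- obs[obs$dose_mg == dose, ]
    pk_obs <- nca(sub[, c("time_h", "conc_ug_per_ml")], dose,
                  route = "oral")
    spec <- population_spec(1, weight_range = c(70, 80),
                            variability = design$iiv,
                            seed = design$seed +
                              1000L * which(design$doses == dose))
    indiv <- sample_population(spec)[[1]]
    sim <- suppressWarnings(
      simulate_pbpk(fixture_drug(), indiv, dose_regimen("oral", dose),
                    duration = max(design$sampling_times),
                    cyp2c19_amount = amt,
                    extra_times = design$sampling_times))
    prof <- profile_frame(sim)
    prof <- prof[prof$time_h %in% design$sampling_times, ]
    pk_pre <- nca(prof, dose, route = "oral")
    rows[[length(rows) + 1L]] <-
      ratio_obs_pre(pk_obs$auc_0_inf, pk_pre$auc_0_inf)
  }
  expect_equal(afe(unlist(rows)), 1, tolerance = 1e-6)
})
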