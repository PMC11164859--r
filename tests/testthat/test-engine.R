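test_that("null dose yields an identically zero profile", {
  sim <- suppressWarnings(
    simulate_pbpk(fixture_drug(), fixture_phys(),
                  dose_regimen("iv_bolus", 0), 12))
  expect_true(all(sim$conc == 0))
  expect_true(all(sim$amounts == 0))
})

test_that("mass balance holds to well below 0.1% for IV and oral", {
  drug <- fixture_drug(); phys <- fixture_phys()
  for (reg in list(dose_regimen("iv_bolus", 100),
                   dose_regimen("oral", 100),
                   dose_regimen("oral", 50, n_doses = 3, interval = 12),
                   dose_regimen("iv_bolus", 100, infusion_duration = 0.5))) {
    sim <- suppressWarnings(simulate_pbpk(drug, phys, reg, 48,
                                          cyp2c19_amount = 5))
    expect_lt(max(abs(mass_balance_error(sim))), 1e-3,
              label = paste("mass balance,", reg$route,
                            reg$n_doses, "doses"))
  }
})

test_that("one-compartment collapse matches the closed form to 0.1%", {
  # All Kp = 1, B:P = 1, linear renal-only clearance: the whole body acts
  # as one well-mixed volume V = sum of all compartments, so
  # C(t) = (D/V) exp(-CL t / V) after mixing.
  drug <- drug_parameters(molecular_weight = 212.29, pka = -10, log_p = -10,
                          solubility = 850, fu = 1,
                          intestinal_permeability = 3.36e-6,
                          km_cyp2c19 = 1e9, kcat_cyp2c19 = 1e-9,
                          renal_clearance = 0.02, blood_plasma_ratio = 1,
                          ka_ap = 0)
  phys <- fixture_phys()
  sim <- suppressWarnings(
    simulate_pbpk(drug, phys, dose_regimen("iv_bolus", 100), 48,
                  cyp2c19_amount = 0))
  organs <- setdiff(names(phys$organ_volumes),
                    c("arterial_blood", "venous_blood"))
  v_eff <- sum(phys$organ_volumes[organs] * sim$kp[organs]) +
    phys$organ_volumes[["arterial_blood"]] +
    phys$organ_volumes[["venous_blood"]]
  # elimination is perfusion-limited in the kidney, so the collapsed
  # system clears at CL Q / (Q + CL) (closed-form well-stirred algebra)
  cl_raw <- drug$renal_clearance * phys$body_weight * 60 / 1000  # L/h
  q_kid <- phys$organ_blood_flows[["kidney"]]
  cl <- cl_raw * q_kid / (q_kid + cl_raw)
  dose_umol <- 100 * 1000 / drug$molecular_weight
  # compare after the mixing phase (several organ time constants)
  sel <- sim$time >= 3
  pred_uM <- dose_umol / v_eff * exp(-cl * sim$time[sel] / v_eff)
  pred <- concentration_units(pred_uM, "uM_to_ug_ml", drug$molecular_weight)
  expect_lt(max(abs(sim$conc[sel] - pred) / pred), 1e-3)
})

test_that("halving solver tolerances leaves Cmax and AUC within 0.1%", {
  drug <- fixture_drug(); phys <- fixture_phys()
  reg <- dose_regimen("oral", 100)
  s1 <- suppressWarnings(simulate_pbpk(drug, phys, reg, 48,
                                       cyp2c19_amount = 5))
  s2 <- suppressWarnings(simulate_pbpk(drug, phys, reg, 48,
                                       cyp2c19_amount = 5,
                                       rtol = 5e-9, atol = 5e-11))
  pk1 <- nca(profile_frame(s1), 100, 73, "oral")
  pk2 <- nca(profile_frame(s2), 100, 73, "oral")
  expect_lt(abs(pk1$cmax - pk2$cmax) / pk2$cmax, 1e-3)
  expect_lt(abs(pk1$auc_0_t - pk2$auc_0_t) / pk2$auc_0_t, 1e-3)
})

test_that("dose linearity below Km and saturation above it", {
  drug <- fixture_drug(); phys <- fixture_phys()
  amt <- fixture_cyp_amount()
  auc_norm <- function(dose) {
    sim <- suppressWarnings(simulate_pbpk(drug, phys,
                                          dose_regimen("oral", dose), 72,
                                          cyp2c19_amount = amt))
    pk <- nca(profile_frame(sim), dose, 73, "oral")
    pk$auc_0_inf / dose
  }
  a10 <- auc_norm(10); a20 <- auc_norm(20); a1400 <- auc_norm(1400)
  expect_lt(abs(a20 / a10 - 1), 0.02)   # linear regime
  expect_gt(a1400, a10)                 # saturation raises normalized AUC
})

test_that("widely separated doses superpose to twice the single-dose AUC", {
  drug <- fixture_drug(); phys <- fixture_phys()
  amt <- fixture_cyp_amount()
  s1 <- suppressWarnings(simulate_pbpk(drug, phys, dose_regimen("oral", 10),
                                       duration = 120, cyp2c19_amount = amt))
  s2 <- suppressWarnings(simulate_pbpk(drug, phys,
                                       dose_regimen("oral", 10, n_doses = 2,
                                                    interval = 120),
                                       duration = 240,
                                       cyp2c19_amount = amt))
  auc1 <- nca(profile_frame(s1), 10, 73, "oral")$auc_0_inf
  auc2 <- nca(profile_frame(s2), 20, 73, "oral")$auc_0_inf
  expect_lt(abs(auc2 / (2 * auc1) - 1), 0.01)
})

test_that("calibration hits the clearance target and is monotone", {
  drug <- fixture_drug(); phys <- fixture_phys()
  amt <- fixture_cyp_amount()
  expect_lt(abs(attr(amt, "achieved_cl") - 3.4) / 3.4, 0.01)
  amt2 <- calibrate_hepatic_activity(drug, phys, target_plasma_cl = 5)
  expect_gt(as.numeric(amt2), as.numeric(amt))
  # renal-only target collapses the enzyme amount to zero
  amt0 <- calibrate_hepatic_activity(drug, phys, target_plasma_cl = 0.1)
  expect_identical(as.numeric(amt0), 0)
})

test_that("calibrated activity agrees with the well-stirred algebra", {
  # In the linear regime the liver behaves as a well-stirred organ:
  # CL_h,blood = Q fu_b CLint / (Q + fu_b CLint) with fu_b = fu / B:P and
  # CLint = Vmax / Km. Plasma CL_h = B:P * CL_h,blood.
  drug <- fixture_drug(); phys <- fixture_phys()
  amt <- fixture_cyp_amount()
  fu <- drug$fu
  bp <- blood_plasma_ratio(drug, phys$hematocrit, fu)
  q <- phys$liver_total_flow
  vmax <- drug$kcat_cyp2c19 * 60 * as.numeric(amt)
  clint <- vmax / drug$km_cyp2c19
  cl_h <- bp * q * (fu / bp) * clint / (q + (fu / bp) * clint)
  cl_ren <- fu * drug$renal_clearance * phys$body_weight * 60 / 1000
  # low-dose simulation stays in the linear regime
  sim <- suppressWarnings(simulate_pbpk(drug, phys, dose_regimen("iv_bolus", 1),
                                        96, cyp2c19_amount = amt))
  cl_sim <- nca(profile_frame(sim), 1, 73, "iv_bolus")$clearance_L_h
  expect_lt(abs(cl_sim - (cl_h + cl_ren)) / (cl_h + cl_ren), 0.02)
})

test_that("unattainable clearance target names the flow limit", {
  drug <- fixture_drug(); phys <- fixture_phys()
  expect_error(calibrate_hepatic_activity(drug, phys,
                                          target_plasma_cl = 500,
                                          duration = 24),
               "not attainable")
})

test_that("oral absorption responds to the gut-transit levers", {
  drug <- fixture_drug()
  base <- fixture_phys()
  slow <- base
  slow$gastric_emptying_time <- base$gastric_emptying_time * 4
  reg <- dose_regimen("oral", 100)
  s_fast <- suppressWarnings(simulate_pbpk(drug, base, reg, 24,
                                           cyp2c19_amount = 5))
  s_slow <- suppressWarnings(simulate_pbpk(drug, slow, reg, 24,
                                           cyp2c19_amount = 5))
  tmax <- function(s) s$time[which.max(s$conc)]
  expect_gt(tmax(s_slow), tmax(s_fast))
  # near-complete absorption: little drug reaches feces
  frac_fecal <- s_fast$amounts[nrow(s_fast$amounts), "feces"] /
    max(s_fast$administered)
  expect_lt(unname(frac_fecal), 0.05)
})
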