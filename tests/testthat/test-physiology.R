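test_that("reference adult satisfies flow and volume invariants", {
  phys <- reference_adult(73, "male", 30)
  expect_s3_class(phys, "physiology_set")
  q <- phys$organ_blood_flows
  expect_equal(sum(q), phys$cardiac_output, tolerance = 1e-12)
  expect_equal(phys$liver_total_flow,
               q[["liver"]] + q[["gut"]] + q[["spleen"]], tolerance = 1e-12)
  expect_true(all(phys$organ_volumes > 0))
  expect_gt(phys$hematocrit, 0); expect_lt(phys$hematocrit, 1)
  expect_identical(phys$disease_label, "healthy")
  expect_equal(phys$albumin_scale, 1)
  expect_equal(phys$gfr, 110)
})

test_that("out-of-range demographics are rejected by name", {
  expect_error(reference_adult(30), "body_weight")
  expect_error(reference_adult(160), "body_weight")
  expect_silent(reference_adult(146))
  expect_error(reference_adult(73, age = 10), "age")
})

test_that("body-weight scaling is linear and preserves balance", {
  p1 <- reference_adult(73); p2 <- reference_adult(100)
  expect_equal(p2$organ_volumes / p1$organ_volumes,
               rep(100 / 73, length(p1$organ_volumes)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(p2$cardiac_output, p1$cardiac_output * 100 / 73)
  validate_physiology(p2)
})

test_that("cirrhosis transformation applies the class table and overrides", {
  base <- reference_adult()
  for (sev in c("CP_A", "CP_B", "CP_C")) {
    cp <- apply_disease(base, disease_spec("cirrhosis", sev))
    expect_identical(cp$disease_label, sev)
    validate_physiology(cp)
    expect_lt(cp$albumin_scale, 1)
    expect_lt(cp$hepatic_enzyme_scale, 1)
    expect_lt(cp$liver_total_flow, base$liver_total_flow)
    expect_lt(cp$organ_volumes[["liver"]], base$organ_volumes[["liver"]])
    # perfusion rerouting preserves cardiac output
    expect_equal(cp$cardiac_output, base$cardiac_output, tolerance = 1e-12)
  }
  # published override quintet carried through verbatim
  cp <- apply_disease(base, disease_spec("cirrhosis", "CP_B",
                                         cirrhosis_reported_overrides()))
  expect_equal(cp$albumin_scale, 0.92)
  expect_equal(cp$hematocrit, 0.4205)
})

test_that("enzyme loss is monotone in Child-Pugh class", {
  base <- reference_adult()
  scales <- sapply(c("CP_A", "CP_B", "CP_C"), function(s)
    apply_disease(base, disease_spec("cirrhosis", s))$hepatic_enzyme_scale)
  expect_true(all(diff(scales) <= 0))
})

test_that("CKD transformation sets published GFR values", {
  base <- reference_adult()
  mod <- apply_disease(base, disease_spec("ckd", "moderate"))
  sev <- apply_disease(base, disease_spec("ckd", "severe"))
  expect_equal(mod$gfr, 45)
  expect_equal(sev$gfr, 20)
  expect_identical(mod$disease_label, "CKD_moderate")
  expect_gt(mod$gastric_emptying_time, base$gastric_emptying_time)
  expect_gt(sev$small_intestinal_transit_time,
            mod$small_intestinal_transit_time)
  validate_physiology(mod); validate_physiology(sev)
})

test_that("disease transformations are pure and guard their inputs", {
  base <- reference_adult()
  a <- apply_disease(base, disease_spec("cirrhosis", "CP_C"))
  b <- apply_disease(base, disease_spec("cirrhosis", "CP_C"))
  expect_identical(a, b)
  expect_identical(base$disease_label, "healthy")  # input untouched
  expect_error(apply_disease(a, disease_spec("ckd", "severe")),
               "healthy")
  expect_error(disease_spec("cirrhosis", "moderate"), "severity")
  expect_error(disease_spec("ckd", "CP_A"), "severity")
  expect_error(apply_disease(base, disease_spec("ckd", "severe",
                                                list(gfr_wrong = 1))),
               "unknown parameter")
})

test_that("disease with identity overrides reproduces healthy simulation", {
  base <- reference_adult()
  spec <- disease_spec("ckd", "moderate",
                       list(gfr = base$gfr, hematocrit = base$hematocrit,
                            albumin_scale = 1, gastric_emptying_scale = 1,
                            small_intestinal_transit_scale = 1))
  ident <- apply_disease(base, spec)
  drug <- fixture_drug()
  reg <- dose_regimen("oral", 50)
  s1 <- suppressWarnings(simulate_pbpk(drug, base, reg, 24,
                                       cyp2c19_amount = 2))
  s2 <- suppressWarnings(simulate_pbpk(drug, ident, reg, 24,
                                       cyp2c19_amount = 2))
  expect_equal(s2$conc, s1$conc, tolerance = 1e-12)
})

test_that("renal clearance scales exactly with GFR", {
  base <- reference_adult()
  drug <- fixture_drug()
  # the engine's renal clearance parameter is proportional to GFR
  cl_ren <- function(phys) drug$renal_clearance * phys$body_weight *
    60 / 1000 * phys$gfr / phys$gfr_healthy
  sev <- apply_disease(base, disease_spec("ckd", "severe"))
  expect_equal(cl_ren(sev) / cl_ren(base), sev$gfr / base$gfr,
               tolerance = 1e-15)
  # and the simulated urine output follows in the linear regime
  reg <- dose_regimen("iv_bolus", 10)
  s_h <- suppressWarnings(simulate_pbpk(drug, base, reg, 24,
                                        cyp2c19_amount = 0))
  spec_gfr_only <- disease_spec("ckd", "severe",
                                list(hematocrit = base$hematocrit,
                                     albumin_scale = 1,
                                     gastric_emptying_scale = 1,
                                     small_intestinal_transit_scale = 1))
  s_d <- suppressWarnings(simulate_pbpk(drug, apply_disease(base, spec_gfr_only),
                                        reg, 24, cyp2c19_amount = 0))
  # early-time urine ratio approaches the GFR ratio
  i <- which.min(abs(s_h$time - 2))
  expect_equal(unname(s_d$amounts[i, "urine"] / s_h$amounts[i, "urine"]),
               20 / 110, tolerance = 0.02)
})
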