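# Shared fixtures. Calibration is deterministic; memoize it so the suite
# pays for it once.
.fixture_env <- new.env(parent = emptyenv())

fixture_drug <- function() brivaracetam()
fixture_phys <- function() reference_adult()

fixture_cyp_amount <- function() {
  if (is.null(.fixture_env$amount))
    .fixture_env$amount <- calibrate_hepatic_activity(fixture_drug(),
                                                      fixture_phys())
  .fixture_env$amount
}

# clinical-style sampling grids used in evaluation-type tests
iv_sampling <- c(5 / 60, 10 / 60, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12,
                 16, 24, 36, 48, 72)
oral_sampling <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24,
                   36, 48, 72)

sample_profile <- function(sim, times) {
  p <- profile_frame(sim)
  data.frame(time_h = times,
             conc_ug_per_ml = approx(p$time_h, p$conc_ug_per_ml, times)$y)
}

# Scalar transcription of the weak-base partitioning equations, written
# step by step as an independent oracle for the vectorized implementation.
scalar_kp_oracle <- function(drug, organ, comp = tissue_composition()) {
  row <- comp[comp$organ == organ, ]
  ph_p <- 7.4; ph_iw <- 7.0; ph_bc <- 7.22
  P <- 10^drug$log_p
  if (organ == "adipose") P_lip <- 10^(1.115 * drug$log_p - 1.35)
  else P_lip <- P
  X <- 1 + 10^(drug$pka - ph_p)
  Y <- 1 + 10^(drug$pka - ph_iw)
  Z <- 1 + 10^(drug$pka - ph_bc)
  if (!is.null(drug$ka_ap)) {
    ka <- drug$ka_ap
  } else {
    bc <- attr(comp, "blood_cells")
    lip_bc <- (P * bc$f_neutral_lipid +
               (0.3 * P + 0.7) * bc$f_neutral_phospholipid) / X
    ka <- (drug$kery - (Z / X) * bc$f_water_intra - lip_bc) * X /
      (bc$acidic_phospholipid * 10^(drug$pka - ph_bc))
    ka <- max(ka, 0)
  }
  water <- row$f_water_extra + (Y / X) * row$f_water_intra
  ap <- ka * row$acidic_phospholipid * 10^(drug$pka - ph_iw) / X
  lipid <- (P_lip * row$f_neutral_lipid +
            (0.3 * P_lip + 0.7) * row$f_neutral_phospholipid) / X
  (water + ap + lipid) * drug$fu
}
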