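#' Drug-specific parameter set
#'
#' Bundles the physicochemical and ADME constants the PBPK engine needs:
#' molecular weight, ionization (a single basic pKa), lipophilicity,
#' aqueous solubility, plasma protein binding, intestinal permeability,
#' CYP2C19 Michaelis-Menten constants and renal clearance.
#'
#' @param molecular_weight Molecular weight (g/mol).
#' @param pka Basic dissociation constant (monoprotic weak base).
#' @param log_p Octanol:water log partition coefficient.
#' @param solubility Aqueous solubility (mg/ml).
#' @param fu Fraction unbound in plasma, in (0, 1].
#' @param binding_protein Plasma binding protein, `"albumin"` or `"AGP"`.
#' @param intestinal_permeability Specific intestinal permeability (cm/min).
#' @param km_cyp2c19 CYP2C19 Michaelis constant (uM).
#' @param kcat_cyp2c19 CYP2C19 catalytic turnover (1/min).
#' @param renal_clearance Renal plasma clearance referenced to unbound
#'   drug (ml/min/kg body weight).
#' @param blood_plasma_ratio Blood:plasma concentration ratio. If `NULL`
#'   (default) it is computed from hematocrit and `fu` at simulation time as
#'   `1 - hct + hct * fu * kery` with an erythrocyte:plasma-water partition
#'   `kery`.
#' @param kery Erythrocyte:unbound-plasma partition coefficient used when
#'   `blood_plasma_ratio` is derived; default 1.
#' @param ka_ap Association constant of the ionized base to tissue acidic
#'   phospholipids. `NULL` (default) back-calculates it from `kery` the
#'   way the partitioning method does from measured erythrocyte data; set
#'   it explicitly (e.g. 0) when erythrocyte partitioning is itself an
#'   assumption rather than a measurement.
#' @return An object of class `drug_parameters`.
#' @export
drug_parameters <- function(molecular_weight, pka, log_p, solubility, fu,
                            binding_protein = c("albumin", "AGP"),
                            intestinal_permeability,
                            km_cyp2c19, kcat_cyp2c19, renal_clearance,
                            blood_plasma_ratio = NULL, kery = 1,
                            ka_ap = NULL) {
  binding_protein <- match.arg(binding_protein)
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  chk_pos(molecular_weight, "molecular_weight")
  chk_pos(solubility, "solubility")
  chk_pos(intestinal_permeability, "intestinal_permeability")
  chk_pos(km_cyp2c19, "km_cyp2c19")
  chk_pos(kcat_cyp2c19, "kcat_cyp2c19")
  chk_pos(renal_clearance, "renal_clearance")
  chk_pos(kery, "kery")
  if (!is.numeric(fu) || fu <= 0 || fu > 1)
    stop("'fu' must lie in (0, 1]", call. = FALSE)
  if (!is.null(blood_plasma_ratio)) chk_pos(blood_plasma_ratio, "blood_plasma_ratio")
  if (!is.null(ka_ap) && (!is.numeric(ka_ap) || ka_ap < 0))
    stop("'ka_ap' must be >= 0 when given", call. = FALSE)
  structure(
    list(molecular_weight = molecular_weight, pka = pka, log_p = log_p,
         solubility = solubility, fu = fu, binding_protein = binding_protein,
         intestinal_permeability = intestinal_permeability,
         km_cyp2c19 = km_cyp2c19, kcat_cyp2c19 = kcat_cyp2c19,
         renal_clearance = renal_clearance,
         blood_plasma_ratio = blood_plasma_ratio, kery = kery,
         ka_ap = ka_ap),
    class = "drug_parameters")
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("<drug_parameters>\n")
  cat(sprintf("  MW %.2f g/mol, pKa %.2f (base), logP %.2f, fu %.2f (%s)\n",
              x$molecular_weight, x$pka, x$log_p, x$fu, x$binding_protein))
  cat(sprintf("  CYP2C19: Km %.2f uM, kcat %.2f /min; renal CL %.3f ml/min/kg\n",
              x$km_cyp2c19, x$kcat_cyp2c19, x$renal_clearance))
  invisible(x)
}

#' Brivaracetam default drug parameters
#'
#' The published brivaracetam parameter set used throughout the package:
#' MW 212.29 g/mol, pKa 7.07, logP 1.04, solubility 850 mg/ml, fu 0.61
#' (the value integrated in the reference model; the literature range is
#' 0.79-0.83), intestinal permeability 3.36e-6 cm/min, CYP2C19 Km 71.20 uM
#' and kcat 0.81 /min, renal clearance 0.06 ml/min/kg. Loaded from the
#' shipped `brivaracetam.json` config.
#'
#' @return A `drug_parameters` object.
#' @export
brivaracetam <- function() {
  read_drug_config(system.file("extdata", "brivaracetam.json",
                               package = "brvpbpk", mustWork = TRUE))
}

#' Tissue composition constants for Rodgers-Rowland partitioning
#'
#' Fractional tissue water, neutral lipid and neutral phospholipid
#' contents plus acidic phospholipid concentrations, compiled from the
#' standard published composition tables of the Rodgers-Rowland
#' partitioning literature. Rows cover every perfused organ of the model;
#' the `rest` compartment carries muscle-like average values. Blood cell
#' composition and compartment pH values are attached as attributes.
#'
#' @return A data.frame with columns `organ`, `f_water_extra`,
#'   `f_water_intra`, `f_neutral_lipid`, `f_neutral_phospholipid`,
#'   `acidic_phospholipid` (mg/g); attributes `blood_cells` (named list),
#'   `ph_plasma`, `ph_intracellular`, `ph_blood_cells`.
#' @export
tissue_composition <- function() {
  comp <- data.frame(
    organ = c("lung", "adipose", "bone", "brain", "gut", "heart", "kidney",
              "liver", "muscle", "skin", "spleen", "rest"),
    f_water_extra = c(0.336, 0.135, 0.100, 0.162, 0.282, 0.320, 0.273,
                      0.161, 0.118, 0.382, 0.207, 0.150),
    f_water_intra = c(0.446, 0.017, 0.346, 0.620, 0.475, 0.456, 0.483,
                      0.573, 0.630, 0.291, 0.579, 0.600),
    f_neutral_lipid = c(0.022, 0.853, 0.017, 0.039, 0.038, 0.014, 0.012,
                        0.014, 0.010, 0.060, 0.0077, 0.017),
    f_neutral_phospholipid = c(0.0128, 0.0016, 0.0017, 0.0015, 0.0125,
                               0.0111, 0.0242, 0.0240, 0.0072, 0.0044,
                               0.0113, 0.0090),
    acidic_phospholipid = c(3.91, 0.40, 0.67, 0.40, 2.41, 2.25, 5.03,
                            4.56, 1.53, 1.32, 3.18, 2.00),
    stringsAsFactors = FALSE)
  attr(comp, "blood_cells") <- list(f_water_intra = 0.603,
                                    f_neutral_lipid = 0.0017,
                                    f_neutral_phospholipid = 0.0029,
                                    acidic_phospholipid = 0.5)
  attr(comp, "ph_plasma") <- 7.4
  attr(comp, "ph_intracellular") <- 7.0
  attr(comp, "ph_blood_cells") <- 7.22
  comp
}

#' Tissue:plasma partition coefficients (Rodgers-Rowland weak base)
#'
#' Computes per-organ tissue:plasma partition coefficients for a
#' monoprotic weak base using the Rodgers-Rowland equations:
#' Henderson-Hasselbalch ionization at plasma and intracellular pH,
#' partitioning of the neutral species into tissue water, neutral lipid
#' and neutral phospholipid, and electrostatic association of the ionized
#' species with acidic phospholipids. The acidic-phospholipid association
#' constant is `drug$ka_ap` when set, else back-calculated from the
#' erythrocyte:unbound-plasma partition coefficient (`drug$kery`).
#'
#' Returned coefficients are total-tissue : total-plasma (`Kp`), i.e. the
#' unbound-referenced `Kpu` multiplied by `fu`.
#'
#' @param drug A [drug_parameters()] object.
#' @param comp Tissue composition table from [tissue_composition()].
#' @param fu Optional fraction unbound overriding `drug$fu` (used when
#'   disease albumin scaling modifies binding).
#' @param organs Optional character vector restricting the output.
#' @return Named numeric vector of Kp values, one per organ.
#' @export
partition_coefficients <- function(drug, comp = tissue_composition(),
                                   fu = drug$fu, organs = NULL) {
  stopifnot(inherits(drug, "drug_parameters"))
  if (fu <= 0) stop("fu must be > 0 for partitioning", call. = FALSE)
  if (!is.null(organs)) {
    missing <- setdiff(organs, comp$organ)
    if (length(missing))
      stop("tissue composition missing organs: ",
           paste(missing, collapse = ", "), call. = FALSE)
    comp <- comp[match(organs, comp$organ), ]
  }
  ph_p <- attr(comp, "ph_plasma"); ph_iw <- attr(comp, "ph_intracellular")
  ph_bc <- attr(comp, "ph_blood_cells"); bc <- attr(comp, "blood_cells")
  P <- 10^drug$log_p
  ion_p <- 1 + 10^(drug$pka - ph_p)     # plasma ionization factor
  ion_iw <- 1 + 10^(drug$pka - ph_iw)
  ion_bc <- 1 + 10^(drug$pka - ph_bc)

  # Association constant to acidic phospholipids: taken from the drug
  # record when set, else back-calculated from the erythrocyte partition
  # coefficient (Kpu,BC = kery, unbound-plasma referenced).
  if (!is.null(drug$ka_ap)) {
    ka_ap <- drug$ka_ap
  } else {
    kpu_bc <- drug$kery
    lip_bc <- (P * bc$f_neutral_lipid +
               (0.3 * P + 0.7) * bc$f_neutral_phospholipid) / ion_p
    ka_ap <- (kpu_bc - (ion_bc / ion_p) * bc$f_water_intra - lip_bc) *
      ion_p / (bc$acidic_phospholipid * 10^(drug$pka - ph_bc))
    ka_ap <- max(ka_ap, 0)  # binding cannot be negative
  }

  # Adipose neutral lipid is closer to vegetable oil than to octanol;
  # use the standard olive-oil:water conversion logD_vo = 1.115 logP - 1.35
  # for its lipid term (all other organs use P directly).
  P_org <- rep(P, nrow(comp))
  P_org[comp$organ == "adipose"] <- 10^(1.115 * drug$log_p - 1.35)
  kpu <- comp$f_water_extra +
    (ion_iw / ion_p) * comp$f_water_intra +
    (ka_ap * comp$acidic_phospholipid * 10^(drug$pka - ph_iw)) / ion_p +
    (P_org * comp$f_neutral_lipid +
       (0.3 * P_org + 0.7) * comp$f_neutral_phospholipid) / ion_p
  kp <- kpu * fu
  names(kp) <- comp$organ
  if (any(!is.finite(kp) | kp <= 0))
    stop("non-positive partition coefficient computed", call. = FALSE)
  kp
}

#' Convert between mass and molar concentration units
#'
#' @param value Concentration value (vectorized).
#' @param direction `"uM_to_ug_ml"` or `"ug_ml_to_uM"`.
#' @param mw Molecular weight (g/mol).
#' @return Converted concentration; `ug/ml = uM * mw / 1000`.
#' @export
concentration_units <- function(value,
                                direction = c("uM_to_ug_ml", "ug_ml_to_uM"),
                                mw) {
  direction <- match.arg(direction)
  if (!is.numeric(mw) || mw <= 0) stop("'mw' must be positive", call. = FALSE)
  switch(direction,
         uM_to_ug_ml = value * mw / 1000,
         ug_ml_to_uM = value * 1000 / mw)
}

#' Scale the unbound fraction with disease albumin level
#'
#' Assumes linear binding to a single protein whose concentration scales
#' with the albumin scale factor: the bound:unbound ratio is proportional
#' to protein concentration, giving
#' `fu' = 1 / (1 + scale * (1 - fu) / fu)`.
#'
#' @param fu_healthy Healthy-plasma fraction unbound in (0, 1].
#' @param albumin_scale Disease albumin concentration relative to healthy
#'   (1 = healthy).
#' @return Disease fraction unbound in (0, 1].
#' @export
adjust_fu_for_albumin <- function(fu_healthy, albumin_scale) {
  if (any(fu_healthy <= 0 | fu_healthy > 1))
    stop("'fu_healthy' must lie in (0, 1]", call. = FALSE)
  if (any(albumin_scale < 0))
    stop("'albumin_scale' must be non-negative", call. = FALSE)
  1 / (1 + albumin_scale * (1 - fu_healthy) / fu_healthy)
}

#' Blood:plasma concentration ratio
#'
#' Uses the drug's explicit `blood_plasma_ratio` when set, else derives it
#' from hematocrit assuming erythrocyte:unbound-plasma partitioning `kery`:
#' `B:P = 1 - hct + hct * fu * kery`.
#'
#' @param drug A [drug_parameters()] object.
#' @param hematocrit Hematocrit fraction in (0, 1).
#' @param fu Fraction unbound actually in force (possibly disease-adjusted).
#' @return Scalar blood:plasma ratio.
#' @export
blood_plasma_ratio <- function(drug, hematocrit, fu = drug$fu) {
  if (!is.null(drug$blood_plasma_ratio)) return(drug$blood_plasma_ratio)
  1 - hematocrit + hematocrit * fu * drug$kery
}
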