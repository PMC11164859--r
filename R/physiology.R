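# Reference whole-body physiology for a 73-kg healthy adult.
# Volumes in L; blood flows in L/h of whole blood; cardiac output is the
# sum of all organ inflows. "rest" closes both the mass and the flow
# balance. Values are package constants in the ICRP adult style.
.reference_weight_kg <- 73

.reference_volumes <- c(
  lung = 0.50, adipose = 15.0, bone = 10.5, brain = 1.45, gut = 1.65,
  heart = 0.33, kidney = 0.31, liver = 1.80, muscle = 28.0, skin = 3.30,
  spleen = 0.15, rest = 4.41, arterial_blood = 1.70, venous_blood = 3.90)

.reference_flows <- c(
  adipose = 19.5, bone = 19.5, brain = 46.8, gut = 58.5, heart = 15.6,
  kidney = 74.1, liver = 25.35,  # hepatic artery only; portal adds gut+spleen
  muscle = 66.3, skin = 19.5, spleen = 11.7, rest = 33.15)

.gfr_healthy_default <- 110  # ml/min/1.73 m^2

.disease_labels <- c("healthy", "CP_A", "CP_B", "CP_C",
                     "CKD_moderate", "CKD_severe")

#' Validate a physiology set
#'
#' Checks the structural invariants: all volumes and flows strictly
#' positive, hematocrit in (0, 1), and flow balance — the sum of organ
#' inflows equals cardiac output, and liver inflow equals hepatic artery
#' plus portal (gut + spleen) flow.
#'
#' @param phys A `physiology_set`.
#' @return `phys`, invisibly; errors describe the violated invariant.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "physiology_set"))
  organs <- names(.reference_volumes)
  if (!setequal(names(phys$organ_volumes), organs))
    stop("organ_volumes must cover exactly: ",
         paste(organs, collapse = ", "), call. = FALSE)
  if (any(phys$organ_volumes <= 0)) stop("all organ volumes must be > 0",
                                         call. = FALSE)
  if (any(phys$organ_blood_flows < 0)) stop("blood flows must be >= 0",
                                            call. = FALSE)
  if (phys$hematocrit <= 0 || phys$hematocrit >= 1)
    stop("hematocrit must lie in (0, 1)", call. = FALSE)
  for (f in c("albumin_scale", "gfr", "hepatic_enzyme_scale",
              "gastric_emptying_time", "small_intestinal_transit_time",
              "body_weight"))
    if (phys[[f]] <= 0) stop(sprintf("'%s' must be > 0", f), call. = FALSE)
  if (!phys$disease_label %in% .disease_labels)
    stop("unknown disease_label: ", phys$disease_label, call. = FALSE)
  q <- phys$organ_blood_flows
  co <- phys$cardiac_output
  if (abs(sum(q) - co) > 1e-9 * co)
    stop("organ inflows do not sum to cardiac output", call. = FALSE)
  liver_in <- q[["liver"]] + q[["gut"]] + q[["spleen"]]
  if (abs(phys$liver_total_flow - liver_in) > 1e-9 * liver_in)
    stop("liver inflow must equal hepatic artery + gut + spleen flow",
         call. = FALSE)
  invisible(phys)
}

new_physiology_set <- function(body_weight, organ_volumes, organ_blood_flows,
                               hematocrit, albumin_scale, gfr,
                               hepatic_enzyme_scale, gastric_emptying_time,
                               small_intestinal_transit_time,
                               disease_label = "healthy",
                               gfr_healthy = .gfr_healthy_default) {
  phys <- structure(
    list(body_weight = body_weight,
         organ_volumes = organ_volumes,
         organ_blood_flows = organ_blood_flows,
         cardiac_output = sum(organ_blood_flows),
         liver_total_flow = organ_blood_flows[["liver"]] +
           organ_blood_flows[["gut"]] + organ_blood_flows[["spleen"]],
         hematocrit = hematocrit,
         albumin_scale = albumin_scale,
         gfr = gfr,
         gfr_healthy = gfr_healthy,
         hepatic_enzyme_scale = hepatic_enzyme_scale,
         gastric_emptying_time = gastric_emptying_time,
         small_intestinal_transit_time = small_intestinal_transit_time,
         disease_label = disease_label),
    class = "physiology_set")
  validate_physiology(phys)
  phys
}

#' Reference healthy adult physiology
#'
#' Builds the healthy whole-body physiology: 14 compartments (11 perfused
#' organs plus `rest`, arterial and venous blood; lung in series with
#' cardiac output), hematocrit 0.45, healthy GFR 110 ml/min/1.73 m2,
#' gastric emptying half-time 15 min and small-intestinal transit time
#' 190 min. Volumes and flows scale linearly with body weight relative to
#' the 73-kg reference.
#'
#' @param body_weight Body weight in kg, within \[40, 150\].
#' @param sex `"male"` or `"female"` (recorded; the reference organ table
#'   is sex-agnostic).
#' @param age Age in years, within \[18, 80\].
#' @return A `physiology_set` with `disease_label = "healthy"`.
#' @export
reference_adult <- function(body_weight = 73, sex = c("male", "female"),
                            age = 30) {
  sex <- match.arg(sex)
  if (!is.numeric(body_weight) || body_weight < 40 || body_weight > 150)
    stop("'body_weight' must lie in [40, 150] kg", call. = FALSE)
  if (!is.numeric(age) || age < 18 || age > 80)
    stop("'age' must lie in [18, 80] years", call. = FALSE)
  w <- body_weight / .reference_weight_kg
  phys <- new_physiology_set(
    body_weight = body_weight,
    organ_volumes = .reference_volumes * w,
    organ_blood_flows = .reference_flows * w,
    hematocrit = 0.45,
    albumin_scale = 1,
    gfr = .gfr_healthy_default,
    hepatic_enzyme_scale = 1,
    gastric_emptying_time = 15,
    small_intestinal_transit_time = 190)
  phys$sex <- sex
  phys$age <- age
  phys
}

#' @export
print.physiology_set <- function(x, ...) {
  cat(sprintf("<physiology_set> %s, %.1f kg\n", x$disease_label,
              x$body_weight))
  cat(sprintf("  cardiac output %.1f L/h, hematocrit %.3f, GFR %.1f ml/min/1.73m2\n",
              x$cardiac_output, x$hematocrit, x$gfr))
  cat(sprintf("  albumin scale %.2f, hepatic enzyme scale %.2f\n",
              x$albumin_scale, x$hepatic_enzyme_scale))
  cat(sprintf("  gastric emptying %.0f min, SI transit %.0f min\n",
              x$gastric_emptying_time, x$small_intestinal_transit_time))
  invisible(x)
}

#' Disease specification
#'
#' @param kind `"cirrhosis"` or `"ckd"`.
#' @param severity For cirrhosis one of `"CP_A"`, `"CP_B"`, `"CP_C"`
#'   (Child-Pugh class); for CKD `"moderate"` or `"severe"`.
#' @param overrides Optional named list of physiology parameters that take
#'   precedence over the packaged disease table (e.g.
#'   `list(albumin_scale = 0.92)`).
#' @return A `disease_spec` object.
#' @export
disease_spec <- function(kind = c("cirrhosis", "ckd"), severity,
                         overrides = list()) {
  kind <- match.arg(kind)
  allowed <- if (kind == "cirrhosis") c("CP_A", "CP_B", "CP_C")
             else c("moderate", "severe")
  if (!is.character(severity) || length(severity) != 1L ||
      !severity %in% allowed)
    stop(sprintf("severity for kind '%s' must be one of: %s", kind,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  if (!is.list(overrides)) stop("'overrides' must be a named list",
                                call. = FALSE)
  structure(list(kind = kind, severity = severity, overrides = overrides),
            class = "disease_spec")
}

# Child-Pugh cirrhosis physiology table. Multiplicative scales except
# hematocrit and gfr handling noted per parameter. Defaults compiled from
# the standard cirrhosis-physiology literature; every entry is overridable
# through disease_spec(overrides=).
.cirrhosis_table <- list(
  CP_A = list(albumin_scale = 0.90, hematocrit = 0.41, gfr_scale = 0.90,
              hepatic_flow_scale = 0.85, liver_volume_scale = 0.90,
              hepatic_enzyme_scale = 0.60),
  CP_B = list(albumin_scale = 0.75, hematocrit = 0.37, gfr_scale = 0.70,
              hepatic_flow_scale = 0.65, liver_volume_scale = 0.80,
              hepatic_enzyme_scale = 0.35),
  CP_C = list(albumin_scale = 0.60, hematocrit = 0.34, gfr_scale = 0.45,
              hepatic_flow_scale = 0.50, liver_volume_scale = 0.65,
              hepatic_enzyme_scale = 0.25))

# CKD physiology table: absolute GFR (ml/min/1.73 m^2), absolute
# hematocrit, multiplicative gut-transit prolongations, albumin scale.
.ckd_table <- list(
  moderate = list(gfr = 45, hematocrit = 0.37, albumin_scale = 0.90,
                  gastric_emptying_scale = 1.3,
                  small_intestinal_transit_scale = 1.2),
  severe = list(gfr = 20, hematocrit = 0.33, albumin_scale = 0.80,
                gastric_emptying_scale = 1.6,
                small_intestinal_transit_scale = 1.4))

#' Reported cirrhosis override quintet
#'
#' The published cirrhosis evaluation lists the parameter values 0.92,
#' 0.4205, 14.56, 24.01 and 1.734 for albumin scale, hematocrit, GFR,
#' blood flow and organ volume without units or Child-Pugh class
#' assignment. This preset exposes the two unambiguous entries
#' (albumin_scale and hematocrit) as overrides; the remaining three are
#' returned as an attribute for reference, uninterpreted.
#'
#' @return Named list usable as `disease_spec(overrides = ...)`.
#' @export
cirrhosis_reported_overrides <- function() {
  out <- list(albumin_scale = 0.92, hematocrit = 0.4205)
  attr(out, "uninterpreted") <- c(gfr = 14.56, blood_flow = 24.01,
                                  organ_volume = 1.734)
  out
}

.apply_overrides <- function(values, overrides) {
  if (!length(overrides)) return(values)
  bad <- setdiff(names(overrides), names(values))
  if (length(bad))
    stop("override of unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  values[names(overrides)] <- overrides
  values
}

#' Apply a disease transformation to healthy physiology
#'
#' Dispatches on `spec$kind`. Cirrhosis (Child-Pugh A/B/C) scales the
#' albumin level, hematocrit, GFR, hepatic (arterial + portal) blood flow,
#' liver volume and CYP2C19 abundance per the packaged class table. CKD
#' sets absolute GFR (45 moderate / 20 severe ml/min/1.73 m2) and adjusts
#' hematocrit, albumin, gastric emptying and small-intestinal transit
#' times. Entries in `spec$overrides` take precedence. The transformation
#' is pure and preserves all flow-balance invariants.
#'
#' @param base Healthy `physiology_set` (disease transformations do not
#'   stack).
#' @param spec A [disease_spec()].
#' @return A new `physiology_set` with the matching `disease_label`.
#' @export
apply_disease <- function(base, spec) {
  stopifnot(inherits(base, "physiology_set"), inherits(spec, "disease_spec"))
  if (base$disease_label != "healthy")
    stop("disease transformations must start from healthy physiology",
         call. = FALSE)
  if (spec$kind == "cirrhosis") apply_liver_cirrhosis(base, spec)
  else apply_ckd(base, spec)
}

#' @rdname apply_disease
#' @export
apply_liver_cirrhosis <- function(base, spec) {
  stopifnot(spec$kind == "cirrhosis")
  tab <- .cirrhosis_table[[spec$severity]]
  if (is.null(tab)) stop("unknown cirrhosis severity: ", spec$severity,
                         call. = FALSE)
  ovr <- spec$overrides
  ovr_gfr <- ovr$gfr  # absolute-GFR override handled outside the scale table
  ovr$gfr <- NULL
  tab <- .apply_overrides(tab, ovr)
  phys <- base
  phys$albumin_scale <- tab$albumin_scale
  phys$hematocrit <- tab$hematocrit
  phys$gfr <- if (!is.null(ovr_gfr)) ovr_gfr else base$gfr * tab$gfr_scale
  phys$hepatic_enzyme_scale <- tab$hepatic_enzyme_scale
  phys$organ_volumes[["liver"]] <-
    base$organ_volumes[["liver"]] * tab$liver_volume_scale
  # Reduced hepatic perfusion: scale hepatic artery and portal inflows;
  # route the difference through "rest" so cardiac output is preserved.
  q <- base$organ_blood_flows
  for (org in c("liver", "gut", "spleen")) {
    delta <- q[[org]] * (1 - tab$hepatic_flow_scale)
    q[[org]] <- q[[org]] - delta
    q[["rest"]] <- q[["rest"]] + delta
  }
  phys$organ_blood_flows <- q
  phys$cardiac_output <- sum(q)
  phys$liver_total_flow <- q[["liver"]] + q[["gut"]] + q[["spleen"]]
  phys$disease_label <- spec$severity
  validate_physiology(phys)
  phys
}

#' @rdname apply_disease
#' @export
apply_ckd <- function(base, spec) {
  stopifnot(spec$kind == "ckd")
  tab <- .ckd_table[[spec$severity]]
  if (is.null(tab)) stop("unknown CKD severity: ", spec$severity,
                         call. = FALSE)
  tab <- .apply_overrides(tab, spec$overrides)
  phys <- base
  phys$gfr <- tab$gfr
  phys$hematocrit <- tab$hematocrit
  phys$albumin_scale <- tab$albumin_scale
  phys$gastric_emptying_time <-
    base$gastric_emptying_time * tab$gastric_emptying_scale
  phys$small_intestinal_transit_time <-
    base$small_intestinal_transit_time * tab$small_intestinal_transit_scale
  phys$disease_label <- paste0("CKD_", spec$severity)
  validate_physiology(phys)
  phys
}
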