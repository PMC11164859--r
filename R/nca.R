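#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes Cmax/Tmax from the samples, AUC0-t by the linear-up/log-down
#' trapezoid rule, the terminal slope lambda_z by log-linear regression
#' over the candidate tail (3 to 8 last positive samples strictly after
#' Tmax, best adjusted R-squared wins), AUC0-inf = AUC0-t +
#' Clast/lambda_z, half-life ln(2)/lambda_z and clearance CL =
#' dose/AUC0-inf (CL/F for the oral route).
#'
#' @param profile data.frame with columns `time_h` (strictly increasing)
#'   and `conc_ug_per_ml` (non-negative; `NA` rows, e.g. censored values,
#'   are dropped).
#' @param dose Administered dose (mg; total over the profile for
#'   multiple-dose AUC work).
#' @param body_weight Body weight (kg) for the per-kg clearance view.
#' @param route `"iv_bolus"` or `"oral"` (recorded; oral clearance is
#'   apparent CL/F).
#' @return An object of class `pk_parameters`: `cmax`, `tmax`, `auc_0_t`,
#'   `auc_0_inf`, `lambda_z`, `half_life`, `clearance_L_h`,
#'   `clearance_ml_min_kg`, `lambda_z_n`, `lambda_z_r2adj`,
#'   `terminal_fit_ok`. When no valid (negative-slope) terminal fit
#'   exists, `terminal_fit_ok` is `FALSE` and the extrapolated quantities
#'   are `NA`.
#' @export
nca <- function(profile, dose, body_weight = 73,
                route = c("iv_bolus", "oral")) {
  route <- match.arg(route)
  if (!all(c("time_h", "conc_ug_per_ml") %in% names(profile)))
    stop("profile needs columns time_h, conc_ug_per_ml", call. = FALSE)
  keep <- is.finite(profile$conc_ug_per_ml)
  t <- profile$time_h[keep]; c_ <- profile$conc_ug_per_ml[keep]
  if (length(t) < 3) stop("need at least 3 concentration samples",
                          call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing",
                              call. = FALSE)
  if (any(c_ < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (all(c_ == 0)) stop("all-zero profile: no PK parameters", call. = FALSE)
  if (dose <= 0) stop("'dose' must be > 0 mg", call. = FALSE)

  imax <- which.max(c_)
  cmax <- c_[imax]; tmax <- t[imax]
  auc_0_t <- .auc_lin_log(t, c_)

  fit <- .lambda_z_fit(t, c_, imax)
  out <- list(cmax = cmax, tmax = tmax, auc_0_t = auc_0_t,
              auc_0_inf = NA_real_, lambda_z = NA_real_,
              half_life = NA_real_, clearance_L_h = NA_real_,
              clearance_ml_min_kg = NA_real_,
              lambda_z_n = fit$n, lambda_z_r2adj = fit$r2adj,
              terminal_fit_ok = fit$ok,
              dose_mg = dose, body_weight = body_weight, route = route)
  if (fit$ok) {
    clast <- c_[max(which(c_ > 0))]
    out$lambda_z <- fit$lambda
    out$half_life <- log(2) / fit$lambda
    out$auc_0_inf <- auc_0_t + clast / fit$lambda
    out$clearance_L_h <- dose / out$auc_0_inf
    out$clearance_ml_min_kg <- out$clearance_L_h * 1000 / 60 / body_weight
  }
  structure(out, class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("<pk_parameters> %s, dose %g mg\n", x$route, x$dose_mg))
  cat(sprintf("  Cmax %.4g ug/ml at %.2f h; AUC0-t %.4g, AUC0-inf %.4g ug.h/ml\n",
              x$cmax, x$tmax, x$auc_0_t, x$auc_0_inf))
  cat(sprintf("  lambda_z %.4g /h (n=%d, R2adj %.4f), t1/2 %.3g h\n",
              x$lambda_z, x$lambda_z_n, x$lambda_z_r2adj, x$half_life))
  cat(sprintf("  CL%s %.4g L/h (%.4g ml/min/kg)\n",
              if (x$route == "oral") "/F" else "", x$clearance_L_h,
              x$clearance_ml_min_kg))
  invisible(x)
}

# linear-up/log-down trapezoid; log segment only for strictly decreasing
# positive pairs
.auc_lin_log <- function(t, c_) {
  dt <- diff(t); c1 <- c_[-length(c_)]; c2 <- c_[-1]
  logdown <- c1 > 0 & c2 > 0 & c2 < c1
  seg <- ifelse(logdown,
                (c1 - c2) / log(c1 / c2) * dt,
                (c1 + c2) / 2 * dt)
  sum(seg)
}

# terminal slope: candidate tails of the last 3..8 positive points
# strictly after tmax; maximize adjusted R^2; slope must be negative
.lambda_z_fit <- function(t, c_, imax) {
  cand <- which(seq_along(t) > imax & c_ > 0)
  best <- list(ok = FALSE, lambda = NA_real_, n = 0L, r2adj = NA_real_)
  if (length(cand) < 3) return(best)
  for (k in 3:min(8, length(cand))) {
    idx <- utils::tail(cand, k)
    fit <- stats::lm(log(c_[idx]) ~ t[idx])
    sl <- unname(stats::coef(fit)[2L])
    y <- log(c_[idx])
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
    r2adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (sl < 0 && (!best$ok || r2adj > best$r2adj))
      best <- list(ok = TRUE, lambda = -sl, n = k, r2adj = r2adj)
  }
  best
}

#' Observed/predicted ratio (model-evaluation ratio)
#'
#' The evaluation ratio R = observed / predicted for a PK parameter.
#'
#' @param observed,predicted Positive values (vectorized).
#' @return `observed / predicted`.
#' @export
ratio_obs_pre <- function(observed, predicted) {
  if (any(observed <= 0) || any(predicted <= 0))
    stop("observed and predicted values must be > 0", call. = FALSE)
  observed / predicted
}

#' Average fold error
#'
#' AFE = 10^(mean(log10(fold error))) — the geometric mean of the fold
#' errors, where a fold error is the observed/predicted ratio of one
#' study's PK parameter.
#'
#' @param fold_errors Non-empty vector of positive fold errors.
#' @return The average fold error (geometric mean).
#' @export
afe <- function(fold_errors) {
  if (!length(fold_errors)) stop("empty fold-error list", call. = FALSE)
  if (any(fold_errors <= 0)) stop("fold errors must be > 0", call. = FALSE)
  10^mean(log10(fold_errors))
}

#' Observed-versus-predicted evaluation table
#'
#' Pairs observed and predicted PK parameter values, computes the
#' evaluation ratio, the closed two-fold conformity flag (ratio in
#' \[0.5, 2\]) and, per parameter, the average fold error and arithmetic
#' mean ratio.
#'
#' @param observed,predicted data.frames with columns `label` (study/dose
#'   identifier), `parameter` (e.g. `"cmax"`, `"auc_0_inf"`, `"cl"`) and
#'   `value` (> 0). Keys (`label` x `parameter`) must match exactly.
#' @return A list with `table` (one row per pair: observed, predicted,
#'   ratio, within_twofold) and `summary` (per parameter: n, afe,
#'   mean_ratio).
#' @export
evaluation_table <- function(observed, predicted) {
  req <- c("label", "parameter", "value")
  if (!all(req %in% names(observed)) || !all(req %in% names(predicted)))
    stop("observed/predicted need columns label, parameter, value",
         call. = FALSE)
  ko <- paste(observed$label, observed$parameter, sep = "\r")
  kp <- paste(predicted$label, predicted$parameter, sep = "\r")
  extra_o <- setdiff(ko, kp); extra_p <- setdiff(kp, ko)
  if (length(extra_o) || length(extra_p))
    stop("observed/predicted keys mismatch: ",
         paste(gsub("\r", "/", c(extra_o, extra_p)), collapse = ", "),
         call. = FALSE)
  m <- match(ko, kp)
  tab <- data.frame(label = observed$label, parameter = observed$parameter,
                    observed = observed$value,
                    predicted = predicted$value[m],
                    stringsAsFactors = FALSE)
  tab$ratio <- ratio_obs_pre(tab$observed, tab$predicted)
  tab$within_twofold <- tab$ratio >= 0.5 & tab$ratio <= 2.0
  summ <- do.call(rbind, lapply(split(tab, tab$parameter), function(d)
    data.frame(parameter = d$parameter[1L], n = nrow(d),
               afe = afe(d$ratio), mean_ratio = mean(d$ratio),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}

#' Published clinical PK reference values
#'
#' Observed PK parameter values from the published brivaracetam clinical
#' studies, paired with the reference model's predicted values, as
#' reported in the source model-evaluation tables (healthy IV and oral,
#' Child-Pugh liver-cirrhosis oral 100 mg). Used for the package's worked
#' examples and the reproduction of the published evaluation statistics.
#'
#' @param population `"healthy"`, `"cirrhosis"`, or `"all"`.
#' @return data.frame with columns `population`, `label`, `dose_mg`,
#'   `parameter`, `observed`, `predicted` (Cmax in ug/ml, AUC0-inf in
#'   ug.h/ml, CL in ml/min/kg).
#' @export
clinical_reference_values <- function(population = c("all", "healthy",
                                                     "cirrhosis")) {
  population <- match.arg(population)
  path <- system.file("extdata", "clinical_pk_reference.csv",
                      package = "brvpbpk", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (population != "all") ref <- ref[ref$population == population, ]
  ref
}
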