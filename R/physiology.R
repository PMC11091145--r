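# Machine-perfusion physiology: oxygen delivery/uptake, vascular
# resistance, weight gain, glomerular sieving, hemofiltration exchange.

# Solubility of O2 in aqueous (acellular) perfusate at the working
# temperature, mL O2 per dL fluid per mmHg.
O2_SOLUBILITY <- 0.0031

#' Oxygen delivery of an acellular perfusate
#'
#' `arterial pO2 (mmHg) x 0.0031 (mL O2 dL^-1 mmHg^-1) x flow (dL/min)`.
#' With no hemoglobin carrier, delivered oxygen is purely the dissolved
#' fraction, so delivery is linear in both pO2 and flow.
#'
#' @param po2_art arterial pO2 in mmHg.
#' @param flow renal flow in mL/min (converted to dL/min internally).
#' @return oxygen delivery in mL O2/min.
#' @examples
#' oxygen_delivery(500, 200)  # 3.1
#' @export
oxygen_delivery <- function(po2_art, flow) {
  if (any(po2_art < 0) || any(flow < 0)) {
    stop_arg("po2_art and flow must be non-negative")
  }
  po2_art * O2_SOLUBILITY * (flow / 100)
}

#' Oxygen uptake across the kidney
#'
#' `(arterial pO2 - venous pO2) x 0.0031 x flow (dL/min)`. A venous pO2
#' above arterial gives a negative uptake, which is physically possible only
#' as measurement error; it is returned with a `reverse_gradient` attribute
#' rather than rejected.
#'
#' @param po2_art,po2_ven arterial and venous pO2 in mmHg.
#' @param flow renal flow in mL/min.
#' @return oxygen uptake in mL O2/min (attribute `reverse_gradient` TRUE
#'   where negative).
#' @examples
#' oxygen_uptake(500, 400, 200)  # 0.62
#' @export
oxygen_uptake <- function(po2_art, po2_ven, flow) {
  if (any(po2_art < 0) || any(po2_ven < 0) || any(flow < 0)) {
    stop_arg("inputs must be non-negative")
  }
  out <- (po2_art - po2_ven) * O2_SOLUBILITY * (flow / 100)
  if (any(out < 0)) attr(out, "reverse_gradient") <- out < 0
  out
}

#' Vascular resistance
#'
#' Conventional perfusion index: mean arterial pressure divided by flow.
#'
#' @param map_pressure mean arterial pressure in mmHg (pump set-point 75 in
#'   the pressure-controlled system).
#' @param flow renal flow in mL/min.
#' @return resistance in mmHg.min/mL; NA (flagged invalid) where flow is 0.
#' @export
vascular_resistance <- function(map_pressure, flow) {
  if (any(map_pressure < 0) || any(flow < 0)) {
    stop_arg("inputs must be non-negative")
  }
  out <- ifelse(flow > 0, map_pressure / flow, NA_real_)
  if (any(flow == 0)) attr(out, "invalid") <- flow == 0
  out
}

#' Percent weight gain over a perfusion run
#'
#' Edema-driven weight gain: `100 * (final - initial) / initial`. Reported
#' both at full precision and rounded half-up to the integer percent used in
#' summary figures.
#'
#' @param w0 initial weight in g (> 0).
#' @param w1 final weight in g.
#' @return list with `percent` (full precision) and `percent_int`.
#' @examples
#' weight_gain_pct(283, 363)  # 28.27 -> 28
#' @export
weight_gain_pct <- function(w0, w1) {
  if (any(w0 <= 0)) stop_arg("initial weight must be positive")
  pct <- 100 * (w1 - w0) / w0
  list(percent = pct, percent_int = round_half_up(pct))
}

#' Glomerular sieving coefficient from dextran fluorescence
#'
#' The urine-to-perfusate fluorescence ratio of a labeled dextran after
#' background subtraction: 0 for a tracer fully retained in the vascular
#' compartment, 1 for free filtration at equal concentration. Negative
#' background-subtracted urine signal clamps to 0 with a flag.
#'
#' @param f_urine,f_perfusate measured fluorescence (a.u.).
#' @param baseline_urine,baseline_perfusate pre-infusion background
#'   fluorescence (default 0).
#' @param eps positivity guard on the perfusate signal (default 1e-9).
#' @return sieving coefficient (>= 0); attribute `clamped` marks values
#'   raised to 0; NA (attribute `invalid`) where the perfusate signal is at
#'   or below background.
#' @examples
#' sieving_coefficient(400, 800)  # 0.5
#' @export
sieving_coefficient <- function(f_urine, f_perfusate, baseline_urine = 0,
                                baseline_perfusate = 0, eps = 1e-9) {
  if (any(f_urine < 0) || any(f_perfusate < 0)) {
    stop_arg("fluorescence must be non-negative")
  }
  num <- f_urine - baseline_urine
  den <- f_perfusate - baseline_perfusate
  out <- ifelse(den > eps, num / den, NA_real_)
  clamped <- !is.na(out) & out < 0
  out[clamped] <- 0
  if (any(clamped)) attr(out, "clamped") <- clamped
  if (anyNA(out)) attr(out, "invalid") <- is.na(out)
  out
}

#' Hemofiltration exchange fraction
#'
#' Percent of the circulating volume exchanged per hour by continuous
#' hemofiltration at `removal_rate`, with fresh substitution at the same
#' rate. The reference volume is a required input: the circuit volume, the
#' filter blood flow per hour, or any other denominator of interest.
#'
#' @param removal_rate filtrate removal rate in mL/h.
#' @param reference_volume reference fluid volume in mL (> 0).
#' @return percent of reference volume exchanged per hour.
#' @examples
#' exchange_fraction(40, 800)  # 5
#' @export
exchange_fraction <- function(removal_rate, reference_volume) {
  if (any(removal_rate < 0)) stop_arg("removal_rate must be non-negative")
  if (any(reference_volume <= 0)) stop_arg("reference_volume must be positive")
  100 * removal_rate / reference_volume
}

#' Read / write perfusion time-series CSV
#'
#' Columns: `time_h`, `flow_ml_min`, `map_mmhg`, `po2_art`, `po2_ven`, plus
#' optional channels (`ph`, `lactate_mmol_l`, `glucose_mmol_l`, ...).
#'
#' @param path CSV path.
#' @return a `perfusion_timeseries` data.frame.
#' @export
read_perfusion_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "flow_ml_min", "map_mmhg", "po2_art", "po2_ven")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_arg("missing columns: %s", paste(miss, collapse = ", "))
  if (any(diff(df$time_h) <= 0)) stop_arg("time_h must be strictly increasing")
  if (any(df$flow_ml_min < 0) || any(df$po2_art < 0) || any(df$po2_ven < 0)) {
    stop_arg("flow and pO2 must be non-negative")
  }
  class(df) <- c("perfusion_timeseries", "data.frame")
  df
}

#' @rdname read_perfusion_csv
#' @param series a `perfusion_timeseries`.
#' @export
write_perfusion_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a perfusion time series
#'
#' Derived physiology channels and daily means: oxygen delivery and uptake,
#' vascular resistance, plus weight gain when weights are attached.
#'
#' @param series a `perfusion_timeseries` (e.g. from
#'   [generate_perfusion_timeseries()] or [read_perfusion_csv()]).
#' @return list with `per_sample` (series plus derived columns), `daily`
#'   (means by day), and `weight_gain` (or NULL).
#' @export
summarize_perfusion <- function(series) {
  s <- as.data.frame(series)
  s$o2_delivery_ml_min <- oxygen_delivery(s$po2_art, s$flow_ml_min)
  s$o2_uptake_ml_min <- as.numeric(oxygen_uptake(s$po2_art, s$po2_ven,
                                                 s$flow_ml_min))
  s$resistance_mmhg_min_ml <- as.numeric(vascular_resistance(s$map_mmhg,
                                                             s$flow_ml_min))
  day <- floor(s$time_h / 24)
  num <- vapply(s, is.numeric, logical(1))
  daily <- stats::aggregate(s[, num], by = list(day = day), FUN = mean)
  wg <- NULL
  w0 <- attr(series, "weight_initial_g")
  w1 <- attr(series, "weight_final_g")
  if (!is.null(w0) && !is.null(w1)) wg <- weight_gain_pct(w0, w1)
  list(per_sample = s, daily = daily, weight_gain = wg)
}
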