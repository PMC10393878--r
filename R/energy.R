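#' Constant-power device model
#'
#' Each compute arm is assigned a constant average power draw: for example
#' 50 W as a conservative estimate for four CPU cores, or a GPU's 295 W
#' maximum power taken as its average. An optional note records the
#' rationale.
#'
#' @param label Device label.
#' @param average_power_w Average power (W), > 0.
#' @param note Free-text rationale.
#' @return A `power_model`.
#' @export
power_model <- function(label, average_power_w, note = "") {
  if (average_power_w <= 0)
    .stopf("power_model: average_power_w must be > 0")
  structure(list(label = label, average_power_w = average_power_w,
                 note = note), class = "power_model")
}

#' Energy consumed by a simulation (watt-hours)
#'
#' `power_w * duration_s / 3600`.
#'
#' @param power_w Average power (W), > 0.
#' @param duration_s Duration (s), >= 0.
#' @return Energy in Wh.
#' @examples
#' energy_wh(50, 607.5)   # 8.44 Wh
#' energy_wh(295, 31.7)   # 2.60 Wh
#' @export
energy_wh <- function(power_w, duration_s) {
  if (any(power_w <= 0))
    .stopf("energy_wh: power_w must be > 0")
  if (any(duration_s < 0))
    .stopf("energy_wh: duration_s must be >= 0")
  power_w * duration_s / 3600
}

#' Monetary cost of a simulation campaign
#'
#' Dimensionally explicit: per-case energy in Wh is converted to kWh
#' before applying the tariff, so
#' `cost = energy_per_case_wh * n_cases / 1000 * tariff_per_kwh`.
#' 1000 cases at 8.44 Wh/case and 0.25 currency/kWh cost 2.11, i.e. the
#' total energy is 8.44 kWh.
#'
#' @param energy_per_case_wh Energy per case (Wh).
#' @param n_cases Number of simulations, >= 0.
#' @param tariff_per_kwh Price per kWh.
#' @return List with `total_kwh` and `cost`.
#' @export
campaign_cost <- function(energy_per_case_wh, n_cases, tariff_per_kwh) {
  if (energy_per_case_wh < 0 || n_cases < 0 || tariff_per_kwh < 0)
    .stopf("campaign_cost: inputs must be non-negative")
  total_kwh <- energy_per_case_wh * n_cases / 1000
  list(total_kwh = total_kwh, cost = total_kwh * tariff_per_kwh)
}

#' Summarize per-case energy use across compute arms
#'
#' Converts per-record durations to watt-hours with each arm's constant
#' power model and reports per-arm median/IQR energy plus a paired
#' Wilcoxon signed-rank comparison of every arm against the first. Because
#' power is constant per arm, energy is a monotone transform of duration
#' and medians commute: `median(energy) = power * median(duration) / 3600`.
#'
#' @param records Benchmark records (`case_id`, `method`,
#'   `fidelity_percent`, `duration_s`).
#' @param power_models Named list/vector mapping arm label to watts. Arm
#'   labels are `reference` and `fidelity_<percent>`.
#' @return A `energy_summary`: `energy_records`, `by_arm` (median/IQR Wh),
#'   `comparisons` (paired signed-rank vs the first arm).
#' @export
summarize_energy <- function(records, power_models) {
  pw <- unlist(lapply(power_models, function(p)
    if (inherits(p, "power_model")) p$average_power_w else p))
  arm <- ifelse(records$method == "reference", "reference",
                paste0("fidelity_", records$fidelity_percent))
  unknown <- setdiff(unique(arm), names(pw))
  if (length(unknown))
    .stopf("summarize_energy: no power model for arm(s): %s",
           paste(unknown, collapse = ", "))
  er <- data.frame(case_id = records$case_id, arm = arm,
                   power_w = unname(pw[arm]),
                   duration_s = records$duration_s,
                   energy_wh = energy_wh(unname(pw[arm]),
                                         records$duration_s))
  arms <- unique(arm)
  qf <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), type = 7,
                                    names = FALSE)
  by_arm <- do.call(rbind, lapply(arms, function(a) {
    q <- qf(er$energy_wh[er$arm == a])
    data.frame(arm = a, n = sum(er$arm == a), median_wh = q[2],
               iqr_low_wh = q[1], iqr_high_wh = q[3])
  }))
  comparisons <- NULL
  if (length(arms) > 1L) {
    base <- er[er$arm == arms[1], c("case_id", "energy_wh")]
    comparisons <- do.call(rbind, lapply(arms[-1], function(a) {
      other <- er[er$arm == a, c("case_id", "energy_wh")]
      m <- merge(base, other, by = "case_id")
      w <- wilcoxon_signed_rank(m$energy_wh.x - m$energy_wh.y)
      data.frame(comparison = sprintf("%s vs %s", arms[1], a),
                 median_difference_wh = w$median_difference,
                 p_value = w$p_value)
    }))
  }
  structure(list(energy_records = er, by_arm = by_arm,
                 comparisons = comparisons),
            class = "energy_summary")
}

#' @export
print.energy_summary <- function(x, ...) {
  cat("<energy_summary>\n")
  print(x$by_arm, row.names = FALSE)
  invisible(x)
}
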