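#' Set-speed to realized-speed calibration
#'
#' Impeller drives under load realize less than the commanded speed; this
#' table maps set speed to measured average speed by monotone piecewise
#' linear interpolation. An empty calibration is the identity.
#'
#' @param set_speed Strictly increasing set speeds (mm/s).
#' @param real_speed Non-decreasing realized speeds (mm/s); a plateau is
#'   allowed.
#' @return Object of class `speed_calibration`.
#' @export
speed_calibration <- function(set_speed = numeric(), real_speed = numeric()) {
  if (length(set_speed) != length(real_speed))
    stop("set_speed and real_speed must have equal length")
  if (length(set_speed) > 1L) {
    if (any(diff(set_speed) <= 0)) stop("set speeds must be strictly increasing")
    if (any(diff(real_speed) < 0)) stop("real speeds must be non-decreasing")
  }
  structure(list(set_speed = set_speed, real_speed = real_speed),
            class = "speed_calibration")
}

#' Realized impeller speed for a commanded set speed
#'
#' Monotone piecewise-linear interpolation through the calibration knots;
#' queries beyond the table clamp to the end values (plateau). With an
#' empty calibration the set speed is returned unchanged.
#'
#' @param set_speed Query set speed(s), mm/s.
#' @param calibration A [speed_calibration()].
#' @return Realized speed(s), mm/s.
#' @export
real_speed <- function(set_speed, calibration = speed_calibration()) {
  stopifnot(inherits(calibration, "speed_calibration"))
  if (length(calibration$set_speed) == 0L) return(set_speed)
  if (length(calibration$set_speed) == 1L)
    return(rep(calibration$real_speed, length(set_speed)))
  stats::approx(calibration$set_speed, calibration$real_speed,
                xout = set_speed, rule = 2)$y
}

#' Select the motion speed matching a reference tank's optimum
#'
#' Scores each candidate summary row by the weighted relative deviation of
#' its volume-averaged turbulent energy and shear stress from the
#' reference optimum:
#' `score = w_k |k_c - k_ref| / k_ref + w_tau |tau_c - tau_ref| / tau_ref`.
#' The candidate with the minimal score is selected (ties broken toward
#' the lower speed, the biologically conservative choice); it is reported
#' as "within band" when both relative deviations are at most `band`.
#'
#' @param reference A one-row `summary_row` (or data frame with
#'   `turbulent_energy`, `shear_stress`, `speed`).
#' @param candidates Data frame of candidate rows, same columns.
#' @param weights Length-2 weights `(w_k, w_tau)`, default equal (1/2, 1/2).
#' @param band Relative-deviation acceptance band (default 0.10).
#' @return Object of class `speed_match`: scores, per-candidate deviations
#'   and verdicts, `selected_speed`, and the selected row.
#' @export
match_speed <- function(reference, candidates, weights = c(0.5, 0.5),
                        band = 0.10) {
  if (nrow(candidates) < 1L) stop("need at least one candidate")
  k_ref <- reference$turbulent_energy[1L]
  t_ref <- reference$shear_stress[1L]
  if (!is.finite(k_ref) || k_ref <= 0 || !is.finite(t_ref) || t_ref <= 0)
    stop("reference turbulent_energy and shear_stress must be > 0")
  stopifnot(length(weights) == 2L, all(weights >= 0), sum(weights) > 0)
  dk <- abs(candidates$turbulent_energy - k_ref) / k_ref
  dt <- abs(candidates$shear_stress - t_ref) / t_ref
  score <- weights[1L] * dk + weights[2L] * dt
  within <- dk <= band & dt <= band
  best <- order(score, candidates$speed)[1L]
  structure(list(
    reference = reference,
    candidates = candidates,
    scores = score,
    dev_k = dk, dev_tau = dt,
    within_band = within,
    band = band, weights = weights,
    selected_index = best,
    selected_speed = candidates$speed[best],
    selected_within_band = within[best]),
    class = "speed_match")
}

#' @export
print.speed_match <- function(x, ...) {
  tab <- data.frame(speed = x$candidates$speed,
                    k = x$candidates$turbulent_energy,
                    tau = x$candidates$shear_stress,
                    dev_k = round(x$dev_k, 4),
                    dev_tau = round(x$dev_tau, 4),
                    score = round(x$scores, 4),
                    within_band = x$within_band)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "selected speed: %g mm/s (%s the %.0f%% band) vs reference k=%g, tau=%g\n",
    x$selected_speed,
    if (x$selected_within_band) "within" else "outside",
    100 * x$band,
    x$reference$turbulent_energy[1L], x$reference$shear_stress[1L]))
  invisible(x)
}

#' Published cross-scale summary table (two-impeller line)
#'
#' The volume-averaged CFD summary of the reciprocating two-impeller tanks
#' at their operating speeds, in the fixed column schema; used as reference
#' and candidate input for [match_speed()] worked examples.
#'
#' @return Data frame with the summary columns.
#' @export
reference_summary_table <- function() {
  data.frame(
    scale = c(3, 10, 50, 50, 50),
    speed = c(150, 150, 200, 300, 400),
    turbulent_energy = c(0.0129, 0.0113, 0.0082, 0.0109, 0.0220),
    shear_stress = c(3.93, 3.29, 2.38, 3.18, 6.41),
    kolmogorov = c(150, 201, 286, 264, 194),
    shear_rate = c(17.29, 10.53, 5.60, 6.67, 8.64),
    vorticity = c(13.4, 7.79, 4.46, 5.27, 6.80),
    dissipation = c(0.099, 0.062, 0.023, 0.038, 0.097))
}

#' Published three-impeller 50 L summary row
#'
#' @return One-row data frame in the same schema.
#' @export
reference_summary_three_impeller <- function() {
  data.frame(scale = 50, speed = 200,
             turbulent_energy = 0.0112, shear_stress = 3.35,
             kolmogorov = 198, shear_rate = 6.22, vorticity = 4.32,
             dissipation = 0.0279)
}
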