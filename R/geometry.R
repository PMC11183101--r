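#' Impeller specification
#'
#' Describes one reciprocating disc impeller mounted on the central shaft.
#'
#' @param center_height Mid-stroke axial position of the disc centre (m).
#' @param disc_radius Disc radius (m); must be smaller than the tank radius.
#' @param disc_thickness Disc thickness (m).
#' @return An object of class `impeller_spec`.
#' @export
impeller_spec <- function(center_height, disc_radius, disc_thickness = 0.005) {
  stopifnot(center_height > 0, disc_radius > 0, disc_thickness > 0)
  structure(list(center_height = center_height,
                 disc_radius = disc_radius,
                 disc_thickness = disc_thickness),
            class = "impeller_spec")
}

#' Impeller motion specification
#'
#' Reciprocating (or rotary placeholder) motion of the impeller assembly.
#' Speeds and strokes are in the operating units of the hardware
#' (mm and mm/s); everything else in the package is SI.
#'
#' @param kind `"reciprocating"` or `"rotary"`.
#' @param set_speed Commanded motion speed (mm/s).
#' @param stroke Total stroke travel (mm); required for reciprocating motion.
#' @param waveform `"triangular"` (constant speed, direction reversal at the
#'   stroke ends) or `"sinusoidal"`.
#' @param n_snapshots Number of quasi-steady impeller positions sampled over
#'   one cycle (>= 2).
#' @param in_phase If `TRUE` (default) all discs move together, as on a single
#'   drive shaft; if `FALSE` alternate discs move in antiphase.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(kind = "reciprocating", set_speed = 300, stroke = 60,
                        waveform = "triangular", n_snapshots = 2L,
                        in_phase = TRUE) {
  kind <- match.arg(kind, c("reciprocating", "rotary"))
  waveform <- match.arg(waveform, c("triangular", "sinusoidal"))
  n_snapshots <- as.integer(n_snapshots)
  if (kind == "reciprocating" && (!is.finite(stroke) || stroke <= 0))
    stop("reciprocating motion requires stroke > 0 (mm)")
  if (n_snapshots < 2L) stop("n_snapshots must be >= 2")
  if (!is.finite(set_speed) || set_speed < 0)
    stop("set_speed must be a non-negative speed in mm/s")
  structure(list(kind = kind, set_speed = set_speed, stroke = stroke,
                 waveform = waveform, n_snapshots = n_snapshots,
                 in_phase = in_phase),
            class = "motion_spec")
}

#' Sample impeller stroke positions and instantaneous speeds
#'
#' Samples `n_snapshots` phases of one motion cycle and returns the signed
#' stroke offset and instantaneous impeller velocity at each. For the
#' triangular waveform the speed magnitude equals `set_speed`; for the
#' sinusoidal waveform the peak speed is `pi/2 * set_speed` so that the mean
#' speed over a cycle matches the set speed. At a stroke extreme the velocity
#' of the following half-cycle is used (top of stroke moving down, bottom
#' moving up).
#'
#' @param motion A [motion_spec()].
#' @return A data frame with columns `phase`, `offset_mm`, `velocity_mm_s`.
#' @export
impeller_positions <- function(motion) {
  stopifnot(inherits(motion, "motion_spec"))
  n <- motion$n_snapshots
  s <- motion$stroke
  v <- motion$set_speed
  phi <- (seq_len(n) - 0.5) / n
  if (motion$waveform == "triangular") {
    off <- ifelse(phi < 0.25, s / 2 * 4 * phi,
           ifelse(phi < 0.75, s / 2 * (2 - 4 * phi), s / 2 * (4 * phi - 4)))
    vel <- ifelse(phi >= 0.25 & phi < 0.75, -v, v)
  } else {
    off <- s / 2 * sin(2 * pi * phi)
    vel <- v * pi / 2 * cos(2 * pi * phi)
  }
  data.frame(phase = phi, offset_mm = off, velocity_mm_s = vel)
}

#' Tank specification
#'
#' A cylindrical tank with a free liquid surface, described by its working
#' volume, inner diameter and liquid height, plus the impeller assembly.
#' The cylinder identity `pi (D/2)^2 H = V` must hold to 1e-6 relative.
#'
#' @param label Free-text tank label.
#' @param working_volume Liquid volume (m^3).
#' @param diameter Inner diameter (m).
#' @param liquid_height Liquid column height (m).
#' @param impellers List of [impeller_spec()] objects (1 to 3).
#' @param motion Optional [motion_spec()] attached to the tank.
#' @return An object of class `tank_spec`.
#' @export
tank_spec <- function(label, working_volume, diameter, liquid_height,
                      impellers, motion = NULL) {
  if (!is.finite(working_volume) || working_volume <= 0)
    stop("working_volume must be > 0")
  vcyl <- pi * (diameter / 2)^2 * liquid_height
  if (abs(vcyl - working_volume) > 1e-6 * working_volume)
    stop(sprintf(
      "inconsistent volume/diameter/height: cylinder volume %.6g != %.6g",
      vcyl, working_volume))
  if (!is.list(impellers) || length(impellers) < 1L || length(impellers) > 3L)
    stop("1 to 3 impellers required")
  for (im in impellers) {
    stopifnot(inherits(im, "impeller_spec"))
    if (im$disc_radius >= diameter / 2)
      stop("impeller disc_radius must be smaller than the tank radius")
    half_stroke <- if (!is.null(motion)) motion$stroke / 2 / 1000 else 0
    if (im$center_height - half_stroke <= 0 ||
        im$center_height + half_stroke >= liquid_height)
      stop("impeller stroke envelope must stay inside the liquid column")
  }
  structure(list(label = label, working_volume = working_volume,
                 diameter = diameter, liquid_height = liquid_height,
                 aspect_ratio = liquid_height / diameter,
                 impellers = impellers, motion = motion),
            class = "tank_spec")
}

# preset table: working volumes from the reactor line's published operating
# points; tank dimensions are not public, so presets use aspect ratio 1.2 and
# discs of half the tank radius, all overridable.
.tank_presets <- function() {
  list(
    "VerMES3"       = list(volume = 0.0024, n_imp = 2L, speed = 150),
    "VerMES10"      = list(volume = 0.008,  n_imp = 2L, speed = 150),
    "VerMES50-2imp" = list(volume = 0.045,  n_imp = 2L, speed = 300),
    "VerMES50-3imp" = list(volume = 0.045,  n_imp = 3L, speed = 200)
  )
}

#' Build a tank from a preset or explicit parameters
#'
#' Presets `"VerMES3"`, `"VerMES10"`, `"VerMES50-2imp"`, `"VerMES50-3imp"`
#' give the 2.4, 8 and 45 L working volumes of the reciprocating-impeller
#' reactor line with a default 60 mm stroke. Two-impeller presets place discs
#' at 1/4 and 3/4 of the liquid height (one per half-column); the
#' three-impeller preset adds the middle disc (1/4, 1/2, 3/4). Alternatively
#' pass explicit `diameter` plus `aspect_ratio` (or `working_volume` plus
#' `aspect_ratio`).
#'
#' @param preset Preset name, or `NULL` for explicit parameters.
#' @param working_volume Working volume (m^3) for explicit construction.
#' @param diameter Tank diameter (m) for explicit construction.
#' @param aspect_ratio Liquid height / diameter (default 1.2 for presets,
#'   required for explicit construction when only one length is given).
#' @param n_impellers Number of discs (explicit construction).
#' @param disc_radius_frac Disc radius as a fraction of tank radius
#'   (default 0.5).
#' @param motion A [motion_spec()]; presets supply a default.
#' @param label Tank label override.
#' @return A [tank_spec()].
#' @export
build_tank <- function(preset = NULL, working_volume = NULL, diameter = NULL,
                       aspect_ratio = NULL, n_impellers = 2L,
                       disc_radius_frac = 0.5, motion = NULL, label = NULL) {
  if (!is.null(preset)) {
    presets <- .tank_presets()
    if (!preset %in% names(presets))
      stop(sprintf("unknown preset '%s'; available: %s", preset,
                   paste(names(presets), collapse = ", ")))
    p <- presets[[preset]]
    working_volume <- p$volume
    n_impellers <- p$n_imp
    if (is.null(aspect_ratio)) aspect_ratio <- 1.2
    if (is.null(motion))
      motion <- motion_spec(set_speed = p$speed, stroke = 60)
    if (is.null(label)) label <- preset
  }
  if (is.null(aspect_ratio)) aspect_ratio <- 1.2
  if (is.null(diameter)) {
    if (is.null(working_volume))
      stop("supply a preset, a working_volume, or a diameter")
    diameter <- (working_volume / (pi / 4 * aspect_ratio))^(1 / 3)
  }
  liquid_height <- aspect_ratio * diameter
  if (is.null(working_volume))
    working_volume <- pi * (diameter / 2)^2 * liquid_height
  n_impellers <- as.integer(n_impellers)
  # two discs at quarter heights serve one half-column each; the
  # three-disc variant adds a middle disc to fill the inter-sweep gap
  fracs <- if (n_impellers == 1L) 0.5
           else if (n_impellers == 2L) c(1, 3) / 4
           else c(1, 2, 3) / 4
  imps <- lapply(fracs, function(f)
    impeller_spec(center_height = f * liquid_height,
                  disc_radius = disc_radius_frac * diameter / 2))
  tank_spec(label = if (is.null(label)) "custom" else label,
            working_volume = working_volume, diameter = diameter,
            liquid_height = liquid_height, impellers = imps, motion = motion)
}

#' Geometrically scale a tank to a target working volume
#'
#' All lengths (diameter, height, impeller positions, radii, thicknesses) are
#' multiplied by `(target_volume / working_volume)^(1/3)`. The stroke is a
#' property of the drive hardware and is left unchanged unless
#' `scale_stroke = TRUE`.
#'
#' @param tank A [tank_spec()].
#' @param target_volume Target working volume (m^3), > 0.
#' @param scale_stroke Also scale the motion stroke by the length factor.
#' @return A new [tank_spec()].
#' @export
scale_tank <- function(tank, target_volume, scale_stroke = FALSE) {
  stopifnot(inherits(tank, "tank_spec"))
  if (!is.finite(target_volume) || target_volume <= 0)
    stop("target_volume must be > 0")
  f <- (target_volume / tank$working_volume)^(1 / 3)
  imps <- lapply(tank$impellers, function(im)
    impeller_spec(im$center_height * f, im$disc_radius * f,
                  im$disc_thickness * f))
  motion <- tank$motion
  if (scale_stroke && !is.null(motion)) motion$stroke <- motion$stroke * f
  tank_spec(label = sprintf("%s-scaled", tank$label),
            working_volume = target_volume,
            diameter = tank$diameter * f,
            liquid_height = tank$liquid_height * f,
            impellers = imps, motion = motion)
}

#' @export
print.tank_spec <- function(x, ...) {
  cat(sprintf("Tank '%s': V = %.4g L, D = %.3f m, H = %.3f m (H/D = %.2f)\n",
              x$label, 1000 * x$working_volume, x$diameter, x$liquid_height,
              x$aspect_ratio))
  for (i in seq_along(x$impellers)) {
    im <- x$impellers[[i]]
    cat(sprintf("  impeller %d: z = %.3f m, disc radius %.3f m\n",
                i, im$center_height, im$disc_radius))
  }
  if (!is.null(x$motion))
    cat(sprintf("  motion: %s, %g mm/s, stroke %g mm, %d snapshots\n",
                x$motion$kind, x$motion$set_speed, x$motion$stroke,
                x$motion$n_snapshots))
  invisible(x)
}
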