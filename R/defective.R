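#' Threshold specification for active-turbulence classification
#'
#' A cell is "active" when the chosen field is at or above the threshold.
#' In `"relative-to-mean"` mode (default) the cutoff is
#' `value x` the volume-averaged field over the reference snapshot set, so
#' the criterion is scale-free; `"absolute"` compares against `value`
#' directly in the field's own units.
#'
#' @param field `"k"`, `"eps"` or `"mu_t"`.
#' @param mode `"relative-to-mean"` or `"absolute"`.
#' @param value Threshold value (> 0); a relative factor or an absolute
#'   field value.
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(field = "k", mode = c("relative-to-mean",
                                                 "absolute"), value = 0.1) {
  field <- match.arg(field, c("k", "eps", "mu_t"))
  mode <- match.arg(mode)
  if (!is.finite(value) || value <= 0) stop("threshold value must be > 0")
  structure(list(field = field, mode = mode, value = value),
            class = "threshold_spec")
}

.threshold_field <- function(state, field) {
  f <- state[[field]]
  if (is.null(f)) stop(sprintf("field '%s' not present in state", field))
  f
}

# absolute cutoff implied by a threshold spec over a snapshot set
.threshold_cutoff <- function(spec, states, grid) {
  if (spec$mode == "absolute") return(spec$value)
  tot <- 0; wtot <- 0
  for (s in states) {
    f <- .threshold_field(s, spec$field)
    tot <- tot + sum(f * grid$vol)
    wtot <- wtot + sum(grid$vol)
  }
  spec$value * tot / wtot
}

#' Classify active turbulent flow in one snapshot
#'
#' @param state A `flow_state` (or synthetic field) holding the threshold
#'   field.
#' @param grid The grid (default `state$grid`).
#' @param spec A [threshold_spec()].
#' @param reference_states Snapshot set defining the mean in
#'   relative-to-mean mode (default: the state itself).
#' @return An object of class `active_mask`: logical matrix `active`, the
#'   spec, and the absolute `cutoff` used. Cells swept by the impeller disc
#'   (`state$solid`) are counted active.
#' @export
classify_active <- function(state, grid = state$grid, spec = threshold_spec(),
                            reference_states = list(state)) {
  stopifnot(inherits(spec, "threshold_spec"))
  cutoff <- .threshold_cutoff(spec, reference_states, grid)
  f <- .threshold_field(state, spec$field)
  active <- f >= cutoff
  # cells the disc occupies or sweeps through each stroke cannot be dead
  if (!is.null(state$solid)) active[state$solid] <- TRUE
  if (!is.null(state$swept)) active[state$swept] <- TRUE
  structure(list(active = active, spec = spec, cutoff = cutoff),
            class = "active_mask")
}

#' Merge snapshots into the defective turbulent flow space
#'
#' A cell belongs to the defective space when it is inactive in every
#' snapshot of the stroke cycle (strict intersection of the per-snapshot
#' inactive sets). The defective volume is the cell-volume sum over that
#' mask, reported in litres; the threshold criterion is echoed in the
#' result so no defective volume is ever reported without it.
#'
#' @param ensemble A `snapshot_ensemble` (or list of states in `$states`).
#' @param grid Shared grid (default: grid of the first state).
#' @param spec A [threshold_spec()].
#' @return Object of class `defective_space`: per-snapshot masks, merged
#'   `defective` mask, `defective_volume_L`, `defective_fraction`, cutoff,
#'   spec, and tank label/scale if available.
#' @export
merge_defective <- function(ensemble, grid = NULL, spec = threshold_spec()) {
  states <- if (inherits(ensemble, "snapshot_ensemble")) ensemble$states
            else ensemble
  if (length(states) < 1L) stop("need at least one snapshot")
  if (is.null(grid)) grid <- states[[1L]]$grid
  dims <- dim(states[[1L]]$k)
  for (s in states)
    if (!identical(dim(s$k), dims))
      stop("grid topology differs across snapshots")
  cutoff <- .threshold_cutoff(spec, states, grid)
  masks <- lapply(states, function(s) {
    m <- classify_active(s, grid, spec_with_cutoff(spec, cutoff))
    m
  })
  defective <- Reduce(`&`, lapply(masks, function(m) !m$active))
  vol_def <- sum(grid$vol[defective])
  vol_tot <- sum(grid$vol)
  tank <- if (inherits(ensemble, "snapshot_ensemble")) ensemble$tank
          else grid$tank
  structure(list(masks = masks, defective = defective,
                 defective_volume_L = 1000 * vol_def,
                 defective_fraction = vol_def / vol_tot,
                 working_volume_L = 1000 * vol_tot,
                 cutoff = cutoff, spec = spec,
                 tank_label = if (!is.null(tank)) tank$label else NA,
                 scale_L = if (!is.null(tank)) 1000 * tank$working_volume
                           else 1000 * vol_tot),
            class = "defective_space")
}

# freeze a relative spec at a precomputed absolute cutoff so all snapshots
# share exactly the same criterion
spec_with_cutoff <- function(spec, cutoff) {
  s <- spec
  s$mode <- "absolute"
  s$value <- cutoff
  s
}

#' @export
print.defective_space <- function(x, ...) {
  cat(sprintf(
    "defective turbulent flow space: %.4g L of %.4g L (fraction %.3f)\n",
    x$defective_volume_L, x$working_volume_L, x$defective_fraction))
  cat(sprintf("  criterion: %s %s %.4g (absolute cutoff %.4g), %d snapshots\n",
              x$spec$field, x$spec$mode, x$spec$value, x$cutoff,
              length(x$masks)))
  invisible(x)
}

#' Compare defective-space results across tank scales
#'
#' Sorts results by working volume and reports whether the defective
#' fraction grows with scale (the scale-up-limiting trend).
#'
#' @param results List of `defective_space` results at distinct scales.
#' @return Object of class `scale_comparison`: table of
#'   (scale_L, defective_volume_L, defective_fraction) sorted by scale and a
#'   `verdict` of `"increasing"`, `"non-increasing/flat"` or `"mixed"`.
#' @export
compare_scales <- function(results) {
  if (length(results) < 2L) stop("need >= 2 results at distinct scales")
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(label = as.character(r$tank_label), scale_L = r$scale_L,
               defective_volume_L = r$defective_volume_L,
               defective_fraction = r$defective_fraction)))
  if (anyDuplicated(tab$scale_L))
    stop("duplicate scales; label them or compare configurations directly")
  tab <- tab[order(tab$scale_L), ]
  d <- diff(tab$defective_fraction)
  verdict <- if (all(d > 0)) "increasing"
             else if (all(d <= 0)) "non-increasing/flat"
             else "mixed"
  structure(list(table = tab, verdict = verdict),
            class = "scale_comparison")
}

#' @export
print.scale_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("defective fraction vs scale:", x$verdict, "\n")
  invisible(x)
}
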