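# Field-container I/O (legacy VTK structured grid + CSV with unit headers),
# run configuration loading, and pipeline orchestration.

# FNV-1a hash of a serialized object, for provenance stamping
.config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.default_units <- c(velocity_r = "m s-1", velocity_z = "m s-1",
                    pressure = "Pa", k = "m2 s-2", epsilon = "m2 s-3",
                    mu_t = "Pa s", gamma_dot = "s-1", tau = "Pa",
                    omega = "s-1", lambda_k = "m", active = "bool",
                    defective = "bool", solid = "bool")

#' Build a field container
#'
#' A field container couples a grid with named cell arrays plus units and
#' provenance metadata; it is the interchange object written to VTK/CSV.
#'
#' @param grid A `structured_grid`.
#' @param arrays Named list of `nr x nz` matrices.
#' @param units Named character vector of units, one per array (defaults
#'   are filled in for the standard names).
#' @param provenance List with e.g. `stage`, `config_hash`.
#' @return Object of class `field_container`.
#' @export
field_container <- function(grid, arrays, units = NULL, provenance = list()) {
  stopifnot(inherits(grid, "structured_grid"), is.list(arrays),
            length(arrays) > 0, !is.null(names(arrays)))
  for (nm in names(arrays))
    if (!identical(dim(arrays[[nm]]), c(grid$nr, grid$nz)))
      stop(sprintf("array '%s' does not match the grid", nm))
  u <- .default_units[names(arrays)]
  names(u) <- names(arrays)
  if (!is.null(units)) u[names(units)] <- units
  if (any(is.na(u)))
    stop(sprintf("missing units for: %s",
                 paste(names(arrays)[is.na(u)], collapse = ", ")))
  provenance$version <- as.character(utils::packageVersion("turbtank"))
  structure(list(grid = grid, arrays = arrays, units = u,
                 provenance = provenance), class = "field_container")
}

#' Convert a flow state (plus optional derived fields) to a container
#'
#' @param state A `flow_state`.
#' @param derived Optional `derived_fields` appended under the fixed array
#'   names `mu_t`, `gamma_dot`, `tau`, `omega`, `lambda_k`.
#' @param provenance Provenance list.
#' @return A [field_container()].
#' @export
as_field_container <- function(state, derived = NULL, provenance = list()) {
  arrays <- list(velocity_r = state$u, velocity_z = state$w,
                 pressure = state$p, k = state$k, epsilon = state$eps)
  if (!is.null(derived))
    arrays <- c(arrays, derived[c("mu_t", "gamma_dot", "tau", "omega",
                                  "lambda_k")])
  field_container(state$grid, arrays, provenance = provenance)
}

#' Write a field container
#'
#' Legacy VTK structured-grid ASCII (`.vtk`) or CSV with a units header
#' row (`.csv`). Values are written with 17 significant digits so a
#' write/read round trip is bit-exact.
#'
#' @param container A [field_container()] (or a `flow_state`, converted
#'   automatically).
#' @param path Output path; the extension selects the format.
#' @export
write_fields <- function(container, path) {
  if (inherits(container, "flow_state"))
    container <- as_field_container(container)
  stopifnot(inherits(container, "field_container"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "vtk") .write_vtk(container, path)
  else if (ext == "csv") .write_fields_csv(container, path)
  else stop("unsupported format: use .vtk or .csv")
  invisible(path)
}

.num17 <- function(x) sprintf("%.17g", x)

.write_vtk <- function(cc, path) {
  g <- cc$grid
  con <- file(path, "w")
  on.exit(close(con))
  meta <- sprintf("turbtank %s units:%s planar:%d",
                  cc$provenance$config_hash %||% "",
                  paste(sprintf("%s=%s", names(cc$units),
                                gsub(" ", "_", cc$units)), collapse = ";"),
                  as.integer(g$planar))
  writeLines(c("# vtk DataFile Version 3.0", meta, "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", g$nr, g$nz),
               sprintf("POINTS %d double", g$nr * g$nz)), con)
  X <- matrix(g$r, g$nr, g$nz); Z <- matrix(g$z, g$nr, g$nz, byrow = TRUE)
  writeLines(paste(.num17(as.vector(X)), .num17(as.vector(Z)), "0"), con)
  writeLines(sprintf("POINT_DATA %d", g$nr * g$nz), con)
  for (nm in names(cc$arrays)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(.num17(as.vector(cc$arrays[[nm]])), con)
  }
}

.write_fields_csv <- function(cc, path) {
  g <- cc$grid
  tab <- grid_table(g)
  for (nm in names(cc$arrays))
    tab[[sprintf("%s (%s)", nm, cc$units[[nm]])]] <-
      as.vector(cc$arrays[[nm]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# turbtank fields config_hash=%s nr=%d nz=%d planar=%d",
                     cc$provenance$config_hash %||% "", g$nr, g$nz,
                     as.integer(g$planar)), con)
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
}

#' Read a field container
#'
#' Reads files written by [write_fields()], and foreign legacy-VTK
#' structured-grid files carrying at least velocity/k/epsilon arrays.
#' CSV field columns must carry a `name (unit)` header; unit-less field
#' columns are rejected unless `allow_unitless = TRUE`.
#'
#' @param path File path (.vtk or .csv).
#' @param allow_unitless Accept CSV field columns without a unit suffix.
#' @return A [field_container()].
#' @export
read_fields <- function(path, allow_unitless = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "vtk") .read_vtk(path)
  else if (ext == "csv") .read_fields_csv(path, allow_unitless)
  else stop("unsupported format: use .vtk or .csv")
}

.read_vtk <- function(path) {
  ln <- readLines(path)
  if (!grepl("^# vtk DataFile", ln[1]))
    stop(sprintf("%s line 1: not a legacy VTK file", path))
  dim_i <- grep("^DIMENSIONS", ln)[1]
  if (is.na(dim_i)) stop(sprintf("%s: DIMENSIONS record missing", path))
  dims <- as.integer(strsplit(ln[dim_i], "\\s+")[[1]][2:4])
  nr <- dims[1]; nz <- dims[2]
  pts_i <- grep("^POINTS", ln)[1]
  npts <- nr * nz
  coords <- do.call(rbind, strsplit(trimws(ln[(pts_i + 1):(pts_i + npts)]),
                                    "\\s+"))
  xs <- as.numeric(coords[, 1]); zs <- as.numeric(coords[, 2])
  r <- unique(xs)[seq_len(nr)]
  z <- zs[seq(1, npts, by = nr)]
  planar <- grepl("planar:1", ln[2])
  g <- .grid_from_centres(r, z, planar)
  units <- character()
  um <- regmatches(ln[2], regexpr("units:\\S+", ln[2]))
  if (length(um) == 1) {
    for (kv in strsplit(sub("units:", "", um), ";")[[1]]) {
      p <- strsplit(kv, "=")[[1]]
      if (length(p) == 2) units[p[1]] <- gsub("_", " ", p[2])
    }
  }
  arrays <- list()
  sc_i <- grep("^SCALARS", ln)
  for (si in sc_i) {
    nm <- strsplit(ln[si], "\\s+")[[1]][2]
    vals <- as.numeric(ln[(si + 2):(si + 1 + npts)])
    arrays[[nm]] <- matrix(vals, nr, nz)
  }
  if (length(arrays) == 0) stop(sprintf("%s: no SCALARS arrays", path))
  for (nm in names(arrays))
    if (is.na(.default_units[nm]) && !nm %in% names(units))
      units[nm] <- "unknown"
  field_container(g, arrays, units = units[names(units) %in% names(arrays)])
}

# reconstruct a uniform grid from cell-centre coordinates
.grid_from_centres <- function(r, z, planar) {
  nr <- length(r); nz <- length(z)
  dr <- if (nr > 1) r[2] - r[1] else 2 * r[1]
  dz <- if (nz > 1) z[2] - z[1] else 2 * z[1]
  Lx <- r[nr] + dr / 2; Lz <- z[nz] + dz / 2
  if (planar) return(planar_grid(Lx, Lz, nr, nz))
  r_faces <- seq(0, Lx, length.out = nr + 1)
  z_faces <- seq(0, Lz, length.out = nz + 1)
  ring <- pi * (r_faces[-1]^2 - r_faces[-(nr + 1)]^2)
  structure(list(planar = FALSE, nr = nr, nz = nz, dr = dr, dz = dz,
                 r = r, z = z, r_faces = r_faces, z_faces = z_faces,
                 vol = outer(ring, rep(dz, nz)),
                 boundary_tags = c(west = "axis", east = "wall",
                                   south = "wall", north = "liquid_surface"),
                 tank = NULL), class = "structured_grid")
}

.read_fields_csv <- function(path, allow_unitless) {
  first <- readLines(path, n = 1)
  skip <- if (grepl("^#", first)) 1L else 0L
  tab <- utils::read.csv(path, skip = skip, check.names = FALSE)
  need <- c("i", "j", "r_m", "z_m", "volume_m3")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: missing grid columns %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  nr <- max(tab$i); nz <- max(tab$j)
  planar <- skip == 1L && grepl("planar=1", first)
  g <- .grid_from_centres(sort(unique(tab$r_m)), sort(unique(tab$z_m)),
                          planar)
  arrays <- list(); units <- character()
  for (cn in setdiff(names(tab), need)) {
    m <- regmatches(cn, regexec("^(.*) \\((.*)\\)$", cn))[[1]]
    if (length(m) == 3) {
      nm <- m[2]; un <- m[3]
    } else if (allow_unitless) {
      nm <- cn; un <- "unknown"
    } else {
      stop(sprintf("%s: column '%s' has no unit header; use 'name (unit)'",
                   path, cn))
    }
    mat <- matrix(NA_real_, nr, nz)
    mat[cbind(tab$i, tab$j)] <- tab[[cn]]
    arrays[[nm]] <- mat
    units[nm] <- un
  }
  field_container(g, arrays, units = units)
}

#' Load and validate a run configuration
#'
#' YAML file with sections `tank`, `motion`, `fluid`, `closure`, `mesh`,
#' `threshold`, `matching` (all optional except `tank` or `preset`). SI
#' units throughout except speeds (mm/s) and strokes (mm). Unknown keys
#' are rejected with their location.
#'
#' @param path YAML file path.
#' @return Object of class `run_config` (validated nested list).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- list(
    tank = c("preset", "working_volume", "diameter", "aspect_ratio",
             "n_impellers", "disc_radius_frac", "label"),
    motion = c("kind", "set_speed", "stroke", "waveform", "n_snapshots",
               "in_phase"),
    fluid = c("rho", "mu"),
    closure = c("c_mu_mode", "c_mu", "sigma_k", "sigma_eps", "c2", "c1_min",
                "eps_denominator_mode", "k_min", "eps_min", "turbulence"),
    mesh = c("nr", "nz"),
    solver = c("max_iter", "tol", "relax_u", "relax_p", "relax_ke",
               "verbose"),
    threshold = c("field", "mode", "value"),
    matching = c("reference", "candidates", "weights", "band"),
    output = c("dir", "tau_mode", "averaging_mode"))
  for (sec in names(cfg)) {
    if (!sec %in% names(known))
      stop(sprintf("%s: unknown section '%s'", path, sec))
    extra <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (sec %in% c("matching") && length(extra) == 0) next
    if (length(extra) > 0)
      stop(sprintf("%s: unknown key(s) in [%s]: %s", path, sec,
                   paste(extra, collapse = ", ")))
  }
  if (is.null(cfg$tank)) stop(sprintf("%s: [tank] section required", path))
  structure(cfg, class = "run_config")
}

.cfg_call <- function(fun, args) do.call(fun, args[!vapply(args, is.null,
                                                           logical(1))])

#' Run the full analysis pipeline from a configuration
#'
#' Stages: build tank and grid, solve the impeller-position snapshot
#' ensemble, derive turbulence metrics and the cross-scale summary row,
#' quantify the defective turbulent flow space, and (if a `matching`
#' section is present) select the matching motion speed. Every output
#' embeds the configuration hash; the threshold criterion and shear-stress
#' mode are always echoed.
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory (default: `output$dir` in the config, or
#'   none: results returned only).
#' @param control Optional [solver_control()] override.
#' @return Object of class `pipeline_report`: summary rows (both averaging
#'   modes), `defective_space` result, optional `speed_match`, diagnostics,
#'   and the config hash.
#' @export
run_pipeline <- function(config, out_dir = NULL, control = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  hash <- .config_hash(unclass(config))
  motion <- .cfg_call(motion_spec, config$motion %||% list())
  tank <- .cfg_call(build_tank, c(config$tank, list(motion = motion)))
  mesh <- config$mesh %||% list()
  grid <- generate_grid(tank, nr = mesh$nr %||% 24L, nz = mesh$nz %||% 36L)
  fluid <- .cfg_call(fluid_properties, config$fluid %||% list())
  closure <- .cfg_call(closure_config, config$closure %||% list())
  if (is.null(control))
    control <- .cfg_call(solver_control, config$solver %||% list())
  ensemble <- run_snapshot_ensemble(grid, fluid, closure, motion, control)
  tau_mode <- config$output$tau_mode %||% "effective"
  rows_af <- summarize_ensemble(ensemble, tau_mode = tau_mode,
                                averaging_mode = "average-of-field")
  rows_fa <- summarize_ensemble(ensemble, tau_mode = tau_mode,
                                averaging_mode = "field-of-average")
  thr <- .cfg_call(threshold_spec, config$threshold %||% list())
  defect <- merge_defective(ensemble, grid, thr)
  match <- NULL
  if (!is.null(config$matching)) {
    ref <- as.data.frame(config$matching$reference)
    cand <- do.call(rbind, lapply(config$matching$candidates, as.data.frame))
    match <- match_speed(ref, cand,
                         weights = unlist(config$matching$weights %||%
                                            c(0.5, 0.5)),
                         band = config$matching$band %||% 0.10)
  }
  report <- structure(list(
    config_hash = hash, tank = tank, motion = motion,
    summary_average_of_field = rows_af,
    summary_field_of_average = rows_fa,
    defective = defect, match = match,
    threshold = thr, tau_mode = tau_mode,
    diagnostics = lapply(ensemble$states, `[[`, "diagnostics")),
    class = "pipeline_report")
  if (!is.null(out_dir %||% config$output$dir)) {
    dir <- out_dir %||% config$output$dir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_summary_csv(rows_af, file.path(dir, "summary.csv"))
    for (i in seq_along(ensemble$states)) {
      st <- ensemble$states[[i]]
      dv <- derive_fields(st, fluid, closure, tau_mode = tau_mode)
      cc <- as_field_container(st, dv,
                               provenance = list(stage = "solve",
                                                 config_hash = hash))
      cc$arrays$active <- defect$masks[[i]]$active + 0
      cc$arrays$defective <- defect$defective + 0
      write_fields(cc, file.path(dir, sprintf("snapshot%02d.vtk", i)))
    }
    writeLines(c(
      sprintf("config_hash: %s", hash),
      sprintf("threshold: %s %s %g (cutoff %g)", thr$field, thr$mode,
              thr$value, defect$cutoff),
      sprintf("tau_mode: %s", tau_mode),
      sprintf("defective_volume_L: %.6g", defect$defective_volume_L),
      sprintf("defective_fraction: %.6g", defect$defective_fraction),
      if (!is.null(match)) sprintf("selected_speed_mm_s: %g",
                                   match$selected_speed)),
      file.path(dir, "report.txt"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report (config %s)\n", x$config_hash))
  print(x$tank)
  cat("\ncycle summary (average-of-field, tau mode ", x$tau_mode, "):\n",
      sep = "")
  print(x$summary_average_of_field[
    x$summary_average_of_field$position == "cycle", ], row.names = FALSE)
  cat("\n")
  print(x$defective)
  if (!is.null(x$match)) { cat("\n"); print(x$match) }
  invisible(x)
}
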