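#' Export a mesh (with fields) in legacy VTK ASCII format
#'
#' Writes an unstructured grid of hexahedra with optional point data (e.g.
#' transmembrane potential, markers) and cell data (fiber vectors are written
#' automatically when present).
#'
#' @param mesh an `lqt8_mesh`
#' @param path output `.vtk` file
#' @param point_data named list of per-node scalar vectors
#' @param cell_data named list of per-element scalar vectors
#' @return the path, invisibly
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list(),
                           cell_data = list()) {
  stopifnot(inherits(mesh, "lqt8_mesh"), !is.null(mesh$elems))
  con <- file(path, "w")
  on.exit(close(con))
  n <- mesh$n_nodes; ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "lqt8sim mesh", "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$coords, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, 9 * ne), con)
  utils::write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  pd <- c(list(layer = as.integer(mesh$layer), depth = mesh$r), point_data)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(pd)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(pd[[nm]], digits = 9), con)
  }
  writeLines(sprintf("CELL_DATA %d", ne), con)
  if (!is.null(mesh$fibers)) {
    writeLines("VECTORS fiber double", con)
    utils::write.table(format(mesh$fibers, digits = 9), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(cell_data[[nm]], digits = 9), con)
  }
  invisible(path)
}

#' Write / read a run configuration
#'
#' Plain hierarchical key-value (YAML) run configuration with a versioned
#' schema; embeds the study defaults so presets can be layered over them.
#'
#' @param preset one of the nine setting names (see [lqt8_presets()])
#' @param scale `"cell0d"`, `"cable1d"`, `"slab2d"` or `"lv3d"`
#' @param resolution mesh resolution (element counts, scale-dependent)
#' @param solver a [solver_config()]
#' @param plan a [pvs_plan()]
#' @param output_dir run output directory
#' @return object of class `run_config`
#' @export
run_config <- function(preset = "WT-HET1",
                       scale = c("cable1d", "cell0d", "slab2d", "lv3d"),
                       resolution = NULL, solver = solver_config(),
                       plan = pvs_plan(), output_dir = "lqt8-run") {
  scale <- match.arg(scale)
  p <- lqt8_preset(preset)
  structure(list(schema = "lqt8sim/run-config/1", preset = p$name,
                 rho = p$rho, het_setting = p$het_setting, scale = scale,
                 resolution = resolution, solver = unclass(solver),
                 plan = unclass(plan), output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path YAML file path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$schema, "lqt8sim/run-config/1"))
    stop("unsupported run-config schema: ", x$schema)
  x$solver <- do.call(solver_config, x$solver[names(x$solver) %in%
                                                names(formals(solver_config))])
  x$plan <- do.call(pvs_plan, x$plan[names(x$plan) %in%
                                       names(formals(pvs_plan))])
  class(x) <- "run_config"
  x
}
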