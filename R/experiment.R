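# Reproducible experiment runs: strict YAML config validation, orchestration
# of the benchmark studies or an external tagged-mesh run, and serialization
# of tables, summaries, fields and a manifest.

run_config_schema <- list(
  experiment = c("stokes2d", "poiseuille", "external_mesh"),
  element_pair = c("P2P1", "P1P1_stabilized"),
  enforcement = c("strong", "nitsche", "default"),
  beta = "numeric",
  stabilization = "list",
  mesh = "list",
  fluid = "list",
  wss_methods = "character",
  output_dir = "character",
  random_seed = "numeric",
  problem_type = c("stokes", "navier_stokes"),
  pseudo_time = "list",
  regions = "list"
)

#' Validate a run configuration
#'
#' Checks the configuration (a named list, e.g. parsed from YAML) against the
#' published schema: unknown keys are rejected, enumerations are enforced,
#' and method/element pairings are checked (e.g. boundary-flux P2 requires a
#' P2 velocity space).
#'
#' @param config named list.
#' @return the validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), names(run_config_schema))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$experiment)) stop("config needs 'experiment'")
  config$experiment <- match.arg(config$experiment,
                                 run_config_schema$experiment)
  config$element_pair <- match.arg(config$element_pair %||% "P2P1",
                                   run_config_schema$element_pair)
  config$enforcement <- match.arg(config$enforcement %||% "default",
                                  run_config_schema$enforcement)
  if (config$enforcement == "default") {
    config$enforcement <- if (config$element_pair == "P1P1_stabilized")
      "nitsche" else "strong"
  }
  config$beta <- config$beta %||% 10
  config$wss_methods <- config$wss_methods %||%
    c("bflux_p1", "proj_p1", "proj_dg1", "proj_dg0")
  bad <- setdiff(config$wss_methods,
                 c("bflux_p1", "bflux_p2", "proj_p1", "proj_dg1", "proj_dg0"))
  if (length(bad)) stop("unknown wss method(s): ", paste(bad, collapse = ", "))
  if (config$element_pair == "P1P1_stabilized" &&
      "bflux_p2" %in% config$wss_methods) {
    stop("schema error: boundary-flux space P2 exceeds the P1 velocity degree")
  }
  if (config$experiment != "external_mesh") {
    lv <- config$mesh$levels
    if (is.null(lv) || length(lv) < 2L) {
      stop("config$mesh$levels must list at least two resolutions")
    }
  } else {
    if (is.null(config$mesh$path)) stop("external_mesh needs config$mesh$path")
  }
  config$mesh$family <- config$mesh$family %||% "uniform"
  if (!config$mesh$family %in% c("uniform", "boundary_layer")) {
    stop("mesh family must be 'uniform' or 'boundary_layer'")
  }
  config$random_seed <- config$random_seed %||% 1
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured experiment
#'
#' Executes the configured study and writes CSV tables, JSON summaries and a
#' manifest into the output directory.  Deterministic given the config.
#'
#' @param config a named list or path to a YAML file.
#' @param output_dir overrides `config$output_dir`.
#' @return invisibly, a list with the study/summary objects and file paths.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  out <- output_dir %||% config$output_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$random_seed))
  if (config$experiment %in% c("stokes2d", "poiseuille")) {
    study <- run_convergence_study(
      problem = config$experiment,
      element_pair = config$element_pair,
      levels = unlist(config$mesh$levels),
      wss_methods = config$wss_methods,
      mesh_family = config$mesh$family,
      beta = config$beta
    )
    files <- export_results(study, out)
    res <- list(study = study, files = files)
  } else {
    res <- run_external_mesh(config, out)
  }
  manifest <- list(
    config = config,
    package_version = as.character(utils::packageVersion("wssbench")),
    r_version = R.version.string
  )
  mf <- file.path(out, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  res$manifest <- mf
  invisible(res)
}

run_external_mesh <- function(config, out) {
  mesh <- read_tagged_mesh(config$mesh$path,
                           region_map = unlist(config$mesh$region_map))
  fl <- config$fluid
  if (is.null(fl$nu) && is.null(fl$mu)) {
    stop("external_mesh runs need fluid properties (the benchmark values are
 not applicable); supply fluid: {nu or mu, rho}")
  }
  props <- fluid_properties(dynamic_viscosity = fl$mu, density = fl$rho %||% 1,
                            kinematic_viscosity = fl$nu,
                            density_scaled = isTRUE(fl$density_scaled))
  cfg <- discretization_config(
    config$element_pair, config$enforcement, beta = config$beta,
    stress_form = "symmetric",
    stabilization = do.call(stabilization_weights,
                            config$stabilization %||% list()),
    cip_style = "interior_penalty",
    pseudo_time = config$pseudo_time %||% list())
  kind <- if (config$enforcement == "nitsche") "dirichlet_nitsche"
          else "dirichlet_strong"
  rg <- config$regions
  mean_v <- rg$mean_inflow %||% 0.5
  inflow <- parabolic_inflow(mesh, rg$inlet %||% "inlet", mean_v)
  args <- list()
  args[[rg$inlet %||% "inlet"]] <- list(kind = kind, value = inflow)
  noslip <- list(kind = kind, value = function(x) matrix(0, nrow(x), mesh$dim))
  args[[rg$wall %||% "wall"]] <- noslip
  if (!is.null(rg$dome)) args[[rg$dome]] <- noslip
  for (ot in rg$outlets %||% list("outlet")) args[[ot]] <- "do_nothing"
  bcs <- do.call(bc_spec, args)
  sol <- if ((config$problem_type %||% "navier_stokes") == "stokes") {
    solve_stokes(mesh, props, cfg, bcs)
  } else {
    solve_navier_stokes_steady(mesh, props, cfg, bcs)
  }
  summaries <- list()
  wall_tags <- c(rg$wall %||% "wall", rg$dome)
  for (mth in config$wss_methods) {
    wf <- switch(mth,
      bflux_p1 = boundary_flux_wss(sol, wall_tags, "P1"),
      bflux_p2 = boundary_flux_wss(sol, wall_tags, "P2"),
      proj_p1 = project_wss(sol, wall_tags, "P1"),
      proj_dg1 = project_wss(sol, wall_tags, "DG1"),
      proj_dg0 = project_wss(sol, wall_tags, "DG0"))
    if (!is.null(rg$dome) && !is.null(rg$parent_artery)) {
      summaries[[mth]] <- hemodynamic_summary(wf, rg$dome, rg$parent_artery)
    }
    write_wss_csv(wf, file.path(out, paste0("wss_", mth, ".csv")))
  }
  files <- character(0)
  if (length(summaries)) {
    sf <- file.path(out, "hemodynamics.json")
    jsonlite::write_json(lapply(summaries, unclass), sf, auto_unbox = TRUE,
                         digits = NA)
    files <- sf
  }
  list(solution = sol, summaries = summaries, files = files)
}

# parabolic profile on a circular inlet, fitted from the tagged facets
parabolic_inflow <- function(mesh, inlet_tag, mean_velocity) {
  tag <- resolve_tag(mesh, inlet_tag)
  sel <- mesh$facet_tags == tag
  cen <- colSums(mesh$boundary_centroid[sel, , drop = FALSE] *
                   mesh$boundary_measure[sel]) / sum(mesh$boundary_measure[sel])
  nrm <- colSums(mesh$boundary_normal[sel, , drop = FALSE] *
                   mesh$boundary_measure[sel])
  nrm <- nrm / sqrt(sum(nrm^2))
  verts <- unique(as.vector(mesh$boundary_facets[sel, , drop = FALSE]))
  rr <- sweep(mesh$vertices[verts, , drop = FALSE], 2, cen)
  rr <- rr - outer(as.vector(rr %*% nrm), nrm)
  R <- max(sqrt(rowSums(rr^2)))
  u_m <- 2 * mean_velocity
  function(x) {
    dx <- sweep(x, 2, cen)
    dx <- dx - outer(as.vector(dx %*% nrm), nrm)
    r2 <- rowSums(dx^2)
    mag <- u_m * pmax(0, 1 - r2 / R^2)
    -outer(mag, nrm)     # inflow opposes the outward normal
  }
}

#' Export convergence-study results
#'
#' Writes the per-level error table (with a trailing rates row) as CSV and a
#' JSON summary of the fitted rates.
#'
#' @param study a `convergence_study`.
#' @param dir output directory.
#' @return character vector of file paths.
#' @export
export_results <- function(study, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("%s_%s_%s", study$problem,
                  tolower(gsub("_stabilized", "", study$element_pair)),
                  study$mesh_family)
  csv <- file.path(dir, paste0(stem, ".csv"))
  tab <- study$table
  tab$seconds <- NULL      # timings vary run to run; tables stay reproducible
  rates_row <- tab[1, ]
  rates_row[] <- NA
  rates_row$level <- NA
  for (qn in names(study$rates)) rates_row[[qn]] <- study$rates[[qn]]
  out_tab <- rbind(cbind(kind = "error", tab),
                   cbind(kind = "rate", rates_row))
  utils::write.csv(out_tab, csv, row.names = FALSE)
  js <- file.path(dir, paste0(stem, "_rates.json"))
  jsonlite::write_json(as.list(study$rates), js, auto_unbox = TRUE, digits = NA)
  c(csv, js)
}

#' Re-import an exported convergence-study table
#'
#' @param csv path written by [export_results()].
#' @return list with `table` (error rows) and `rates` (named vector).
#' @export
import_results <- function(csv) {
  tab <- utils::read.csv(csv, check.names = FALSE)
  err <- tab[tab$kind == "error", setdiff(names(tab), "kind")]
  rr <- tab[tab$kind == "rate", ]
  qty <- grep("^(v$|p$|wss_)", names(tab), value = TRUE)
  rates <- stats::setNames(as.numeric(rr[1, qty]), qty)
  list(table = err, rates = rates)
}
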