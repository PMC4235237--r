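# End-to-end pipeline: configuration, the three-model comparison run, and
# the functions behind the command-line front end (inst/scripts/orthobone).

#' Default run configuration
#'
#' Encodes a complete reproducible comparison run: proxy geometry, seed
#' sets for both harmonic fields, the virtual-fill flag, per-region
#' material assignments, the model variants, a bite-like load case, ROI
#' band width, and the random seed.
#'
#' @param seed integer seed (geometry jitter).
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    geometry = list(arc_radius = 25, arc_angle = 120, outer_radius = 7,
                    cortical_thickness = 2, notch_depth = 3,
                    notch_center = 0.35, notch_extent = 30,
                    implant_length = 10, implant_diameter = 4.8,
                    implant_pos = 0.65, edge_length = 1.75,
                    jitter = 0.05),
    use_virtual = TRUE,
    long_seeds = list(end_cap_A = 0, end_cap_B = 1),
    rad_seeds = list(inner_interface = 0, outer_surface = 1),
    materials = list(
      isotropic = list(cortical = "bone_cortical_iso",
                       cancellous = "bone_cancellous_iso",
                       implant = "titanium"),
      orthotropic = list(cortical = "bone_cortical_ortho",
                         cancellous = "bone_cancellous_ortho",
                         implant = "titanium")),
    variants = c("isotropic", "orthotropic", "zoned"),
    n_zones = 4L,
    bcs = list(fixed = list(end_cap_A = "all", end_cap_B = "all"),
               forces = list(implant_top = c(20, 0, -150))),
    roi_distance = 1.0,
    nu_eff = 0.3,
    seed = as.integer(seed)), class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file.
#' @return A `run_config` (for the reader); invisibly the path (writer).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  # YAML turns vectors into lists; normalise numeric leaves
  base$variants <- unlist(base$variants)
  if (!is.null(base$bcs$forces))
    base$bcs$forces <- lapply(base$bcs$forces, unlist)
  if (!is.null(base$bcs$tractions))
    base$bcs$tractions <- lapply(base$bcs$tractions, unlist)
  base$seed <- as.integer(base$seed)
  base$n_zones <- as.integer(base$n_zones)
  class(base) <- "run_config"
  base
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

resolve_material <- function(x) {
  if (is.character(x)) material_db(x) else x
}

config_bcs <- function(config) {
  bc_spec(fixed = config$bcs$fixed,
          forces = config$bcs$forces %||% list(),
          tractions = config$bcs$tractions %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the isotropic / orthotropic / zoned comparison
#'
#' The full pipeline: generate (or accept) the proxy mesh, solve the
#' longitudinal and radial harmonic fields (the longitudinal one through
#' the virtual fill when enabled), build per-element material frames, and
#' for each requested variant assemble per-element stiffness, solve the
#' elastostatic problem under the configured load case, recover element
#' stress/strain, and summarise the six scalar measures over the cortical
#' and cancellous peri-implant ROIs.  Ends with the percent-change
#' comparison against the isotropic baseline.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param mesh optional pre-built [tet_mesh()]; by default generated from
#'   `config$geometry`.
#' @return List with `mesh`, `fields`, `frames`, `zoned` frames (if run),
#'   per-variant `models` (displacements, measures), `summaries`, and the
#'   `comparison` table.
#' @export
run_comparison <- function(config = default_run_config(), mesh = NULL) {
  tags <- region_tags()
  if (is.null(mesh)) {
    gp <- do.call(proxy_params, c(config$geometry, list(seed = config$seed)))
    mesh <- generate_proxy(gp)
  }
  use_virtual <- isTRUE(config$use_virtual) &&
    any(mesh$region == tags[["virtual"]])

  fields <- solve_field_pair(
    mesh,
    long_spec = do.call(dirichlet_spec, config$long_seeds),
    rad_spec = do.call(dirichlet_spec, config$rad_seeds),
    use_virtual = use_virtual)

  bone <- c(tags[["cortical"]], tags[["cancellous"]])
  long_regions <- if (use_virtual) c(bone, tags[["virtual"]]) else bone
  gl <- element_gradients(mesh, fields$phi_long, long_regions)
  gr <- element_gradients(mesh, fields$phi_rad, bone)
  ref <- NULL
  gp <- attr(mesh, "proxy_params")
  if (!is.null(gp))
    ref <- centerline_tangent(gp, element_centroids(mesh))
  frames <- build_frames(mesh, gl, gr, bone_regions = bone, reference = ref)

  bcs <- config_bcs(config)
  roi_cort <- select_roi(mesh, "implant_surface", config$roi_distance,
                         "cortical")
  roi_canc <- select_roi(mesh, "implant_surface", config$roi_distance,
                         "cancellous")

  run_variant <- function(label, frm) {
    mats <- if (label == "isotropic") config$materials$isotropic
            else config$materials$orthotropic
    mats <- lapply(mats, resolve_material)
    Ce <- element_stiffness(mesh, mats, frames = frm)
    sol <- solve_elasticity(mesh, Ce, bcs)
    fld <- recover_fields(mesh, sol$u, Ce, elem_ids = sol$elem_ids)
    sm_stress <- scalar_measures(fld$stress, "stress")
    sm_strain <- scalar_measures(fld$strain, "strain", nu_eff = config$nu_eff)
    summ <- rbind(
      summarize_region(sm_stress, sm_strain, mesh, roi_cort, label,
                       "cortical"),
      summarize_region(sm_stress, sm_strain, mesh, roi_canc, label,
                       "cancellous"))
    list(label = label, solution = sol, fields = fld,
         stress_measures = sm_stress, strain_measures = sm_strain,
         summary = summ)
  }

  models <- list()
  zoned <- NULL
  for (v in config$variants) {
    if (v == "isotropic") models[[v]] <- run_variant("isotropic", NULL)
    else if (v == "orthotropic") models[[v]] <- run_variant("orthotropic",
                                                            frames)
    else if (v == "zoned") {
      zoned <- zoned_frames(mesh, fields$phi_long, frames,
                            n_zones = config$n_zones)
      models[[v]] <- run_variant("zoned", zoned)
    } else stop("unknown variant: ", v)
  }

  summaries <- do.call(rbind, lapply(models, `[[`, "summary"))
  rownames(summaries) <- NULL
  comparison <- if ("isotropic" %in% names(models))
    compare_models(summaries, baseline = "isotropic") else summaries

  list(mesh = mesh, fields = fields, frames = frames, zoned = zoned,
       roi = list(cortical = roi_cort, cancellous = roi_canc),
       models = models, summaries = summaries, comparison = comparison)
}
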