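#' Pipeline configuration
#'
#' Nested configuration for the whole pipeline with the muscle-section
#' defaults: diffusion `tau = 1`, `sigma = 1e-4` px, `rho = 4` px,
#' `c1 = 1e-10`, `c2 = 1e-3`, 20 steps; minimum region area 750 px, closing
#' disk radius 4 px, marker erosion radius 10 px; pixel scale 0.899 um/px.
#' `validate_config()` rejects unknown keys and checks every field against
#' its invariants; [load_config]/[save_config] round-trip the configuration
#' through YAML.
#'
#' @return A nested named list of class `myoseg_config`.
#' @examples
#' cfg <- default_config()
#' cfg$ced$rho
#' @export
default_config <- function() {
  structure(list(
    image = list(px_scale_um = 0.899),
    preprocess = list(nmf_seed = 101L, nmf_max_iter = 1000L, nmf_tol = 1e-4,
                      clahe_tiles = c(8L, 8L), clahe_clip = 0.01,
                      clahe_bins = 256L),
    ced = list(tau = 1, sigma = 1e-4, rho = 4, c1 = 1e-10, c2 = 1e-3,
               n_steps = 20L, stable_tau = 0.25),
    postprocess = list(t_area = 750L, closing_radius = 4L,
                       erosion_radius = 10L),
    metrics = list(encompass_frac = 0.5, min_component_px = 5L,
                   vc_scale = 1000, cdf_grid = 512L),
    synth = list(height = 512L, width = 512L, n_seeds = 36L,
                 boundary_width = 5, noise_level = "low",
                 weak_boundary_frac = 0, jitter = 0.35, nucleus_frac = 0.5)
  ), class = "myoseg_config")
}

#' @rdname default_config
#' @param cfg a configuration list to validate (unknown keys are an error).
#' @export
validate_config <- function(cfg) {
  ref <- default_config()
  if (!is.list(cfg)) stop("config must be a list")
  extra_sections <- setdiff(names(cfg), names(ref))
  if (length(extra_sections))
    stop("unknown config section(s): ", paste(extra_sections, collapse = ", "))
  merged <- unclass(ref)
  for (sec in names(cfg)) {
    extra <- setdiff(names(cfg[[sec]]), names(ref[[sec]]))
    if (length(extra))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(extra, collapse = ", ")))
    merged[[sec]] <- utils::modifyList(merged[[sec]], cfg[[sec]])
  }
  with(merged$image, stopifnot(px_scale_um > 0))
  with(merged$preprocess, stopifnot(nmf_max_iter >= 1, nmf_tol > 0,
                                    length(clahe_tiles) == 2,
                                    all(clahe_tiles >= 1),
                                    clahe_clip > 0, clahe_clip <= 1,
                                    clahe_bins >= 2))
  with(merged$ced, stopifnot(tau > 0, sigma >= 0, rho > 0, c1 > 0, c1 < 1,
                             c2 > 0, n_steps >= 1, stable_tau > 0))
  with(merged$postprocess, stopifnot(t_area >= 1, closing_radius >= 1,
                                     erosion_radius >= 1))
  with(merged$metrics, stopifnot(encompass_frac > 0, encompass_frac <= 1,
                                 min_component_px >= 1, vc_scale > 0,
                                 cdf_grid >= 16))
  with(merged$synth, stopifnot(height >= 64, width >= 64, n_seeds >= 4,
                               boundary_width >= 1,
                               noise_level %in% c("low", "medium", "high"),
                               weak_boundary_frac >= 0,
                               weak_boundary_frac <= 1))
  structure(merged, class = "myoseg_config")
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname default_config
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
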