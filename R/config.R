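# Unified run configuration: one YAML with per-section blocks.

#' Default run configuration
#'
#' A fully serializable list with sections `geometry`, `phantom`, `sim`,
#' and `train`; every command resolves its settings from such a list, and
#' every output directory records the configuration that produced it, so a
#' saved configuration reproduces a desk-scale run exactly.
#'
#' @return Nested list of class `usgan_run_config`.
#' @export
run_config <- function() {
  structure(list(
    geometry = list(fov_deg = 70, depth_cm = 15, probe_radius_cm = 4,
                    n_axial = 64L, n_lines = 64L),
    phantom = list(n_axial = 64L, n_lines = 64L),
    sim = unclass(sim_config()),
    train = unclass(train_config()),
    seed = 1L
  ), class = "usgan_run_config")
}

#' Read / write a run configuration as YAML
#'
#' `load_config` merges the file over the defaults of [run_config()], so
#' partial files are valid.
#'
#' @param path YAML path.
#' @param cfg A run configuration.
#' @export
load_config <- function(path) {
  base <- run_config()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && is.list(base[[sec]])) {
      for (k in names(user[[sec]])) base[[sec]][[k]] <- user[[sec]][[k]]
    } else base[[sec]] <- user[[sec]]
  }
  base
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(strip_classes(cfg), path)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x$cache <- NULL
    lapply(x, strip_classes)
  } else x
}

# Stable short hash of a configuration (for manifests): md5 of the
# canonical YAML serialization.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(strip_classes(cfg), tmp)
  unname(tools::md5sum(tmp))
}

resolve_geometry <- function(cfg) {
  g <- cfg$geometry
  fan_geometry(fov_deg = g$fov_deg, depth_cm = g$depth_cm,
               probe_radius_cm = g$probe_radius_cm,
               n_axial = g$n_axial, n_lines = g$n_lines,
               out_shape = g$out_shape)
}

resolve_phantom <- function(cfg) do.call(phantom_config, cfg$phantom)

resolve_sim <- function(cfg) do.call(sim_config, cfg$sim[
  intersect(names(cfg$sim), names(formals(sim_config)))])

resolve_train <- function(cfg) do.call(train_config, cfg$train[
  intersect(names(cfg$train), names(formals(train_config)))])
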