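#' Analysis configuration
#'
#' Collects every convention the downstream statistics depend on, so each run
#' records how its numbers were obtained. Two conventions in particular have
#' to be pinned per run because both are in common use: the normalizer of the
#' barycenter distance (TAD radius of gyration vs half the TAD major axis,
#' the latter being the sampling radius R of the analytic random null) and
#' the central tendency of the radial density distribution (median vs mean).
#'
#' @section Fields:
#' \describe{
#'   \item{convention}{barycenter-distance normalizer, `"half_major_axis"`
#'     (default; the null derivation's R) or `"rg"`.}
#'   \item{rdd_tendency}{`"median"` (default) or `"mean"`.}
#'   \item{rdd_normalizer}{`"rg"` (default) or `"half_major_axis"`.}
#'   \item{dimensionality}{`"2d_projected"` (default) or `"3d"`.}
#'   \item{segmentation}{list: `method` (`"dbscan"` or `"voronoi"`),
#'     Voronoi `density_factor_tad` (3), `density_factor_focus` (20),
#'     `density_factor_protein` (3.5), `min_detections` (10), and optional
#'     explicit DBSCAN `r`, `n_min`, `r_ref` (auto-derived when `NULL`).}
#'   \item{simulate}{list of generator settings: `preset`, `n_cells`,
#'     `n_tad_localizations`, `n_foci`, `locs_per_focus`, `tad_radius_nm`,
#'     `focus_diameter_nm`, `precision_nm` (lateral, axial),
#'     `background_per_channel`.}
#'   \item{seed}{integer; every stochastic stage derives its streams from it.}
#'   \item{out_dir}{directory for pipeline outputs.}
#' }
#'
#' @param ... named overrides of the defaults, nested lists merged per key.
#' @return a validated list of class `"analysis_config"`.
#' @export
analysis_config <- function(...) {
  cfg <- modifyList(default_config(), list(...))
  validate_config(cfg)
}

default_config <- function() {
  list(
    convention = "half_major_axis",
    rdd_tendency = "median",
    rdd_normalizer = "rg",
    dimensionality = "2d_projected",
    segmentation = list(
      method = "voronoi",
      density_factor_tad = 3,
      density_factor_focus = 20,
      density_factor_protein = 3.5,
      min_detections = 10,
      r = NULL, n_min = NULL, r_ref = NULL
    ),
    simulate = list(
      preset = "g1_uniform",
      n_cells = 16,
      n_tad_localizations = 2500,
      n_foci = 7,
      locs_per_focus = 200,
      tad_radius_nm = 283,
      focus_diameter_nm = 30,
      precision_nm = c(20, 50),
      background_per_channel = 50,
      n_frames = 2000L
    ),
    register = list(
      drift_nm = c(80, -40),
      block_size = 200,
      bead_interval = 100
    ),
    seed = 1L,
    out_dir = "results/run"
  )
}

.config_enums <- list(
  convention = c("half_major_axis", "rg"),
  rdd_tendency = c("median", "mean"),
  rdd_normalizer = c("rg", "half_major_axis"),
  dimensionality = c("2d_projected", "3d")
)

validate_config <- function(cfg) {
  for (key in names(.config_enums)) {
    allowed <- .config_enums[[key]]
    if (!is.character(cfg[[key]]) || length(cfg[[key]]) != 1 || !cfg[[key]] %in% allowed)
      stop("config key '", key, "' must be one of: ", paste(allowed, collapse = ", "))
  }
  if (!cfg$segmentation$method %in% c("dbscan", "voronoi"))
    stop("config key 'segmentation.method' must be one of: dbscan, voronoi")
  if (!cfg$simulate$preset %in% c("g1_uniform", "g1s_peripheral", "interior"))
    stop("config key 'simulate.preset' must be one of: g1_uniform, g1s_peripheral, interior")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "analysis_config"
  cfg
}

#' Load an analysis configuration from YAML
#'
#' Absent keys take package defaults; enum values are validated with the
#' allowed set named in the error. The fully resolved configuration is
#' echoed with [message()] so run logs capture it.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return an `analysis_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- validate_config(modifyList(default_config(), user))
  message("resolved config: ", jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"))
  cfg
}
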