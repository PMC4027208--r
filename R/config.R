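#' Run configuration files
#'
#' YAML configuration with a flat, schema-validated key tree; unknown
#' keys anywhere are rejected so typos never silently change a run.
#' Units are fixed globally (kcal/mol, \enc{Å}{A}, ps, K, rad). The
#' sections and their keys:
#'
#' \describe{
#'   \item{system}{`type` (`double_well`, `hopping` or `quadruplex`)
#'     plus the parameters of [make_double_well()], [hopping_spec()] or
#'     [build_toy_quadruplex()].}
#'   \item{metad}{[wt_params()] fields plus `bias_cvs`.}
#'   \item{sampler}{[langevin_params()] fields plus `stride` and `x0`.}
#'   \item{walls}{list of [wall_spec()] entries (`cv`, `limit`, `k`).}
#'   \item{analysis}{`bound`, `unbound`, `bins`, `depth_cutoff`,
#'     `n_blocks`, `reweight_cv`, `checkpoints`.}
#'   \item{output}{`dir`, `prefix`.}
#' }
#'
#' @param path YAML file.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

config_schema <- list(
  seed = NULL,
  system = c("type", "barrier", "separation", "asymmetry", "offsets",
             "barrier_ab_b", "plateau", "widths", "centers",
             "beads_per_strand", "rise", "side"),
  metad = c("temperature", "delta_t", "w0", "tau", "widths", "grid_min",
            "grid_max", "grid_bins", "bias_cvs"),
  sampler = c("temperature", "friction", "timestep", "mass", "nsteps",
              "seed", "stride", "x0"),
  walls = NULL,
  analysis = c("bound", "unbound", "bins", "depth_cutoff", "n_blocks",
               "reweight_cv", "checkpoints"),
  output = c("dir", "prefix")
)

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop_param("config must be a key-value mapping")
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop_param("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(cfg), names(config_schema))) {
    allowed <- config_schema[[sec]]
    if (is.null(allowed)) next
    unknown <- setdiff(names(cfg[[sec]]), allowed)
    if (length(unknown))
      stop_param("unknown key(s) in '", sec, "': ",
                 paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$walls)) {
    for (w in cfg$walls) {
      unknown <- setdiff(names(w), c("cv", "limit", "k"))
      if (length(unknown))
        stop_param("unknown key(s) in wall entry: ",
                   paste(unknown, collapse = ", "))
      if (is.null(w$cv)) stop_param("wall entry missing 'cv'")
    }
  }
  if (is.null(cfg$system) || is.null(cfg$system$type))
    stop_param("config must declare system type")
  if (!cfg$system$type %in% c("double_well", "hopping", "quadruplex"))
    stop_param("unknown system type: ", cfg$system$type)
  structure(cfg, class = c("run_config", "list"))
}

config_potential <- function(cfg) {
  s <- cfg$system
  switch(s$type,
    double_well = make_double_well(s$barrier %||% 6, s$separation %||% 4,
                                   s$asymmetry %||% 0),
    hopping = {
      spec_args <- list()
      if (!is.null(s$offsets)) spec_args$offsets <-
          c(Ab = s$offsets$Ab, B = s$offsets$B)
      if (!is.null(s$barrier)) spec_args$barrier <- s$barrier
      if (!is.null(s$barrier_ab_b)) spec_args$barrier_ab_b <- s$barrier_ab_b
      if (!is.null(s$plateau)) spec_args$plateau <- s$plateau
      if (!is.null(s$centers))
        spec_args$centers <- lapply(s$centers, as.numeric)
      if (!is.null(s$widths))
        spec_args$widths <- c(Aa = s$widths[[1]], Ab = s$widths[[2]],
                              B = s$widths[[3]])
      make_hopping_landscape(do.call(hopping_spec, spec_args))
    },
    quadruplex = stop_param("system type 'quadruplex' is a structure, ",
                            "not a sampleable landscape"))
}

config_structure <- function(cfg) {
  s <- cfg$system
  if (s$type != "quadruplex") stop_param("system type is not 'quadruplex'")
  build_toy_quadruplex(s$beads_per_strand %||% 6, s$rise %||% 3.4,
                       s$side %||% 8)
}

config_wt <- function(cfg) {
  m <- cfg$metad %||% list()
  wt_params(temperature = m$temperature %||% 300,
            delta_t = m$delta_t %||% 2700,
            w0 = m$w0 %||% 0.5, tau = m$tau %||% 1,
            widths = if (!is.null(m$widths)) as.numeric(m$widths),
            grid_min = m$grid_min, grid_max = m$grid_max,
            grid_bins = m$grid_bins)
}

config_ld <- function(cfg, seed_override = NULL) {
  s <- cfg$sampler %||% list()
  seed <- seed_override %||% s$seed %||% cfg$seed
  if (is.null(seed))
    stop_param("a seed is required: set sampler.seed or pass --seed")
  langevin_params(temperature = s$temperature %||% 300,
                  friction = s$friction %||% 50,
                  timestep = s$timestep %||% 0.02,
                  mass = s$mass %||% 40,
                  nsteps = s$nsteps %||% 1e5,
                  seed = seed)
}

config_walls <- function(cfg) {
  if (is.null(cfg$walls)) return(NULL)
  lapply(cfg$walls, function(w)
    wall_spec(w$cv, w$limit %||% 27.0, w$k %||% 10))
}

config_regions <- function(cfg) {
  a <- cfg$analysis %||% list()
  binding_regions(as.numeric(a$bound %||% c(7, 14)),
                  as.numeric(a$unbound %||% c(24, 26)))
}
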