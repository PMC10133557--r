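# Declarative run configuration: YAML/JSON in, fully-resolved config out.
# Unknown keys are rejected (typo safety) and every violation is reported at
# once, not just the first.

config_defaults <- function() {
  list(
    geometry = list(
      outer_diameter = 3.5,        # mm
      wall_thickness = 0.5,        # mm
      height = 5.0,                # mm
      voxel_size = 0.25,           # mm (production-scale runs use 0.08)
      eccentricity = 0.25,         # canal offset / wall thickness
      thickness_noise_sd = 0.03,   # mm
      mask_path = NULL             # optional segmented mask overrides the generator
    ),
    material = list(
      E_L = 13498, E_T = 11025,    # MPa
      nu_LT = 0.3, nu_TT = 0.3,
      G_LT = NULL                  # NULL -> E_L / (2 (1 + nu_LT))
    ),
    damage = list(
      epsilon_f = 0.043,
      D_max = 0.9,
      residual_fraction = 0.1
    ),
    simulation = list(
      total_displacement = 0.5,    # mm
      n_increments = 100,
      criterion = "min_principal",
      stagger_tolerance = 1e-3,
      max_stagger_iterations = 25,
      stiffness_floor = 1e-4,
      load_drop_fraction = 0.2,
      percolation_check = TRUE,
      bisection_fraction = 0.05
    ),
    boundary = list(
      top = "stick_platen",
      bottom = "frictionless_platen"
    ),
    output = list(
      dir = "results",
      write_vtu = TRUE
    ),
    seed = 1L
  )
}

# recursive merge of user values over defaults, collecting unknown keys
merge_config <- function(defaults, user, path = "") {
  unknown <- character(0)
  for (k in names(user)) {
    full <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(defaults)) {
      unknown <- c(unknown, full)
      next
    }
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (is.list(user[[k]])) {
        sub <- merge_config(defaults[[k]], user[[k]], full)
        defaults[[k]] <- sub$config
        unknown <- c(unknown, sub$unknown)
      } else if (!is.null(user[[k]])) {
        unknown <- c(unknown, paste0(full, " (expected a section)"))
      }
    } else {
      val <- user[[k]]
      # keep the default's storage mode so round-tripped configs (YAML/JSON
      # integers vs doubles) resolve and hash identically
      if (!is.null(val) && is.numeric(val) && is.numeric(defaults[[k]])) {
        storage.mode(val) <- storage.mode(defaults[[k]])
      }
      defaults[k] <- list(val)    # [ ] keeps explicit NULLs
    }
  }
  list(config = defaults, unknown = unknown)
}

validate_config_values <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  g <- cfg$geometry
  chk(g$outer_diameter > 2 * g$wall_thickness && g$wall_thickness > 0,
      "geometry: need outer_diameter > 2 * wall_thickness > 0")
  chk(g$voxel_size > 0 && g$voxel_size <= g$wall_thickness / 2,
      "geometry.voxel_size: must lie in (0, wall_thickness / 2]")
  chk(g$height >= g$voxel_size, "geometry.height: must be >= voxel_size")
  chk(g$eccentricity >= 0 && g$eccentricity < 1,
      "geometry.eccentricity: must lie in [0, 1)")
  chk(g$thickness_noise_sd >= 0,
      "geometry.thickness_noise_sd: must be >= 0")
  m <- cfg$material
  chk(m$E_L > 0 && m$E_T > 0, "material.E_L, material.E_T: must be > 0")
  chk(m$nu_LT > -1 && m$nu_LT < 0.5, "material.nu_LT: must lie in (-1, 0.5)")
  chk(m$nu_TT > -1 && m$nu_TT < 0.5, "material.nu_TT: must lie in (-1, 0.5)")
  d <- cfg$damage
  chk(d$epsilon_f > 0 && d$epsilon_f < 1,
      "damage.epsilon_f: must lie in (0, 1)")
  chk(d$D_max > 0 && d$D_max < 1, "damage.D_max: must lie in (0, 1)")
  chk(abs(d$residual_fraction - (1 - d$D_max)) < 1e-12,
      "damage.residual_fraction: must equal 1 - D_max")
  s <- cfg$simulation
  chk(s$total_displacement > 0,
      "simulation.total_displacement: must be > 0")
  chk(s$n_increments >= 1, "simulation.n_increments: must be >= 1")
  chk(s$criterion %in% c("min_principal", "equivalent"),
      "simulation.criterion: must be 'min_principal' or 'equivalent'")
  chk(s$stiffness_floor > 0 && s$stiffness_floor < 1 - d$D_max,
      "simulation.stiffness_floor: must lie in (0, 1 - D_max)")
  chk(is.null(s$load_drop_fraction) ||
        (s$load_drop_fraction > 0 && s$load_drop_fraction < 1),
      "simulation.load_drop_fraction: must lie in (0, 1) or be null")
  b <- cfg$boundary
  chk(b$top %in% c("stick_platen", "frictionless_platen"),
      "boundary.top: must be 'stick_platen' or 'frictionless_platen'")
  chk(identical(b$bottom, "frictionless_platen"),
      "boundary.bottom: only 'frictionless_platen' is supported")
  bad
}

#' Load and resolve a run configuration
#'
#' Reads a YAML or JSON configuration (chosen by extension; an empty file
#' yields all defaults), merges it over the documented defaults, rejects
#' unknown keys, validates every value, and returns the fully-resolved
#' configuration with a content hash.  All schema violations are reported in
#' one error.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for pure
#'   defaults.
#' @return Object of class `run_config`: the resolved configuration list
#'   with attribute `hash`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(path)
    } else if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      stop("unsupported config format '", ext, "' (use YAML or JSON)",
           call. = FALSE)
    }
    if (is.null(user)) user <- list()
  }
  resolve_config(user)
}

#' Resolve an in-memory configuration list
#'
#' @param user Named list of overrides (possibly empty).
#' @return Object of class `run_config`.
#' @export
resolve_config <- function(user = list()) {
  mg <- merge_config(config_defaults(), user)
  errs <- character(0)
  if (length(mg$unknown)) {
    errs <- c(errs, paste0("unknown key: ", mg$unknown))
  }
  cfg <- mg$config
  # derived default
  if (is.null(cfg$material$G_LT)) {
    cfg$material$G_LT <- cfg$material$E_L / (2 * (1 + cfg$material$nu_LT))
  }
  if (length(errs) == 0) errs <- validate_config_values(cfg)
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config", hash = config_hash(cfg))
}

#' Configuration reference: every key, its default and units
#'
#' @return A data.frame with one row per configuration key (`key`,
#'   `default`, `units`), generated from the live defaults so it cannot
#'   drift from the code.
#' @export
config_reference <- function() {
  units <- c(
    "geometry.outer_diameter" = "mm", "geometry.wall_thickness" = "mm",
    "geometry.height" = "mm", "geometry.voxel_size" = "mm",
    "geometry.eccentricity" = "fraction of wall thickness",
    "geometry.thickness_noise_sd" = "mm", "geometry.mask_path" = "path",
    "material.E_L" = "MPa", "material.E_T" = "MPa",
    "material.nu_LT" = "-", "material.nu_TT" = "-", "material.G_LT" = "MPa",
    "damage.epsilon_f" = "strain", "damage.D_max" = "-",
    "damage.residual_fraction" = "-",
    "simulation.total_displacement" = "mm", "simulation.n_increments" = "-",
    "simulation.criterion" = "-", "simulation.stagger_tolerance" = "-",
    "simulation.max_stagger_iterations" = "-",
    "simulation.stiffness_floor" = "-",
    "simulation.load_drop_fraction" = "-",
    "simulation.percolation_check" = "-",
    "simulation.bisection_fraction" = "-",
    "boundary.top" = "-", "boundary.bottom" = "-",
    "output.dir" = "path", "output.write_vtu" = "-", "seed" = "-")
  flat <- unlist(lapply(config_defaults(), function(x) {
    if (is.list(x)) lapply(x, function(v) if (is.null(v)) "NULL" else v)
    else x
  }))
  keys <- names(flat)
  data.frame(key = keys,
             default = vapply(flat, function(v) paste(v, collapse = " "), ""),
             units = unname(units[keys]),
             row.names = NULL)
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(unclass(cfg)), tf)
  unname(tools::md5sum(tf))
}

# constructors from a resolved config section
constants_from_config <- function(cfg) {
  m <- cfg$material
  elastic_constants(m$E_L, m$E_T, m$nu_LT, m$nu_TT, m$G_LT)
}

law_from_config <- function(cfg) {
  d <- cfg$damage
  damage_law(d$epsilon_f, d$D_max, d$residual_fraction)
}

sim_config_from_config <- function(cfg) {
  s <- cfg$simulation
  simulation_config(s$total_displacement, s$n_increments, s$criterion,
                    s$stagger_tolerance, s$max_stagger_iterations,
                    s$stiffness_floor, s$load_drop_fraction,
                    s$percolation_check, s$bisection_fraction)
}

bcs_from_config <- function(cfg) {
  boundary_conditions(cfg$boundary$top, cfg$boundary$bottom,
                      -cfg$simulation$total_displacement)
}

specimen_from_config <- function(cfg) {
  g <- cfg$geometry
  if (!is.null(g$mask_path)) return(read_voxel_mask(g$mask_path))
  generate_hollow_cylinder(g$outer_diameter, g$wall_thickness, g$height,
                           g$voxel_size, g$eccentricity,
                           g$thickness_noise_sd, cfg$seed)
}

#' Run one complete simulation from a resolved configuration
#'
#' Convenience driver tying the modules together: builds (or reads) the
#' specimen, meshes it, runs the progressive-failure simulation, and
#' summarizes.
#'
#' @param cfg A [load_config()] / [resolve_config()] result.
#' @param criterion Optional criterion override (`"min_principal"` or
#'   `"equivalent"`; overrides the configuration value).
#' @param verbose Print progress.
#' @return List with `spec`, `mesh`, `result`, `summary`, `config`.
#' @export
run_from_config <- function(cfg, criterion = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  spec <- specimen_from_config(cfg)
  mesh <- voxels_to_mesh(spec)
  res <- run_compression(mesh, constants_from_config(cfg),
                         law_from_config(cfg),
                         criterion = criterion,
                         config = sim_config_from_config(cfg),
                         bcs = bcs_from_config(cfg), verbose = verbose)
  list(spec = spec, mesh = mesh, result = res,
       summary = summarize_fracture(res, mesh), config = cfg)
}
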