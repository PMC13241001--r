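#' @title Run configuration
#' @description
#' One flat, human-readable YAML file governs every module hyperparameter
#' and seed. [defaultConfig()] is the single source of truth for keys,
#' types and defaults; [loadConfig()] validates a user file against it
#' (unknown keys and type mismatches are rejected with the offending key
#' path).
#' @name config
NULL

#' Default run configuration
#'
#' Returns the full nested configuration with the package defaults. The
#' `simulate` block fixes the synthetic benchmark conditions (192 x 192
#' scenes, 20 particles of radius 8 px, dark contrast -1, raw SNR -3 dB);
#' the remaining blocks hold network and training hyperparameters, all of
#' which are ordinary config choices rather than code constants.
#'
#' @return nested named list
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    simulate = list(
      height = 192, width = 192, n_particles = 20, radius = 8,
      min_distance = 20, edge_softness = 1, contrast = -1,
      background = "flat", target_snr_db = -3,
      n_train = 100, n_test = 20
    ),
    denoiser = list(
      n_levels = 3, base_channels = 16, channel_growth = 2,
      activation = "relu", residual = TRUE
    ),
    sfi = list(
      enabled = TRUE, attn_max_tokens = 32
    ),
    apg = list(
      n_levels = 3, base_channels = 16, channel_growth = 2,
      fpn_channels = 32, grid_stride = 8, head_hidden = 64,
      coarse_scale = 2, clamp_offsets = TRUE
    ),
    loss = list(
      gamma = 0.05, alpha = 0.5,
      lambda_reg = 2, lambda_cls = 1, lambda_seg = 1,
      focal_alpha = 0.25, focal_gamma = 2, conf_eps = 1e-7
    ),
    promptseg = list(
      patch_size = 8, embed_dim = 64, depth = 3, n_heads = 4,
      mona_dim = 16, lambda_f = 20
    ),
    train = list(
      denoiser_steps = 300, denoiser_lr = 0.002, denoiser_patch = 64,
      apg_steps = 250, apg_lr = 0.001, apg_crop = 96,
      joint_steps = 40, joint_lr = 0.0003,
      joint_denoise_weight = 1, joint_apg_weight = 1,
      seg_steps = 200, seg_lr = 0.001
    ),
    pick = list(
      conf_threshold = 0.5, prob_threshold = 0.5,
      min_area_frac = 0.3, min_distance_frac = 0.8,
      max_prompts = 64
    ),
    eval = list(
      iou_threshold = 0.5, box_shape = "square"
    )
  )
}

checkAgainst <- function(value, ref, path) {
  if (is.list(ref)) {
    if (!is.list(value)) stop("config key '", path, "' must be a block")
    unknown <- setdiff(names(value), names(ref))
    if (length(unknown)) {
      stop("unknown config key(s): ",
           paste(paste(path, unknown, sep = "."), collapse = ", "))
    }
    out <- ref
    for (nm in names(value)) {
      out[[nm]] <- checkAgainst(value[[nm]], ref[[nm]],
                                if (nzchar(path)) paste(path, nm, sep = ".") else nm)
    }
    return(out)
  }
  if (is.numeric(ref) && !is.numeric(value))
    stop("config key '", path, "' must be numeric, got ", class(value)[1L])
  if (is.character(ref) && !is.character(value))
    stop("config key '", path, "' must be character, got ", class(value)[1L])
  if (is.logical(ref) && !is.logical(value))
    stop("config key '", path, "' must be logical, got ", class(value)[1L])
  value
}

#' Load and validate a configuration file
#'
#' Reads a YAML file and merges it over [defaultConfig()]. Unknown keys and
#' type mismatches raise errors naming the key path.
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @return validated nested config list
#' @export
loadConfig <- function(path = NULL) {
  if (is.null(path)) return(defaultConfig())
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  checkAgainst(user, defaultConfig(), "")
}

#' Save a configuration to YAML
#' @param config nested config list
#' @param path output path
#' @return invisibly, `path`
#' @export
saveConfig <- function(config, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  yaml::write_yaml(config, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Scene parameters from a config block
#' @param config full config list
#' @param seed scene seed
#' @return a [SceneParams-class]
#' @export
configSceneParams <- function(config, seed = config$seed) {
  s <- config$simulate
  SceneParams(height = s$height, width = s$width, nParticles = s$n_particles,
              radius = s$radius, minDistance = s$min_distance,
              edgeSoftness = s$edge_softness, contrast = s$contrast,
              background = s$background, seed = seed)
}
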