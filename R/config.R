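# Declarative run configuration.  A run config is a nested named list
# validated against a typed schema: unknown keys are fatal (silent typos in
# training configs are costly), every leaf is overridable from the command
# line as --key.subkey=value with YAML scalar parsing, and configs
# round-trip losslessly through YAML.

# Schema leaves: list(type=..., default=..., choices=..., min=...).
# type "free" accepts any YAML value (used for backbone kwargs);
# type "transforms" is the ordered preprocessing list.
.leaf <- function(type, default, choices = NULL, min = NULL, max = NULL)
  list(.leaf = TRUE, type = type, default = default, choices = choices,
       min = min, max = max)

config_schema <- function() {
  list(
    data = list(
      mode = .leaf("enum", "paired_folders",
                   choices = c("csv_manifest", "paired_folders",
                               "suffix_convention", "presplit_folders")),
      data_path = .leaf("str", ""),
      source_key = .leaf("str", "source_path"),
      target_key = .leaf("str", "target_path"),
      exclusion_key = .leaf("str", "exclusion_path"),
      weight_key = .leaf("str", "weight_path"),
      source_folder = .leaf("str", "image"),
      target_folder = .leaf("str", "ground_truth"),
      source_suffix = .leaf("str", "_IM"),
      target_suffix = .leaf("str", "_GT"),
      val_fraction = .leaf("num", 0.2, min = 0, max = 0.999),
      portion_fraction = .leaf("num", 1.0, min = 1e-9, max = 1),
      reload_every = .leaf("int", 1L, min = 1),
      cache_dir = .leaf("str", "")
    ),
    preprocess = .leaf("transforms", list(
      list(name = "percentile_normalize", lo = 0.5, hi = 99.5,
           out_lo = -1, out_hi = 1, deterministic = TRUE)
    )),
    sampling = list(
      patch_size = .leaf("intvec", c(32L, 32L)),
      patches_per_image = .leaf("int", 4L, min = 1),
      weighting = .leaf("enum", "uniform",
                        choices = c("uniform", "foreground_weighted")),
      fg_ratio = .leaf("num", 0.5, min = 0, max = 1)
    ),
    framework = list(
      kind = .leaf("enum", "fcn",
                   choices = c("fcn", "pix2pix", "cyclegan", "embedseg")),
      recon_loss = .leaf("enum", "mae",
                         choices = c("mae", "mse", "smooth_mae")),
      adv_weight = .leaf("num", 1, min = 0),
      recon_weight = .leaf("num", 100, min = 0),
      cycle_weight = .leaf("num", 10, min = 0),
      identity_weight = .leaf("num", 5, min = 0),
      gan_objective = .leaf("enum", "lsgan", choices = c("lsgan", "vanilla")),
      generator_init = .leaf("str", ""),
      embed = list(
        center_mode = .leaf("enum", "medoid", choices = c("medoid", "centroid")),
        fg_threshold = .leaf("num", 0.5, min = 0, max = 1),
        seed_threshold = .leaf("num", 0.9, min = 0, max = 1),
        min_size = .leaf("int", 2L, min = 1),
        w_instance = .leaf("num", 1, min = 0),
        w_seed = .leaf("num", 1, min = 0),
        fg_seed_weight = .leaf("num", 10, min = 0),
        w_smooth = .leaf("num", 10, min = 0),
        margin = .leaf("int", 5, min = 0)
      )
    ),
    network = list(
      name = .leaf("str", "unet_2d"),
      dim = .leaf("int", 2L, min = 2, max = 3),
      in_channels = .leaf("int", 1L, min = 1),
      out_channels = .leaf("int", 1L, min = 1),
      depth = .leaf("int", 2L, min = 1),
      base_filters = .leaf("int", 8L, min = 1),
      z_factors = .leaf("intvec", integer(0)),
      norm = .leaf("enum", "instance", choices = c("instance", "batch", "none")),
      final_activation = .leaf("enum", "none",
                               choices = c("none", "tanh", "sigmoid")),
      kwargs = .leaf("free", list())
    ),
    trainer = list(
      max_epochs = .leaf("int", 2L, min = 1),
      steps_per_epoch = .leaf("int", 50L, min = 1),
      batch_size = .leaf("int", 4L, min = 1),
      learning_rate = .leaf("num", 1e-3, min = 1e-12),
      precision = .leaf("enum", "32", choices = c("32", "16-mixed")),
      seed = .leaf("int", 42L, min = 0),
      swa_enabled = .leaf("bool", FALSE),
      early_stop = .leaf("int", 0L, min = 0),
      checkpoint_every = .leaf("int", 1L, min = 1),
      out_dir = .leaf("str", "")
    ),
    inference = list(
      window_size = .leaf("intvec", integer(0)),
      overlap = .leaf("num", 0.25, min = 0, max = 0.9),
      blend = .leaf("enum", "gaussian", choices = c("gaussian", "uniform")),
      gaussian_sigma_scale = .leaf("num", 0.125, min = 1e-9),
      output_dtype = .leaf("enum", "float", choices = c("float", "uint", "int")),
      un_normalize = .leaf("bool", FALSE)
    ),
    output = list(
      path = .leaf("str", "")
    )
  )
}

.is_leaf <- function(x) is.list(x) && isTRUE(x$.leaf)

schema_defaults <- function(schema = config_schema()) {
  if (.is_leaf(schema)) return(schema$default)
  lapply(schema, schema_defaults)
}

.coerce_leaf <- function(leaf, value, path) {
  fail <- function(msg) stop("config field '", path, "': ", msg,
                             " (got: ", deparse(value, nlines = 1), ")",
                             call. = FALSE)
  v <- switch(leaf$type,
    int = {
      if (!is.numeric(value) || length(value) != 1 ||
          abs(value - round(value)) > 1e-9) fail("expected an integer")
      as.integer(round(value))
    },
    num = {
      if (!is.numeric(value) || length(value) != 1) fail("expected a number")
      as.numeric(value)
    },
    bool = {
      if (!is.logical(value) || length(value) != 1) fail("expected true/false")
      value
    },
    str = {
      if (length(value) != 1) fail("expected a string")
      as.character(value)
    },
    enum = {
      value <- as.character(value)
      if (length(value) != 1 || !value %in% leaf$choices)
        fail(paste0("expected one of {", paste(leaf$choices, collapse = ", "),
                    "}"))
      value
    },
    intvec = {
      value <- unlist(value)
      if (is.null(value) || !length(value)) integer(0)
      else {
        if (!is.numeric(value) || any(abs(value - round(value)) > 1e-9))
          fail("expected a list of integers")
        as.integer(round(value))
      }
    },
    numvec = {
      value <- unlist(value)
      if (is.null(value) || !length(value)) numeric(0)
      else {
        if (!is.numeric(value)) fail("expected numbers")
        as.numeric(value)
      }
    },
    free = value,
    transforms = {
      if (is.null(value)) value <- list()
      if (!is.list(value)) fail("expected a list of transform entries")
      lapply(value, function(tr) {
        if (!is.list(tr) || is.null(tr$name))
          fail("each transform entry needs a 'name'")
        if (is.null(tr$deterministic)) tr$deterministic <- TRUE
        tr
      })
    },
    fail("unknown schema type"))
  if (!is.null(leaf$min) && is.numeric(v) && length(v) && any(v < leaf$min))
    fail(paste0("must be >= ", leaf$min))
  if (!is.null(leaf$max) && is.numeric(v) && length(v) && any(v > leaf$max))
    fail(paste0("must be <= ", leaf$max))
  v
}

.validate_tree <- function(schema, value, path = character(0)) {
  pstr <- paste(path, collapse = ".")
  if (.is_leaf(schema)) return(.coerce_leaf(schema, value, pstr))
  if (is.null(value)) value <- list()
  if (!is.list(value))
    stop("config field '", pstr, "': expected a mapping", call. = FALSE)
  extra <- setdiff(names(value), names(schema))
  if (length(extra))
    stop("unknown config key: '",
         paste0(if (nzchar(pstr)) paste0(pstr, ".") else "", extra[1], "'"),
         call. = FALSE)
  out <- lapply(names(schema), function(nm)
    .validate_tree(schema[[nm]],
                   if (nm %in% names(value)) value[[nm]] else
                     schema_defaults(schema[[nm]]),
                   c(path, nm)))
  names(out) <- names(schema)
  out
}

.set_dotted <- function(cfg, keys, value) {
  if (length(keys) == 1) { cfg[[keys]] <- value; return(cfg) }
  cfg[[keys[1]]] <- .set_dotted(cfg[[keys[1]]], keys[-1], value)
  cfg
}

.parse_override <- function(s) {
  m <- regmatches(s, regexec("^-{0,2}([A-Za-z0-9_.]+)=(.*)$", s))[[1]]
  if (length(m) != 3)
    stop("cannot parse override '", s, "' (expected key.subkey=value)",
         call. = FALSE)
  list(key = strsplit(m[2], ".", fixed = TRUE)[[1]],
       value = yaml::yaml.load(m[3]))
}

#' Load and validate a run configuration
#'
#' Reads a YAML config file, fills unset fields with defaults, validates the
#' result against the config schema (unknown keys are an error naming the
#' offending dotted path) and applies command-line style overrides after the
#' file values.
#'
#' @param path path to a YAML file, or the name of a packaged example config
#'   (no file extension) under `inst/configs/`.
#' @param overrides character vector of `"key.subkey=value"` strings; values
#'   are parsed as YAML scalars.
#' @return validated config (nested named list) of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = character(0)) {
  schema <- config_schema()
  raw <- list()
  if (!is.null(path) && nzchar(path)) {
    if (!file.exists(path) && !grepl("\\.ya?ml$", path)) {
      packaged <- system.file("configs", paste0(path, ".yaml"),
                              package = "im2im")
      if (nzchar(packaged)) path <- packaged
    }
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  # reject unknown keys present in the file before filling defaults
  cfg <- .validate_tree(schema, raw)
  for (s in overrides) {
    ov <- .parse_override(s)
    # check the dotted path exists in the schema
    node <- schema
    for (k in ov$key) {
      if (.is_leaf(node) || !k %in% names(node))
        stop("unknown config key: '", paste(ov$key, collapse = "."), "'",
             call. = FALSE)
      node <- node[[k]]
    }
    if (!.is_leaf(node))
      stop("override '", paste(ov$key, collapse = "."),
           "' does not name a leaf field", call. = FALSE)
    cfg <- .set_dotted(cfg, ov$key, ov$value)
  }
  cfg <- .validate_tree(schema, cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Serialize a config to YAML text
#' @param cfg a `run_config`.
#' @return a YAML string; `load_config` on this string's file form returns an
#'   identical config.
#' @export
config_to_yaml <- function(cfg) {
  cfg <- unclass(cfg)
  yaml::as.yaml(cfg, precision = 15)
}

#' Stable digest of a config (used for cache keys and run records)
#' @param x any serializable R object.
#' @return hex string.
#' @export
spec_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x, precision = 15), f)
  unname(tools::md5sum(f))
}
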