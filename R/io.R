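# Run configuration, checkpoint archive, and image I/O.

.rc_schema <- list(
  resolution     = list(default = 32L,    check = function(v) is.numeric(v) && v >= 8 && v <= 512 && bitwAnd(as.integer(v), as.integer(v) - 1L) == 0L,
                        msg = "a power of two in [8, 512]"),
  L              = list(default = 512L,   check = function(v) is.numeric(v) && v >= 1, msg = "a positive integer"),
  mapping_depth  = list(default = 4L,     check = function(v) is.numeric(v) && v >= 1, msg = "a positive integer"),
  s              = list(default = 4L,     check = function(v) is.numeric(v) && v >= 2, msg = "an integer >= 2"),
  channels_max   = list(default = 128L,   check = function(v) is.numeric(v) && v >= 4, msg = "an integer >= 4"),
  channels_base  = list(default = 2048L,  check = function(v) is.numeric(v) && v >= 16, msg = "an integer >= 16"),
  noise          = list(default = TRUE,   check = is.logical, msg = "logical"),
  block_types    = list(default = "CL",   check = function(v) all(v %in% c("CL", "CBL")), msg = "'CL' or 'CBL'"),
  epochs         = list(default = 500L,   check = function(v) is.numeric(v) && v >= 1, msg = "a positive integer"),
  lr             = list(default = 0.001,  check = function(v) is.numeric(v) && v > 0, msg = "a positive number"),
  beta1          = list(default = 0,      check = function(v) is.numeric(v) && v >= 0 && v < 1, msg = "in [0, 1)"),
  beta2          = list(default = 0.99,   check = function(v) is.numeric(v) && v >= 0 && v < 1, msg = "in [0, 1)"),
  batch_size     = list(default = 16L,    check = function(v) is.numeric(v) && v >= 1, msg = "a positive integer"),
  critic_steps   = list(default = 1L,     check = function(v) is.numeric(v) && v >= 1, msg = "a positive integer"),
  gp_lambda      = list(default = 10,     check = function(v) is.numeric(v) && v >= 0, msg = "nonnegative"),
  plr_weight     = list(default = 2,      check = function(v) is.numeric(v) && v >= 0, msg = "nonnegative"),
  plr_interval   = list(default = 8L,     check = function(v) is.numeric(v) && v >= 1, msg = "a positive integer"),
  plr_decay      = list(default = 0.99,   check = function(v) is.numeric(v) && v > 0 && v < 1, msg = "in (0, 1)"),
  mixing_prob    = list(default = 0.5,    check = function(v) is.numeric(v) && v >= 0 && v <= 1, msg = "in [0, 1]"),
  psi            = list(default = 0.7,    check = function(v) is.numeric(v) && is.finite(v), msg = "a finite number"),
  seed           = list(default = 1L,     check = function(v) is.numeric(v), msg = "an integer"),
  fixture_n      = list(default = 64L,    check = function(v) is.numeric(v) && v >= 1, msg = "a positive integer"),
  out_dir        = list(default = NULL,   check = function(v) is.null(v) || is.character(v), msg = "a path or NULL"))

#' Run configuration
#'
#' Validated, fully defaulted settings for architecture and training.
#' Unknown keys are rejected; invalid values are reported by key name.
#'
#' @param ... settings overriding the defaults (see the schema in the
#'   package vignette): `resolution`, `L`, `mapping_depth`, `s`,
#'   `channels_max`, `channels_base`, `noise`, `block_types`, `epochs`,
#'   `lr`, `beta1`, `beta2`, `batch_size`, `critic_steps`, `gp_lambda`,
#'   `plr_weight`, `plr_interval`, `plr_decay`, `mixing_prob`, `psi`,
#'   `seed`, `fixture_n`, `out_dir`.
#' @return list of class `fg_runconfig`.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user)))
    user <- user[[1]]
  unknown <- setdiff(names(user), names(.rc_schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- lapply(.rc_schema, `[[`, "default")
  for (nm in names(user)) {
    v <- user[[nm]]
    sc <- .rc_schema[[nm]]
    if (!isTRUE(sc$check(v)))
      stop("invalid value for '", nm, "': must be ", sc$msg)
    cfg[[nm]] <- if (is.numeric(v) && is.numeric(sc$default) &&
                     is.integer(sc$default)) as.integer(v) else v
  }
  structure(cfg, class = "fg_runconfig")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file; keys as in [run_config()].
#' @return validated `fg_runconfig` with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' Save a run configuration to YAML
#' @param config an `fg_runconfig`.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "fg_runconfig"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

.ckpt_version <- "flowergan-checkpoint-1"

#' Save a training checkpoint
#'
#' A single versioned archive holding the model (mapping, generator and
#' critic weights, path-length state, step counter, config snapshot),
#' optimizer states, and the loss log.  Loading restores bitwise-identical
#' forward outputs.
#'
#' @param fit an `fg_fit` or `fg_model`.
#' @param path output file.
#' @export
save_checkpoint <- function(fit, path) {
  if (inherits(fit, "fg_model")) fit <- list(model = fit, opt = NULL, log = NULL)
  stopifnot(inherits(fit$model, "fg_model"))
  obj <- list(version = .ckpt_version, model = fit$model, opt = fit$opt,
              log = fit$log)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @param expected_resolution if given, loading a checkpoint trained at a
#'   different resolution is rejected.
#' @return list with `model`, `opt`, `log`.
#' @export
load_checkpoint <- function(path, expected_resolution = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable checkpoint (", path,
                                           "): ", conditionMessage(e)))
  if (!identical(obj$version, .ckpt_version))
    stop("incompatible checkpoint version: ",
         obj$version %||% "<missing>", " (expected ", .ckpt_version, ")")
  if (!is.null(expected_resolution) &&
      obj$model$config$resolution != expected_resolution)
    stop("checkpoint resolution ", obj$model$config$resolution,
         " does not match configured resolution ", expected_resolution)
  obj
}

#' Load a folder of images as a training batch
#'
#' Reads PNG (and, when the EBImage package is available, JPEG/TIFF) files
#' in stable filename order, resizes them bilinearly to the requested square
#' resolution, and scales 8-bit values to `[-1, 1]` via `v / 127.5 - 1`.
#' Unreadable files are skipped with a warning.
#'
#' @param path directory of images.
#' @param resolution output side length in pixels.
#' @return array `(3, resolution, resolution, n)`.
#' @export
load_image_folder <- function(path, resolution) {
  if (!dir.exists(path)) stop("image folder not found: ", path)
  files <- sort(list.files(path, pattern = "\\.(png|jpe?g|tiff?)$",
                           ignore.case = TRUE, full.names = TRUE))
  out <- list()
  for (f in files) {
    im <- tryCatch(.read_image(f), error = function(e) {
      warning("skipping unreadable image: ", f)
      NULL
    })
    if (is.null(im)) next
    im <- .resize_bilinear(im, resolution)
    out <- c(out, list(aperm(im, c(3, 1, 2)) * 2 - 1))
  }
  if (!length(out)) stop("no usable images in ", path)
  arr <- array(unlist(out), c(3L, resolution, resolution, length(out)))
  arr
}

# Read an image as (H, W, 3) in [0, 1].
.read_image <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    im <- png::readPNG(f)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading non-PNG images requires the EBImage package")
    im <- EBImage::imageData(EBImage::readImage(f))
    if (length(dim(im)) == 3L) im <- aperm(im, c(2, 1, 3)) # EBImage is x,y
    else im <- t(im)
  }
  if (length(dim(im)) == 2L) im <- array(rep(im, 3L), c(dim(im), 3L))
  if (dim(im)[3] > 3L) im <- im[, , 1:3, drop = FALSE]
  im
}

.resize_bilinear <- function(im, res) {
  d <- dim(im)
  if (d[1] == res && d[2] == res) return(im)
  # sample positions at pixel centers
  sy <- (seq_len(res) - 0.5) * d[1] / res + 0.5 - 0.5
  sx <- (seq_len(res) - 0.5) * d[2] / res + 0.5 - 0.5
  y0 <- pmin(pmax(floor(sy), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(sx), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, c(res, res, d[3]))
  for (ch in seq_len(d[3])) {
    p <- im[, , ch]
    a <- p[y0, x0] * (1 - fy) + p[y1, x0] * fy
    b <- p[y0, x1] * (1 - fy) + p[y1, x1] * fy
    out[, , ch] <- a * matrix(1 - fx, res, res, byrow = TRUE) +
      b * matrix(fx, res, res, byrow = TRUE)
  }
  out
}

#' Write a run manifest
#'
#' Records the config snapshot, seed and package version so a run can be
#' reproduced exactly.
#'
#' @param config an `fg_runconfig`.
#' @param path output JSON file.
#' @export
write_manifest <- function(config, path) {
  stopifnot(inherits(config, "fg_runconfig"))
  obj <- list(package = "flowergan",
              version = as.character(utils::packageVersion("flowergan")),
              r_version = R.version.string,
              config = Filter(Negate(is.null), unclass(config)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
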