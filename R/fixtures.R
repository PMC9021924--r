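# Procedural, seeded generator of labeled flower-head scenes.
#
# Scenes emulate the unstructured field conditions a detector faces: round
# petal rosettes at three growth stages on a textured background, an
# illumination gradient, inter-flower overlap, and occluding foreground
# strips.  Every per-flower fraction (lit, shadowed, overlapped, occluded)
# is measured on the rendered masks, so occluders of any shape are
# supported, and each flower is labeled by fixed percentage thresholds.

#' Scene specification
#'
#' @param resolution square canvas side in pixels.
#' @param n_flowers integer range `c(min, max)` of flowers per scene.
#' @param radius_frac flower radius range as a fraction of the canvas side.
#' @param petal_counts integer range of petals per rosette.
#' @param stage_probs sampling probabilities for the growth stages
#'   (bud, early flowering, full bloom).
#' @param illumination illumination gradient strength in `[0, 1]`
#'   (0 disables the ramp).
#' @param n_occluders integer range of occluding strips per scene.
#' @param background `"textured"` or `"plain"`.
#' @param style `"rosette"` (petaled flowers) or `"disk"` (plain bright
#'   disks, a minimal distribution for training smoke tests).
#' @param fixed_flowers optional data frame `cx, cy, r` (pixels, 1-based
#'   centers) and optionally `stage`, `petals`, overriding random placement.
#' @param fixed_occluders optional list of `list(cx, cy, w, h, angle)`
#'   rotated rectangles overriding random occluders.
#' @param seed integer seed; the scene is a pure function of the spec.
#' @return list of class `fg_scenespec`.
#' @export
scene_spec <- function(resolution = 64L, n_flowers = c(2L, 5L),
                       radius_frac = c(0.10, 0.20),
                       petal_counts = c(8L, 14L),
                       stage_probs = c(bud = 0.25, early = 0.5, full = 0.25),
                       illumination = 0.4, n_occluders = c(0L, 2L),
                       background = c("textured", "plain"),
                       style = c("rosette", "disk"),
                       fixed_flowers = NULL, fixed_occluders = NULL,
                       seed = 1L) {
  background <- match.arg(background)
  style <- match.arg(style)
  stopifnot(resolution >= 8L, all(radius_frac > 0),
            illumination >= 0, illumination <= 1)
  structure(list(resolution = as.integer(resolution),
                 n_flowers = as.integer(n_flowers),
                 radius_frac = radius_frac,
                 petal_counts = as.integer(petal_counts),
                 stage_probs = stage_probs, illumination = illumination,
                 n_occluders = as.integer(n_occluders),
                 background = background, style = style,
                 fixed_flowers = fixed_flowers,
                 fixed_occluders = fixed_occluders,
                 seed = as.integer(seed)),
            class = "fg_scenespec")
}

#' Classify a flower's environment from measured fractions
#'
#' Thresholds: overlap and occlusion are `high` above 0.6, `moderate` in
#' the closed band `[0.3, 0.6]`, `normal` below 0.3.  Light is `strong`
#' when strong sunlight covers more than half the petal area
#' (`lit_fraction > 0.5`); otherwise `weak` when any shadow is present;
#' otherwise `normal`.
#'
#' @param lit_fraction fraction of the petal area under strong light.
#' @param overlap_fraction fraction overlapped by other flowers.
#' @param occluded_fraction fraction hidden behind occluders.
#' @param shadow_fraction fraction in shadow (default 0).
#' @return list with `light`, `overlap`, `occlusion` labels.
#' @export
classify_environment <- function(lit_fraction, overlap_fraction,
                                 occluded_fraction, shadow_fraction = 0) {
  fr <- c(lit_fraction, overlap_fraction, occluded_fraction, shadow_fraction)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("fractions must lie in [0, 1]")
  band <- function(f) if (f > 0.6) "high" else if (f >= 0.3) "moderate" else "normal"
  light <- if (lit_fraction > 0.5) "strong"
           else if (shadow_fraction > 0) "weak"
           else "normal"
  list(light = light, overlap = band(overlap_fraction),
       occlusion = band(occluded_fraction))
}

# Rasterize a rotated-rectangle occluder on the pixel grid.
.rect_mask <- function(xs, ys, cx, cy, w, h, angle) {
  u <- (xs - cx) * cos(angle) + (ys - cy) * sin(angle)
  v <- -(xs - cx) * sin(angle) + (ys - cy) * cos(angle)
  abs(u) <= w / 2 & abs(v) <= h / 2
}

# Rasterize one flower; returns its support mask and an RGB color array.
.flower_mask <- function(xs, ys, cx, cy, r, stage, petals, style) {
  if (style == "disk") return(((xs - cx)^2 + (ys - cy)^2) <= r^2)
  openness <- switch(stage, bud = 0.3, early = 0.65, full = 1.0)
  core <- ((xs - cx)^2 + (ys - cy)^2) <= (0.4 * r)^2
  m <- core
  len <- pmax(openness * 0.65 * r, 1)
  wid <- pmax(0.28 * r, 0.8)
  d <- openness * 0.55 * r
  for (j in seq_len(petals)) {
    th <- 2 * pi * (j - 1) / petals
    px <- cx + d * cos(th)
    py <- cy + d * sin(th)
    u <- (xs - px) * cos(th) + (ys - py) * sin(th)
    v <- -(xs - px) * sin(th) + (ys - py) * cos(th)
    m <- m | ((u / len)^2 + (v / wid)^2 <= 1)
  }
  m
}

.stage_color <- function(stage, style) {
  if (style == "disk") return(c(0.95, 0.92, 0.80))
  switch(stage,
         bud = c(0.72, 0.75, 0.30),
         early = c(0.98, 0.88, 0.38),
         full = c(0.99, 0.95, 0.62))
}

#' Render a labeled scene
#'
#' Deterministic for a fixed spec (the seed is part of the spec).  Flowers
#' are drawn back-to-front, then occluders, then the illumination ramp.
#' Per flower, the lit/shadow/overlap/occlusion fractions are measured on
#' the rendered support masks and classified with
#' [classify_environment()].
#'
#' @param spec an [scene_spec()].
#' @return list with `image` (array `(H, W, 3)` in `[0, 1]`),
#'   `annotations` (data frame: 0-based tight `x, y, width, height`, stage,
#'   labels, and the measured fractions), and `masks` (per-flower logical
#'   support matrices).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "fg_scenespec"))
  withr::with_seed(spec$seed, .render_scene_impl(spec))
}

.render_scene_impl <- function(spec) {
  R <- spec$resolution
  xs <- matrix(rep(seq_len(R), each = R), R)   # column index
  ys <- matrix(rep(seq_len(R), R), R)          # row index

  img <- array(0, c(R, R, 3))
  if (spec$background == "textured") {
    base <- c(0.16, 0.19, 0.11)
    tex <- matrix(0, R, R)
    for (k in 1:3) {
      fx <- stats::runif(1, 0.5, 2.5) * 2 * pi / R
      fy <- stats::runif(1, 0.5, 2.5) * 2 * pi / R
      ph <- stats::runif(2, 0, 2 * pi)
      tex <- tex + sin(fx * xs + ph[1]) * sin(fy * ys + ph[2])
    }
    tex <- tex / 6
    for (ch in 1:3)
      img[, , ch] <- base[ch] * (1 + tex) +
        matrix(stats::rnorm(R * R, sd = 0.015), R)
  } else {
    for (ch in 1:3) img[, , ch] <- c(0.09, 0.10, 0.08)[ch]
  }

  # flower layout
  if (!is.null(spec$fixed_flowers)) {
    fl <- spec$fixed_flowers
    if (is.null(fl$stage)) fl$stage <- rep("early", nrow(fl))
    if (is.null(fl$petals))
      fl$petals <- rep(spec$petal_counts[1], nrow(fl))
  } else {
    nf <- if (spec$n_flowers[1] >= spec$n_flowers[2]) spec$n_flowers[1] else
      sample(spec$n_flowers[1]:spec$n_flowers[2], 1L)
    fl <- NULL
    if (nf > 0) {
      r <- stats::runif(nf, spec$radius_frac[1], spec$radius_frac[2]) * R
      fl <- data.frame(
        cx = stats::runif(nf, r + 1, R - r),
        cy = stats::runif(nf, r + 1, R - r),
        r = r,
        stage = sample(c("bud", "early", "full"), nf, replace = TRUE,
                       prob = spec$stage_probs),
        petals = sample(spec$petal_counts[1]:spec$petal_counts[2], nf,
                        replace = TRUE))
    }
  }
  n <- if (is.null(fl)) 0L else nrow(fl)

  masks <- vector("list", 0L)
  for (i in seq_len(n)) {
    m <- .flower_mask(xs, ys, fl$cx[i], fl$cy[i], fl$r[i], fl$stage[i],
                      fl$petals[i], spec$style)
    col <- .stage_color(fl$stage[i], spec$style) *
      stats::runif(1, 0.9, 1.05)
    shade <- 1 - 0.35 * pmin(sqrt((xs - fl$cx[i])^2 + (ys - fl$cy[i])^2) /
                               max(fl$r[i], 1), 1)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[m] <- (col[ch] * shade)[m]
      img[, , ch] <- pl
    }
    masks <- c(masks, list(m))
  }

  # occluders
  if (!is.null(spec$fixed_occluders)) {
    occs <- spec$fixed_occluders
  } else {
    no <- if (spec$n_occluders[1] >= spec$n_occluders[2]) spec$n_occluders[1]
      else sample(spec$n_occluders[1]:spec$n_occluders[2], 1L)
    occs <- lapply(seq_len(no), function(k)
      list(cx = stats::runif(1, 1, R), cy = stats::runif(1, 1, R),
           w = stats::runif(1, 0.08, 0.2) * R,
           h = stats::runif(1, 0.5, 1.2) * R,
           angle = stats::runif(1, 0, pi)))
  }
  occ <- matrix(FALSE, R, R)
  for (o in occs) {
    om <- .rect_mask(xs, ys, o$cx, o$cy, o$w, o$h, o$angle)
    occ <- occ | om
    col <- c(0.10, 0.28, 0.10) * stats::runif(1, 0.8, 1.1)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[om] <- col[ch]
      img[, , ch] <- pl
    }
  }

  # illumination ramp; a pixel counts as strongly lit above 1.2x base
  # intensity and as shadowed below 0.8x.
  if (spec$illumination > 0) {
    phi <- stats::runif(1, 0, 2 * pi)
    t <- ((xs / R - 0.5) * cos(phi) + (ys / R - 0.5) * sin(phi)) / 0.7071
    mult <- 1 + spec$illumination * t
    for (ch in 1:3) img[, , ch] <- img[, , ch] * mult
  } else {
    mult <- matrix(1, R, R)
  }
  img <- pmin(pmax(img, 0), 1)

  # annotations
  rows <- list()
  for (i in seq_len(n)) {
    m <- masks[[i]]
    area <- sum(m)
    others <- matrix(FALSE, R, R)
    for (j in seq_len(n)) if (j != i) others <- others | masks[[j]]
    overlap_frac <- if (area) sum(m & others) / area else 0
    occl_frac <- if (area) sum(m & occ) / area else 0
    lit_frac <- if (area) sum(m & (mult >= 1.2)) / area else 0
    shadow_frac <- if (area) sum(m & (mult <= 0.8)) / area else 0
    cls <- classify_environment(min(lit_frac, 1), min(overlap_frac, 1),
                                min(occl_frac, 1), min(shadow_frac, 1))
    cols_in <- range(xs[m])
    rows_in <- range(ys[m])
    rows <- c(rows, list(data.frame(
      x = cols_in[1] - 1L, y = rows_in[1] - 1L,
      width = cols_in[2] - cols_in[1] + 1L,
      height = rows_in[2] - rows_in[1] + 1L,
      stage = fl$stage[i],
      light = cls$light, overlap = cls$overlap, occlusion = cls$occlusion,
      lit_frac = lit_frac, shadow_frac = shadow_frac,
      overlap_frac = overlap_frac, occluded_frac = occl_frac)))
  }
  ann <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = integer(0), y = integer(0), width = integer(0),
               height = integer(0), stage = character(0),
               light = character(0), overlap = character(0),
               occlusion = character(0), lit_frac = numeric(0),
               shadow_frac = numeric(0), overlap_frac = numeric(0),
               occluded_frac = numeric(0))
  list(image = img, annotations = ann, masks = masks)
}

#' Generate a labeled dataset of scenes
#'
#' Renders `n` scenes with per-scene seeds derived from `seed`, optionally
#' writing PNG images plus a JSON-lines annotation file in the detection
#' schema of [read_detections_jsonl()].
#'
#' @param n number of scenes.
#' @param template an [scene_spec()]; its seed is replaced per scene.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @return list with `images` (list of arrays), `annotations` (list of data
#'   frames), and `label_counts` (table of environment labels).
#' @export
generate_dataset <- function(n, template = scene_spec(), seed = 1L,
                             out_dir = NULL) {
  stopifnot(n >= 1L, inherits(template, "fg_scenespec"))
  images <- list()
  anns <- list()
  for (i in seq_len(n)) {
    sp <- template
    sp$seed <- substream_seed(seed, "scene", i)
    sc <- render_scene(sp)
    images <- c(images, list(sc$image))
    anns <- c(anns, list(sc$annotations))
  }
  lab <- do.call(rbind, lapply(anns, function(a)
    a[, c("light", "overlap", "occlusion")]))
  label_counts <- list(light = table(lab$light), overlap = table(lab$overlap),
                       occlusion = table(lab$occlusion))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dets <- list()
    for (i in seq_len(n)) {
      id <- sprintf("scene_%04d", i)
      png::writePNG(images[[i]], file.path(out_dir, paste0(id, ".png")))
      a <- anns[[i]]
      gt <- lapply(seq_len(nrow(a)), function(k)
        bbox(a$x[k], a$y[k], a$width[k], a$height[k]))
      dets <- c(dets, list(list(image = id, gt = gt, pred = list())))
    }
    write_detections_jsonl(dets, file.path(out_dir, "annotations.jsonl"))
  }
  list(images = images, annotations = anns, label_counts = label_counts)
}

#' Minimal bright-disk fixture distribution
#'
#' Bright disks on a dark, untextured ground with no illumination ramp and
#' no occluders: the simplest distribution for training smoke tests.
#'
#' @param resolution canvas side.
#' @param n_flowers disk count range.
#' @return an [scene_spec()].
#' @export
disk_fixture_spec <- function(resolution = 32L, n_flowers = c(1L, 2L)) {
  scene_spec(resolution = resolution, n_flowers = n_flowers,
             radius_frac = c(0.2, 0.3), illumination = 0,
             n_occluders = c(0L, 0L), background = "plain", style = "disk")
}
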