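# Schematic-person renderer. PPE is encoded by distinct colour patches
# (mask: light blue, gloves: purple, gown: pale yellow) with within-class hue
# jitter and additive noise: classification is learnable but not trivial.
# This verifies pipeline mechanics only -- toy accuracy here says nothing
# about accuracy on real people.

ppe_palette <- function() {
  list(
    skin = c(0.85, 0.70, 0.60),
    scrubs = c(0.30, 0.55, 0.50),
    casual = c(0.55, 0.30, 0.30),
    white_coat = c(0.88, 0.84, 0.40), # deliberately near the gown hue
    gown = c(0.92, 0.86, 0.35),
    mask = c(0.45, 0.65, 0.95),
    glove = c(0.55, 0.35, 0.75),
    pants = c(0.25, 0.25, 0.30)
  )
}

#' Landmarks of an upright schematic person
#'
#' Canonical standing layout scaled to a figure height and translated to a
#' position in the frame. Used by the scene renderer and handy for geometry
#' examples.
#'
#' @param center_x Horizontal centre of the figure (pixels).
#' @param top_y Vertical position of the top of the head (pixels).
#' @param height Figure height head-to-ankle (pixels).
#' @return A `ppe_landmarks` tibble.
#' @export
person_landmarks <- function(center_x = 128, top_y = 28, height = 200) {
  u <- list(
    nose = c(0, 0.080), left_eye = c(0.025, 0.065), right_eye = c(-0.025, 0.065),
    left_ear = c(0.050, 0.080), right_ear = c(-0.050, 0.080),
    left_shoulder = c(0.110, 0.200), right_shoulder = c(-0.110, 0.200),
    left_elbow = c(0.160, 0.330), right_elbow = c(-0.160, 0.330),
    left_wrist = c(0.180, 0.460), right_wrist = c(-0.180, 0.460),
    left_hip = c(0.075, 0.500), right_hip = c(-0.075, 0.500),
    left_knee = c(0.080, 0.720), right_knee = c(-0.080, 0.720),
    left_ankle = c(0.080, 0.950), right_ankle = c(-0.080, 0.950)
  )
  m <- vapply(u[keypoint_names()], identity, numeric(2))
  landmark_set(x = center_x + height * m[1, ], y = top_y + height * m[2, ])
}

#' @rdname person_landmarks
#' @export
demo_landmarks <- function() person_landmarks()

#' Describe a synthetic schematic-person scene
#'
#' A scene spec fully determines one rendered frame: the landmark layout,
#' the PPE permutation, confounder tags, background style, jitter/noise
#' amplitudes and a seed. Rendering the same spec twice gives bit-identical
#' output.
#'
#' @param landmarks A landmark set, or NULL to place a standard upright
#'   figure via `center_x`, `top_y`, `height`.
#' @param center_x,top_y,height Figure placement used when `landmarks` is
#'   NULL.
#' @param mask,gown,glove_left,glove_right Logical PPE state.
#' @param hidden Character vector of keypoint names to flag hidden
#'   (confidence 0 in the ground truth).
#' @param clothing `"scrubs"`, `"casual"` or `"white_coat"` (a casual mode
#'   whose hue deliberately approaches the gown colour, for regression tests
#'   of that confusion).
#' @param scenery `"hospital"` or `"regular"` background.
#' @param background_style Integer 1..4 selecting a background gradient.
#' @param jitter Within-class hue jitter amplitude (per RGB channel,
#'   default 0.04).
#' @param noise_sigma Additive Gaussian pixel noise sd (default 0.02).
#' @param frame_size Integer `c(width, height)` in pixels.
#' @param seed Integer seed for jitter and noise.
#' @return A `ppe_scene_spec` list.
#' @export
scene_spec <- function(landmarks = NULL, center_x = 128, top_y = 28,
                       height = 200, mask = TRUE, gown = TRUE,
                       glove_left = TRUE, glove_right = TRUE,
                       hidden = character(), clothing = "scrubs",
                       scenery = "hospital", background_style = 1L,
                       jitter = 0.04, noise_sigma = 0.02,
                       frame_size = c(256L, 256L), seed = 1L) {
  stopifnot(
    clothing %in% c("scrubs", "casual", "white_coat"),
    scenery %in% c("hospital", "regular"),
    jitter >= 0, noise_sigma >= 0
  )
  lm <- landmarks %||% person_landmarks(center_x, top_y, height)
  if (!all(hidden %in% keypoint_names())) abort("unknown hidden keypoint name")
  structure(
    list(
      landmarks = lm, mask = mask, gown = gown,
      glove_left = glove_left, glove_right = glove_right, hidden = hidden,
      clothing = clothing, scenery = scenery,
      background_style = as.integer(background_style),
      jitter = jitter, noise_sigma = noise_sigma,
      frame_size = as.integer(frame_size), seed = as.integer(seed)
    ),
    class = "ppe_scene_spec"
  )
}

# -- raster helpers on a precomputed coordinate grid ------------------------

paint <- function(img, mask, col) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- col[ch]
    img[, , ch] <- plane
  }
  img
}

disc_mask <- function(X, Y, cx, cy, r) (X - cx)^2 + (Y - cy)^2 <= r^2

ellipse_mask <- function(X, Y, cx, cy, rx, ry) {
  ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
}

rect_mask <- function(X, Y, x0, x1, y0, y1) X >= x0 & X <= x1 & Y >= y0 & Y <= y1

# capsule: all points within r of segment p-q
segment_mask <- function(X, Y, p, q, r) {
  vx <- q[1] - p[1]
  vy <- q[2] - p[2]
  L2 <- vx^2 + vy^2
  if (L2 == 0) {
    return(disc_mask(X, Y, p[1], p[2], r))
  }
  t <- pmin(1, pmax(0, ((X - p[1]) * vx + (Y - p[2]) * vy) / L2))
  (X - (p[1] + t * vx))^2 + (Y - (p[2] + t * vy))^2 <= r^2
}

#' Render a synthetic scene
#'
#' Draws the schematic person described by a [scene_spec()] -- background,
#' limbs, head, clothing panel, then PPE colour patches (nose-anchored mask
#' rectangle, glove discs at the palm centres given by the palm geometry
#' rule, gown panel over the torso) -- applies hue jitter and additive
#' noise, and returns the frame together with its ground truth.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (height x width x 3 array in `[0, 1]`),
#'   `landmarks` (ground truth, confidence 0 for hidden joints), `labels`
#'   (tibble: mask, gloves_left, gloves_right, gown) and `tags` (tibble:
#'   clothing, scenery).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "ppe_scene_spec"))
  lm <- spec$landmarks
  w <- spec$frame_size[1]
  h <- spec$frame_size[2]
  H <- max(lm$y) - min(lm$y)
  if (H <= 0) H <- h * 0.75
  pal <- ppe_palette()

  withr::with_seed(spec$seed, {
    jit <- function(col) {
      pmin(1, pmax(0, col + runif(3, -spec$jitter, spec$jitter)))
    }
    # pixel-centre coordinate grids (x rightward, y downward, 0-based)
    X <- matrix(seq_len(w) - 0.5, nrow = h, ncol = w, byrow = TRUE)
    Y <- matrix(seq_len(h) - 0.5, nrow = h, ncol = w)

    base <- switch(spec$scenery,
      hospital = c(0.78, 0.88, 0.90),
      regular = c(0.85, 0.80, 0.70)
    )
    floor_col <- switch(spec$scenery,
      hospital = c(0.62, 0.68, 0.72),
      regular = c(0.58, 0.48, 0.40)
    )
    grad_dir <- c(1, -1, 1, -1)[spec$background_style]
    grad_amp <- c(0.04, 0.04, 0.08, 0.08)[spec$background_style]
    img <- array(0, dim = c(h, w, 3))
    shade <- grad_amp * grad_dir * (X / w - 0.5)
    for (ch in 1:3) img[, , ch] <- base[ch] + shade
    img <- paint(img, Y > 0.85 * h, floor_col)

    skin <- jit(pal$skin)
    cloth <- jit(pal[[spec$clothing]])
    pants <- jit(pal$pants)

    limb_r <- 0.030 * H
    limbs <- list(
      c("left_shoulder", "left_elbow"), c("left_elbow", "left_wrist"),
      c("right_shoulder", "right_elbow"), c("right_elbow", "right_wrist")
    )
    for (seg in limbs) {
      img <- paint(img, segment_mask(X, Y, kp_xy(lm, seg[1]), kp_xy(lm, seg[2]), limb_r), skin)
    }
    legs <- list(
      c("left_hip", "left_knee"), c("left_knee", "left_ankle"),
      c("right_hip", "right_knee"), c("right_knee", "right_ankle")
    )
    for (seg in legs) {
      img <- paint(img, segment_mask(X, Y, kp_xy(lm, seg[1]), kp_xy(lm, seg[2]), 1.1 * limb_r), pants)
    }

    nose <- kp_xy(lm, "nose")
    img <- paint(img, ellipse_mask(X, Y, nose[1], nose[2] - 0.010 * H, 0.058 * H, 0.075 * H), skin)

    # clothing panel spanning shoulders to hips
    sh_l <- kp_xy(lm, "left_shoulder")
    sh_r <- kp_xy(lm, "right_shoulder")
    hp_l <- kp_xy(lm, "left_hip")
    hp_r <- kp_xy(lm, "right_hip")
    torso_box <- rect_mask(
      X, Y,
      min(sh_r[1], hp_r[1]) - 0.015 * H, max(sh_l[1], hp_l[1]) + 0.015 * H,
      min(sh_l[2], sh_r[2]) - 0.015 * H, max(hp_l[2], hp_r[2]) + 0.015 * H
    )
    img <- paint(img, torso_box, cloth)

    if (isTRUE(spec$gown)) {
      gown_box <- rect_mask(
        X, Y,
        min(sh_r[1], hp_r[1]) - 0.030 * H, max(sh_l[1], hp_l[1]) + 0.030 * H,
        min(sh_l[2], sh_r[2]) - 0.020 * H, max(hp_l[2], hp_r[2]) + 0.030 * H
      )
      img <- paint(img, gown_box, jit(pal$gown))
    }

    if (isTRUE(spec$mask)) {
      img <- paint(
        img,
        rect_mask(
          X, Y, nose[1] - 0.048 * H, nose[1] + 0.048 * H,
          nose[2] - 0.008 * H, nose[2] + 0.048 * H
        ),
        jit(pal$mask)
      )
    }

    # hands sit at the palm-rule centres so palm crops always contain them
    gcfg <- geometry_config()
    for (s in c("left", "right")) {
      pr <- palm_region(lm, s, gcfg)
      if (!isTRUE(pr$visible)) next
      gloved <- if (s == "left") spec$glove_left else spec$glove_right
      col <- if (isTRUE(gloved)) jit(pal$glove) else skin
      img <- paint(img, disc_mask(X, Y, pr$center_x, pr$center_y, 0.042 * H), col)
    }

    if (spec$noise_sigma > 0) {
      img <- img + array(rnorm(h * w * 3, 0, spec$noise_sigma), dim = c(h, w, 3))
    }
    img[] <- pmin(1, pmax(0, img))
  })

  conf <- ifelse(lm$name %in% spec$hidden, 0, 1)
  truth <- landmark_set(lm$x, lm$y, conf)
  list(
    image = img,
    landmarks = truth,
    labels = tibble::tibble(
      mask = spec$mask, gloves_left = spec$glove_left,
      gloves_right = spec$glove_right, gown = spec$gown
    ),
    tags = tibble::tibble(clothing = spec$clothing, scenery = spec$scenery)
  )
}

#' Colour-rule oracle classifier for synthetic crops
#'
#' Decides whether a PPE item is present in a crop by the fraction of pixels
#' whose colour lies near the item's palette hue. Exact on noiseless scenes
#' and robust to the default jitter; used as a reference predictor in tests
#' and as the "oracle head" in pipeline checks.
#'
#' @param crop Crop array (any square size).
#' @param item `"mask"`, `"gloves"` or `"gown"`.
#' @param min_fraction Minimum fraction of near-hue pixels to call the item
#'   present (default 0.01).
#' @return Logical.
#' @export
oracle_color_rule <- function(crop, item = c("mask", "gloves", "gown"),
                              min_fraction = 0.01) {
  item <- match.arg(item)
  assert_image(crop, "crop")
  ref <- ppe_palette()[[switch(item, mask = "mask", gloves = "glove", gown = "gown")]]
  d2 <- (crop[, , 1] - ref[1])^2 + (crop[, , 2] - ref[2])^2 + (crop[, , 3] - ref[3])^2
  mean(d2 < 0.12^2) >= min_fraction
}

#' The eight mask/gown/gloves wear permutations
#'
#' @return Tibble with logical columns `mask`, `gown`, `gloves` (8 rows).
#' @export
ppe_permutations <- function() {
  tidyr::expand_grid(
    mask = c(FALSE, TRUE), gown = c(FALSE, TRUE), gloves = c(FALSE, TRUE)
  )
}

region_item <- function(kind) {
  switch(kind,
    face = "mask", torso = "gown",
    left_palm = "gloves", right_palm = "gloves"
  )
}

#' Generate a balanced labelled crop dataset for one region
#'
#' Renders `2 * n_per_class` independent scenes (random pose placement,
#' figure scale, clothing, scenery and background under the seed), with the
#' region's PPE item present in half of them, and crops the region from each.
#' Stands in for the field image collections the region models were trained
#' on. Confounder tags (clothing, scenery, a figure-scale class standing in
#' for height/sex) ride along in the manifest so stratified analysis can run
#' end to end.
#'
#' @param n_per_class Crops per class (>= 2).
#' @param region `"face"`, `"torso"`, `"left_palm"` or `"right_palm"`.
#' @param jitter,noise_sigma Passed to [scene_spec()].
#' @param seed Integer seed.
#' @param cfg A [geometry_config()].
#' @param out_dir Optional directory; when given, crops are written as PNGs
#'   and the manifest gains a `crop_path` column.
#' @return List with `manifest` (tibble: crop_id, region_kind, label,
#'   participant_id, clothing, scenery, scale_class) and `crops` (list of
#'   crop arrays, same order).
#' @export
generate_dataset <- function(n_per_class, region, jitter = 0.04,
                             noise_sigma = 0.02, seed = 1L,
                             cfg = geometry_config(), out_dir = NULL) {
  stopifnot(n_per_class >= 2, region %in% region_kinds())
  item <- region_item(region)
  n <- 2L * as.integer(n_per_class)
  labels <- rep(c(TRUE, FALSE), each = n_per_class)

  draws <- withr::with_seed(derive_seed(seed, paste0("dataset_", region)), {
    tibble::tibble(
      center_x = runif(n, 108, 148),
      top_y = runif(n, 16, 40),
      height = runif(n, 160, 210),
      clothing = sample(c("scrubs", "casual"), n, replace = TRUE),
      scenery = sample(c("hospital", "regular"), n, replace = TRUE),
      background_style = sample(1:4, n, replace = TRUE),
      participant_id = sample(sprintf("P%02d", 1:11), n, replace = TRUE),
      other_ppe = runif(n) < 0.5, # items outside the target region vary freely
      scene_seed = sample.int(2^30, n)
    )
  })

  crops <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[i, ]
    sp <- scene_spec(
      center_x = d$center_x, top_y = d$top_y, height = d$height,
      mask = if (item == "mask") labels[i] else d$other_ppe,
      gown = if (item == "gown") labels[i] else d$other_ppe,
      glove_left = if (region == "left_palm") labels[i] else d$other_ppe,
      glove_right = if (region == "right_palm") labels[i] else d$other_ppe,
      clothing = d$clothing, scenery = d$scenery,
      background_style = d$background_style,
      jitter = jitter, noise_sigma = noise_sigma, seed = d$scene_seed
    )
    sc <- render_scene(sp)
    reg <- switch(region,
      face = face_region(sc$landmarks, cfg),
      torso = torso_region(sc$landmarks, cfg),
      left_palm = palm_region(sc$landmarks, "left", cfg),
      right_palm = palm_region(sc$landmarks, "right", cfg)
    )
    cr <- crop_region(sc$image, reg, cfg)
    if (!cr$visible) abort("generated scene produced a non-visible region")
    crops[[i]] <- cr$image
    rows[[i]] <- tibble::tibble(
      crop_id = sprintf("%s_%04d", region, i),
      region_kind = region, label = as.integer(labels[i]),
      participant_id = d$participant_id, clothing = d$clothing,
      scenery = d$scenery,
      scale_class = ifelse(d$height >= 185, "tall", "short")
    )
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$crop_path <- file.path(out_dir, paste0(manifest$crop_id, ".png"))
    purrr::walk2(crops, manifest$crop_path, ~ png::writePNG(.x, .y))
  }
  list(manifest = manifest, crops = crops)
}

#' Describe a synthetic event
#'
#' An event is one person entering the scene in a fixed PPE permutation,
#' rendered as an ordered frame sequence with a continuous lateral walk-in
#' trajectory.
#'
#' @param n_frames Number of frames (>= 1).
#' @param mask,gown,glove_left,glove_right Logical PPE state, fixed for the
#'   whole event.
#' @param clothing,scenery,background_style,jitter,noise_sigma,frame_size
#'   As in [scene_spec()].
#' @param x_from,x_to Figure centre at the first and last frame (pixels).
#' @param height Figure height (pixels).
#' @param seed Integer seed.
#' @return A `ppe_event_spec` list.
#' @export
event_spec <- function(n_frames = 50L, mask = TRUE, gown = TRUE,
                       glove_left = TRUE, glove_right = TRUE,
                       clothing = "scrubs", scenery = "hospital",
                       background_style = 1L, jitter = 0.04,
                       noise_sigma = 0.02, frame_size = c(256L, 256L),
                       x_from = 100, x_to = 156, height = 190, seed = 1L) {
  stopifnot(n_frames >= 1)
  structure(
    list(
      n_frames = as.integer(n_frames), mask = mask, gown = gown,
      glove_left = glove_left, glove_right = glove_right,
      clothing = clothing, scenery = scenery,
      background_style = as.integer(background_style),
      jitter = jitter, noise_sigma = noise_sigma,
      frame_size = as.integer(frame_size),
      x_from = x_from, x_to = x_to, height = height, seed = as.integer(seed)
    ),
    class = "ppe_event_spec"
  )
}

#' Render the ordered frames of an event
#'
#' @param spec An [event_spec()].
#' @return List of per-frame lists as returned by [render_scene()], each
#'   with a `frame_id` added.
#' @export
generate_event <- function(spec) {
  stopifnot(inherits(spec, "ppe_event_spec"))
  n <- spec$n_frames
  xs <- if (n == 1) spec$x_from else seq(spec$x_from, spec$x_to, length.out = n)
  seeds <- withr::with_seed(
    derive_seed(spec$seed, "event_frames"),
    sample.int(2^30, n)
  )
  purrr::map(seq_len(n), function(i) {
    sp <- scene_spec(
      center_x = xs[i], top_y = 24, height = spec$height,
      mask = spec$mask, gown = spec$gown,
      glove_left = spec$glove_left, glove_right = spec$glove_right,
      clothing = spec$clothing, scenery = spec$scenery,
      background_style = spec$background_style,
      jitter = spec$jitter, noise_sigma = spec$noise_sigma,
      frame_size = spec$frame_size, seed = seeds[i]
    )
    out <- render_scene(sp)
    out$frame_id <- sprintf("f%04d", i - 1L)
    out
  })
}
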