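#' Geometry configuration for landmark-driven region extraction
#'
#' Holds the crop coefficients and conventions for the three
#' region-of-interest rules. The measurement-scale coefficients (1.2 face,
#' 0.5 palm offset, 1.6 palm side, 0.83 torso) were derived empirically for
#' the original system; they are exposed here so either a half-side or a
#' full-side reading of each factor is reproducible.
#'
#' @param face_coeff Face factor applied to the mean ear-to-nose distance
#'   (default 1.2).
#' @param palm_offset_coeff Fraction of the elbow-to-wrist distance the palm
#'   centre is extrapolated beyond the wrist (default 0.5).
#' @param palm_side_coeff Palm square side as a multiple of the
#'   elbow-to-wrist distance (default 1.6).
#' @param torso_coeff Torso factor applied to the distance from the
#'   shoulder/hip centroid to the furthest of the four landmarks
#'   (default 0.83).
#' @param side_convention Named character vector mapping each region kind to
#'   `"half"` (coefficient times scale is a half-side) or `"full"` (it is the
#'   full side). Defaults: face and torso half-side, palms full-side.
#' @param visibility_confidence_threshold Minimum keypoint confidence for a
#'   landmark to count as detected (default 0.3).
#' @param crop_out_size Output crop resolution in pixels (default 224).
#' @return A `ppe_geometry_config` list.
#' @export
geometry_config <- function(face_coeff = 1.2,
                            palm_offset_coeff = 0.5,
                            palm_side_coeff = 1.6,
                            torso_coeff = 0.83,
                            side_convention = c(
                              face = "half", torso = "half",
                              left_palm = "full", right_palm = "full"
                            ),
                            visibility_confidence_threshold = 0.3,
                            crop_out_size = 224) {
  stopifnot(
    face_coeff > 0, palm_offset_coeff > 0, palm_side_coeff > 0,
    torso_coeff > 0, crop_out_size >= 8,
    all(side_convention %in% c("half", "full"))
  )
  structure(
    list(
      face_coeff = face_coeff,
      palm_offset_coeff = palm_offset_coeff,
      palm_side_coeff = palm_side_coeff,
      torso_coeff = torso_coeff,
      side_convention = side_convention,
      visibility_confidence_threshold = visibility_confidence_threshold,
      crop_out_size = crop_out_size
    ),
    class = "ppe_geometry_config"
  )
}

region_kinds <- function() c("face", "torso", "left_palm", "right_palm")

#' @noRd
region_row <- function(kind, cx = NA_real_, cy = NA_real_, side = NA_real_,
                       visible = FALSE, reason = NA_character_) {
  tibble::tibble(
    kind = kind, center_x = cx, center_y = cy, side = side,
    visible = visible, reason = reason
  )
}

apply_convention <- function(cfg, kind, half_extent) {
  if (cfg$side_convention[[kind]] == "half") 2 * half_extent else half_extent
}

#' Face region from nose and ear landmarks
#'
#' The measurement scale is the mean Euclidean distance from each ear to the
#' nose; a square is centred on the nose with extent `face_coeff` times that
#' scale (a half-side under the default convention). Degenerate geometry or
#' low-confidence landmarks yield `visible = FALSE` rather than an error: a
#' live frame loop must never crash on a bad pose.
#'
#' @param lm A landmark set ([landmark_set()]).
#' @param cfg A [geometry_config()].
#' @return One-row tibble: `kind`, `center_x`, `center_y`, `side`, `visible`,
#'   `reason`.
#' @examples
#' lm <- demo_landmarks()
#' face_region(lm, geometry_config())
#' @export
face_region <- function(lm, cfg = geometry_config()) {
  need <- c("nose", "left_ear", "right_ear")
  if (!kp_ok(lm, need, cfg$visibility_confidence_threshold)) {
    return(region_row("face", reason = "low-confidence landmark"))
  }
  nose <- kp_xy(lm, "nose")
  scale <- mean(c(
    euclid(kp_xy(lm, "right_ear"), nose),
    euclid(kp_xy(lm, "left_ear"), nose)
  ))
  if (scale <= 0) {
    return(region_row("face", reason = "degenerate scale"))
  }
  side <- apply_convention(cfg, "face", cfg$face_coeff * scale)
  region_row("face", nose[1], nose[2], side, visible = TRUE)
}

#' Palm region extrapolated along the forearm
#'
#' The measurement scale is the elbow-to-wrist distance. The palm centre is
#' the point on the elbow-through-wrist line `palm_offset_coeff` times the
#' scale beyond the wrist; the square side is `palm_side_coeff` times the
#' scale (a full side by default).
#'
#' @inheritParams face_region
#' @param side_of_body `"left"` or `"right"`.
#' @return One-row tibble as in [face_region()].
#' @examples
#' lm <- demo_landmarks()
#' palm_region(lm, "right", geometry_config())
#' @export
palm_region <- function(lm, side_of_body = c("left", "right"),
                        cfg = geometry_config()) {
  side_of_body <- match.arg(side_of_body)
  kind <- paste0(side_of_body, "_palm")
  need <- paste0(side_of_body, c("_elbow", "_wrist"))
  if (!kp_ok(lm, need, cfg$visibility_confidence_threshold)) {
    return(region_row(kind, reason = "low-confidence landmark"))
  }
  elbow <- kp_xy(lm, need[1])
  wrist <- kp_xy(lm, need[2])
  scale <- euclid(elbow, wrist)
  if (scale <= 0) {
    return(region_row(kind, reason = "degenerate scale"))
  }
  centre <- wrist + cfg$palm_offset_coeff * scale * (wrist - elbow) / scale
  side <- apply_convention(cfg, kind, cfg$palm_side_coeff * scale)
  region_row(kind, centre[1], centre[2], side, visible = TRUE)
}

#' Torso region from shoulder and hip landmarks
#'
#' Centred on the centroid of the two shoulders and two hips, with extent
#' `torso_coeff` times the distance from the centroid to the furthest of the
#' four landmarks (a half-side under the default convention).
#'
#' @inheritParams face_region
#' @return One-row tibble as in [face_region()].
#' @export
torso_region <- function(lm, cfg = geometry_config()) {
  need <- c("left_shoulder", "right_shoulder", "left_hip", "right_hip")
  if (!kp_ok(lm, need, cfg$visibility_confidence_threshold)) {
    return(region_row("torso", reason = "low-confidence landmark"))
  }
  pts <- vapply(need, function(n) kp_xy(lm, n), numeric(2))
  centre <- rowMeans(pts)
  furthest <- max(sqrt(colSums((pts - centre)^2)))
  if (furthest <= 0) {
    return(region_row("torso", reason = "degenerate scale"))
  }
  side <- apply_convention(cfg, "torso", cfg$torso_coeff * furthest)
  region_row("torso", centre[1], centre[2], side, visible = TRUE)
}

#' All four candidate regions for one landmark set
#'
#' @inheritParams face_region
#' @return A 4-row tibble (face, torso, left_palm, right_palm).
#' @export
extract_regions <- function(lm, cfg = geometry_config()) {
  dplyr::bind_rows(
    face_region(lm, cfg),
    torso_region(lm, cfg),
    palm_region(lm, "left", cfg),
    palm_region(lm, "right", cfg)
  )
}

#' Which regions of interest are visible in a frame
#'
#' A region is visible iff all of its defining landmarks pass the confidence
#' threshold and, for palms, the wrist lies inside the frame. These rules are
#' automated proxies for the manual cleaning of the original study (frames
#' with an out-of-field wrist, or showing the back of the head, were
#' discarded); the nose-confidence requirement stands in for the
#' back-of-head check.
#'
#' @inheritParams face_region
#' @param frame_size Integer `c(width, height)` of the frame in pixels.
#' @return Character vector, a subset of
#'   `c("face", "torso", "left_palm", "right_palm")`.
#' @export
visible_regions <- function(lm, frame_size, cfg = geometry_config()) {
  thr <- cfg$visibility_confidence_threshold
  w <- frame_size[1]
  h <- frame_size[2]
  in_frame <- function(p) p[1] >= 0 && p[1] < w && p[2] >= 0 && p[2] < h
  out <- character()
  if (kp_ok(lm, c("nose", "left_ear", "right_ear"), thr)) out <- c(out, "face")
  if (kp_ok(lm, c("left_shoulder", "right_shoulder", "left_hip", "right_hip"), thr)) {
    out <- c(out, "torso")
  }
  for (s in c("left", "right")) {
    wk <- paste0(s, "_wrist")
    if (kp_ok(lm, paste0(s, c("_elbow", "_wrist")), thr) &&
      in_frame(kp_xy(lm, wk))) {
      out <- c(out, paste0(s, "_palm"))
    }
  }
  out
}

#' Crop a square region out of a frame
#'
#' Extracts the axis-aligned square window of `region` and resamples it to
#' `crop_out_size` pixels square. Windows extending past the frame edges are
#' zero-padded (not clamped) so the region's geometric centre stays centred
#' in the crop. Nearest-neighbour resampling is the default so that an
#' in-bounds window resampled at its own size reproduces the source pixels
#' exactly.
#'
#' @param image Numeric `height x width x 3` array in `[0, 1]`.
#' @param region One-row region tibble from [face_region()] and friends.
#' @param cfg A [geometry_config()].
#' @return A list with `image` (the resampled crop), `inside_fraction`
#'   (fraction of the window area inside the frame) and `visible` (FALSE when
#'   the window is degenerate or entirely outside the frame, in which case
#'   `image` is NULL).
#' @export
crop_region <- function(image, region, cfg = geometry_config()) {
  assert_image(image)
  not_vis <- function(reason) list(image = NULL, inside_fraction = 0, visible = FALSE, reason = reason)
  if (!isTRUE(region$visible)) {
    return(not_vis(region$reason %||% "region not visible"))
  }
  side <- region$side
  if (!is.finite(side) || side < 1) {
    return(not_vis("degenerate window"))
  }
  h <- dim(image)[1]
  w <- dim(image)[2]
  # window in continuous pixel coordinates [x0, x0+side) x [y0, y0+side)
  x0 <- region$center_x - side / 2
  y0 <- region$center_y - side / 2
  fx <- max(0, min(x0 + side, w) - max(x0, 0)) / side
  fy <- max(0, min(y0 + side, h) - max(y0, 0)) / side
  inside <- fx * fy
  if (inside <= 0) {
    return(not_vis("window outside frame"))
  }
  out_n <- cfg$crop_out_size
  # nearest-neighbour sample positions at output-pixel centres
  sx <- floor(x0 + (seq_len(out_n) - 0.5) * side / out_n) + 1L
  sy <- floor(y0 + (seq_len(out_n) - 0.5) * side / out_n) + 1L
  ok_x <- sx >= 1L & sx <= w
  ok_y <- sy >= 1L & sy <= h
  crop <- array(0, dim = c(out_n, out_n, 3))
  if (any(ok_y) && any(ok_x)) {
    crop[ok_y, ok_x, ] <- image[sy[ok_y], sx[ok_x], , drop = FALSE]
  }
  list(image = crop, inside_fraction = inside, visible = TRUE, reason = NA_character_)
}

#' Crop all visible regions of a frame and write a manifest
#'
#' Convenience wrapper used by the `extract` subcommand: runs
#' [extract_regions()] + [visible_regions()] + [crop_region()] for one frame
#' and optionally writes `<frame_id>_<kind>.png` files.
#'
#' @param image Frame array.
#' @param lm Landmark set for the frame.
#' @param frame_id Frame identifier used in file names.
#' @param cfg A [geometry_config()].
#' @param out_dir Directory to write PNG crops into, or NULL to skip writing.
#' @return A list: `manifest` tibble (`frame_id`, `kind`, `center_x`,
#'   `center_y`, `side`, `inside_fraction`, `visible`, `path`) and `crops`,
#'   a named list of crop arrays for the visible regions.
#' @export
extract_frame_crops <- function(image, lm, frame_id, cfg = geometry_config(),
                                out_dir = NULL) {
  vis <- visible_regions(lm, c(dim(image)[2], dim(image)[1]), cfg)
  regions <- extract_regions(lm, cfg)
  crops <- list()
  rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    reg$visible <- reg$visible && reg$kind %in% vis
    cr <- crop_region(image, reg, cfg)
    path <- NA_character_
    if (cr$visible) {
      crops[[reg$kind]] <<- cr$image
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, sprintf("%s_%s.png", frame_id, reg$kind))
        png::writePNG(cr$image, path)
      }
    }
    tibble::tibble(
      frame_id = frame_id, kind = reg$kind,
      center_x = reg$center_x, center_y = reg$center_y, side = reg$side,
      inside_fraction = cr$inside_fraction, visible = cr$visible, path = path
    )
  })
  list(manifest = dplyr::bind_rows(rows), crops = crops)
}
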