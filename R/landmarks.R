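#' The 17 COCO-style anatomical keypoint names
#'
#' Ordered nose, eyes, ears, shoulders, elbows, wrists, hips, knees, ankles
#' (left before right within each pair).
#'
#' @return Character vector of length 17.
#' @export
keypoint_names <- function() {
  c(
    "nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle"
  )
}

#' Build a landmark set
#'
#' A landmark set is a tibble with one row per keypoint and columns `name`,
#' `x`, `y`, `confidence`. Coordinates are pixels, origin top-left, x
#' rightward, y downward; they may lie outside the frame (that encodes
#' "out of field"). Confidences are unitless in `[0, 1]`.
#'
#' @param x,y Numeric length-17 vectors of pixel coordinates, in
#'   [keypoint_names()] order.
#' @param confidence Numeric length-17 vector in `[0, 1]` (default all 1).
#' @return A `ppe_landmarks` tibble (17 rows).
#' @examples
#' lm <- landmark_set(x = rep(100, 17), y = seq(20, 180, length.out = 17))
#' @export
landmark_set <- function(x, y, confidence = rep(1, 17)) {
  nm <- keypoint_names()
  stopifnot(length(x) == 17, length(y) == 17, length(confidence) == 17)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("landmark coordinates must be finite")
  }
  if (any(confidence < 0 | confidence > 1 | !is.finite(confidence))) {
    abort("landmark confidences must lie in [0, 1]")
  }
  out <- tibble::tibble(
    name = nm, x = as.double(x), y = as.double(y),
    confidence = as.double(confidence)
  )
  class(out) <- c("ppe_landmarks", class(out))
  out
}

#' @noRd
as_landmarks <- function(df) {
  stopifnot(is.data.frame(df), all(c("name", "x", "y", "confidence") %in% names(df)))
  df <- df[match(keypoint_names(), df$name), ]
  if (anyNA(df$name)) abort("landmark table must contain all 17 keypoints")
  landmark_set(df$x, df$y, df$confidence)
}

#' Look up one keypoint
#'
#' @param lm A landmark set.
#' @param name Keypoint name.
#' @return Named list with `x`, `y`, `confidence`.
#' @export
keypoint <- function(lm, name) {
  i <- match(name, lm$name)
  if (is.na(i)) abort(sprintf("unknown keypoint '%s'", name))
  list(x = lm$x[i], y = lm$y[i], confidence = lm$confidence[i])
}

kp_xy <- function(lm, name) {
  k <- keypoint(lm, name)
  c(k$x, k$y)
}

kp_ok <- function(lm, names, threshold) {
  all(lm$confidence[match(names, lm$name)] >= threshold)
}

#' Read / write landmark JSON
#'
#' The interchange format is
#' `{"frame_id": str, "keypoints": [{"name", "x", "y", "confidence"} x 17]}`
#' with 0-based float pixel coordinates.
#'
#' @param path File path.
#' @return `read_landmarks()` returns a list with `frame_id` and `landmarks`
#'   (a `ppe_landmarks` tibble).
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  list(frame_id = obj$frame_id, landmarks = as_landmarks(obj$keypoints))
}

#' @rdname read_landmarks
#' @param lm A landmark set.
#' @param frame_id Frame identifier string.
#' @export
write_landmarks <- function(lm, frame_id, path) {
  obj <- list(
    frame_id = frame_id,
    keypoints = as.data.frame(lm[, c("name", "x", "y", "confidence")])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
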