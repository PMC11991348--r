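#' Pose providers
#'
#' A pose provider maps an image to a 17-keypoint landmark set. Two kinds
#' exist: the ground-truth provider, which carries the known landmark layout
#' of a synthetic scene (confidence 1 for rendered joints, 0 for joints
#' flagged hidden), and an external-model adapter wrapping any user function
#' `function(image) -> ppe_landmarks` (e.g. a binding to a lightweight pose
#' network). Providers are deterministic: identical input gives an identical
#' landmark set.
#'
#' Only single-person scenes are supported; a provider that can describe no
#' person returns all-zero confidences, which downstream code treats as "no
#' region visible" rather than an error.
#'
#' @param landmarks The known landmark set (ground-truth provider).
#' @return A `ppe_pose_provider` list with fields `name`, `kind` and
#'   `estimate`.
#' @examples
#' sc <- render_scene(scene_spec(seed = 3))
#' prov <- ground_truth_provider(sc$landmarks)
#' estimate_pose(prov, sc$image)
#' @export
ground_truth_provider <- function(landmarks) {
  stopifnot(inherits(landmarks, "ppe_landmarks"))
  structure(
    list(
      name = "ground_truth", kind = "ground_truth",
      estimate = function(image) landmarks
    ),
    class = "ppe_pose_provider"
  )
}

#' @rdname ground_truth_provider
#' @param fn Function mapping an RGB image array to a `ppe_landmarks`
#'   tibble.
#' @param name Provider name recorded in run metadata.
#' @export
external_pose_provider <- function(fn, name = "external_model") {
  stopifnot(is.function(fn))
  structure(
    list(name = name, kind = "external_model", estimate = fn),
    class = "ppe_pose_provider"
  )
}

#' A provider that sees no person
#'
#' Returns the given layout (or a degenerate all-origin layout) with every
#' confidence 0, so every region is treated as not visible.
#'
#' @export
no_person_provider <- function() {
  structure(
    list(
      name = "no_person", kind = "ground_truth",
      estimate = function(image) {
        landmark_set(rep(0, 17), rep(0, 17), rep(0, 17))
      }
    ),
    class = "ppe_pose_provider"
  )
}

#' Estimate landmarks for an image
#'
#' @param provider A `ppe_pose_provider`.
#' @param image RGB array with positive dimensions.
#' @return A `ppe_landmarks` tibble.
#' @export
estimate_pose <- function(provider, image) {
  stopifnot(inherits(provider, "ppe_pose_provider"))
  assert_image(image)
  if (any(dim(image)[1:2] <= 0)) abort("image must have positive dimensions")
  lm <- provider$estimate(image)
  if (!inherits(lm, "ppe_landmarks")) lm <- as_landmarks(lm)
  lm
}
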