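# Shared fixtures, all generated in code.

# small geometry/feature scale for fast unit tests
small_cfg <- function() geometry_config(crop_out_size = 64)

small_fx <- function() {
  projection_feature_extractor(output_dim = 64, input_size = 64, pool = 8, seed = 11)
}

# plausible random upright skeleton, all confidences 1
random_landmarks <- function() {
  base <- person_landmarks(
    center_x = runif(1, 60, 200),
    top_y = runif(1, 5, 50),
    height = runif(1, 80, 220)
  )
  landmark_set(
    base$x + rnorm(17, 0, 2),
    base$y + rnorm(17, 0, 2)
  )
}

# mirror a landmark set about x = 0 and swap left/right keypoint roles
mirror_landmarks <- function(lm) {
  nm <- lm$name
  swapped <- ifelse(
    startsWith(nm, "left_"), sub("^left_", "right_", nm),
    ifelse(startsWith(nm, "right_"), sub("^right_", "left_", nm), nm)
  )
  idx <- match(keypoint_names(), swapped)
  landmark_set(-lm$x[idx], lm$y[idx], lm$confidence[idx])
}

# the published per-item confusion counts (a=TP, b=FN, c=FP, d=TN)
published_item_counts <- function() {
  tibble::tribble(
    ~item, ~split, ~a, ~b, ~c, ~d,
    "mask", "training", 2620, 148, 74, 2832,
    "mask", "live", 476, 70, 118, 1120,
    "gloves", "training", 5577, 264, 468, 4527,
    "gloves", "live", 1161, 168, 186, 1765,
    "gown", "training", 3725, 51, 136, 3117,
    "gown", "live", 376, 29, 239, 1561
  )
}

# brute-force upper-tail chi-square probability by numeric integration
chi2_tail_oracle <- function(x, df = 1) {
  if (x == 0) return(1)
  f <- function(t) t^(df / 2 - 1) * exp(-t / 2) / (2^(df / 2) * gamma(df / 2))
  stats::integrate(f, x, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}
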