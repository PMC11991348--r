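#' Deterministic projection feature extractor
#'
#' The default desk-scale feature extractor: the crop is block-mean pooled
#' to `pool x pool x 3`, standardised per image (zero mean, unit variance),
#' and mapped through a fixed seeded Gaussian random projection to a
#' length-`output_dim` vector. Deterministic by construction, with a
#' projection matrix of full support so any single-pixel change perturbs
#' the output. A real backbone can be plugged in via
#' [custom_feature_extractor()]; the classifier head adapts to whatever
#' output dimension the extractor reports.
#'
#' @param output_dim Feature vector length F (default 712).
#' @param input_size Expected crop side in pixels (default 224; must be a
#'   multiple of `pool`).
#' @param pool Pooled grid side (default 14).
#' @param seed Seed fixing the projection matrix.
#' @return A `ppe_feature_extractor` list.
#' @export
projection_feature_extractor <- function(output_dim = 712L, input_size = 224L,
                                         pool = 14L, seed = 2026L) {
  stopifnot(output_dim >= 1, input_size %% pool == 0)
  d_in <- as.integer(pool)^2 * 3L
  W <- withr::with_seed(
    seed,
    matrix(rnorm(output_dim * d_in, sd = 1 / sqrt(d_in)), nrow = output_dim)
  )
  structure(
    list(
      name = "seeded_projection", output_dim = as.integer(output_dim),
      input_size = as.integer(input_size), pool = as.integer(pool), W = W
    ),
    class = "ppe_feature_extractor"
  )
}

#' @rdname projection_feature_extractor
#' @param fn Function mapping a crop array to a numeric vector of length
#'   `output_dim`.
#' @param name Extractor name recorded in run metadata.
#' @export
custom_feature_extractor <- function(fn, output_dim, name = "custom") {
  stopifnot(is.function(fn), output_dim >= 1)
  structure(
    list(name = name, output_dim = as.integer(output_dim), fn = fn),
    class = "ppe_feature_extractor"
  )
}

block_pool <- function(image, pool) {
  n <- dim(image)[1]
  f <- n %/% pool
  arr <- array(image, dim = c(f, pool, f, pool, 3))
  apply(arr, c(2, 4, 5), mean)
}

#' Extract a feature vector from one crop
#'
#' @param fx A feature extractor.
#' @param image Crop array of the extractor's expected size.
#' @return Numeric vector of length `fx$output_dim`.
#' @export
extract_features <- function(fx, image) {
  stopifnot(inherits(fx, "ppe_feature_extractor"))
  assert_image(image, "crop")
  if (!is.null(fx$fn)) {
    v <- fx$fn(image)
    if (length(v) != fx$output_dim) abort("custom extractor returned wrong length")
    return(as.numeric(v))
  }
  if (any(dim(image)[1:2] != fx$input_size)) {
    abort(sprintf(
      "crop must be %d x %d x 3, got %s",
      fx$input_size, fx$input_size, paste(dim(image), collapse = " x ")
    ))
  }
  v <- as.vector(block_pool(image, fx$pool))
  v <- (v - mean(v)) / (stats::sd(v) + 1e-8)
  as.numeric(fx$W %*% v)
}

#' Feature matrix for a list of crops
#'
#' @param fx A feature extractor.
#' @param crops List of crop arrays.
#' @return Numeric matrix, one row per crop.
#' @export
extract_feature_matrix <- function(fx, crops) {
  t(vapply(crops, function(cr) extract_features(fx, cr), numeric(fx$output_dim)))
}
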