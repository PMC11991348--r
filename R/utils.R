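#' Derive a child seed from a run seed
#'
#' All randomness in the package funnels through one integer run seed;
#' per-module seeds are derived deterministically from it so that two runs
#' with the same configuration and seed are byte-identical.
#'
#' @param seed Integer run seed.
#' @param what Character tag naming the consumer (e.g. `"render"`,
#'   `"train_face"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(what))
  # cheap deterministic string hash (polynomial rolling, 31-bit)
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(what)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

euclid <- function(p, q) sqrt(sum((p - q)^2))

#' @noRd
assert_image <- function(image, what = "image") {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort(sprintf("%s must be a height x width x 3 numeric array", what))
  }
  invisible(image)
}
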