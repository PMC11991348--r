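#' Train the three region models on synthetic crops
#'
#' Generates balanced synthetic crop datasets (face for the mask model,
#' torso for the gown model, both palms pooled for the glove model), trains
#' one classifier head per item, and returns the bundle ready for
#' [process_frame()]. All randomness derives from `seed`.
#'
#' @param n_per_class Crops per class per region (palms: split evenly
#'   between left and right).
#' @param seed Run seed.
#' @param fx Feature extractor (default [projection_feature_extractor()]).
#' @param epochs Training epochs per head (default 10).
#' @param jitter,noise_sigma Scene generator amplitudes.
#' @param cfg A [geometry_config()].
#' @return List with `models` (a [ppe_models()]), `heads`, `manifests`
#'   (per-region crop manifests) and `evaluation` (tibble of held-out
#'   confusion counts and accuracy per item).
#' @export
train_region_models <- function(n_per_class = 200L, seed = 1L,
                                fx = projection_feature_extractor(),
                                epochs = 10L, jitter = 0.04,
                                noise_sigma = 0.02, cfg = geometry_config()) {
  half <- max(1L, as.integer(n_per_class) %/% 2L)
  sets <- list(
    mask = generate_dataset(n_per_class, "face",
      jitter = jitter,
      noise_sigma = noise_sigma, seed = derive_seed(seed, "ds_face"), cfg = cfg
    ),
    gown = generate_dataset(n_per_class, "torso",
      jitter = jitter,
      noise_sigma = noise_sigma, seed = derive_seed(seed, "ds_torso"), cfg = cfg
    ),
    gloves = {
      l <- generate_dataset(half, "left_palm",
        jitter = jitter,
        noise_sigma = noise_sigma, seed = derive_seed(seed, "ds_lpalm"), cfg = cfg
      )
      r <- generate_dataset(half, "right_palm",
        jitter = jitter,
        noise_sigma = noise_sigma, seed = derive_seed(seed, "ds_rpalm"), cfg = cfg
      )
      list(
        manifest = dplyr::bind_rows(l$manifest, r$manifest),
        crops = c(l$crops, r$crops)
      )
    }
  )

  heads <- purrr::imap(sets, function(ds, item) {
    X <- extract_feature_matrix(fx, ds$crops)
    head <- classifier_head(
      input_dim = fx$output_dim,
      seed = derive_seed(seed, paste0("init_", item))
    )
    train_head(head, X, ds$manifest$label, train_config(
      epochs = epochs, seed = derive_seed(seed, paste0("train_", item))
    ))
  })

  evaluation <- purrr::imap(heads, function(hd, item) {
    h <- hd$history
    tibble::tibble(
      item = item, epochs = nrow(h),
      val_acc = h$val_acc[nrow(h)], val_loss = h$val_loss[nrow(h)]
    )
  }) |> dplyr::bind_rows()

  list(
    models = ppe_models(fx, heads$mask, heads$gloves, heads$gown),
    heads = heads,
    manifests = purrr::map(sets, "manifest"),
    evaluation = evaluation
  )
}
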