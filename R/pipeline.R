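# End-to-end per-frame inference: pose -> visibility -> crops -> three
# binary heads -> per-item verdicts; frame scoring uses the visible-regions
# rule (a frame is "correct" only if every visible region's prediction
# matches ground truth).

#' Bundle the per-item models used by the pipeline
#'
#' Three trained heads (mask on the face crop, gloves on each palm crop,
#' gown on the torso crop) sharing one feature extractor -- or, for tests
#' and oracles, the synthetic colour-rule predictor.
#'
#' @param feature_extractor A `ppe_feature_extractor`.
#' @param mask_head,gloves_head,gown_head Trained [classifier_head()]s.
#' @return A `ppe_models` object.
#' @export
ppe_models <- function(feature_extractor, mask_head, gloves_head, gown_head) {
  stopifnot(
    inherits(feature_extractor, "ppe_feature_extractor"),
    inherits(mask_head, "ppe_head"), inherits(gloves_head, "ppe_head"),
    inherits(gown_head, "ppe_head")
  )
  structure(
    list(
      kind = "heads", fx = feature_extractor,
      heads = list(mask = mask_head, gloves = gloves_head, gown = gown_head)
    ),
    class = "ppe_models"
  )
}

#' @rdname ppe_models
#' @description `oracle_models()` predicts via [oracle_color_rule()]; exact
#'   on synthetic scenes, used to isolate pipeline mechanics from classifier
#'   quality.
#' @export
oracle_models <- function() {
  structure(list(kind = "oracle"), class = "ppe_models")
}

predict_crop <- function(models, item, crop) {
  if (models$kind == "oracle") {
    pred <- oracle_color_rule(crop, item)
    return(tibble::tibble(probability = as.numeric(pred), prediction = pred))
  }
  predict_head(models$heads[[item]], extract_features(models$fx, crop))
}

#' Keep every k-th frame of a sequence
#'
#' Temporal 1:k subsampling (default 1:5) to decorrelate neighbouring
#' frames; keeps indices 0, k, 2k, ... counting from the first frame.
#'
#' @param frames A list (or vector) of frames.
#' @param ratio Keep one frame in `ratio` (integer >= 1, default 5).
#' @return The subsampled list, possibly empty.
#' @export
sample_frames <- function(frames, ratio = 5L) {
  stopifnot(ratio >= 1)
  n <- length(frames)
  if (n == 0) {
    return(frames[0])
  }
  frames[seq(1L, n, by = as.integer(ratio))]
}

#' Process one frame end to end
#'
#' Estimates landmarks, decides region visibility, crops exactly the
#' visible regions, and classifies each with its item's model. Item
#' verdicts: mask from the face region, gown from the torso region, gloves
#' aggregated over the visible palms -- gloved only if every visible palm
#' is predicted gloved (a single visible palm decides alone; mixed gloving
#' is non-adherent). An item with no visible supporting region is
#' not-assessable (`NA`).
#'
#' @param image Frame array.
#' @param provider A pose provider ([ground_truth_provider()] or
#'   [external_pose_provider()]).
#' @param models A [ppe_models()] bundle.
#' @param cfg A [geometry_config()].
#' @param frame_id Identifier carried through the result.
#' @return A `ppe_frame_result`: list with `frame_id`, `regions` (tibble:
#'   kind, visible, probability, prediction, inside_fraction) and `items`
#'   (tibble: item, assessable, probability, prediction).
#' @export
process_frame <- function(image, provider, models, cfg = geometry_config(),
                          frame_id = "frame") {
  stopifnot(inherits(models, "ppe_models"))
  lm <- estimate_pose(provider, image)
  vis <- visible_regions(lm, c(dim(image)[2], dim(image)[1]), cfg)
  regions <- extract_regions(lm, cfg)

  rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    out <- tibble::tibble(
      kind = reg$kind, visible = FALSE, probability = NA_real_,
      prediction = NA, inside_fraction = 0
    )
    if (!reg$kind %in% vis || !isTRUE(reg$visible)) {
      return(out)
    }
    cr <- crop_region(image, reg, cfg)
    if (!cr$visible) {
      return(out)
    }
    pr <- predict_crop(models, region_item(reg$kind), cr$image)
    tibble::tibble(
      kind = reg$kind, visible = TRUE, probability = pr$probability,
      prediction = pr$prediction, inside_fraction = cr$inside_fraction
    )
  })
  regions <- dplyr::bind_rows(rows)

  item_row <- function(item, kinds) {
    sub <- dplyr::filter(regions, .data$kind %in% kinds, .data$visible)
    if (nrow(sub) == 0) {
      return(tibble::tibble(
        item = item, assessable = FALSE,
        probability = NA_real_, prediction = NA
      ))
    }
    tibble::tibble(
      item = item, assessable = TRUE,
      probability = min(sub$probability),
      prediction = all(sub$prediction)
    )
  }
  items <- dplyr::bind_rows(
    item_row("mask", "face"),
    item_row("gloves", c("left_palm", "right_palm")),
    item_row("gown", "torso")
  )

  structure(
    list(frame_id = frame_id, regions = regions, items = items),
    class = "ppe_frame_result"
  )
}

#' @export
print.ppe_frame_result <- function(x, ...) {
  cat(sprintf("<ppe_frame_result> %s\n", x$frame_id))
  print(x$items)
  invisible(x)
}

region_truth <- function(truth, kind) {
  switch(kind,
    face = truth$mask, torso = truth$gown,
    left_palm = truth$gloves_left, right_palm = truth$gloves_right
  )
}

#' Score a frame result against ground-truth labels
#'
#' Correctness is defined over visible regions only:
#' `all_regions_correct` requires every visible region's prediction to
#' match truth; `mask_gown_correct` applies the same rule restricted to
#' the face and torso regions (isolating the impact of glove errors).
#' A flag is `NA` when no region in its scope is visible.
#'
#' @param result A `ppe_frame_result`.
#' @param truth One-row tibble with logical `mask`, `gloves_left`,
#'   `gloves_right`, `gown` (as produced by [render_scene()]).
#' @return List with `frame` (one-row tibble: frame_id, n_visible,
#'   all_regions_correct, mask_gown_correct) and `regions` (tibble:
#'   frame_id, kind, item, truth, prediction, correct, one row per visible
#'   region).
#' @export
score_frame <- function(result, truth) {
  stopifnot(inherits(result, "ppe_frame_result"))
  vis <- dplyr::filter(result$regions, .data$visible)
  regions <- vis |>
    dplyr::mutate(
      frame_id = result$frame_id,
      item = purrr::map_chr(.data$kind, region_item),
      truth = purrr::map_lgl(.data$kind, ~ region_truth(truth, .x)),
      correct = .data$prediction == .data$truth
    ) |>
    dplyr::select("frame_id", "kind", "item", "truth", "prediction", "correct")
  fm <- dplyr::filter(regions, .data$kind %in% c("face", "torso"))
  frame <- tibble::tibble(
    frame_id = result$frame_id,
    n_visible = nrow(regions),
    all_regions_correct = if (nrow(regions) == 0) NA else all(regions$correct),
    mask_gown_correct = if (nrow(fm) == 0) NA else all(fm$correct)
  )
  list(frame = frame, regions = regions)
}

#' Process and score a list of rendered frames
#'
#' Runs [process_frame()] with each frame's ground-truth landmarks (or a
#' supplied provider) and scores against the frame's labels.
#'
#' @param frames List of frames as produced by [render_scene()] /
#'   [generate_event()] (each with `image`, `landmarks`, `labels` and
#'   optionally `frame_id`).
#' @param models A [ppe_models()] bundle.
#' @param cfg A [geometry_config()].
#' @param provider Optional pose provider applied to every frame; default
#'   uses each frame's own ground-truth landmarks.
#' @return List of tibbles `frames` (one row per frame), `regions` (one row
#'   per visible region) and `items` (per-frame item verdicts).
#' @export
run_frames <- function(frames, models, cfg = geometry_config(), provider = NULL) {
  scored <- purrr::imap(frames, function(fr, i) {
    fid <- fr$frame_id %||% sprintf("f%04d", as.integer(i) - 1L)
    prov <- provider %||% ground_truth_provider(fr$landmarks)
    res <- process_frame(fr$image, prov, models, cfg, frame_id = fid)
    sc <- score_frame(res, fr$labels)
    list(
      frame = sc$frame, regions = sc$regions,
      items = dplyr::mutate(res$items, frame_id = fid, .before = 1)
    )
  })
  list(
    frames = purrr::map(scored, "frame") |> dplyr::bind_rows(),
    regions = purrr::map(scored, "regions") |> dplyr::bind_rows(),
    items = purrr::map(scored, "items") |> dplyr::bind_rows()
  )
}

#' Event-level adherence verdict
#'
#' Samples an event's frames at the given ratio, processes them, and takes
#' a majority vote per item over the assessable sampled frames; ties are
#' non-adherent. Frame-level statistics are the primary output of the
#' system -- the event verdict is an aggregation layer on top of them.
#'
#' @param event_frames Ordered list of frames from [generate_event()].
#' @param models A [ppe_models()] bundle.
#' @param cfg A [geometry_config()].
#' @param ratio Frame sampling ratio (default 5, i.e. 1:5).
#' @param event_id Identifier.
#' @return List with `event` (tibble: event_id, item, n_assessed, verdict)
#'   and the `run_frames()` tibbles for the sampled frames.
#' @export
run_event <- function(event_frames, models, cfg = geometry_config(),
                      ratio = 5L, event_id = "event") {
  sampled <- sample_frames(event_frames, ratio)
  run <- run_frames(sampled, models, cfg)
  event <- run$items |>
    dplyr::filter(.data$assessable) |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(
      n_assessed = dplyr::n(),
      verdict = sum(.data$prediction) > dplyr::n() / 2,
      .groups = "drop"
    ) |>
    dplyr::mutate(event_id = event_id, .before = 1)
  c(list(event = event), run)
}

#' Aggregate scored frames into accuracy and confusion tables
#'
#' @param frames Frame-score tibble from [run_frames()].
#' @param regions Region-score tibble from [run_frames()].
#' @param tags Optional tibble keyed by `frame_id` with extra grouping
#'   columns (e.g. clothing, scenery); when given, overall accuracy is also
#'   stratified by each tag column.
#' @return List with `overall` (tibble: definition, correct, incorrect, n,
#'   accuracy), `per_region` (tibble: kind, a, b, c, d, n, accuracy) and,
#'   when tags are supplied, `strata` (correct/incorrect counts and
#'   chi-square per tag column).
#' @export
aggregate_run <- function(frames, regions, tags = NULL) {
  overall <- dplyr::bind_rows(
    tibble::tibble(
      definition = "no_misclassified_regions",
      correct = sum(frames$all_regions_correct, na.rm = TRUE),
      incorrect = sum(!frames$all_regions_correct, na.rm = TRUE)
    ),
    tibble::tibble(
      definition = "no_misclassified_mask_or_gown",
      correct = sum(frames$mask_gown_correct, na.rm = TRUE),
      incorrect = sum(!frames$mask_gown_correct, na.rm = TRUE)
    )
  ) |>
    dplyr::mutate(n = .data$correct + .data$incorrect, accuracy = .data$correct / .data$n)

  per_region <- regions |>
    dplyr::group_by(kind = .data$kind) |>
    dplyr::summarise(
      a = sum(.data$truth & .data$prediction),
      b = sum(.data$truth & !.data$prediction),
      c = sum(!.data$truth & .data$prediction),
      d = sum(!.data$truth & !.data$prediction),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = .data$a + .data$b + .data$c + .data$d,
      accuracy = (.data$a + .data$d) / .data$n
    )

  out <- list(overall = overall, per_region = per_region)

  if (!is.null(tags)) {
    stopifnot("frame_id" %in% names(tags))
    joined <- dplyr::inner_join(frames, tags, by = "frame_id")
    tag_cols <- setdiff(names(tags), "frame_id")
    out$strata <- purrr::map(
      setNames(tag_cols, tag_cols),
      function(col) {
        grp <- joined |>
          dplyr::filter(!is.na(.data$all_regions_correct)) |>
          dplyr::group_by(group = .data[[col]]) |>
          dplyr::summarise(
            correct = sum(.data$all_regions_correct),
            incorrect = sum(!.data$all_regions_correct),
            .groups = "drop"
          )
        if (nrow(grp) != 2) abort(sprintf("tag '%s' must have exactly two groups", col))
        # a run with no errors (or none correct) has a zero marginal: report
        # the counts with an undefined statistic instead of failing
        ct <- tryCatch(
          pearson_chi2(grp$correct, grp$incorrect),
          error = function(e) tibble::tibble(statistic = NA_real_, p_value = NA_real_)
        )
        dplyr::mutate(grp,
          confounder = col, statistic = ct$statistic,
          p_value = ct$p_value
        )
      }
    ) |> dplyr::bind_rows()
  }
  out
}
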