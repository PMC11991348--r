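lm_with <- function(...) {
  # standard skeleton with selected keypoints overridden: lm_with(nose = c(100, 100))
  over <- list(...)
  lm <- person_landmarks(100, 10, 120)
  for (nm in names(over)) {
    i <- match(nm, lm$name)
    lm$x[i] <- over[[nm]][1]
    lm$y[i] <- over[[nm]][2]
  }
  landmark_set(lm$x, lm$y, lm$confidence)
}

test_that("face rule: nose-centred square scaled by the mean ear-nose distance", {
  lm <- lm_with(
    nose = c(100, 100), left_ear = c(120, 100), right_ear = c(80, 100)
  )
  r <- face_region(lm)
  expect_true(r$visible)
  expect_equal(c(r$center_x, r$center_y), c(100, 100))
  expect_equal(r$side, 2 * 1.2 * 20) # 48

  # degenerate: ears coincide with the nose
  deg <- face_region(lm_with(
    nose = c(100, 100), left_ear = c(100, 100), right_ear = c(100, 100)
  ))
  expect_false(deg$visible)
  expect_match(deg$reason, "degenerate")

  # low-confidence required landmark is a visibility signal, not an error
  lo <- lm
  lo$confidence[lo$name == "left_ear"] <- 0.1
  expect_false(face_region(landmark_set(lo$x, lo$y, lo$confidence))$visible)
})

test_that("palm rule: centre extrapolated past the wrist, side 1.6x the forearm", {
  lm <- lm_with(left_elbow = c(0, 0), left_wrist = c(100, 0))
  r <- palm_region(lm, "left")
  expect_equal(c(r$center_x, r$center_y), c(150, 0))
  expect_equal(r$side, 160)

  lm2 <- lm_with(left_elbow = c(0, 0), left_wrist = c(0, 100))
  r2 <- palm_region(lm2, "left")
  expect_equal(c(r2$center_x, r2$center_y), c(0, 150))
  expect_equal(r2$side, 160)

  expect_false(
    palm_region(lm_with(left_elbow = c(5, 5), left_wrist = c(5, 5)), "left")$visible
  )
})

test_that("torso rule: centroid of shoulders and hips, extent to furthest landmark", {
  lm <- lm_with(
    left_shoulder = c(120, 50), right_shoulder = c(80, 50),
    left_hip = c(120, 150), right_hip = c(80, 150)
  )
  r <- torso_region(lm)
  expect_equal(c(r$center_x, r$center_y), c(100, 100))
  expect_equal(r$side, 2 * 0.83 * sqrt(2900))

  sq <- lm_with(
    left_shoulder = c(10, -10), right_shoulder = c(-10, -10),
    left_hip = c(10, 10), right_hip = c(-10, 10)
  )
  rs <- torso_region(sq)
  expect_equal(c(rs$center_x, rs$center_y), c(0, 0))

  expect_false(torso_region(lm_with(
    left_shoulder = c(3, 3), right_shoulder = c(3, 3),
    left_hip = c(3, 3), right_hip = c(3, 3)
  ))$visible)
})

test_that("region constructors are translation, scale and mirror equivariant", {
  withr::with_seed(99, {
    for (i in 1:60) {
      lm <- random_landmarks()
      dx <- runif(1, -50, 50)
      dy <- runif(1, -50, 50)
      s <- runif(1, 0.5, 2)
      shifted <- landmark_set(lm$x + dx, lm$y + dy, lm$confidence)
      scaled <- landmark_set(lm$x * s, lm$y * s, lm$confidence)
      mirrored <- mirror_landmarks(lm)

      for (build in list(
        face_region, torso_region,
        function(l, ...) palm_region(l, "left"),
        function(l, ...) palm_region(l, "right")
      )) {
        r0 <- build(lm)
        expect_true(r0$visible)
        expect_true(r0$side > 0)
        r1 <- build(shifted)
        expect_equal(c(r1$center_x, r1$center_y),
          c(r0$center_x + dx, r0$center_y + dy),
          tolerance = 1e-10
        )
        expect_equal(r1$side, r0$side, tolerance = 1e-10)
        r2 <- build(scaled)
        expect_equal(r2$side, r0$side * s, tolerance = 1e-9)
      }
      # mirroring swaps the palm sides
      rl <- palm_region(lm, "left")
      rm <- palm_region(mirrored, "right")
      expect_equal(rm$center_x, -rl$center_x, tolerance = 1e-10)
      expect_equal(rm$center_y, rl$center_y, tolerance = 1e-10)
      expect_equal(rm$side, rl$side, tolerance = 1e-10)
    }
  })
})

test_that("visibility rules: confidence threshold, in-frame wrist, monotonicity", {
  lm <- person_landmarks(100, 10, 150)
  expect_setequal(
    visible_regions(lm, c(256, 256)),
    c("face", "torso", "left_palm", "right_palm")
  )

  # wrist out of the image field excludes that palm
  out <- lm
  i <- match("right_wrist", out$name)
  out$x[i] <- -10
  out <- landmark_set(out$x, out$y, out$confidence)
  expect_false("right_palm" %in% visible_regions(out, c(256, 256)))
  expect_true("left_palm" %in% visible_regions(out, c(256, 256)))

  # zero-confidence nose excludes the face (back-of-head proxy)
  conf <- rep(1, 17)
  conf[match("nose", keypoint_names())] <- 0
  noface <- landmark_set(lm$x, lm$y, conf)
  expect_false("face" %in% visible_regions(noface, c(256, 256)))

  # raising the threshold never adds a region
  withr::with_seed(7, {
    for (i in 1:40) {
      lmr <- random_landmarks()
      lmr$confidence <- runif(17)
      lmr <- landmark_set(lmr$x, lmr$y, lmr$confidence)
      thresholds <- sort(runif(3))
      vis <- lapply(thresholds, function(th) {
        visible_regions(lmr, c(256, 256), geometry_config(visibility_confidence_threshold = th))
      })
      expect_true(all(vis[[2]] %in% vis[[1]]))
      expect_true(all(vis[[3]] %in% vis[[2]]))
    }
  })
})

test_that("cropping zero-pads, reports inside fraction, and is exact in-bounds", {
  img <- array(0, dim = c(40, 40, 3))
  img[, , 1] <- matrix(runif(1600), 40, 40)
  img[, , 2] <- 0.5

  # in-bounds window resampled at its own size reproduces the source exactly
  reg <- tibble::tibble(
    kind = "face", center_x = 20, center_y = 20, side = 16,
    visible = TRUE, reason = NA_character_
  )
  cfg <- geometry_config(crop_out_size = 16)
  cr <- crop_region(img, reg, cfg)
  expect_equal(cr$inside_fraction, 1)
  expect_equal(cr$image, img[13:28, 13:28, ])

  # independent nearest-neighbour oracle at a different output size
  cfg8 <- geometry_config(crop_out_size = 8)
  cr8 <- crop_region(img, reg, cfg8)
  oracle <- array(0, dim = c(8, 8, 3))
  for (i in 1:8) {
    for (j in 1:8) {
      sy <- floor(12 + (i - 0.5) * 2) + 1
      sx <- floor(12 + (j - 0.5) * 2) + 1
      oracle[i, j, ] <- img[sy, sx, ]
    }
  }
  expect_equal(cr8$image, oracle)

  # constant-colour frame -> constant crop
  flat <- array(0.3, dim = c(40, 40, 3))
  expect_true(all(crop_region(flat, reg, cfg)$image == 0.3))

  # window half outside: zero-padded band and inside fraction 1/2
  half <- tibble::tibble(
    kind = "face", center_x = 0, center_y = 20, side = 16,
    visible = TRUE, reason = NA_character_
  )
  ch <- crop_region(flat, half, cfg)
  expect_equal(ch$inside_fraction, 0.5)
  expect_true(all(ch$image[, 1:8, ] == 0))
  expect_true(all(ch$image[, 9:16, ] == 0.3))

  # degenerate and fully-outside windows are visibility signals
  tiny <- tibble::tibble(
    kind = "face", center_x = 20, center_y = 20, side = 0.5,
    visible = TRUE, reason = NA_character_
  )
  expect_false(crop_region(img, tiny, cfg)$visible)
  gone <- tibble::tibble(
    kind = "face", center_x = 500, center_y = 500, side = 16,
    visible = TRUE, reason = NA_character_
  )
  expect_false(crop_region(img, gone, cfg)$visible)
})

test_that("frame crop extraction writes a manifest consistent with visibility", {
  sc <- render_scene(scene_spec(seed = 21))
  out <- withr::local_tempdir()
  res <- extract_frame_crops(sc$image, sc$landmarks, "f0", out_dir = out)
  expect_equal(nrow(res$manifest), 4)
  expect_true(all(res$manifest$visible))
  expect_setequal(names(res$crops), res$manifest$kind)
  expect_true(all(file.exists(res$manifest$path)))
  # written PNG round-trips the crop
  back <- png::readPNG(res$manifest$path[res$manifest$kind == "face"])
  expect_equal(back, res$crops$face, tolerance = 1 / 255)
})
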