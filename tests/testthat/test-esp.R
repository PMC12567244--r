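test_that("single-hue and background images classify as expected", {
  blue <- classify_pixels(flat_image(c(0, 0, 255)))
  expect_equal(unname(pixel_class_counts(blue)["positive"]), 100L)

  white <- classify_pixels(flat_image(c(255, 255, 255)))
  expect_equal(unname(pixel_class_counts(white)["background"]), 100L)
  expect_error(quantify_areas(white), "background")

  magenta <- classify_pixels(flat_image(c(255, 0, 255)))
  expect_equal(unname(pixel_class_counts(magenta)["other"]), 100L)

  expect_error(classify_pixels(array(0, dim = c(0, 3, 3))), "empty image")
})

test_that("every default palette color lands in its intended class", {
  pal <- default_mep_palette()
  for (cls in names(pal)) {
    for (j in seq_len(nrow(pal[[cls]]))) {
      counts <- pixel_class_counts(classify_pixels(flat_image(pal[[cls]][j, ])))
      expect_equal(unname(counts[cls]), 100L)
    }
  }
})

test_that("generator-produced class counts are recovered exactly", {
  # 3000 blue, 1000 red, 6000 green on 90,000 white background pixels
  spec <- synthetic_image_spec(
    width = 400L, height = 250L,
    class_fractions = c(positive = 0.3, negative = 0.1, neutral = 0.6),
    surface_fraction = 0.1,
    palette = list(positive = rbind(c(0, 0, 255)),
                   negative = rbind(c(255, 0, 0)),
                   neutral = rbind(c(0, 200, 0))),
    seed = 7L
  )
  im <- gen_esp_image(spec)
  counts <- pixel_class_counts(classify_pixels(im$image))
  expect_equal(unname(counts),
               c(3000L, 1000L, 6000L, 0L, 90000L))
  expect_equal(im$ledger$n_pixels, c(3000L, 1000L, 6000L))
})

test_that("area percentages and balance reproduce the reference examples", {
  strong <- area_result_for(26.86, 8.80, seed = 3L)
  expect_equal(strong$pct_positive, 26.86, tolerance = 1e-9)
  expect_equal(strong$pct_negative, 8.80, tolerance = 1e-9)
  expect_equal(strong$area_balance, 18.06, tolerance = 1e-9)

  moderate <- area_result_for(24.89, 6.00, seed = 4L)
  expect_equal(moderate$area_balance, 18.89, tolerance = 1e-9)

  negative <- area_result_for(9.85, 14.82, seed = 5L)
  expect_equal(negative$area_balance, -4.97, tolerance = 1e-9)
})

test_that("class percentages always sum to 100 over the surface", {
  set.seed(11)
  for (i in 1:10) {
    f_pos <- runif(1, 0.05, 0.4)
    f_neg <- runif(1, 0.05, 0.4)
    spec <- synthetic_image_spec(
      width = 120L, height = 120L,
      class_fractions = c(positive = f_pos, negative = f_neg,
                          neutral = 1 - f_pos - f_neg),
      surface_fraction = runif(1, 0.2, 0.8), seed = i
    )
    res <- quantify_areas(classify_pixels(gen_esp_image(spec)$image))
    expect_equal(res$pct_positive + res$pct_negative + res$pct_neutral, 100,
                 tolerance = 1e-9)
    expect_true(abs(res$area_balance) <= 100)
  }
})

test_that("all-neutral surface gives zero balance", {
  spec <- synthetic_image_spec(
    width = 60L, height = 60L,
    class_fractions = c(positive = 0, negative = 0, neutral = 1),
    surface_fraction = 0.5, seed = 2L
  )
  res <- quantify_areas(classify_pixels(gen_esp_image(spec)$image))
  expect_equal(res$pct_neutral, 100)
  expect_equal(res$area_balance, 0)
})

test_that("quantification is invariant under translation and 90-degree rotation", {
  im <- gen_esp_image(synthetic_image_spec(width = 80L, height = 80L,
                                           surface_fraction = 0.3, seed = 9L))
  base <- quantify_areas(classify_pixels(im$image))

  # translate: embed in a larger white canvas at an offset
  big <- array(1, dim = c(120L, 130L, 3L))
  big[31:110, 41:120, ] <- im$image
  shifted <- quantify_areas(classify_pixels(big))
  expect_equal(shifted[1:4], base[1:4])
  expect_equal(shifted$n_surface_pixels, base$n_surface_pixels)

  # rotate 90 degrees
  rot <- aperm(im$image, c(2, 1, 3))[dim(im$image)[2]:1, , , drop = FALSE]
  rotated <- quantify_areas(classify_pixels(rot))
  expect_equal(rotated[1:4], base[1:4])
})

test_that("esp_features forms the contrast and validates extrema", {
  area <- area_result_for(26.86, 8.80)
  f <- esp_features(area, esp_max = 0.05, esp_min = -0.05)
  expect_equal(f$contrast, 0.10)
  expect_equal(f$area_balance, area$area_balance)
  expect_true(is.na(f$esp_score))
  expect_equal(esp_features(area, 0, 0)$contrast, 0)
  expect_error(esp_features(area, -0.02, 0.01), "esp_max")
})

test_that("ESP Score rewards cohort-dominant profiles and handles degeneracy", {
  # one compound dominating all four components scores 1, the other 0
  feats <- data.frame(esp_max = c(0.08, 0.02), esp_min = c(-0.09, -0.03),
                      contrast = c(0.17, 0.05), area_balance = c(20, -5))
  scored <- esp_score(feats)
  expect_equal(scored$esp_score, c(1, 0))

  # single-compound cohort: all components constant -> 0.5
  expect_equal(esp_score(feats[1, ])$esp_score, 0.5)
  expect_error(esp_score(feats[0, ]), "empty cohort")
  # reversing the minimum-sign convention changes the ordering weighting
  flipped <- esp_score(feats, esp_min_sign = 1)
  expect_equal(flipped$esp_score, c(0.75, 0.25))
})

test_that("ESP Score is invariant under positive affine rescaling of a component", {
  set.seed(21)
  feats <- data.frame(esp_max = runif(6, 0.01, 0.1),
                      esp_min = runif(6, -0.1, -0.01))
  feats$contrast <- feats$esp_max - feats$esp_min
  feats$area_balance <- runif(6, -30, 30)
  base <- esp_score(feats)$esp_score
  shifted <- feats
  shifted$area_balance <- 3.7 * shifted$area_balance + 11
  expect_equal(esp_score(shifted)$esp_score, base, tolerance = 1e-12)
})

test_that("cohort quantification joins extrema and refuses silent reduction", {
  td <- withr::local_tempdir()
  ids <- c("A", "B")
  paths <- file.path(td, paste0(ids, ".png"))
  specs <- list(exact_image_spec(30, 10, seed = 1L),
                exact_image_spec(10, 25, seed = 2L))
  for (i in 1:2) write_esp_image(gen_esp_image(specs[[i]])$image, paths[i])
  manifest <- data.frame(compound_id = ids, image_path = paths)
  extrema <- data.frame(compound_id = ids, esp_max = c(0.06, 0.03),
                        esp_min = c(-0.04, -0.08))

  out <- esp_quantify(manifest, extrema)
  expect_equal(out$compound_id, ids)
  expect_equal(out$area_balance, c(20, -15), tolerance = 1e-9)
  expect_equal(out$contrast, c(0.10, 0.11))
  expect_true(all(out$esp_score >= 0 & out$esp_score <= 1))

  expect_error(esp_quantify(manifest), "area_only")
  reduced <- esp_quantify(manifest, area_only = TRUE)
  expect_equal(reduced$esp_score, c(1, 0))

  manifest$image_path[2] <- file.path(td, "missing.png")
  expect_error(esp_quantify(manifest, extrema), "missing image for compound B")
})
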