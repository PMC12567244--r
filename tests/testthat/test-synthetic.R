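test_that("image generation is a pure function of its spec", {
  spec <- synthetic_image_spec(width = 90L, height = 70L, seed = 5L)
  a <- gen_esp_image(spec)
  b <- gen_esp_image(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$ledger, b$ledger)

  td <- withr::local_tempdir()
  p1 <- file.path(td, "a.png"); p2 <- file.path(td, "b.png")
  write_esp_image(a$image, p1)
  write_esp_image(b$image, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # a different seed moves the blob but keeps the ledger
  c <- gen_esp_image(synthetic_image_spec(width = 90L, height = 70L, seed = 6L))
  expect_false(identical(a$image, c$image))
  expect_identical(a$ledger, c$ledger)
})

test_that("ledger counts follow floor-with-leftover-to-neutral rounding", {
  spec <- synthetic_image_spec(
    width = 100L, height = 100L,
    class_fractions = c(positive = 0.333, negative = 0.333, neutral = 0.334),
    surface_fraction = 0.07, seed = 1L  # 700 surface pixels
  )
  led <- gen_esp_image(spec)$ledger
  expect_equal(led$n_pixels, c(floor(0.333 * 700), floor(0.333 * 700),
                               700L - 2L * floor(0.333 * 700)))
  expect_equal(sum(led$n_pixels), 700L)
})

test_that("invalid image specs are rejected", {
  expect_error(synthetic_image_spec(class_fractions = c(positive = 0.6,
                                                        negative = 0.6,
                                                        neutral = -0.2)),
               "sum to 1")
  expect_error(synthetic_image_spec(surface_fraction = 0), "0, 1")
})

test_that("descriptor cohorts are reproducible and respect ranges", {
  spec <- synthetic_cohort_spec(n_compounds = 16L, seed = 12L)
  a <- gen_descriptor_cohort(spec)
  b <- gen_descriptor_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a$energies), 16L)
  expect_true(all(a$energies$e_homo < a$energies$e_lumo))
  expect_true(all(a$truth$gap >= 0.005 & a$truth$gap <= 0.11))
  expect_true(all(a$truth$frac_neutral > 0))
})

test_that("planted component orderings produce the planted composite ranking", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(4:20, 1)
    planted <- sample(n)
    spec <- synthetic_cohort_spec(n_compounds = n, planted_order = planted,
                                  seed = 1000L + rep)
    cohort <- gen_descriptor_cohort(spec)
    desc <- compute_descriptor_table(cohort$energies)
    esp <- esp_score(cohort$truth[c("esp_max", "esp_min", "contrast",
                                    "area_balance")])
    esp$compound_id <- cohort$truth$compound_id
    tab <- build_score_table(desc, esp)
    got <- tab$rank[match(cohort$truth$compound_id, tab$compound_id)]
    expect_equal(got, planted)
    expect_false(any(tab$tied))
  }
})

test_that("a degenerate gap range collapses the gap columns to the 0.5 rule", {
  spec <- synthetic_cohort_spec(n_compounds = 6L, gap_range = c(0.05, 0.05),
                                seed = 3L)
  cohort <- gen_descriptor_cohort(spec)
  desc <- compute_descriptor_table(cohort$energies)
  expect_equal(minmax_normalize(desc$inv_gap), rep(0.5, 6))
  expect_equal(minmax_normalize(desc$softness), rep(0.5, 6))
})

test_that("planted order must be a permutation", {
  expect_error(synthetic_cohort_spec(n_compounds = 4L,
                                     planted_order = c(1, 2, 2, 4)),
               "permutation")
  expect_error(synthetic_cohort_spec(n_compounds = 4L, planted_order = 1:3),
               "permutation")
})

test_that("synthetic IC50 tables land in the plausible cytotoxicity range", {
  tab <- gen_ic50_table(3, seed = 5L)
  expect_equal(nrow(tab), 12L)
  expect_identical(tab, gen_ic50_table(3, seed = 5L))
  expect_true(all(tab$ic50 >= 3 & tab$ic50 <= 100))
  si <- si_table(tab)
  expect_true(all(is.finite(si$si) & si$si > 0))

  # planted ratio comes straight back out
  planted <- data.frame(compound_id = "P", cell_line = c("WI-38", "HeLa"),
                        ic50 = c(42, 4.2))
  expect_equal(display_si(si_table(planted)$si), 10.00)
})

test_that("study-input writer materializes a consistent fixture set", {
  td <- withr::local_tempdir()
  out <- gen_study_inputs(td, synthetic_cohort_spec(n_compounds = 3L, seed = 8L),
                          image_width = 120L, image_height = 120L)
  for (f in c("energies", "manifest", "extrema", "ic50", "truth_csv"))
    expect_true(file.exists(out[[f]]))
  manifest <- read_image_manifest(out$manifest)
  expect_true(all(file.exists(manifest$image_path)))
  # ledger percentages in the truth table match the written images
  esp <- esp_quantify(manifest, read_esp_extrema(out$extrema))
  expect_equal(esp$pct_positive, out$truth$ledger_pct_positive,
               tolerance = 1e-9)
  expect_equal(esp$pct_negative, out$truth$ledger_pct_negative,
               tolerance = 1e-9)
})
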