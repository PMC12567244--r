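# shared fixture builders: everything generated in code at test time

# exact-count surface image: 10,000 surface pixels on a 250x400 canvas so a
# fraction given to 4 decimals maps to an integer pixel count
exact_image_spec <- function(pct_positive, pct_negative, seed = 1L,
                             palette = default_mep_palette()) {
  synthetic_image_spec(
    width = 400L, height = 250L,
    class_fractions = c(positive = pct_positive / 100,
                        negative = pct_negative / 100,
                        neutral = 1 - (pct_positive + pct_negative) / 100),
    surface_fraction = 0.1,
    palette = palette,
    seed = seed
  )
}

area_result_for <- function(pct_positive, pct_negative, seed = 1L) {
  im <- gen_esp_image(exact_image_spec(pct_positive, pct_negative, seed))
  quantify_areas(classify_pixels(im$image))
}

random_valid_energies <- function(n) {
  e1 <- runif(n, -1, 1)
  e2 <- runif(n, -1, 1)
  data.frame(compound_id = sprintf("C%03d", seq_len(n)),
             e_homo = pmin(e1, e2) - 1e-6, e_lumo = pmax(e1, e2) + 1e-6)
}

# flat single-color image (height x width x 3, values in [0,1])
flat_image <- function(rgb, width = 10L, height = 10L) {
  array(rep(rgb / 255, each = width * height), dim = c(height, width, 3L))
}
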