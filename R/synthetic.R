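# Synthetic study inputs with known ground truth: descriptor cohorts,
# MEP-style images with exact per-class pixel ledgers, ESP extrema, IC50
# tables. Every generator is a pure function of its spec + seed.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Default synthetic MEP palette
#'
#' Per-class RGB colors (0-255 rows) at the centers of the default HSV hue
#' windows of [esp_color_thresholds()]: red/orange/yellow for negative,
#' green for neutral, cyan/blue for positive.
#'
#' @return Named list of RGB matrices, one row per color.
#' @export
default_mep_palette <- function() {
  list(
    positive = rbind(c(0, 255, 255), c(0, 0, 255)),
    negative = rbind(c(255, 0, 0), c(255, 165, 0), c(255, 255, 0)),
    neutral  = rbind(c(0, 200, 0))
  )
}

#' Specification for one synthetic MEP-style image
#'
#' Describes a flat-colored surface blob on a white background whose
#' per-class pixel counts are known exactly. The blob is the set of surface
#' pixels nearest a (seed-jittered) center, sliced into angular sectors
#' that are filled class by class, so regions are contiguous as in a real
#' MEP render. Class pixel counts are `floor(fraction * n_surface)` for the
#' positive and negative classes with every leftover pixel assigned to
#' neutral, making the ledger exact by construction.
#'
#' @param width,height Image dimensions in pixels.
#' @param class_fractions Named fractions of surface pixels for `positive`,
#'   `negative`, `neutral`; non-negative, summing to 1.
#' @param surface_fraction Fraction of the image covered by the surface
#'   blob, in `(0, 1]`.
#' @param palette Per-class colors, see [default_mep_palette()].
#' @param seed Integer; fixes blob center jitter and sector start angle.
#' @return List of class `"synthetic_image_spec"`.
#' @export
synthetic_image_spec <- function(width = 400L, height = 400L,
                                 class_fractions = c(positive = 0.30,
                                                     negative = 0.10,
                                                     neutral = 0.60),
                                 surface_fraction = 0.35,
                                 palette = default_mep_palette(),
                                 seed = 1L) {
  stopifnot(width >= 1L, height >= 1L)
  cls <- c("positive", "negative", "neutral")
  if (!setequal(names(class_fractions), cls))
    stop("class_fractions must be named exactly ",
         paste(cls, collapse = ", "), call. = FALSE)
  cf <- class_fractions[cls]
  if (any(cf < 0) || abs(sum(cf) - 1) > 1e-9)
    stop("class fractions must be non-negative and sum to 1", call. = FALSE)
  if (surface_fraction <= 0 || surface_fraction > 1)
    stop("surface_fraction must lie in (0, 1]", call. = FALSE)
  stopifnot(setequal(names(palette), cls))
  structure(list(width = as.integer(width), height = as.integer(height),
                 class_fractions = cf, surface_fraction = surface_fraction,
                 palette = palette, seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

#' Generate a synthetic MEP-style image with an exact pixel ledger
#'
#' @param spec A [synthetic_image_spec()].
#' @return List with `image` (`height x width x 3` array in `[0, 1]`),
#'   `ledger` (`data.frame` of per-class pixel counts and exact percentages
#'   of surface pixels) and `n_surface_pixels`. Deterministic for a fixed
#'   spec: the same spec yields byte-identical images.
#' @export
gen_esp_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  w <- spec$width; h <- spec$height
  n_total <- w * h
  n_surface <- max(1L, round(spec$surface_fraction * n_total))

  cf <- spec$class_fractions
  # epsilon guard: fractions entered as exact decimals (0.06 * 10000 ->
  # 599.9999...) must not lose a pixel to binary representation fuzz
  n_pos <- as.integer(floor(cf[["positive"]] * n_surface + 1e-9))
  n_neg <- as.integer(floor(cf[["negative"]] * n_surface + 1e-9))
  n_neu <- n_surface - n_pos - n_neg  # leftover pixels land in neutral
  counts <- c(positive = n_pos, negative = n_neg, neutral = n_neu)

  jit <- with_seed(spec$seed, list(
    cx = (w - 1) / 2 + stats::runif(1, -0.05, 0.05) * w,
    cy = (h - 1) / 2 + stats::runif(1, -0.05, 0.05) * h,
    a0 = stats::runif(1, 0, 2 * pi)
  ))

  idx <- seq_len(n_total) - 1L
  px <- idx %% w
  py <- idx %/% w
  d2 <- (px - jit$cx)^2 + (py - jit$cy)^2
  surf <- order(d2, idx)[seq_len(n_surface)]
  ang <- (atan2(py[surf] - jit$cy, px[surf] - jit$cx) - jit$a0) %% (2 * pi)
  surf <- surf[order(ang, d2[surf], surf)]

  img <- array(1, dim = c(h, w, 3L))
  offset <- 0L
  for (k in c("positive", "negative", "neutral")) {
    nk <- counts[[k]]
    if (nk == 0L) next
    sector <- surf[offset + seq_len(nk)]
    offset <- offset + nk
    cols <- spec$palette[[k]]
    nc <- nrow(cols)
    sub <- floor((seq_len(nk) - 1L) * nc / nk) + 1L  # contiguous sub-arcs
    for (j in seq_len(nc)) {
      ii <- sector[sub == j]
      if (!length(ii)) next
      cells <- cbind(py[ii] + 1L, px[ii] + 1L)
      img[cbind(cells, 1L)] <- cols[j, 1] / 255
      img[cbind(cells, 2L)] <- cols[j, 2] / 255
      img[cbind(cells, 3L)] <- cols[j, 3] / 255
    }
  }

  ledger <- data.frame(
    class = names(counts),
    n_pixels = as.integer(counts),
    pct = 100 * as.integer(counts) / n_surface
  )
  list(image = img, ledger = ledger, n_surface_pixels = n_surface)
}

#' Write an image array to PNG or JPEG
#'
#' @param image `height x width x 3` array in `[0, 1]`.
#' @param path Output path; format chosen by extension.
#' @param quality JPEG quality in `(0, 1]` (ignored for PNG).
#' @return `path`, invisibly.
#' @export
write_esp_image <- function(image, path, quality = 0.95) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(image, path, quality = quality),
    stop("unsupported image format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Specification for a synthetic compound cohort
#'
#' Emulates a small medicinal-chemistry cohort: frontier-orbital energies
#' whose gaps span roughly 0.005-0.11 energy units (the spread typical of a
#' series of closely related heterocycles), plus per-compound ESP surface
#' truth (extrema and class fractions). An optional `planted_order` plants
#' a known composite ranking: all score components (softness,
#' electrophilicity, inverse gap, ESP features) are co-ordered so that the
#' compound with planted rank 1 dominates every component, making the true
#' ranking unambiguous and tie-free.
#'
#' @param n_compounds Cohort size.
#' @param gap_range Strictly positive interval for HOMO-LUMO gaps.
#' @param homo_range Interval for HOMO energies (typically negative).
#' @param planted_order Optional integer permutation of `1:n_compounds`;
#'   `planted_order[i]` is the intended composite rank of compound `i`.
#' @param seed Integer seed.
#' @return List of class `"synthetic_cohort_spec"`.
#' @export
synthetic_cohort_spec <- function(n_compounds = 16L,
                                  gap_range = c(0.005, 0.11),
                                  homo_range = c(-0.31, -0.18),
                                  planted_order = NULL,
                                  seed = 1L) {
  stopifnot(n_compounds >= 1L,
            length(gap_range) == 2L, gap_range[1] > 0,
            gap_range[2] >= gap_range[1],
            length(homo_range) == 2L, homo_range[2] >= homo_range[1])
  if (!is.null(planted_order)) {
    planted_order <- as.integer(planted_order)
    if (length(planted_order) != n_compounds ||
        !setequal(planted_order, seq_len(n_compounds)))
      stop("planted_order must be a permutation of 1:", n_compounds,
           call. = FALSE)
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 gap_range = gap_range, homo_range = homo_range,
                 planted_order = planted_order, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# distinct sorted draws; strictly increasing with probability 1
.sorted_runif <- function(n, lo, hi) sort(stats::runif(n, lo, hi))

#' Generate a synthetic compound cohort with ground truth
#'
#' Draws frontier-orbital energies and ESP surface truth for
#' `n_compounds`. Without a planted order, energies and ESP features are
#' independent uniform draws. With `planted_order`, gaps are assigned
#' ascending in rank (rank 1 gets the smallest gap, hence the highest
#' softness and inverse gap), HOMO energies descending in magnitude with
#' rank (so electronegativity and electrophilicity are also descending in
#' rank), and ESP maxima/minima/fractions are co-ordered the same way, so
#' the true composite ranking equals `planted_order` for any non-negative
#' weights.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return List with `energies` (`compound_id`, `e_homo`, `e_lumo`) and
#'   `truth` (per-compound descriptors via [compute_descriptor_table()]
#'   plus `esp_max`, `esp_min`, `frac_positive`, `frac_negative`,
#'   `frac_neutral`, `area_balance` and, when planted, `planted_rank`).
#' @export
gen_descriptor_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  n <- spec$n_compounds
  ids <- sprintf("C%02d", seq_len(n))
  gr <- spec$gap_range; hr <- spec$homo_range

  draws <- with_seed(spec$seed, {
    if (is.null(spec$planted_order)) {
      list(gap = stats::runif(n, gr[1], gr[2]),
           e_homo = stats::runif(n, hr[1], hr[2]),
           esp_max = stats::runif(n, 0.02, 0.09),
           esp_min = stats::runif(n, -0.09, -0.02),
           f_pos = stats::runif(n, 0.10, 0.30),
           f_neg = stats::runif(n, 0.05, 0.20))
    } else {
      r <- spec$planted_order
      # sorted component pools, dealt out by rank so rank 1 dominates all
      list(gap = .sorted_runif(n, gr[1], gr[2])[r],
           e_homo = .sorted_runif(n, hr[1], hr[2])[r],
           esp_max = rev(.sorted_runif(n, 0.02, 0.09))[r],
           esp_min = .sorted_runif(n, -0.09, -0.02)[r],
           f_pos = rev(.sorted_runif(n, 0.10, 0.30))[r],
           f_neg = .sorted_runif(n, 0.05, 0.20)[r])
    }
  })

  energies <- data.frame(compound_id = ids,
                         e_homo = draws$e_homo,
                         e_lumo = draws$e_homo + draws$gap,
                         stringsAsFactors = FALSE)
  truth <- compute_descriptor_table(energies)
  truth$esp_max <- draws$esp_max
  truth$esp_min <- draws$esp_min
  truth$contrast <- truth$esp_max - truth$esp_min
  truth$frac_positive <- draws$f_pos
  truth$frac_negative <- draws$f_neg
  truth$frac_neutral <- 1 - draws$f_pos - draws$f_neg
  truth$area_balance <- 100 * (draws$f_pos - draws$f_neg)
  if (!is.null(spec$planted_order)) truth$planted_rank <- spec$planted_order
  list(energies = energies, truth = truth)
}

#' Generate a synthetic IC50 table
#'
#' Draws log-normally distributed IC50 values (µM) for one normal line and
#' three tumor lines, clamped to the 3-100 µM window typical of moderately
#' active cytotoxic heterocycles; the normal fibroblast line is drawn less
#' sensitive (40-100 µM) than the tumor lines. The `sd` column is a nominal
#' 5% of the value, mimicking triplicate-assay spread.
#'
#' @param n_compounds Number of compounds.
#' @param seed Integer seed.
#' @param tumor_lines Character vector of tumor cell-line names.
#' @param normal_line Name of the normal line.
#' @return Long-format `data.frame`: `compound_id`, `cell_line`, `ic50`,
#'   `sd`; `n_compounds * (length(tumor_lines) + 1)` rows.
#' @export
gen_ic50_table <- function(n_compounds, seed = 1L,
                           tumor_lines = c("HeLa", "HepG-2", "MCF-7"),
                           normal_line = "WI-38") {
  stopifnot(n_compounds >= 1L)
  ids <- sprintf("C%02d", seq_len(n_compounds))
  lines <- c(normal_line, tumor_lines)
  with_seed(seed, {
    rows <- lapply(ids, function(id) {
      normal <- pmin(pmax(stats::rlnorm(1, log(70), 0.15), 40), 100)
      tumor <- pmin(pmax(stats::rlnorm(length(tumor_lines), log(15), 0.7),
                         3), 100)
      data.frame(compound_id = id, cell_line = lines,
                 ic50 = c(normal, tumor), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$sd <- round(0.05 * out$ic50, 2)
    rownames(out) <- NULL
    out
  })
}

#' Write a complete synthetic study-input set to disk
#'
#' Materializes everything the full pipeline consumes: a frontier-orbital
#' energy CSV, one PNG MEP-style image per compound (class fractions taken
#' from the cohort truth), an image manifest, an ESP-extrema CSV, an IC50
#' CSV, and the ground-truth table (including each image's exact pixel
#' ledger percentages).
#'
#' @param dir Output directory (created if needed).
#' @param spec A [synthetic_cohort_spec()].
#' @param image_width,image_height,surface_fraction Image geometry passed to
#'   [synthetic_image_spec()].
#' @return List of file paths (`energies`, `manifest`, `extrema`, `ic50`,
#'   `truth`) plus the `truth` `data.frame` itself.
#' @export
gen_study_inputs <- function(dir, spec = synthetic_cohort_spec(),
                             image_width = 400L, image_height = 400L,
                             surface_fraction = 0.35) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  cohort <- gen_descriptor_cohort(spec)
  truth <- cohort$truth
  ids <- truth$compound_id

  img_paths <- character(length(ids))
  led_pos <- led_neg <- led_neu <- numeric(length(ids))
  for (i in seq_along(ids)) {
    ispec <- synthetic_image_spec(
      width = image_width, height = image_height,
      class_fractions = c(positive = truth$frac_positive[i],
                          negative = truth$frac_negative[i],
                          neutral = truth$frac_neutral[i]),
      surface_fraction = surface_fraction,
      seed = spec$seed + i
    )
    im <- gen_esp_image(ispec)
    img_paths[i] <- file.path(dir, "images", paste0(ids[i], ".png"))
    write_esp_image(im$image, img_paths[i])
    led <- im$ledger
    led_pos[i] <- led$pct[led$class == "positive"]
    led_neg[i] <- led$pct[led$class == "negative"]
    led_neu[i] <- led$pct[led$class == "neutral"]
  }
  truth$ledger_pct_positive <- led_pos
  truth$ledger_pct_negative <- led_neg
  truth$ledger_pct_neutral <- led_neu

  paths <- list(
    energies = file.path(dir, "energies.csv"),
    manifest = file.path(dir, "manifest.csv"),
    extrema = file.path(dir, "extrema.csv"),
    ic50 = file.path(dir, "ic50.csv"),
    truth_csv = file.path(dir, "truth.csv")
  )
  utils::write.csv(cohort$energies, paths$energies, row.names = FALSE)
  # image paths are stored relative to the manifest's own directory
  utils::write.csv(data.frame(compound_id = ids,
                              image_path = file.path("images",
                                                     basename(img_paths)),
                              stringsAsFactors = FALSE),
                   paths$manifest, row.names = FALSE)
  utils::write.csv(truth[c("compound_id", "esp_max", "esp_min")],
                   paths$extrema, row.names = FALSE)
  utils::write.csv(gen_ic50_table(spec$n_compounds, seed = spec$seed),
                   paths$ic50, row.names = FALSE)
  utils::write.csv(truth, paths$truth_csv, row.names = FALSE)
  c(paths, list(truth = truth))
}
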