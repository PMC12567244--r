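#' Default HSV color thresholds for MEP image classification
#'
#' Rendered molecular electrostatic potential (MEP) maps conventionally use a
#' rainbow palette: red/orange/yellow for negative potential, green for
#' near-neutral, cyan/blue for positive, on a light background. Pixels are
#' classified in HSV space: low-saturation (and very bright, nearly
#' unsaturated) pixels are background; the rest are split by hue into
#' negative, neutral, positive and an unassigned "other" window
#' (magenta/purple, which rainbow MEP palettes do not use for potential).
#'
#' @param background_saturation Pixels with saturation below this are
#'   background regardless of hue. Default 0.15.
#' @param background_value,background_value_saturation Additionally, pixels
#'   brighter than `background_value` with saturation below
#'   `background_value_saturation` are background (catches near-white
#'   antialiasing). Defaults 0.95 and 0.20.
#' @param negative_hue,neutral_hue,positive_hue,other_hue Half-open hue
#'   windows in degrees `[lo, hi)`; `negative_hue` additionally includes
#'   `[wrap_hue, 360)` to close the red wrap-around.
#' @param wrap_hue Lower edge of the high-red wrap window. Default 345.
#' @return A named list of thresholds, class `"esp_thresholds"`.
#' @export
esp_color_thresholds <- function(background_saturation = 0.15,
                                 background_value = 0.95,
                                 background_value_saturation = 0.20,
                                 negative_hue = c(0, 75),
                                 neutral_hue = c(75, 165),
                                 positive_hue = c(165, 270),
                                 other_hue = c(270, 345),
                                 wrap_hue = 345) {
  th <- list(
    background_saturation = background_saturation,
    background_value = background_value,
    background_value_saturation = background_value_saturation,
    negative_hue = negative_hue,
    neutral_hue = neutral_hue,
    positive_hue = positive_hue,
    other_hue = other_hue,
    wrap_hue = wrap_hue
  )
  for (w in list(negative_hue, neutral_hue, positive_hue, other_hue))
    stopifnot(length(w) == 2L, w[1] <= w[2], w[1] >= 0, w[2] <= 360)
  class(th) <- "esp_thresholds"
  th
}

.pixel_classes <- c("positive", "negative", "neutral", "other", "background")

#' Read an MEP image from PNG or JPEG
#'
#' @param path Image file; format chosen by extension (`.png`, `.jpg`,
#'   `.jpeg`). Grayscale images are expanded to RGB; an alpha channel is
#'   dropped.
#' @return Numeric `height x width x 3` array in `[0, 1]`.
#' @export
read_esp_image <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '.", ext, "' for ", path, call. = FALSE)
  )
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]
  img
}

#' Classify MEP image pixels into potential classes
#'
#' Deterministically labels every pixel of a rendered MEP image as
#' `positive`, `negative`, `neutral`, `other` or `background` using HSV
#' thresholds (see [esp_color_thresholds()]). Label counts are reproducible
#' bit-exactly for a fixed image and threshold configuration.
#'
#' @param image Numeric `height x width x 3` RGB array in `[0, 1]`, e.g.
#'   from [read_esp_image()].
#' @param thresholds An `esp_thresholds` configuration.
#' @return An object of class `"pixel_class_map"`: a list with `width`,
#'   `height`, and `labels` (a `height x width` factor-coded integer matrix;
#'   levels in `attr(, "classes")`).
#' @export
classify_pixels <- function(image, thresholds = esp_color_thresholds()) {
  if (is.null(image) || length(image) == 0L)
    stop("empty image", call. = FALSE)
  d <- dim(image)
  if (length(d) != 3L || d[3] < 3L)
    stop("image must be a height x width x 3 RGB array", call. = FALSE)
  if (d[1] < 1L || d[2] < 1L)
    stop("empty image", call. = FALSE)
  th <- thresholds

  rgb <- rbind(as.vector(image[, , 1]),
               as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- hsv[1L, ] * 360
  s <- hsv[2L, ]
  v <- hsv[3L, ]

  lab <- rep.int(4L, length(h))  # other
  in_win <- function(w) h >= w[1] & h < w[2]
  bg <- s < th$background_saturation |
    (v > th$background_value & s < th$background_value_saturation)
  fg <- !bg
  lab[fg & (in_win(th$negative_hue) | h >= th$wrap_hue)] <- 2L
  lab[fg & in_win(th$neutral_hue)]  <- 3L
  lab[fg & in_win(th$positive_hue)] <- 1L
  lab[bg] <- 5L

  labels <- matrix(lab, nrow = d[1], ncol = d[2])
  attr(labels, "classes") <- .pixel_classes
  structure(list(width = d[2], height = d[1], labels = labels),
            class = "pixel_class_map")
}

#' @export
print.pixel_class_map <- function(x, ...) {
  cat("pixel class map:", x$width, "x", x$height, "\n")
  print(pixel_class_counts(x))
  invisible(x)
}

#' Per-class pixel counts of a classification map
#'
#' @param map A `pixel_class_map` from [classify_pixels()].
#' @return Named integer vector over
#'   `positive, negative, neutral, other, background`.
#' @export
pixel_class_counts <- function(map) {
  stopifnot(inherits(map, "pixel_class_map"))
  counts <- tabulate(map$labels, nbins = 5L)
  names(counts) <- .pixel_classes
  counts
}

#' Quantify positive/negative/neutral surface areas
#'
#' Converts a pixel classification into surface-area percentages. The
#' denominator is the classified molecular surface only — pixels labeled
#' positive, negative or neutral — so the three percentages sum to 100.
#' `other` pixels (hues outside the rainbow potential palette) are counted
#' and reported but excluded from the denominator. The area balance is
#' `pct_positive - pct_negative`, in percentage points.
#'
#' @param map A `pixel_class_map` from [classify_pixels()].
#' @return A one-row `data.frame`, class includes `"esp_area_result"`:
#'   `pct_positive`, `pct_negative`, `pct_neutral`, `area_balance`,
#'   `n_surface_pixels`, `n_other_pixels`.
#' @export
quantify_areas <- function(map) {
  counts <- pixel_class_counts(map)
  n_surface <- sum(counts[c("positive", "negative", "neutral")])
  if (n_surface == 0L)
    stop("no surface pixels: image is entirely background/other", call. = FALSE)
  pct <- 100 * counts[c("positive", "negative", "neutral")] / n_surface
  out <- data.frame(
    pct_positive = pct[["positive"]],
    pct_negative = pct[["negative"]],
    pct_neutral  = pct[["neutral"]],
    area_balance = pct[["positive"]] - pct[["negative"]],
    n_surface_pixels = as.integer(n_surface),
    n_other_pixels   = as.integer(counts[["other"]])
  )
  class(out) <- c("esp_area_result", class(out))
  out
}

#' Assemble per-compound ESP features
#'
#' Combines areal quantities with the electrostatic-potential extrema of the
#' mapped surface: the maximum (most positive) and minimum (most negative)
#' potential, their contrast `esp_max - esp_min`, and the area balance. The
#' cohort-relative `esp_score` is left unset; fill it with [esp_score()].
#'
#' @param area An `esp_area_result` from [quantify_areas()], or anything with
#'   an `area_balance` column.
#' @param esp_max,esp_min Surface potential extrema (any consistent potential
#'   unit); `esp_max >= esp_min` required.
#' @return One-row `data.frame`: `esp_max`, `esp_min`, `contrast`,
#'   `area_balance`, `esp_score` (`NA` until scored).
#' @export
esp_features <- function(area, esp_max, esp_min) {
  stopifnot(is.numeric(esp_max), is.numeric(esp_min))
  if (!is.finite(esp_max) || !is.finite(esp_min))
    stop("ESP extrema must be finite", call. = FALSE)
  if (esp_max < esp_min)
    stop("esp_max (", esp_max, ") must be >= esp_min (", esp_min, ")",
         call. = FALSE)
  data.frame(
    esp_max = esp_max,
    esp_min = esp_min,
    contrast = esp_max - esp_min,
    area_balance = area$area_balance,
    esp_score = NA_real_
  )
}

#' Cohort-relative ESP Score
#'
#' Scores each compound's ESP profile relative to its cohort as a weighted
#' mean (equal weights by default) of four cohort-wise min-max-normalized
#' components: `n(esp_max)`, `n(esp_min_sign * esp_min)`, `n(contrast)` and
#' `n(area_balance)`. With the default `esp_min_sign = -1` the second
#' component is `n(-esp_min)`, so deeper (more negative) potential minima
#' increase it; set `esp_min_sign = +1` to reward shallower minima instead.
#' Constant components normalize to 0.5 for every compound (see
#' [minmax_normalize()]), so a single-compound cohort scores 0.5.
#'
#' @param features `data.frame` with columns `esp_max`, `esp_min`,
#'   `contrast`, `area_balance` (one row per compound; e.g. rbind of
#'   [esp_features()] rows).
#' @param component_weights Non-negative weights for
#'   `(esp_max, esp_min term, contrast, area_balance)`; normalized to sum
#'   to 1 internally.
#' @param esp_min_sign Sign applied to `esp_min` before normalization;
#'   `-1` (default) or `+1`.
#' @return `features` with `esp_score` filled, each score in `[0, 1]`.
#' @export
esp_score <- function(features,
                      component_weights = c(1, 1, 1, 1),
                      esp_min_sign = -1) {
  if (is.null(features) || nrow(features) == 0L)
    stop("empty cohort: at least one compound is required", call. = FALSE)
  req <- c("esp_max", "esp_min", "contrast", "area_balance")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols))
    stop("features table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  stopifnot(length(component_weights) == 4L, all(component_weights >= 0),
            sum(component_weights) > 0, esp_min_sign %in% c(-1, 1))
  w <- component_weights / sum(component_weights)
  comp <- cbind(
    minmax_normalize(features$esp_max),
    minmax_normalize(esp_min_sign * features$esp_min),
    minmax_normalize(features$contrast),
    minmax_normalize(features$area_balance)
  )
  features$esp_score <- as.vector(comp %*% w)
  features
}

#' Quantify a cohort of MEP images
#'
#' Runs [classify_pixels()] and [quantify_areas()] over every image in a
#' manifest and assembles the cohort ESP feature table, including the
#' cohort-relative ESP Score. Potential extrema are required unless
#' `area_only = TRUE` is given explicitly, in which case a reduced score —
#' the min-max-normalized area balance alone — is used; the reduction is
#' never applied silently.
#'
#' @param manifest `data.frame` with columns `compound_id`, `image_path`.
#' @param extrema Optional `data.frame` with `compound_id`, `esp_max`,
#'   `esp_min` covering every manifest compound.
#' @param thresholds [esp_color_thresholds()] configuration.
#' @param area_only Set `TRUE` to score without extrema (see Details).
#' @param component_weights,esp_min_sign Passed to [esp_score()].
#' @return `data.frame` with one row per compound: `compound_id`,
#'   `pct_positive`, `pct_negative`, `pct_neutral`, `area_balance`,
#'   `esp_max`, `esp_min`, `contrast`, `esp_score`.
#' @export
esp_quantify <- function(manifest, extrema = NULL,
                         thresholds = esp_color_thresholds(),
                         area_only = FALSE,
                         component_weights = c(1, 1, 1, 1),
                         esp_min_sign = -1) {
  req <- c("compound_id", "image_path")
  missing_cols <- setdiff(req, names(manifest))
  if (length(missing_cols))
    stop("image manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(manifest) == 0L)
    stop("empty cohort: image manifest has no rows", call. = FALSE)
  ids <- as.character(manifest$compound_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate compound_id in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (is.null(extrema) && !isTRUE(area_only))
    stop("ESP extrema are required; pass `extrema` or set `area_only = TRUE` ",
         "explicitly to score on area balance alone", call. = FALSE)

  areas <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- manifest$image_path[i]
    if (!file.exists(path))
      stop("missing image for compound ", ids[i], ": ", path, call. = FALSE)
    quantify_areas(classify_pixels(read_esp_image(path), thresholds))
  })
  areas <- do.call(rbind, areas)
  out <- cbind(data.frame(compound_id = ids, stringsAsFactors = FALSE),
               areas[c("pct_positive", "pct_negative", "pct_neutral",
                       "area_balance")])

  if (!is.null(extrema)) {
    ereq <- c("compound_id", "esp_max", "esp_min")
    missing_cols <- setdiff(ereq, names(extrema))
    if (length(missing_cols))
      stop("extrema table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    miss <- setdiff(ids, as.character(extrema$compound_id))
    if (length(miss))
      stop("no ESP extrema for compound(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    m <- match(ids, as.character(extrema$compound_id))
    out$esp_max <- extrema$esp_max[m]
    out$esp_min <- extrema$esp_min[m]
    if (any(out$esp_max < out$esp_min))
      stop("esp_max < esp_min for compound ",
           ids[which(out$esp_max < out$esp_min)[1L]], call. = FALSE)
    out$contrast <- out$esp_max - out$esp_min
    out <- esp_score(out, component_weights, esp_min_sign)
  } else {
    out$esp_max <- NA_real_
    out$esp_min <- NA_real_
    out$contrast <- NA_real_
    out$esp_score <- minmax_normalize(out$area_balance)
  }
  rownames(out) <- NULL
  out
}
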