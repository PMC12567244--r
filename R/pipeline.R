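# Top-level pipeline: configuration, input validation, staged execution
# with a provenance manifest.

#' Pipeline configuration
#'
#' Bundles every tunable of the prioritization pipeline. Unknown fields are
#' rejected, so a typo in a config file fails loudly rather than silently
#' falling back to a default.
#'
#' @param energies Path to the frontier-orbital energy CSV
#'   (`compound_id,e_homo,e_lumo`).
#' @param images Path to the image manifest CSV (`compound_id,image_path`;
#'   relative image paths are resolved against the manifest's directory).
#' @param out_dir Output directory for result CSVs and the run manifest.
#' @param extrema Optional path to the ESP-extrema CSV
#'   (`compound_id,esp_max,esp_min`).
#' @param ic50 Optional path to a long-format IC50 CSV
#'   (`compound_id,cell_line,ic50[,sd]`).
#' @param weights [score_weights()] for the composite score.
#' @param thresholds [esp_color_thresholds()] for pixel classification.
#' @param convention Descriptor convention, `"paper"` or `"textbook"`.
#' @param esp_component_weights,esp_min_sign Passed to [esp_score()].
#' @param area_only Score ESP on area balance alone (explicit opt-in when
#'   no extrema are available).
#' @param normal_line Normal cell line for the selectivity table.
#' @param display_digits Decimal places used by [format_score_table()].
#' @param seed Optional integer recorded in the run manifest.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(energies, images, out_dir,
                            extrema = NULL, ic50 = NULL,
                            weights = score_weights(),
                            thresholds = esp_color_thresholds(),
                            convention = c("paper", "textbook"),
                            esp_component_weights = c(1, 1, 1, 1),
                            esp_min_sign = -1,
                            area_only = FALSE,
                            normal_line = "WI-38",
                            display_digits = 4L,
                            seed = NULL) {
  convention <- match.arg(convention)
  if (!inherits(weights, "score_weights"))
    weights <- do.call(score_weights, as.list(weights))
  if (!inherits(thresholds, "esp_thresholds"))
    thresholds <- do.call(esp_color_thresholds, as.list(thresholds))
  structure(list(energies = energies, images = images, out_dir = out_dir,
                 extrema = extrema, ic50 = ic50, weights = weights,
                 thresholds = thresholds, convention = convention,
                 esp_component_weights = esp_component_weights,
                 esp_min_sign = esp_min_sign, area_only = area_only,
                 normal_line = normal_line,
                 display_digits = as.integer(display_digits), seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected. Relative input paths are resolved against the config file's
#' directory.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "'", call. = FALSE)
  )
  known <- setdiff(names(formals(pipeline_config)), "")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base <- dirname(normalizePath(path))
  for (f in c("energies", "images", "extrema", "ic50"))
    if (!is.null(raw[[f]]) && !grepl("^(/|[A-Za-z]:)", raw[[f]]))
      raw[[f]] <- file.path(base, raw[[f]])
  do.call(pipeline_config, raw)
}

# --- CSV readers with schema checks -----------------------------------------

.read_table <- function(path, required, what) {
  if (!file.exists(path))
    stop(what, " file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab
}

#' @rdname run_pipeline
#' @param path CSV file path.
#' @export
read_compound_energies <- function(path) {
  tab <- .read_table(path, c("compound_id", "e_homo", "e_lumo"),
                     "compound energies")
  if (!is.numeric(tab$e_homo) || !is.numeric(tab$e_lumo))
    stop("e_homo and e_lumo must be numeric in ", path, call. = FALSE)
  tab
}

#' @rdname run_pipeline
#' @export
read_image_manifest <- function(path) {
  tab <- .read_table(path, c("compound_id", "image_path"), "image manifest")
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", tab$image_path)
  tab$image_path[rel] <- file.path(base, tab$image_path[rel])
  tab
}

#' @rdname run_pipeline
#' @export
read_esp_extrema <- function(path) {
  .read_table(path, c("compound_id", "esp_max", "esp_min"), "ESP extrema")
}

#' @rdname run_pipeline
#' @export
read_ic50_table <- function(path) {
  .read_table(path, c("compound_id", "cell_line", "ic50"), "IC50")
}

#' Validate pipeline inputs without running the pipeline
#'
#' Checks that every referenced file exists, has the required columns, and
#' is internally consistent (numeric energies, e_homo < e_lumo, readable
#' image files). Report-only: inputs are never modified and no error is
#' thrown for content problems.
#'
#' @param config A [pipeline_config()].
#' @return `data.frame` with columns `file`, `problem`; zero rows when all
#'   inputs validate.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- list()
  note <- function(file, problem)
    issues[[length(issues) + 1L]] <<- data.frame(file = file,
                                                 problem = problem)
  tab_or_note <- function(path, reader, what) {
    if (is.null(path)) return(NULL)
    tryCatch(reader(path), error = function(e) {
      note(path, conditionMessage(e))
      NULL
    })
  }

  energies <- tab_or_note(config$energies, read_compound_energies)
  if (!is.null(energies)) {
    if (anyDuplicated(energies$compound_id))
      note(config$energies, "duplicate compound_id")
    if (is.numeric(energies$e_homo) && is.numeric(energies$e_lumo) &&
        any(energies$e_homo >= energies$e_lumo))
      note(config$energies,
           paste("e_homo >= e_lumo for compound",
                 energies$compound_id[which(energies$e_homo >=
                                              energies$e_lumo)[1L]]))
  }
  manifest <- tab_or_note(config$images, read_image_manifest)
  if (!is.null(manifest)) {
    for (i in seq_len(nrow(manifest))) {
      p <- manifest$image_path[i]
      if (!file.exists(p)) {
        note(p, paste("missing image for compound",
                      manifest$compound_id[i]))
      } else {
        ok <- tryCatch({ read_esp_image(p); TRUE },
                       error = function(e) FALSE)
        if (!ok) note(p, "not a readable PNG/JPEG image")
      }
    }
  }
  tab_or_note(config$extrema, read_esp_extrema)
  tab_or_note(config$ic50, read_ic50_table)

  if (length(issues)) do.call(rbind, issues)
  else data.frame(file = character(0), problem = character(0))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full prioritization pipeline
#'
#' Executes descriptors -> ESP quantification -> composite scoring (and,
#' when an IC50 table is configured, the selectivity stage), writing
#' `descriptors.csv`, `esp.csv`, `scores.csv`, optionally `si.csv`, and a
#' `manifest.json` provenance record (config echo, package version, seed,
#' MD5 checksums of all inputs, timestamp) into `config$out_dir`. A fixed
#' config over fixed inputs produces byte-identical outputs, except for the
#' manifest's timestamp field.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the result tables (`descriptors`, `esp`,
#'   `scores`, `si` or `NULL`) and the output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  energies <- .stage("read", read_compound_energies(config$energies))
  manifest <- .stage("read", read_image_manifest(config$images))
  extrema <- if (!is.null(config$extrema))
    .stage("read", read_esp_extrema(config$extrema))
  ic50 <- if (!is.null(config$ic50))
    .stage("read", read_ic50_table(config$ic50))

  descriptors <- .stage("descriptors",
    compute_descriptor_table(energies, config$convention))
  esp <- .stage("esp_quant",
    esp_quantify(manifest, extrema, config$thresholds,
                 area_only = config$area_only,
                 component_weights = config$esp_component_weights,
                 esp_min_sign = config$esp_min_sign))
  scores <- .stage("scoring",
    build_score_table(descriptors, esp, config$weights))
  si <- if (!is.null(ic50))
    .stage("selectivity", si_table(ic50, config$normal_line))

  paths <- list(
    descriptors = file.path(config$out_dir, "descriptors.csv"),
    esp = file.path(config$out_dir, "esp.csv"),
    scores = file.path(config$out_dir, "scores.csv"),
    si = if (!is.null(si)) file.path(config$out_dir, "si.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  utils::write.csv(descriptors, paths$descriptors, row.names = FALSE)
  utils::write.csv(esp, paths$esp, row.names = FALSE)
  utils::write.csv(scores, paths$scores, row.names = FALSE)
  if (!is.null(si)) utils::write.csv(si, paths$si, row.names = FALSE)

  inputs <- Filter(Negate(is.null),
                   list(energies = config$energies, images = config$images,
                        extrema = config$extrema, ic50 = config$ic50))
  run_manifest <- list(
    package = "cdftrank",
    version = as.character(utils::packageVersion("cdftrank")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    convention = config$convention,
    weights = unclass(config$weights),
    thresholds = unclass(config$thresholds),
    esp_component_weights = config$esp_component_weights,
    esp_min_sign = config$esp_min_sign,
    area_only = config$area_only,
    normal_line = config$normal_line,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(run_manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(descriptors = descriptors, esp = esp, scores = scores,
                 si = si, paths = paths))
}

#' Round a score table for display
#'
#' @param table A score table from [build_score_table()].
#' @param digits Decimal places (default 4, matching the precision at which
#'   composite scores are conventionally reported).
#' @return The table with numeric columns rounded.
#' @export
format_score_table <- function(table, digits = 4L) {
  num <- vapply(table, is.numeric, logical(1)) & names(table) != "rank"
  table[num] <- lapply(table[num], round, digits = digits)
  table
}
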