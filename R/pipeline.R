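# Read a YAML or JSON config file into a plain list.
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Run the full micrograph-to-concentration pipeline
#'
#' Executes binarize -> extract -> fiber criteria over every field-of-view
#' image in order, applying the stopping rule after each field, then
#' classifies the detected particles against the EDS table and converts
#' the counted fibers to an airborne concentration. The analytical
#' sensitivity uses the number of fields actually analyzed.
#'
#' @param config A list, or path to a YAML/JSON file, with entries:
#'   \describe{
#'     \item{images}{data frame (or list of lists) with `path` and optional
#'       `fov_id` per field-of-view image, in scan order.}
#'     \item{pixel_size}{um per pixel (required; never guessed).}
#'     \item{threshold}{intensity threshold (required).}
#'     \item{min_pixels, include_border, gain, offset}{detection settings
#'       (defaults 4, FALSE, 1, 0).}
#'     \item{eds}{path to the per-particle EDS CSV (`particle_id`, element
#'       mass% columns).}
#'     \item{rules}{optional path to a classification-rules file.}
#'     \item{sampling}{path to the sampling-parameters file, or a list.}
#'     \item{fiber_cap, n_max}{stopping rule (defaults 100 and the number
#'       of images).}
#'     \item{out_dir}{optional; when set, results are written there via
#'       [write_results()].}
#'     \item{seed}{echoed into the report for provenance.}
#'   }
#'   Relative paths are resolved against the config file's directory.
#' @param quiet Suppress per-FOV progress messages? Default `TRUE`.
#' @return An object of class `"analysis_report"`: list with `n_fibers`,
#'   `per_fov_counts`, `per_class_counts`, `analytical_sensitivity`,
#'   `concentration_fcc`, `ci_fcc`, `lod_fcc`, `confidence`,
#'   `fovs_analyzed`, `termination_reason`, `params` (sampling echo),
#'   `config` (verbatim echo), `version`; plus data frames `particles` and
#'   `classified` as attributes.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1L) {
    base_dir <- dirname(config)
    config <- read_config_file(config)
  }
  stopifnot(is.list(config))
  rel <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base_dir, p)
  if (is.null(config$pixel_size))
    stop("'pixel_size' is required metadata and is never guessed from images")
  if (is.null(config$threshold)) stop("'threshold' is required")
  images <- config$images
  if (is.null(images)) stop("no images listed in config")
  if (!is.data.frame(images))
    images <- do.call(rbind, lapply(images, function(x)
      data.frame(path = x$path,
                 fov_id = if (is.null(x$fov_id)) NA_character_ else x$fov_id,
                 stringsAsFactors = FALSE)))
  if (is.null(images$fov_id)) images$fov_id <- NA_character_
  min_pixels <- if (is.null(config$min_pixels)) 4L else config$min_pixels
  include_border <- isTRUE(config$include_border)
  gain <- if (is.null(config$gain)) 1 else config$gain
  offset <- if (is.null(config$offset)) 0 else config$offset
  fiber_cap <- if (is.null(config$fiber_cap)) 100 else config$fiber_cap
  n_max <- if (is.null(config$n_max)) nrow(images) else config$n_max

  particle_tabs <- list()
  per_fov <- integer(0)
  reason <- "n_max"
  for (i in seq_len(nrow(images))) {
    fid <- images$fov_id[i]
    img <- read_micrograph(rel(images$path[i]), pixel_size = config$pixel_size,
                           fov_id = if (is.na(fid)) NULL else fid,
                           gain = gain, offset = offset)
    mask <- binarize(img, config$threshold)
    parts <- extract_particles(mask, img$pixel_size, min_pixels = min_pixels,
                               fov_id = img$fov_id)
    parts <- apply_fiber_criteria(parts, include_border = include_border)
    particle_tabs[[i]] <- parts
    per_fov <- c(per_fov, sum(parts$counted))
    if (!quiet)
      message(sprintf("FOV %s: %d particles, %d counted fibers",
                      img$fov_id, nrow(parts), sum(parts$counted)))
    tc <- termination_check(i, sum(per_fov), fiber_cap = fiber_cap,
                            n_max = n_max)
    if (tc$stop) { reason <- tc$reason; break }
  }
  particles <- do.call(rbind, particle_tabs)
  rownames(particles) <- NULL

  rules <- if (is.null(config$rules)) classification_rules()
    else read_classification_rules(rel(config$rules))
  classified <- particles
  if (!is.null(config$eds) && nrow(particles) > 0) {
    eds <- utils::read.csv(rel(config$eds), stringsAsFactors = FALSE)
    # a truncated scan legitimately leaves EDS rows for unanalyzed fields
    analyzed <- unique(particles$fov_id)
    eds <- eds[sub("_p[0-9]+$", "", eds$particle_id) %in% analyzed, ,
               drop = FALSE]
    classified <- classify_particles(particles, eds, rules)
  } else if (nrow(particles) > 0) {
    classified$label <- ifelse(classified$is_fiber,
                               "unclassified_mineral", "non_fiber")
    classified$tsi <- NA_real_
    classified$rule_trace <- "no_eds"
  }

  sampling <- config$sampling
  if (is.character(sampling)) sampling <- read_config_file(rel(sampling))
  sampling$n_fov <- length(per_fov) # fields actually analyzed
  p <- do.call(sampling_params, sampling)
  n_fibers <- sum(per_fov)
  est <- count_to_concentration(n_fibers, p)
  counted <- classified[which(classified$counted), , drop = FALSE]
  per_class <- if (nrow(counted)) lapply(as.list(table(counted$label)),
                                         as.integer) else list()
  report <- structure(list(
    n_fibers = n_fibers,
    per_fov_counts = per_fov,
    per_class_counts = per_class,
    analytical_sensitivity = est$analytical_sensitivity,
    concentration_fcc = est$concentration_fcc,
    ci_fcc = est$ci_fcc,
    lod_fcc = est$lod_fcc,
    confidence = est$confidence,
    fovs_analyzed = length(per_fov),
    termination_reason = reason,
    params = unclass(p),
    config = config,
    version = as.character(utils::packageVersion("empscan"))
  ), class = "analysis_report")
  attr(report, "particles") <- particles
  attr(report, "classified") <- classified
  if (!is.null(config$out_dir))
    write_results(report, particles, classified, rel(config$out_dir))
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report (empscan %s)\n", x$version))
  cat(sprintf("  %d FOVs analyzed (stop: %s); N = %d counted fibers\n",
              x$fovs_analyzed, x$termination_reason, x$n_fibers))
  cat(sprintf("  concentration %.3g f/cc, %.0f%% CI [%.3g, %.3g], LOD %.3g f/cc\n",
              x$concentration_fcc, 100 * x$confidence,
              x$ci_fcc[1], x$ci_fcc[2], x$lod_fcc))
  if (length(x$per_class_counts)) {
    cat("  counted fibers by class:\n")
    for (nm in names(x$per_class_counts))
      cat(sprintf("    %-22s %d\n", nm, x$per_class_counts[[nm]]))
  }
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Writes `particles.csv`, `classified.csv`, `report.json`, and
#' `summary.csv` (one row) into `out_dir`. CSVs are comma-separated UTF-8
#' with a header row and round-trip losslessly; the report JSON is a
#' deterministic serialization of the [run_pipeline()] report (no
#' wall-clock fields), so re-running with the same config and seed
#' reproduces it byte for byte.
#'
#' @param report An `"analysis_report"`.
#' @param particles,classified The particle tables from the run (ids must
#'   agree).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(report, particles, classified, out_dir) {
  if (nrow(particles) != nrow(classified) ||
      !identical(particles$particle_id, classified$particle_id))
    stop("particle/classification id mismatch")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(particles = file.path(out_dir, "particles.csv"),
             classified = file.path(out_dir, "classified.csv"),
             report = file.path(out_dir, "report.json"),
             summary = file.path(out_dir, "summary.csv"))
  utils::write.csv(particles, files["particles"], row.names = FALSE)
  utils::write.csv(classified, files["classified"], row.names = FALSE)
  rep_out <- unclass(report)
  jsonlite::write_json(rep_out, files["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  summary_row <- data.frame(
    n_fibers = report$n_fibers,
    fovs_analyzed = report$fovs_analyzed,
    analytical_sensitivity = report$analytical_sensitivity,
    concentration_fcc = report$concentration_fcc,
    ci_low_fcc = report$ci_fcc[1], ci_high_fcc = report$ci_fcc[2],
    lod_fcc = report$lod_fcc, confidence = report$confidence,
    termination_reason = report$termination_reason)
  utils::write.csv(summary_row, files["summary"], row.names = FALSE)
  invisible(files)
}

#' Generate a complete synthetic file-based dataset
#'
#' Simulates `n_fov` scenes, writes them as 8-bit PNGs, runs detection once
#' to assign particle ids, simulates an EDS composition for every detected
#' particle (from the template of the nearest ground-truth particle), and
#' writes the EDS table, sampling parameters, ground truth, and a pipeline
#' config — a fully self-contained input set for [run_pipeline()].
#'
#' @param out_dir Directory to create the dataset in.
#' @param n_fov Number of fields of view (default 10).
#' @param spec A [scene_spec()] template; each field uses
#'   `seed = spec$seed + fov_index - 1`.
#' @param sampling A [sampling_params()] object (its `n_fov` is set to
#'   `n_fov`); default: PE-standard parameters.
#' @param threshold Detection threshold written into the config (default
#'   110, separating background 20 from particles 200).
#' @param acquisition_time EDS acquisition time in seconds (default 10).
#' @return Path to the written `config.yaml`, invisibly.
#' @export
simulate_dataset <- function(out_dir, n_fov = 10,
                             spec = scene_spec(fiber_count = 12,
                                               distractor_disks = 4,
                                               distractor_blobs = 4,
                                               pixel_size = 0.0625),
                             sampling = NULL, threshold = 110,
                             acquisition_time = 10) {
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE,
             recursive = TRUE)
  if (is.null(sampling))
    sampling <- sampling_params(385, 0.0031, n_fov, 2000, 1)
  templates <- composition_templates()
  eds_rows <- list()
  image_entries <- list()
  truth_all <- list()
  for (i in seq_len(n_fov)) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    fov_id <- sprintf("fov%02d", i)
    sim <- simulate_scene(sp)
    sim$image$fov_id <- fov_id
    img_path <- file.path(out_dir, "images", paste0(fov_id, ".png"))
    write_micrograph(sim$image, img_path)
    parts <- extract_particles(binarize(sim$image, threshold),
                               sp$pixel_size, fov_id = fov_id)
    if (nrow(parts) > 0 && nrow(sim$truth) > 0) {
      # EDS from the template of the nearest ground-truth particle
      px <- (parts$centroid_col + 0.5) * sp$pixel_size
      py <- (parts$centroid_row + 0.5) * sp$pixel_size
      for (j in seq_len(nrow(parts))) {
        nearest <- which.min((sim$truth$x_um - px[j])^2 +
                               (sim$truth$y_um - py[j])^2)
        comp <- simulate_eds(templates[[sim$truth$template[nearest]]],
                             acquisition_time = acquisition_time,
                             seed = sp$seed * 10000L + j)
        eds_rows[[length(eds_rows) + 1L]] <- data.frame(
          particle_id = parts$particle_id[j],
          as.list(round(comp$mass_pct, 4)),
          acquisition_time_s = acquisition_time,
          stringsAsFactors = FALSE)
      }
    }
    sim$truth$fov_id <- if (nrow(sim$truth)) fov_id else character(0)
    truth_all[[i]] <- sim$truth
    image_entries[[i]] <- list(path = file.path("images", paste0(fov_id, ".png")),
                               fov_id = fov_id)
  }
  eds <- if (length(eds_rows)) do.call(rbind, eds_rows) else
    data.frame(particle_id = character(), stringsAsFactors = FALSE)
  utils::write.csv(eds, file.path(out_dir, "eds.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truth_all),
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(sampling), file.path(out_dir, "sampling.yaml"))
  config <- list(images = image_entries,
                 pixel_size = spec$pixel_size, threshold = threshold,
                 min_pixels = 4L, include_border = FALSE,
                 eds = "eds.csv", sampling = "sampling.yaml",
                 seed = spec$seed)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(file.path(out_dir, "config.yaml"))
}
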