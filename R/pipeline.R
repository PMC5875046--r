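#' Experiment configuration for a full evaluation grid
#'
#' Describes the algorithm x dose x pitch grid, replication, geometry, ROI
#' and MTF settings for [run_experiment()].
#'
#' @param algorithms algorithm labels to run (subset of the model names).
#' @param doses CTDIvol grid in mGy (all > 0); the conventional Catphan grid
#'   is 1, 2, 3, 6, 12, 18, 24.
#' @param pitches pitch factors.
#' @param n_replicates replicates per condition (>= 2 for any statistical
#'   output; 10 by convention).
#' @param seed master seed.
#' @param matrix_size image matrix.
#' @param models named list of [algorithm_model()]s (default
#'   [builtin_algorithm_models()]).
#' @param layouts named list with elements `sensitometry` (noise/HU/MTF
#'   layout, default ctp404) and optionally `low_contrast` (CNR layout,
#'   default ctp515).
#' @param reference list(algorithm, dose): the image-quality baseline cell
#'   (default MBIR at 1 mGy).
#' @param mtf list with `target_freq_lp_cm` (default 5; 5.625 is the other
#'   conventional grid point), `length_mm`, `enabled`.
#' @param noise_roi_area_cm2,cnr_roi_area_cm2 ROI areas.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(algorithms = names(models),
                              doses = c(1, 2, 3, 6, 12, 18, 24),
                              pitches = 0.984, n_replicates = 10L, seed = 1L,
                              matrix_size = 512L,
                              models = builtin_algorithm_models(),
                              layouts = list(
                                sensitometry = builtin_layouts("ctp404"),
                                low_contrast = builtin_layouts("ctp515")),
                              reference = list(algorithm = "MBIR", dose = 1),
                              mtf = list(enabled = TRUE,
                                         target_freq_lp_cm = 5,
                                         length_mm = 14),
                              noise_roi_area_cm2 = 0.4,
                              cnr_roi_area_cm2 = 0.4) {
  stopifnot(length(algorithms) >= 1, length(doses) >= 1, all(doses > 0),
            n_replicates >= 1, all(algorithms %in% names(models)))
  if (!reference$algorithm %in% algorithms ||
      !any(abs(doses - reference$dose) < 1e-9)) {
    stop("reference cell must be part of the configured grid")
  }
  mtf <- utils::modifyList(list(enabled = TRUE, target_freq_lp_cm = 5,
                                length_mm = 14), mtf)
  structure(list(algorithms = algorithms, doses = doses, pitches = pitches,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 matrix_size = as.integer(matrix_size), models = models,
                 layouts = layouts, reference = reference, mtf = mtf,
                 noise_roi_area_cm2 = noise_roi_area_cm2,
                 cnr_roi_area_cm2 = cnr_roi_area_cm2),
            class = "experiment_config")
}

#' Run the full generator -> metrics -> statistics pipeline
#'
#' For every grid cell: simulates the replicate stacks, measures noise
#' (three background ROIs), insert HU, edge-method MTF at the target
#' frequency and (when a low-contrast layout is configured) CNR; then builds
#' the comparison tables: per-condition (log-)means, contrasts vs the
#' baseline reference cell with Dunnett-adjusted p-values, fold-improvement
#' vs FBP, HU deltas vs FBP at the highest dose, and the MTF ratio-vs-FBP
#' table. Deterministic under a fixed seed.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-cell progress lines.
#' @return a `ctiq_report`: list of record data.frames (`noise_records`,
#'   `cnr_records`, `mtf_records`, `hu_records`) and tables (`noise_means`,
#'   `noise_vs_reference`, `cnr_means`, `cnr_vs_reference`,
#'   `fold_improvement`, `hu_delta`, `mtf_ratio`), plus `manifest` metadata.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- expand.grid(algorithm = config$algorithms, dose = config$doses,
                      pitch = config$pitches, stringsAsFactors = FALSE)
  sens <- config$layouts$sensitometry
  lowc <- config$layouts$low_contrast
  sens_clean <- render_layout(sens, config$matrix_size)
  lowc_clean <- if (!is.null(lowc)) render_layout(lowc, config$matrix_size)
  n_rois <- background_rois(config$noise_roi_area_cm2, radius_mm = 30)
  hu_rois <- insert_rois(sens)
  if (!is.null(lowc)) {
    target_feat <- lowc$features[[1]]
    t_roi <- roi_spec(target_feat$center, config$cnr_roi_area_cm2, "target")
    c_rois <- background_rois(config$cnr_roi_area_cm2, radius_mm = 15,
                              center = target_feat$center)
  }
  noise_rec <- cnr_rec <- mtf_rec <- list()
  hu_rec <- list()
  for (g in seq_len(nrow(grid))) {
    cond <- scan_condition(grid$algorithm[g], grid$dose[g], grid$pitch[g])
    model <- config$models[[cond$algorithm]]
    cell_seed <- substream_seed(config$seed, 7919L * g)
    if (verbose) {
      message(sprintf("[%d/%d] %s @ %g mGy pitch %g", g, nrow(grid),
                      cond$algorithm, cond$ctdi_vol, cond$pitch))
    }
    stack <- simulate_stack(sens, cond, model, config$n_replicates,
                            seed = cell_seed,
                            matrix_size = config$matrix_size,
                            .clean = sens_clean)
    nm <- measure_noise(stack, n_rois)
    noise_rec[[g]] <- cell_records(cond, nm$per_replicate)
    hu <- measure_hu(stack, hu_rois)
    hu_rec[[g]] <- hu
    if (isTRUE(config$mtf$enabled)) {
      curves <- measure_mtf(stack, length_mm = config$mtf$length_mm,
                            per_replicate = TRUE)
      vals <- vapply(curves, mtf_at_frequency,
                     0, f_lp_cm = config$mtf$target_freq_lp_cm)
      if (any(!is.finite(vals) | vals <= 0)) {
        warning("MTF at ", config$mtf$target_freq_lp_cm, " lp/cm is not ",
                "reliably measurable for ", cond$algorithm, " @ ",
                cond$ctdi_vol, " mGy at this matrix size; ",
                "dropping unusable replicates")
        vals <- vals[is.finite(vals) & vals > 0]
      }
      if (length(vals) >= 2) mtf_rec[[g]] <- cell_records(cond, vals)
    }
    if (!is.null(lowc)) {
      cstack <- simulate_stack(lowc, cond, model, config$n_replicates,
                               seed = substream_seed(cell_seed, 1L),
                               matrix_size = config$matrix_size,
                               .clean = lowc_clean)
      cm <- measure_cnr(cstack, t_roi, c_rois)
      cnr_rec[[g]] <- cell_records(cond, cm$per_replicate)
    }
  }
  noise_records <- do.call(rbind, noise_rec)
  hu_records <- do.call(rbind, hu_rec)
  res <- list(noise_records = noise_records, hu_records = hu_records)
  noise_means <- estimate_condition_means(noise_records, log_scale = TRUE)
  res$noise_means <- noise_means
  res$noise_vs_reference <- difference_vs_reference(noise_means,
                                                    config$reference)
  noise_sum <- data.frame(algorithm = noise_means$algorithm,
                          dose = noise_means$dose,
                          pitch = noise_means$pitch,
                          value = exp(noise_means$estimate))
  if ("FBP" %in% config$algorithms) {
    res$fold_improvement <- fold_improvement(noise_sum, "noise", "FBP")
  }
  ref_dose <- max(config$doses)
  if ("FBP" %in% config$algorithms) {
    res$hu_delta <- hu_difference_from_reference(hu_records, "FBP", ref_dose)
  }
  if (length(cnr_rec)) {
    cnr_records <- do.call(rbind, cnr_rec)
    res$cnr_records <- cnr_records
    cnr_means <- estimate_condition_means(cnr_records, log_scale = FALSE)
    res$cnr_means <- cnr_means
    res$cnr_vs_reference <- difference_vs_reference(cnr_means,
                                                    config$reference)
    if ("FBP" %in% config$algorithms) {
      cnr_sum <- data.frame(algorithm = cnr_means$algorithm,
                            dose = cnr_means$dose, pitch = cnr_means$pitch,
                            value = cnr_means$estimate)
      res$cnr_fold_improvement <- fold_improvement(cnr_sum, "cnr", "FBP")
    }
  }
  if (length(mtf_rec)) {
    res$mtf_records <- do.call(rbind, mtf_rec)
    if ("FBP" %in% config$algorithms && length(config$algorithms) > 1) {
      res$mtf_ratio <- tryCatch(mtf_ratio_table(res$mtf_records, "FBP"),
                                error = function(e) {
                                  warning("MTF ratio table skipped: ",
                                          conditionMessage(e))
                                  NULL
                                })
    }
  }
  res$manifest <- list(
    schema_version = "1.0",
    seed = config$seed,
    n_replicates = config$n_replicates,
    matrix_size = config$matrix_size,
    grid = grid,
    reference = config$reference,
    mtf_target_freq_lp_cm = config$mtf$target_freq_lp_cm)
  structure(res, class = "ctiq_report")
}

cell_records <- function(cond, values) {
  data.frame(algorithm = cond$algorithm, dose = cond$ctdi_vol,
             pitch = cond$pitch, replicate = seq_along(values),
             value = values)
}

#' Write a report bundle to disk
#'
#' Emits every table of a [run_experiment()] result as CSV plus a JSON
#' manifest (schema version, config echo, per-file md5 checksums).
#'
#' @param report a `ctiq_report`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "ctiq_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tables <- Filter(is.data.frame, report)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- report$manifest
  manifest$files <- lapply(files, function(f) {
    list(name = basename(f), md5 = unname(tools::md5sum(f)))
  })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Verify a written report against its manifest
#'
#' @param outdir directory written by [write_report()].
#' @return `TRUE` if all checksums match; otherwise a character vector of
#'   mismatching file names.
#' @export
verify_report <- function(outdir) {
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  bad <- character(0)
  for (f in manifest$files) {
    path <- file.path(outdir, f$name)
    if (!file.exists(path) ||
        !identical(unname(tools::md5sum(path)), f$md5)) {
      bad <- c(bad, f$name)
    }
  }
  if (length(bad)) bad else TRUE
}

#' Portable replicate-stack container
#'
#' Writes each replicate as a 16-bit signed little-endian raster
#' (`replicate_###.raw`, HU rounded to integer) plus a JSON sidecar
#' (`stack.json`: matrix size, spacing, condition, seed, layout name).
#' Reading validates that all replicates share shape and spacing.
#'
#' @param stack a `ct_stack`.
#' @param path directory for the container.
#' @return `write_stack()`: `path`, invisibly. `read_stack()`: a `ct_stack`
#'   (without the layout object; `layout_name` is kept).
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ct_stack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$images)
  if (any(abs(stack$images) > 32767)) stop("HU out of int16 range")
  for (k in seq_len(d[3])) {
    con <- file(file.path(path, sprintf("replicate_%03d.raw", k)), "wb")
    writeBin(as.integer(round(stack$images[, , k])), con, size = 2L,
             endian = "little")
    close(con)
  }
  sidecar <- list(matrix = d[1], n_replicates = d[3],
                  spacing_mm = stack$spacing_mm,
                  condition = unclass(stack$condition),
                  seed = stack$seed, layout = stack$layout_name,
                  sigma_hu = stack$sigma_hu,
                  noise_correlation_mm = stack$noise_correlation_mm)
  jsonlite::write_json(sidecar, file.path(path, "stack.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sidecar <- jsonlite::read_json(file.path(path, "stack.json"),
                                 simplifyVector = TRUE)
  n <- sidecar$matrix
  nk <- sidecar$n_replicates
  files <- file.path(path, sprintf("replicate_%03d.raw", seq_len(nk)))
  if (!all(file.exists(files))) stop("malformed container: missing rasters")
  sizes <- file.size(files)
  if (any(sizes != 2 * n * n)) {
    stop("inconsistent replicate shapes in container")
  }
  images <- array(0L, dim = c(n, n, nk))
  for (k in seq_len(nk)) {
    con <- file(files[k], "rb")
    images[, , k] <- readBin(con, "integer", n * n, size = 2L,
                             signed = TRUE, endian = "little")
    close(con)
  }
  cond <- sidecar$condition
  structure(list(images = images, spacing_mm = sidecar$spacing_mm,
                 condition = scan_condition(cond$algorithm, cond$ctdi_vol,
                                            cond$pitch),
                 model_name = cond$algorithm, sigma_hu = sidecar$sigma_hu,
                 noise_correlation_mm = sidecar$noise_correlation_mm,
                 seed = sidecar$seed, layout = NULL,
                 layout_name = sidecar$layout),
            class = "ct_stack")
}
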