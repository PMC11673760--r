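results_columns <- c("Label", "Area", "Perim.", "Circ.", "Solidity",
                     "EquivRadius", "X", "Y", "OnBorder")

#' Write particle records as a results CSV
#'
#' Column names mirror an ImageJ Results table (Label, Area, Perim., Circ.,
#' Solidity plus EquivRadius, centroid X/Y and the border flag) so tables
#' from either origin interoperate. All lengths are in micrometres; floats
#' are written at full precision with period decimal separator.
#'
#' @param records a \code{particle_records} data frame.
#' @param path output CSV path.
#' @export
write_results_csv <- function(records, path) {
  df <- data.frame(Label = records$label,
                   Area = records$area_um2,
                   Perim. = records$perimeter_um,
                   Circ. = records$circularity,
                   Solidity = records$solidity,
                   EquivRadius = records$equiv_radius_um,
                   X = records$centroid_col_px,
                   Y = records$centroid_row_px,
                   OnBorder = records$on_border,
                   check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results CSV back into particle records
#'
#' Accepts any CSV carrying at least the Label, Area, Perim., Circ.,
#' Solidity and EquivRadius columns (an original ImageJ-style results
#' table parses too; missing X/Y/OnBorder become NA).
#'
#' @param path CSV path.
#' @return a \code{particle_records} data frame.
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("Label", "Area", "Perim.", "Circ.", "Solidity", "EquivRadius")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("results CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(label = as.integer(df$Label),
                    area_um2 = as.numeric(df$Area),
                    perimeter_um = as.numeric(df$`Perim.`),
                    circularity = as.numeric(df$`Circ.`),
                    solidity = as.numeric(df$Solidity),
                    equiv_radius_um = as.numeric(df$EquivRadius),
                    centroid_row_px =
                      if ("Y" %in% names(df)) as.numeric(df$Y) else NA_real_,
                    centroid_col_px =
                      if ("X" %in% names(df)) as.numeric(df$X) else NA_real_,
                    on_border = if ("OnBorder" %in% names(df))
                      as.logical(df$OnBorder) else NA)
  structure(out, class = c("particle_records", "data.frame"))
}

#' Run configuration for a batch analysis
#'
#' @param pixel_size_um spatial calibration of the input frames.
#' @param chamber_height_um imaging chamber height.
#' @param params a \code{segmentation_params}.
#' @param criteria a \code{filter_criteria}.
#' @param dilution_factor dilution applied before imaging.
#' @return a \code{run_config} list.
#' @export
run_config <- function(pixel_size_um, chamber_height_um = 10,
                       params = segmentation_params(),
                       criteria = filter_criteria(),
                       dilution_factor = 1) {
  if (pixel_size_um <= 0 || chamber_height_um <= 0)
    stop("calibration values must be positive")
  structure(list(pixel_size_um = pixel_size_um,
                 chamber_height_um = chamber_height_um,
                 params = params, criteria = criteria,
                 dilution_factor = dilution_factor),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' The fully resolved configuration is written next to every batch output
#' so a run can be reproduced exactly from its own record.
#'
#' @param config a \code{run_config}.
#' @param path YAML path.
#' @return \code{read_run_config} returns a \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(pixel_size_um = config$pixel_size_um,
                        chamber_height_um = config$chamber_height_um,
                        params = unclass(config$params),
                        criteria = unclass(config$criteria),
                        dilution_factor = config$dilution_factor), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(pixel_size_um = y$pixel_size_um,
             chamber_height_um = y$chamber_height_um,
             params = do.call(segmentation_params, y$params),
             criteria = do.call(filter_criteria, y$criteria),
             dilution_factor = y$dilution_factor)
}

#' Batch-process a directory of brightfield TIFFs
#'
#' Reads every TIFF in the directory in lexicographic order, segments each
#' frame, writes one results CSV per image into \code{out_dir}, then pools
#' all records into a size distribution and concentration estimate written
#' as \code{summary.json} (with the resolved config as
#' \code{run_config.yaml}). Unreadable files are skipped with a message and
#' recorded in the summary.
#'
#' @param directory input directory of greyscale TIFFs.
#' @param config a \code{run_config}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with per-image records, the pooled
#'   \code{size_distribution}, the \code{concentration_estimate} and the
#'   names of skipped files.
#' @export
run_batch <- function(directory, config, out_dir) {
  files <- sort(list.files(directory, pattern = "\\.tiff?$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no readable images in ", directory)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- list(); counts <- integer(); skipped <- character()
  fov <- NULL
  for (f in files) {
    res <- tryCatch({
      frame <- read_image(f, config$pixel_size_um)
      if (is.null(fov)) fov <- dim(frame$pixels)
      segment_image(frame, config$params, config$criteria)
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { skipped <- c(skipped, basename(f)); next }
    csv <- file.path(out_dir,
                     paste0(tools::file_path_sans_ext(basename(f)), ".csv"))
    write_results_csv(res, csv)
    records[[basename(f)]] <- res
    counts <- c(counts, nrow(res))
  }
  if (length(records) == 0L) stop("no image in ", directory, " could be processed")
  pooled <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  dist <- if (nrow(pooled) > 0) build_distribution(pooled) else NULL
  vol <- imaged_volume(fov, config$pixel_size_um, config$chamber_height_um)
  conc <- estimate_concentration(counts, vol, config$dilution_factor)
  summary <- list(n_images = length(records),
                  skipped = as.list(skipped),
                  n_objects = nrow(pooled),
                  n_bins = if (!is.null(dist)) dist$n_bins else 0L,
                  mean_radius_um = if (!is.null(dist)) dist$mean_radius_um else NA,
                  sd_radius_um = if (!is.null(dist)) dist$sd_radius_um else NA,
                  imaged_volume_mL = vol,
                  concentration_per_mL = conc$concentration_per_mL,
                  concentration_sd_per_mL = conc$concentration_sd_per_mL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  invisible(list(records = records, distribution = dist,
                 concentration = conc, skipped = skipped))
}
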