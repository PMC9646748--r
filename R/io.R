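#' Write a single microwell frame as a 16-bit grayscale TIFF
#'
#' @param img `well_image` (or integer-valued matrix in [0, 65535]).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_well_image <- function(img, path) {
  meta <- jsonlite::toJSON(list(pixel_size_um = attr(img, "pixel_size_um")),
                           auto_unbox = TRUE)
  tiff_write(list(img), path, bits = 16L, description = as.character(meta))
}

#' Read a single microwell frame
#'
#' @param path TIFF path (grayscale, uncompressed).
#' @return `well_image` matrix.
#' @export
read_well_image <- function(path) {
  t <- tiff_read(path)
  img <- t$frames[[1]]
  px <- NA_real_
  if (!is.null(t$description)) {
    meta <- tryCatch(jsonlite::fromJSON(t$description), error = function(e) NULL)
    if (!is.null(meta$pixel_size_um)) px <- meta$pixel_size_um
  }
  structure(img, pixel_size_um = px, bit_depth = 16L,
            class = c("well_image", "matrix", "array"))
}

#' Write a microwell time-lapse as a multi-frame TIFF
#'
#' Frames go into one multi-IFD 16-bit grayscale TIFF; the timestamps (in
#' minutes) and pixel size are embedded as JSON in the first frame's
#' ImageDescription, so the stack is self-describing.
#'
#' @param timelapse a `well_timelapse` with rendered frames.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_timelapse_stack <- function(timelapse, path) {
  check(inherits(timelapse, "well_timelapse"), "need a well_timelapse")
  check(!is.null(timelapse$frames), "time-lapse has no rendered frames")
  meta <- jsonlite::toJSON(list(times_min = timelapse$times_min,
                                pixel_size_um = timelapse$pixel_size_um),
                           auto_unbox = TRUE, digits = NA)
  tiff_write(timelapse$frames, path, bits = 16L,
             description = as.character(meta))
}

#' Read a microwell time-lapse stack
#'
#' Reads a multi-frame grayscale TIFF; per-frame timestamps come from the
#' embedded JSON description, from a sidecar CSV (`<stem>_times.csv` with
#' a `time_min` column, or an explicit `times_csv`), or from `times_min`.
#' Timestamps must be strictly increasing; non-uniform frame intervals are
#' tolerated but reported with a message.
#'
#' @param path TIFF path.
#' @param times_min optional explicit timestamps (minutes).
#' @param times_csv optional sidecar CSV path.
#' @param min_frames minimum accepted frame count (tracking requires 3).
#' @return A `well_timelapse`.
#' @export
read_timelapse_stack <- function(path, times_min = NULL, times_csv = NULL,
                                 min_frames = 1L) {
  t <- tiff_read(path)
  nfr <- length(t$frames)
  check(nfr >= min_frames,
        sprintf("stack has %d frame(s) but %d are required%s", nfr,
                min_frames,
                if (min_frames >= 3) " (the initial vote needs 3 frames)"
                else ""))
  px <- NA_real_
  if (is.null(times_min) && !is.null(t$description)) {
    meta <- tryCatch(jsonlite::fromJSON(t$description),
                     error = function(e) NULL)
    if (!is.null(meta$times_min)) times_min <- meta$times_min
    if (!is.null(meta$pixel_size_um)) px <- meta$pixel_size_um
  }
  if (is.null(times_min)) {
    sidecar <- if (!is.null(times_csv)) times_csv else
      paste0(tools::file_path_sans_ext(path), "_times.csv")
    if (file.exists(sidecar)) {
      tab <- utils::read.csv(sidecar)
      check("time_min" %in% names(tab), "sidecar CSV needs a time_min column")
      times_min <- tab$time_min
    }
  }
  check(!is.null(times_min),
        paste0("no frame timestamps: embed them in the TIFF description, ",
               "provide a '<stem>_times.csv' sidecar with a time_min ",
               "column, or pass times_min="))
  check(length(times_min) == nfr,
        "timestamp count does not match frame count")
  check(nfr < 2 || all(diff(times_min) > 0),
        "timestamps must be strictly increasing")
  if (nfr > 2 && length(unique(round(diff(times_min), 6))) > 1)
    message("note: non-uniform frame intervals in ", path)
  frames <- lapply(t$frames, function(f)
    structure(f, pixel_size_um = px, bit_depth = 16L,
              class = c("well_image", "matrix", "array")))
  structure(list(frames = frames, times_min = as.numeric(times_min),
                 pixel_size_um = px),
            class = "well_timelapse")
}

#' Write pipeline outputs
#'
#' Writes the standard result files into `out_dir`: `fates.csv` (one fate
#' record per well), `dynamics.csv` (the dynamics series grid),
#' optionally `predictions.csv` (well, frame, time, the four class
#' probabilities and the argmax label), and `run_metadata.json` (seeds,
#' configuration echo, package version).  Existing files are refused
#' unless `overwrite = TRUE`.
#'
#' @param records fate-record data frame (may be `NULL`).
#' @param series `dynamics_series` (may be `NULL`).
#' @param out_dir output directory (created if needed).
#' @param predictions optional long-format prediction data frame.
#' @param config optional configuration list echoed into the metadata.
#' @param seed seed echoed into the metadata.
#' @param overwrite overwrite existing files.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(records = NULL, series = NULL, out_dir,
                          predictions = NULL, config = NULL, seed = NULL,
                          overwrite = FALSE) {
  check(!is.null(records) || !is.null(series) || !is.null(predictions),
        "nothing to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  targets <- c(fates = "fates.csv", dynamics = "dynamics.csv",
               predictions = "predictions.csv",
               metadata = "run_metadata.json")
  paths <- file.path(out_dir, targets)
  names(paths) <- names(targets)
  want <- c(fates = !is.null(records), dynamics = !is.null(series),
            predictions = !is.null(predictions), metadata = TRUE)
  clash <- paths[want & file.exists(paths)]
  check(overwrite || length(clash) == 0,
        paste0("refusing to overwrite existing output(s): ",
               paste(basename(clash), collapse = ", "),
               " (use overwrite = TRUE)"))
  if (!is.null(records))
    utils::write.csv(records, paths[["fates"]], row.names = FALSE)
  if (!is.null(series))
    utils::write.csv(as.data.frame(series), paths[["dynamics"]],
                     row.names = FALSE)
  if (!is.null(predictions))
    utils::write.csv(predictions, paths[["predictions"]], row.names = FALSE)
  meta <- list(package = "wellfate",
               version = as.character(utils::packageVersion("wellfate")),
               timestamp = format(Sys.time(), tz = "UTC",
                                  "%Y-%m-%dT%H:%M:%SZ"),
               seed = seed, config = config)
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths[want])
}
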