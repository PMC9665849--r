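#' Write a projection stack as a multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled by a recorded
#' intensity scale (TIFF float pages are kept in \[0, 1\]); the sidecar
#' carries the timestamps (minutes), pixel size (mm), the scale, and any
#' extra metadata (e.g. a ground-truth summary).
#'
#' @param stack A [projection_stack()].
#' @param tif_path,json_path Output paths; the sidecar defaults to the
#'   TIFF path with a `.json` extension.
#' @param metadata Optional list merged into the sidecar.
#' @return Invisibly, the sidecar list.
#' @export
write_stack <- function(stack, tif_path,
                        json_path = sub("\\.tif{1,2}$", ".json", tif_path),
                        metadata = list()) {
  stopifnot(inherits(stack, "projection_stack"))
  scale <- max(vapply(stack$frames, max, numeric(1))) * 1.0001
  tiff::writeTIFF(lapply(stack$frames, function(fr) fr / scale),
                  tif_path, bits.per.sample = 32L)
  side <- c(list(timestamps_min = stack$timestamps,
                 pixel_size_mm = stack$pixel_size,
                 intensity_scale = scale), metadata)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a projection stack written by [write_stack()]
#'
#' @param tif_path,json_path Input paths.
#' @return A [projection_stack()].
#' @export
read_stack <- function(tif_path,
                       json_path = sub("\\.tif{1,2}$", ".json", tif_path)) {
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  frames <- lapply(pages, function(p) p * side$intensity_scale)
  projection_stack(frames, side$timestamps_min, side$pixel_size_mm)
}

#' Write an intensity profile as CSV
#'
#' Depth header column in micrometres, time header row in minutes.
#'
#' @param profile An [intensity_profile()].
#' @param path Output path.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  df <- data.frame(depth_um = profile$depth * 1000, profile$values,
                   check.names = FALSE)
  names(df)[-1] <- format(profile$time, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an intensity profile written by [write_profile_csv()]
#'
#' @param path Input path.
#' @param stage Processing stage of the stored values.
#' @return An [intensity_profile()].
#' @export
read_profile_csv <- function(path, stage = "standardized_uhat") {
  df <- utils::read.csv(path, check.names = FALSE)
  intensity_profile(df[[1]] / 1000,
                    as.numeric(names(df)[-1]),
                    as.matrix(df[, -1, drop = FALSE]),
                    stage = stage)
}
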