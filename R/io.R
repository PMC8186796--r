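# Shared I/O: multi-page TIFF image containers, CSV measurement tables,
# YAML run configuration. Images are stored as 16-bit grayscale TIFF with
# intensities in [0, 1]; values already on the 16-bit grid (see
# quantize16()) survive a write/read round trip bit-exactly.

#' Write / read a 3D stack as multi-page TIFF
#'
#' Pages are z-slices; intensities are clamped to `[0, 1]` and stored at
#' 16 bits. Voxel sizes are not embedded: they travel in the sidecar
#' config and are supplied at read time.
#'
#' @param stack [image_stack3d()] or 3D array `[y, x, z]`.
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  v <- as_voxels(stack)
  ss_check(is.array(v) && length(dim(v)) == 3, "`stack` must be 3D")
  pages <- lapply(seq_len(dim(v)[3]), function(k)
    pmin(pmax(v[, , k], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @param voxel_size um per voxel `(y, x, z)`.
#' @param channel channel label.
#' @return [image_stack3d()] for `read_stack`; a [frame_sequence()] for
#'   `read_video`.
#' @export
read_stack <- function(path, voxel_size, channel = "nuclear") {
  pages <- read_tiff_pages(path)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  image_stack3d(arr, voxel_size, channel)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path))
    ss_stop(sprintf("cannot read '%s': no such file", path),
            "spherosed_io_error")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) ss_stop(
                      sprintf("cannot read '%s': %s", path,
                              conditionMessage(e)), "spherosed_io_error"))
  if (is.matrix(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    ss_stop(sprintf("'%s': inconsistent page shapes", path),
            "spherosed_io_error")
  pages
}

#' Write / read a fall video (multi-page TIFF + sidecar metadata)
#'
#' @param seq a [frame_sequence()].
#' @param path TIFF file.
#' @export
write_video <- function(seq, path) {
  ss_check(inherits(seq, "frame_sequence"), "`seq` must be a frame_sequence")
  write_stack(seq$frames, path)
}

#' @rdname write_video
#' @param meta list with `pixel_size_um`, `polarity`, and either
#'   `timestamps` (s) or `fps`.
#' @export
read_video <- function(path, meta) {
  pages <- read_tiff_pages(path)
  n <- length(pages)
  ts <- meta$timestamps
  if (is.null(ts)) {
    ss_check(!is.null(meta$fps), "metadata needs `timestamps` or `fps`")
    ts <- (seq_len(n) - 1) / meta$fps
  }
  pol <- if (is.null(meta$polarity)) "dark" else meta$polarity
  frame_sequence(array(unlist(pages), c(dim(pages[[1]]), n)),
                 ts, meta$pixel_size_um, pol)
}

#' Flatten a biophysical measurement into a CSV-ready row
#'
#' @param id spheroid identifier.
#' @param bm a [biophysical_measurement()].
#' @return one-row data.frame matching the results schema.
#' @export
measurement_row <- function(id, bm) {
  data.frame(id = id, n_repetitions = bm$n_repetitions,
             velocity_m_s = bm$terminal_velocity,
             velocity_se = bm$velocity_se, diameter_um = bm$diameter,
             density_g_cm3 = bm$mass_density, mass_ug = bm$mass,
             buoyant_weight_nN = bm$buoyant_weight, reynolds = bm$reynolds,
             qc_flags = paste(bm$qc_flags, collapse = ";"))
}

#' Write a results table / read a cohort table (CSV)
#'
#' CSV with a fixed header order, '.' decimal separator, UTF-8; the cohort
#' reader validates the condition/state/parameter enumerations and names
#' the offending row on failure.
#'
#' @param rows data.frame to write.
#' @param path CSV file.
#' @export
write_results <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    ss_stop(sprintf("cannot read '%s': no such file", path),
            "spherosed_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  suppressWarnings(cohort_table(df))
}

#' Read and validate a YAML run configuration
#'
#' Recognized top-level sections: `fluid` (density, viscosity,
#' temperature), `channel` (radius, gravity), `flags` (wall_correction,
#' reynolds_threshold), `video` (pixel_size_um, fps, timestamps,
#' polarity), `imaging` (voxel_size_um plus [quantify_nuclei()] params),
#' `stats` (alpha, k), `seed`, `output`. Unknown sections are rejected.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    ss_stop(sprintf("cannot read config '%s': no such file", path),
            "spherosed_io_error")
  cfg <- yaml::read_yaml(path)
  known <- c("fluid", "channel", "flags", "video", "imaging", "stats",
             "seed", "output")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    ss_stop(sprintf("unknown config section(s): %s",
                    paste(extra, collapse = ", ")),
            "spherosed_schema_error")
  cfg
}

config_fluid <- function(cfg) {
  f <- cfg$fluid
  if (is.null(f)) return(fluid_medium())
  if (!is.null(f$viscosity))
    fluid_medium(density = f$density %||% 1005, viscosity = f$viscosity,
                 temperature = f$temperature %||% 25)
  else fluid_medium(density = f$density %||% 1005,
                    temperature = f$temperature %||% 25)
}

config_channel <- function(cfg) {
  ch <- cfg$channel
  if (is.null(ch)) return(channel_geometry())
  channel_geometry(radius = ch$radius %||% 0.5e-3,
                   gravity = ch$gravity %||% 9.80665)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
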