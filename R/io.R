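#' Read a calibrated multi-page TIFF stack
#'
#' Reads a single-channel multi-page grayscale TIFF into a
#' [calibrated_stack()]. TIFF metadata is untrusted: the explicit
#' `pixel_size` / `frame_interval` arguments always win; if a calibration
#' sidecar written by [write_stack()] disagrees, a warning is emitted.
#' Integer pixel values are preserved bit-exactly; float stacks written by
#' [write_stack()] are restored via the intensity scale recorded in the
#' sidecar.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param pixel_size Micrometres per pixel (> 0).
#' @param frame_interval Seconds per frame (> 0).
#' @param channel_label Optional channel description.
#' @return A [calibrated_stack()].
#' @export
read_stack <- function(path, pixel_size, frame_interval, channel_label = "") {
  if (!file.exists(path)) {
    stop("cannot read stack: file not found: ", path, call. = FALSE)
  }
  first <- tryCatch(
    tiff::readTIFF(path, info = TRUE),
    error = function(e) stop("unreadable TIFF: ", conditionMessage(e),
                             call. = FALSE)
  )
  is_float <- identical(attr(first, "sample.format"), "float") ||
    identical(attr(first, "bits.per.sample"), 32L)
  # as.is returns raw integer values for integer TIFFs (bit-exact); float
  # samples must be read as stored
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1)))) {
    stop("multi-channel/RGB TIFF pages are not supported; ",
         "supply a single-channel grayscale stack", call. = FALSE)
  }
  sidecar <- sidecar_path(path)
  meta <- if (file.exists(sidecar)) {
    jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  } else NULL
  if (!is.null(meta)) {
    if (!is.null(meta$pixel_size) &&
        abs(meta$pixel_size - pixel_size) > 1e-9 * pixel_size) {
      warning(sprintf(
        "pixel_size argument (%g) overrides sidecar value (%g)",
        pixel_size, meta$pixel_size), call. = FALSE)
    }
    if (!is.null(meta$frame_interval) &&
        abs(meta$frame_interval - frame_interval) > 1e-9 * frame_interval) {
      warning(sprintf(
        "frame_interval argument (%g) overrides sidecar value (%g)",
        frame_interval, meta$frame_interval), call. = FALSE)
    }
    if (!is.null(meta$intensity_scale)) {
      pages <- lapply(pages, function(p) p * meta$intensity_scale)
    }
  }
  calibrated_stack(pages, pixel_size, frame_interval, channel_label)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a calibrated stack to a multi-page TIFF
#'
#' Integer-valued stacks (all intensities integral, within 16-bit range) are
#' written as 16-bit TIFF and round-trip bit-exactly. Other stacks are
#' written as 32-bit float TIFF, rescaled to `[0, 1]` with the scale factor
#' recorded in a JSON calibration sidecar (`<path>.json`), which also stores
#' `pixel_size` and `frame_interval`.
#'
#' @param stack A [calibrated_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  nt <- n_frames(stack)
  if (nt == 0L) stop("cannot write an empty stack (0 frames)", call. = FALSE)
  if (!dir.exists(dirname(path))) {
    stop("unwritable path: directory does not exist: ", dirname(path),
         call. = FALSE)
  }
  fr <- stack$frames
  integral <- all(fr == round(fr)) && min(fr) >= 0 && max(fr) <= 65535
  pages <- lapply(seq_len(nt), function(i) fr[i, , ])
  meta <- list(
    pixel_size = stack$pixel_size,
    frame_interval = stack$frame_interval,
    channel_label = stack$channel_label
  )
  if (integral) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L)
  } else {
    scale <- max(fr)
    if (scale <= 0) scale <- 1
    tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                    bits.per.sample = 32L)
    meta$intensity_scale <- scale
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Construct a measurement result record
#'
#' One row of the long results table every pipeline stage appends to.
#'
#' @param embryo_id,genotype,stage Identifiers (free text).
#' @param measurement Measurement name.
#' @param value Numeric value.
#' @param units One of `"um"`, `"um/min"`, `"um/s"`, `"um^2"`, `"s"`,
#'   `"dimensionless"`.
#' @return A one-row tibble.
#' @export
result_record <- function(embryo_id, genotype, stage, measurement, value,
                          units) {
  allowed <- c("um", "um/min", "um/s", "um^2", "s", "dimensionless")
  if (!units %in% allowed) {
    stop("units must be one of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    embryo_id = as.character(embryo_id),
    genotype = as.character(genotype),
    stage = as.character(stage),
    measurement = as.character(measurement),
    value = as.numeric(value),
    units = units
  )
}

#' Write result records to CSV
#'
#' Fixed header `embryo_id, genotype, stage, measurement, value, units`;
#' rows written in input order, values with full double precision.
#'
#' @param records A data frame of result records (see [result_record()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a non-empty data frame of result records",
         call. = FALSE)
  }
  cols <- c("embryo_id", "genotype", "stage", "measurement", "value", "units")
  if (!all(cols %in% names(records))) {
    stop("records must have columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(records[cols], path, row.names = FALSE)
  invisible(path)
}
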