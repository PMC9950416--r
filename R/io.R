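# Plain-text and flat-binary interchange: pose/trace CSVs, protocol JSON,
# ECoG flat binary with a JSON header.

#' Write and read pose tables
#'
#' @param poses pose table from [track()] or [poses_from_gt()].
#' @param path CSV file path.
#' @export
write_poses_csv <- function(poses, path) {
  utils::write.csv(poses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_poses_csv
#' @export
read_poses_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$valid <- as.logical(d$valid)
  d
}

#' Write and read ROI activation traces
#'
#' Long CSV format: `frame`, `label`, `value`, with ROI metadata columns
#' repeated per ROI on read from the accompanying ROI table.
#'
#' @param traces a `roi_traces` object.
#' @param path CSV file path.
#' @export
write_traces_csv <- function(traces, path) {
  wide <- data.frame(frame = seq_len(nrow(traces$values)) - 1L,
                     traces$values, check.names = FALSE)
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param rois ROI table matching the stored labels.
#' @param frame_rate frames per second.
#' @export
read_traces_csv <- function(path, rois, frame_rate = NA_real_) {
  d <- utils::read.csv(path, check.names = FALSE)
  values <- as.matrix(d[, -1, drop = FALSE])
  stopifnot(identical(colnames(values), rois$label))
  structure(list(values = values, rois = rois, frame_rate = frame_rate),
            class = "roi_traces")
}

#' Write and read a protocol schedule as JSON
#'
#' @param protocol trial table from [generate_protocol()].
#' @param path JSON file path.
#' @export
write_protocol_json <- function(protocol, path) {
  jsonlite::write_json(protocol, path, dataframe = "columns")
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write and read ECoG recordings as flat binary + JSON header
#'
#' Voltage samples are stored channel-major as little-endian float32; the
#' JSON sidecar holds the rate, channel metadata, strobe and counters.
#'
#' @param recording an `ecog_recording`.
#' @param path base path; writes `<path>.bin` and `<path>.json`.
#' @export
write_ecog_bin <- function(recording, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$samples)), con, size = 4L,
           endian = "little")
  header <- list(sample_rate = recording$sample_rate,
                 n_channels = nrow(recording$samples),
                 n_samples = ncol(recording$samples),
                 channel_info = recording$channel_info,
                 strobe = recording$strobe,
                 frame_counters = recording$frame_counters)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ecog_bin
#' @export
read_ecog_bin <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = header$n_channels * header$n_samples,
                 size = 4L, endian = "little")
  samples <- t(matrix(raw, ncol = header$n_channels))
  structure(list(samples = samples, sample_rate = header$sample_rate,
                 strobe = header$strobe,
                 frame_counters = header$frame_counters,
                 channel_info = as.data.frame(header$channel_info)),
            class = "ecog_recording")
}
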