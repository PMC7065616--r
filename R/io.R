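# On-disk formats: 16-bit grayscale TIFF + JSON sidecar for M-scans,
# `time_s,value` CSV for traces, JSON for ground-truth records.

#' Write / read an M-scan as 16-bit TIFF with a JSON sidecar
#'
#' The image is stored as a 16-bit grayscale TIFF (rows = depth, columns =
#' time); intensities are divided by `intensity_scale` (the image maximum)
#' before quantization, and the scale is stored in the sidecar
#' `<path>.json` alongside `axial_pitch_um`, `ascan_rate_hz` and `t0_s`,
#' so `read_mscan` restores physical intensity up to 16-bit quantization.
#'
#' @param m An [mscan()].
#' @param path Path of the TIFF file to write (sidecar goes to `<path>.json`).
#' @return `write_mscan` returns `path` invisibly; `read_mscan` returns an
#'   [mscan()].
#' @export
write_mscan <- function(m, path) {
  if (!inherits(m, "mscan"))
    cp_stop("corneapuff_invalid_spec", "m must be an mscan")
  scale <- max(m$intensity, 1e-12)
  tiff::writeTIFF(m$intensity / scale, path, bits.per.sample = 16,
                  compression = "none")
  meta <- list(axial_pitch_um = m$axial_pitch, ascan_rate_hz = m$ascan_rate,
               t0_s = m$t0, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mscan
#' @export
read_mscan <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    cp_stop("corneapuff_invalid_spec", "missing sidecar %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  if (is.array(img) && length(dim(img)) == 3L) img <- img[, , 1]
  mscan(img * meta$intensity_scale, axial_pitch = meta$axial_pitch_um,
        ascan_rate = meta$ascan_rate_hz, t0 = meta$t0_s)
}
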