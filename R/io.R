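#' Read a micrograph with its physical-scale sidecar
#'
#' Reads an 8/16-bit grayscale TIFF or PNG and the JSON sidecar
#' `<image>.json` holding `{"nm_per_pixel": <value>}`.
#'
#' @param path image file (`.tif`, `.tiff` or `.png`).
#' @param nm_per_pixel physical scale; overrides / replaces the sidecar.
#' @return a `micrograph` list (`image` indexed `[x, y]`, `nm_per_pixel`,
#'   `id`).
#' @export
read_micrograph <- function(path, nm_per_pixel = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (is.null(nm_per_pixel)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    if (!file.exists(sidecar))
      stop("no nm_per_pixel given and no sidecar found: ", sidecar)
    nm_per_pixel <- jsonlite::read_json(sidecar)$nm_per_pixel
  }
  # image files store row-major [y, x]; internal convention is [x, y]
  structure(list(image = t(img), nm_per_pixel = nm_per_pixel,
                 id = basename(path)),
            class = "micrograph")
}

#' Write a micrograph as 16-bit TIFF plus JSON sidecar
#'
#' @param m a `micrograph` list.
#' @param path output `.tif` path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path) {
  img <- pmin(pmax(m$image, 0), 1)
  tiff::writeTIFF(t(img), path, bits.per.sample = 16)
  jsonlite::write_json(list(nm_per_pixel = m$nm_per_pixel, id = m$id),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a time-series trace from CSV
#'
#' Expects a header `time_s,<channel>` where `<channel>` is `force_mN`,
#' `length_ml`, `fluorescence_au` or `volts`; the sampling rate is inferred
#' from the time grid.
#'
#' @param path CSV file.
#' @return a [mech_trace].
#' @export
read_trace <- function(path) {
  d <- read.csv(path)
  stopifnot(names(d)[1] == "time_s", ncol(d) >= 2)
  chan <- switch(names(d)[2],
    force_mN = "force", length_ml = "length",
    fluorescence_au = "fluorescence", volts = "vibration",
    stop("unknown channel column: ", names(d)[2]))
  fs <- 1 / median(diff(d$time_s))
  mech_trace(d$time_s, d[[2]], fs, chan)
}

#' Write a trace to CSV with the standard header
#'
#' @param trace a [mech_trace].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  col <- switch(trace_channel(trace),
    force = "force_mN", length = "length_ml",
    fluorescence = "fluorescence_au", vibration = "volts")
  d <- data.frame(time_s = trace$time, v = trace$value)
  names(d)[2] <- col
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
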