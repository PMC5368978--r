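#' Write a FLIM stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float TIFF page per time bin (counts scaled into `[0, 1]` by
#' the stack maximum, which round-trips integer counts exactly), with the
#' acquisition metadata, channel label and scale factor in a JSON sidecar
#' next to the image.
#'
#' @param stack A `flim_stack`.
#' @param path Output TIFF path; the sidecar is written at the same path
#'   with extension `.json`.
#' @return Invisibly, a list with the `tiff` and `json` paths.
#' @export
write_flim_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  d <- dim(stack$counts)
  scale <- max(stack$counts, 1)
  pages <- lapply(seq_len(d[3]), function(b) stack$counts[, , b] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- sub("\\.tif{1,2}$", ".json", path)
  if (sidecar == path) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(rep_rate = stack$acq$rep_rate, period_t = stack$acq$period_t,
         n_bins = stack$acq$n_bins, channel = stack$channel,
         scale = scale, shape = d[1:2]),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(tiff = path, json = sidecar))
}

#' Read a FLIM stack written by [write_flim_stack()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it.
#' @return A `flim_stack`; counts round-trip bit-identically.
#' @export
read_flim_stack <- function(path) {
  sidecar <- sub("\\.tif{1,2}$", ".json", path)
  if (sidecar == path) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_bins)
    stop("sidecar n_bins (", meta$n_bins, ") does not match TIFF pages (",
         length(pages), ")")
  d <- dim(pages[[1]])
  if (!identical(as.integer(meta$shape), as.integer(d)))
    stop("sidecar shape does not match TIFF page shape")
  counts <- array(0L, dim = c(d, meta$n_bins))
  for (b in seq_along(pages))
    counts[, , b] <- as.integer(round(pages[[b]] * meta$scale))
  acq <- acquisition_spec(rep_rate = meta$rep_rate, n_bins = meta$n_bins)
  structure(list(counts = counts, acq = acq, channel = meta$channel),
            class = "flim_stack")
}

#' Write an intensity image (or any numeric map) as 32-bit TIFF
#'
#' @param image Numeric matrix.
#' @param path Output TIFF path.
#' @return Invisibly, `path`. The scale factor is appended as a JSON
#'   sidecar so values round-trip.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  scale <- max(abs(image), 1)
  tiff::writeTIFF(image / scale, path, bits.per.sample = 32L)
  sidecar <- sub("\\.tif{1,2}$", ".json", path)
  if (sidecar == path) sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(scale = scale), sidecar, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
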