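#' Marker channels required by the pipeline
#'
#' Canonical channel names, in spectral order: nuclear counterstain (DAPI),
#' pan-endothelial CD31, alpha smooth muscle actin (aSMA), lymphatic
#' podoplanin (PDPN, clone D2-40), endometrial stroma CD10, and VEGF.
#' @export
VQ_CHANNELS <- c("DAPI", "CD31", "aSMA", "PDPN", "CD10", "VEGF")

#' Construct a multichannel field (ChannelStack)
#'
#' A ChannelStack is one registered multispectral field: a named list of 2-D
#' intensity planes (one per marker, values in `[0, 1]`), plus the physical
#' pixel size in micrometres, and identifiers.
#'
#' @param planes Named list of numeric matrices, all with identical
#'   dimensions; names must cover [VQ_CHANNELS] (after alias resolution).
#' @param pixel_um Physical pixel edge length, micrometres per pixel.
#' @param field_id,specimen_id Identifiers carried through all records.
#' @param aliases Optional named character vector mapping canonical channel
#'   names to the names used in `planes`, e.g. `c(PDPN = "D2-40")`.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(planes, pixel_um, field_id = "field1",
                          specimen_id = "specimen1", aliases = NULL) {
  stopifnot(is.list(planes), length(planes) >= 1L,
            is.numeric(pixel_um), length(pixel_um) == 1L, pixel_um > 0)
  if (!is.null(aliases)) {
    for (canon in names(aliases)) {
      alias <- aliases[[canon]]
      if (!canon %in% names(planes) && alias %in% names(planes)) {
        names(planes)[names(planes) == alias] <- canon
      }
    }
  }
  missing <- setdiff(VQ_CHANNELS, names(planes))
  if (length(missing)) {
    stop("channel_stack: missing required channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dims <- lapply(planes, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("channel_stack: all planes must share identical dimensions",
         call. = FALSE)
  }
  structure(list(planes = planes[VQ_CHANNELS], pixel_um = pixel_um,
                 field_id = field_id, specimen_id = specimen_id),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$planes[[1L]])
  cat(sprintf("<channel_stack> %s / %s: %d x %d px @ %.3g um/px (%s)\n",
              x$specimen_id, x$field_id, d[1], d[2], x$pixel_um,
              paste(names(x$planes), collapse = ", ")))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$planes[[1L]])

#' Write one field to disk as a multipage TIFF plus JSON sidecar
#'
#' Planes are written as 16-bit multipage TIFF in the canonical channel
#' order. Physical pixel size, channel names and identifiers go into a JSON
#' sidecar (`<path>.json`) because baseline TIFF carries no reliable
#' pixel-size tag through every reader. Intensities are already quantized to
#' the 16-bit grid by the generator, so the round trip via [read_field()] is
#' bit-exact.
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_field <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  tiff::writeTIFF(unname(stack$planes), path, bits.per.sample = 16,
                  compression = "deflate", reduce = FALSE)
  meta <- list(pixel_um = stack$pixel_um, channels = names(stack$planes),
               field_id = stack$field_id, specimen_id = stack$specimen_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read one field from a multipage TIFF
#'
#' Channel names and pixel size are taken from the JSON sidecar written by
#' [write_field()]; both can be overridden. Fails if the pixel size cannot be
#' resolved, because densities per mm^2 would be meaningless without it.
#'
#' @param path TIFF path.
#' @param aliases Optional named character vector mapping canonical channel
#'   names to names used in the file metadata, e.g. `c(PDPN = "D2-40")`.
#' @param pixel_um Override for the physical pixel size (um/px).
#' @param channels Override for the per-page channel names.
#' @return A [channel_stack()].
#' @export
read_field <- function(path, aliases = NULL, pixel_um = NULL, channels = NULL) {
  if (!file.exists(path)) stop("read_field: no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  channels <- channels %||% meta$channels
  if (is.null(channels) || length(channels) != length(pages)) {
    stop("read_field: channel names unavailable or inconsistent for ", path,
         call. = FALSE)
  }
  pixel_um <- as.numeric(pixel_um %||% meta$pixel_um %||% numeric(0))
  if (!length(pixel_um)) {
    stop("read_field: pixel size (um/px) missing for ", path,
         "; provide pixel_um or a metadata sidecar", call. = FALSE)
  }
  names(pages) <- channels
  channel_stack(pages, pixel_um = pixel_um,
                field_id = meta$field_id %||% tools::file_path_sans_ext(basename(path)),
                specimen_id = meta$specimen_id %||% "unknown",
                aliases = aliases)
}
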