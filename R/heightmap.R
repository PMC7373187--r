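#' Height map objects
#'
#' A `height_map` is the central raster object of the pipeline: a rectangular
#' grid of surface heights in nanometres together with the lateral pixel size.
#' Rows are scanlines (the AFM fast axis runs along columns), so row `r`,
#' column `c` is the pixel centred at x = (c - 0.5) * pixel_size,
#' y = (r - 0.5) * pixel_size.
#'
#' @param heights Numeric matrix of heights in nm; all values must be finite.
#' @param pixel_size_nm Lateral size of one pixel in nm (> 0).
#' @param metadata Free-form provenance list (seeds, parameters, stage log).
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size_nm, metadata = list()) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("`heights` must be a numeric matrix")
  if (!all(is.finite(heights)))
    stop("`heights` must be finite everywhere")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number")
  structure(
    list(heights = heights, pixel_size_nm = as.numeric(pixel_size_nm),
         metadata = metadata),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf(
    "<height_map> %d x %d px, %.4g nm/px (%.3g x %.3g nm), range [%.3g, %.3g] nm\n",
    d[1], d[2], x$pixel_size_nm, d[2] * x$pixel_size_nm, d[1] * x$pixel_size_nm,
    min(x$heights), max(x$heights)))
  invisible(x)
}

#' @export
dim.height_map <- function(x) dim(x$heights)

sidecar_path <- function(path) paste0(path, ".json")

#' Write a height map to disk
#'
#' Two on-disk formats are supported, selected by file extension. `.txt` /
#' `.dat` writes an ASCII matrix (one scanline per row, `%.17g`, so the double
#' grid round-trips bit-identically). `.tif` / `.tiff` writes a single-channel
#' 32-bit float TIFF; because the TIFF writer stores the [0, 1] range, heights
#' are affinely rescaled and the offset/scale recorded in the metadata sidecar,
#' making the round-trip exact to float32 precision only. Either way a JSON
#' sidecar `<path>.json` carries the pixel size (and any metadata); a map
#' without its sidecar cannot be read back, because a silently assumed pixel
#' size would corrupt every nm-valued quantity downstream.
#'
#' @param map A [height_map()].
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  ext <- tolower(tools::file_ext(path))
  side <- list(
    format_version = 1L,
    pixel_size_nm = map$pixel_size_nm,
    n_rows = nrow(map$heights),
    n_cols = ncol(map$heights),
    metadata = map$metadata
  )
  if (ext %in% c("tif", "tiff")) {
    rng <- range(map$heights)
    offset <- rng[1]
    scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    tiff::writeTIFF((map$heights - offset) / scale, path,
                    bits.per.sample = 32L)
    side$tiff_offset_nm <- offset
    side$tiff_scale_nm <- scale
  } else if (ext %in% c("txt", "dat", "asc")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(apply(map$heights, 1L,
                     function(r) paste(sprintf("%.17g", r), collapse = " ")),
               con)
  } else {
    stop("unknown height-map format: .", ext,
         " (use .tif/.tiff or .txt/.dat)")
  }
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a height map from disk
#'
#' @param path Path previously written by [write_height_map()] (a
#'   `<path>.json` sidecar with the pixel size must sit next to it).
#' @return A [height_map()].
#' @export
read_height_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing pixel-size metadata sidecar '", sp,
         "': refusing to guess a pixel size")
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(side$pixel_size_nm))
    stop("sidecar '", sp, "' lacks pixel_size_nm")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    h <- tiff::readTIFF(path)
    if (is.null(side$tiff_offset_nm) || is.null(side$tiff_scale_nm))
      stop("sidecar '", sp, "' lacks the TIFF offset/scale needed to restore nm values")
    h <- h * side$tiff_scale_nm + side$tiff_offset_nm
  } else if (ext %in% c("txt", "dat", "asc")) {
    rows <- readLines(path)
    h <- do.call(rbind, lapply(strsplit(rows, " ", fixed = TRUE), as.numeric))
  } else {
    stop("unknown height-map format: .", ext)
  }
  md <- side$metadata
  if (is.null(md)) md <- list()
  height_map(h, side$pixel_size_nm, md)
}
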