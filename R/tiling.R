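#' Enumerate overlapping tile positions on a slide
#'
#' Tiles are `tile_px` squares placed every `stride_px` pixels in both
#' axes (the default stride of half a tile gives adjacent tiles a 50%
#' overlap). Coordinates are 0-based, half-open, expressed at level 0, and
#' returned in row-major order. Edge strips too narrow for a full tile are
#' discarded, not padded.
#'
#' @param width_px,height_px slide dimensions in level-0 pixels.
#' @param tile_px tile side length (default 256).
#' @param stride_px stride between tile origins (default `tile_px / 2`).
#' @return data.frame with integer columns `x`, `y` (tile origins). If a
#'   dimension is smaller than `tile_px`, an empty grid is returned with a
#'   warning.
#' @examples
#' nrow(enumerate_tiles(1024, 512))  # 7 x 3 = 21 tiles
#' @export
enumerate_tiles <- function(width_px, height_px, tile_px = 256L,
                            stride_px = tile_px %/% 2L) {
  stopifnot(tile_px >= 1, stride_px >= 1)
  if (width_px < tile_px || height_px < tile_px) {
    warning(sprintf("slide (%d x %d) smaller than tile size %d: empty grid",
                    width_px, height_px, tile_px))
    return(data.frame(x = integer(), y = integer()))
  }
  xs <- seq.int(0L, width_px - tile_px, by = stride_px)
  ys <- seq.int(0L, height_px - tile_px, by = stride_px)
  data.frame(x = rep(as.integer(xs), times = length(ys)),
             y = rep(as.integer(ys), each = length(xs)))
}

#' Number of tiles in a grid, in closed form
#'
#' @inheritParams enumerate_tiles
#' @return `(floor((W - tile)/stride) + 1) * (floor((H - tile)/stride) + 1)`,
#'   or 0 when a dimension is below `tile_px`.
#' @export
n_tiles <- function(width_px, height_px, tile_px = 256L,
                    stride_px = tile_px %/% 2L) {
  if (width_px < tile_px || height_px < tile_px) return(0L)
  as.integer((((width_px - tile_px) %/% stride_px) + 1L) *
             (((height_px - tile_px) %/% stride_px) + 1L))
}

#' Read an RGB slide image from PNG or TIFF
#'
#' Plain (non-pyramidal) PNG and TIFF images are supported; MIRAX and other
#' proprietary WSI containers are not.
#'
#' @param path image file path.
#' @return numeric array `height x width x 3` with values in 0..255.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("package 'tiff' is required to read TIFF slides")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported slide format: .", ext, " (PNG or TIFF expected)")
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE] * 255
  img
}

# Area-averaging resize of one channel from n_in to n_out rows/cols.
# For integer scale factors this is an exact block mean.
area_resize <- function(mat, out_h, out_w) {
  in_h <- nrow(mat); in_w <- ncol(mat)
  row_bin <- floor((seq_len(in_h) - 1L) * out_h / in_h) + 1L
  col_bin <- floor((seq_len(in_w) - 1L) * out_w / in_w) + 1L
  sums <- rowsum(mat, row_bin)
  sums <- t(rowsum(t(sums), col_bin))
  counts <- tabulate(row_bin, out_h) %o% tabulate(col_bin, out_w)
  sums / counts
}

#' Extract one tile from a slide image, rescaling to the target resolution
#'
#' The tile footprint at level 0 spans `tile_px * scale_factor` pixels; the
#' window is read and downscaled to `tile_px` by area averaging. A scale
#' factor of 2 corresponds to a slide scanned at 0.25 um/px being read out
#' at the working resolution of 0.5 um/px.
#'
#' @param slide numeric array `H x W x 3` in 0..255 (see
#'   [read_slide_image()]).
#' @param coord length-2 integer vector `(x, y)`: the 0-based level-0 tile
#'   origin.
#' @param tile_px output tile side (default 256).
#' @param scale_factor ratio target_mpp / source_mpp, >= 1.
#' @return numeric array `tile_px x tile_px x 3` in 0..255 (rounded to
#'   integer values).
#' @export
read_tile <- function(slide, coord, tile_px = 256L, scale_factor = 1) {
  stopifnot(length(dim(slide)) == 3L, scale_factor >= 1)
  span <- as.integer(round(tile_px * scale_factor))
  x0 <- as.integer(coord[[1]]); y0 <- as.integer(coord[[2]])
  H <- dim(slide)[1]; W <- dim(slide)[2]
  if (x0 < 0L || y0 < 0L || x0 + span > W || y0 + span > H) {
    stop(sprintf("tile footprint (%d,%d)+%d outside slide bounds %dx%d",
                 x0, y0, span, W, H))
  }
  win <- slide[(y0 + 1L):(y0 + span), (x0 + 1L):(x0 + span), , drop = FALSE]
  if (span == tile_px) {
    out <- win
  } else {
    out <- array(0, c(tile_px, tile_px, 3L))
    for (ch in 1:3) out[, , ch] <- area_resize(win[, , ch], tile_px, tile_px)
  }
  round(out)
}

#' Write a tile coordinate table
#'
#' @param slide_id slide identifier.
#' @param coords data.frame from [enumerate_tiles()].
#' @param path output CSV (`slide_id,x,y`).
#' @export
write_tile_coords <- function(slide_id, coords, path) {
  utils::write.csv(
    data.frame(slide_id = slide_id, x = coords$x, y = coords$y),
    path, row.names = FALSE
  )
  invisible(path)
}
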