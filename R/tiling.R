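# Tiling of full-resolution orchard frames into model-input sections.

#' Build a tile layout
#'
#' The `"paper11"` layout reproduces the published section count for
#' 5184 x 3456 frames cut into 1088 x 1088 inputs: 4 columns at
#' x in {0, 1365, 2731, 4096} and 3 rows at y in {0, 1184, 2368}, minus the
#' bottom-right tile, giving 11 tiles. The geometry behind the printed
#' count is not documented anywhere, so only the count — not the exact
#' offsets — is contractual; pass explicit `origins` for any other layout.
#' The `"grid"` layout covers the source with minimally overlapping tiles.
#'
#' @param source_size `c(width, height)` of the source image in px.
#' @param tile_size `c(width, height)` of each tile (default 1088 x 1088).
#' @param layout `"paper11"`, `"grid"`, or `"custom"` with `origins`.
#' @param origins Optional two-column matrix of (x, y) tile top-left
#'   positions for `layout = "custom"`.
#' @return A `TileLayout`: list with `tile_size`, `origins`, `source_size`.
#' @export
tile_layout <- function(source_size, tile_size = c(1088, 1088),
                        layout = c("paper11", "grid", "custom"), origins = NULL) {
  layout <- match.arg(layout)
  sw <- source_size[1]; sh <- source_size[2]
  tw <- tile_size[1]; th <- tile_size[2]
  ot_assert(tw <= sw && th <= sh,
            "configuration error: tile larger than source")
  if (layout == "paper11") {
    xs <- pmin(c(0, 1365, 2731, 4096), sw - tw)
    ys <- pmin(c(0, 1184, 2368), sh - th)
    org <- as.matrix(expand.grid(x = unique(xs), y = unique(ys)))
    # drop the bottom-right tile to honor the published 11-section count
    if (nrow(org) == 12) {
      org <- org[!(org[, 1] == max(org[, 1]) & org[, 2] == max(org[, 2])), , drop = FALSE]
    }
  } else if (layout == "grid") {
    nx <- ceiling(sw / tw); ny <- ceiling(sh / th)
    xs <- if (nx == 1) 0 else round(seq(0, sw - tw, length.out = nx))
    ys <- if (ny == 1) 0 else round(seq(0, sh - th, length.out = ny))
    org <- as.matrix(expand.grid(x = xs, y = ys))
  } else {
    ot_assert(!is.null(origins), "custom layout needs origins")
    org <- as.matrix(origins)
    colnames(org) <- c("x", "y")
  }
  ot_assert(all(org[, 1] >= 0 & org[, 1] + tw <= sw &
                  org[, 2] >= 0 & org[, 2] + th <= sh),
            "configuration error: tile origins out of bounds")
  ot_assert(!anyDuplicated(paste(org[, 1], org[, 2])), "tile origins must be unique")
  structure(list(tile_size = as.integer(tile_size), origins = org,
                 source_size = as.integer(source_size)),
            class = "TileLayout")
}

#' Cut an image into tiles
#'
#' @param image h x w x 3 array (or h x w matrix).
#' @param layout A `TileLayout` matching the image size.
#' @return A list of `list(tile, origin)`; `origin` is the tile's (x, y)
#'   top-left in source coordinates, for mapping detections back.
#' @export
tile_image <- function(image, layout) {
  d <- dim(image)
  ot_assert(d[2] == layout$source_size[1] && d[1] == layout$source_size[2],
            "image size does not match layout source_size")
  tw <- layout$tile_size[1]; th <- layout$tile_size[2]
  lapply(seq_len(nrow(layout$origins)), function(i) {
    x0 <- as.numeric(layout$origins[i, 1]); y0 <- as.numeric(layout$origins[i, 2])
    tile <- if (length(d) == 3) image[y0 + seq_len(th), x0 + seq_len(tw), , drop = FALSE]
            else image[y0 + seq_len(th), x0 + seq_len(tw), drop = FALSE]
    list(tile = tile, origin = c(x = x0, y = y0))
  })
}

#' Write tiles as PNG files with origins encoded in the filename
#'
#' Files are named `img_x{X}_y{Y}.png` under `out_dir`.
#'
#' @param image h x w x 3 array.
#' @param layout A `TileLayout`.
#' @param out_dir Output directory.
#' @param prefix Filename prefix (default `"img"`).
#' @return Character vector of file paths, invisibly.
#' @export
write_tiles <- function(image, layout, out_dir, prefix = "img") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tiles <- tile_image(image, layout)
  paths <- vapply(tiles, function(tl) {
    p <- file.path(out_dir, sprintf("%s_x%d_y%d.png", prefix, tl$origin[["x"]], tl$origin[["y"]]))
    write_image_png(tl$tile, p)
    p
  }, character(1))
  invisible(paths)
}
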