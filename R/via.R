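# VGG Image Annotator (VIA) 2.x project I/O. Only polygon/polyline regions
# are supported; other region shapes are skipped with a warning.

#' Construct a polygon annotation
#'
#' @param image_name Image file name the polygon belongs to.
#' @param xs,ys Vertex coordinates (>= 3 vertices).
#' @param attributes Optional named list of free-form region attributes.
#' @return A `PolygonAnnotation` object.
#' @export
polygon_annotation <- function(image_name, xs, ys, attributes = list()) {
  ot_assert(length(xs) == length(ys) && length(xs) >= 3,
            "polygon annotation needs at least 3 vertices")
  structure(list(image_name = image_name, xs = as.numeric(xs),
                 ys = as.numeric(ys), attributes = attributes),
            class = "PolygonAnnotation")
}

#' @export
print.PolygonAnnotation <- function(x, ...) {
  cat(sprintf("<PolygonAnnotation %s, %d vertices>\n", x$image_name, length(x$xs)))
  invisible(x)
}

#' Read polygon annotations from a VIA project
#'
#' Accepts either a full VIA 2.x project (with `_via_img_metadata`) or the
#' bare image-metadata map. Regions whose shape is not `polygon` or
#' `polyline` are skipped with a warning.
#'
#' @param path Path to a VIA JSON file, or a JSON string.
#' @return A list of `PolygonAnnotation`, grouped by image (project order).
#' @export
read_via <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed VIA JSON: ", conditionMessage(e),
                                           call. = FALSE))
  meta <- if (!is.null(doc$`_via_img_metadata`)) doc$`_via_img_metadata` else doc
  meta <- meta[!startsWith(names(meta), "_via_")]
  anns <- list()
  for (key in names(meta)) {
    entry <- meta[[key]]
    fname <- entry$filename
    if (is.null(fname)) stop("malformed VIA JSON: missing 'filename' in entry '",
                             key, "'", call. = FALSE)
    for (reg in entry$regions) {
      sa <- reg$shape_attributes
      if (is.null(sa) || is.null(sa$name)) {
        stop("malformed VIA JSON: missing 'shape_attributes' in '", key, "'",
             call. = FALSE)
      }
      if (!sa$name %in% c("polygon", "polyline")) {
        warning("skipping non-polygon region of shape '", sa$name, "' in '",
                fname, "'")
        next
      }
      anns[[length(anns) + 1]] <- polygon_annotation(
        fname, unlist(sa$all_points_x), unlist(sa$all_points_y),
        attributes = if (is.null(reg$region_attributes)) list() else reg$region_attributes)
    }
  }
  anns
}

#' Write polygon annotations as a VIA project
#'
#' Inverse of [read_via()]: the round trip preserves vertex lists and image
#' names exactly.
#'
#' @param annotations List of `PolygonAnnotation`.
#' @param path Output file, or `NULL` to return the JSON string.
#' @return The path (invisibly) or the JSON string.
#' @export
write_via <- function(annotations, path = NULL) {
  by_img <- split(annotations,
                  vapply(annotations, function(a) a$image_name, character(1)))
  by_img <- by_img[unique(vapply(annotations, function(a) a$image_name, character(1)))]
  meta <- lapply(names(by_img), function(fname) {
    regions <- lapply(by_img[[fname]], function(a) {
      list(shape_attributes = list(name = "polygon",
                                   all_points_x = as.list(a$xs),
                                   all_points_y = as.list(a$ys)),
           region_attributes = a$attributes)
    })
    list(filename = fname, size = -1, regions = regions, file_attributes = c())
  })
  names(meta) <- paste0(names(by_img), "-1")
  doc <- list(`_via_settings` = list(ui = c(), core = c(), project = list(name = "orchardtrack")),
              `_via_img_metadata` = meta,
              `_via_attributes` = list(region = c(), file = c()))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
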