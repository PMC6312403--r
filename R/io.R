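# File I/O: multi-page TIFF stacks, mask images, polygon ROI tables,
# tidy CSV export.

#' Read and write TIFF image stacks
#'
#' Stacks are stored as multi-page TIFF. TIFF integer samples cover
#' `[0, 1]` after reading, so camera units are mapped through a `scale`
#' factor on write and restored on read; use the same `scale` on both
#' sides (the default 65535 maps one camera unit to one 16-bit step,
#' which round-trips integer-valued camera data exactly).
#'
#' @param path file path.
#' @param channel,frameInterval,startTime stack metadata (see
#'   [tirfStack()]); not stored in the TIFF, so they must be supplied on
#'   read (or carried in a sidecar metadata file).
#' @param scale camera units corresponding to full scale.
#' @return `readTirfStack` returns a [TirfStack-class]; `writeTirfStack`
#'   returns `path` invisibly.
#' @export
readTirfStack <- function(path, channel = "biosensor", frameInterval = 10,
                          startTime = 0, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  tirfStack(arr * scale, channel = channel,
            frameInterval = frameInterval, startTime = startTime)
}

#' @rdname readTirfStack
#' @param stack a [TirfStack-class].
#' @export
writeTirfStack <- function(stack, path, scale = 65535) {
  stopifnot(is(stack, "TirfStack"))
  mx <- max(stack@frames)
  if (mx > scale)
    stop("intensities exceed the TIFF scale (max ", format(mx),
         " > ", scale, "); increase `scale`")
  d <- dim(stack@frames)
  pages <- lapply(seq_len(d[3L]), function(t) stack@frames[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Rasterize a polygon to a pixel mask
#'
#' Even-odd (ray crossing) fill over pixel centers. Coordinates are
#' 0-based: pixel `(r, c)` of the mask (1-based R indices) has its center
#' at `x = c - 1`, `y = r - 1`, matching the convention of common image
#' tools.
#'
#' @param x,y polygon vertex coordinates (0-based pixel coordinates,
#'   at least 3 vertices; the polygon is closed implicitly).
#' @param dim integer(2), mask dimensions (rows, cols).
#' @return Logical matrix of dimensions `dim`.
#' @export
polygonMask <- function(x, y, dim) {
  stopifnot(length(x) == length(y), length(x) >= 3L, length(dim) == 2L)
  px <- rep(seq_len(dim[2L]) - 1, each = dim[1L])
  py <- rep(seq_len(dim[1L]) - 1, times = dim[2L])
  inside <- logical(length(px))
  n <- length(x)
  j <- n
  for (i in seq_len(n)) {
    # edge (j -> i) crossed by a horizontal ray to the left of the pixel
    straddles <- (y[i] > py) != (y[j] > py)
    if (any(straddles)) {
      xCross <- (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]
      inside <- xor(inside, straddles & px < xCross)
    }
    j <- i
  }
  matrix(inside, nrow = dim[1L], ncol = dim[2L])
}

#' Build an ROI set from a polygon table
#'
#' The table format is one row per vertex with columns `roi_id`
#' (`"cell"` or `"background"`), `vertex_index` (ordering within the
#' polygon), `x`, `y` (0-based pixel coordinates).
#'
#' @param vertices `data.frame` with the columns above, or a CSV path
#'   (for `readPolygonRoi`).
#' @param dim integer(2), image dimensions (rows, cols).
#' @return A [RoiSet-class].
#' @export
roiSetFromPolygons <- function(vertices, dim) {
  needed <- c("roi_id", "vertex_index", "x", "y")
  if (!all(needed %in% names(vertices)))
    stop("polygon table needs columns: ", paste(needed, collapse = ", "))
  oneMask <- function(id) {
    v <- vertices[vertices$roi_id == id, , drop = FALSE]
    if (nrow(v) < 3L)
      stop("roi '", id, "' needs at least 3 vertices")
    v <- v[order(v$vertex_index), , drop = FALSE]
    polygonMask(v$x, v$y, dim)
  }
  roiSet(oneMask("cell"), oneMask("background"))
}

#' @rdname roiSetFromPolygons
#' @param path CSV file with the polygon table.
#' @export
readPolygonRoi <- function(path, dim) {
  roiSetFromPolygons(read.csv(path), dim)
}

#' Read an ROI set from binary mask images
#'
#' Pixels with intensity above `threshold` (after the image is read into
#' `[0, 1]`) are in the ROI.
#'
#' @param cellPath,backgroundPath TIFF mask images.
#' @param threshold inclusion threshold in `[0, 1)`.
#' @return A [RoiSet-class].
#' @export
readMaskRoi <- function(cellPath, backgroundPath, threshold = 0.5) {
  readOne <- function(p) {
    img <- tiff::readTIFF(p)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img > threshold
  }
  roiSet(readOne(cellPath), readOne(backgroundPath))
}

#' Export footprint traces as tidy CSV
#'
#' One row per (cell, frame), columns `cell_id`, `channel`, `time_s`,
#' `raw`, `background`, `corrected`, `normalized`.
#'
#' @param traces named list of [FootprintTrace-class] objects (names are
#'   cell ids).
#' @param channel channel label recorded in the output.
#' @param path output CSV path, or `NULL` to return the data frame.
#' @return The tidy `data.frame` (invisibly when written to `path`).
#' @export
writeTraceTable <- function(traces, channel = "biosensor", path = NULL) {
  stopifnot(is.list(traces), !is.null(names(traces)))
  tab <- do.call(rbind, lapply(names(traces), function(id) {
    df <- as.data.frame(traces[[id]])
    cbind(cell_id = id, channel = channel, df)
  }))
  if (is.null(path)) return(tab)
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
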