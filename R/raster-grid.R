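#' Raster grid container
#'
#' A minimal single-band raster on a flat local grid in metres: a numeric
#' matrix (rows run north to south, columns west to east) plus the outer
#' corner of the upper-left pixel, the pixel size, and a nodata sentinel.
#' Pixel-is-area convention: the centre of pixel `[i, j]` sits at
#' `x0 + (j - 1/2) * pixel_size`, `y0 - (i - 1/2) * pixel_size`.
#'
#' @param values numeric matrix of cell values (`NA` allowed).
#' @param origin numeric length-2, `c(x0, y0)` of the upper-left corner (m).
#' @param pixel_size cell edge length in metres; must be positive.
#' @param nodata sentinel written to file for missing cells (default -9999).
#' @return an object of class `raster_grid`.
#' @examples
#' r <- raster_grid(matrix(1:12, 3, 4), pixel_size = 30)
#' dim(r$values)
#' @export
raster_grid <- function(values, origin = c(0, nrow(values) * pixel_size),
                        pixel_size = 30, nodata = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(values) && !is.logical(values))
    stop("raster values must be numeric", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must be non-empty", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar", call. = FALSE)
  structure(
    list(values = values, origin = as.numeric(origin),
         pixel_size = as.numeric(pixel_size), nodata = as.numeric(nodata)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "raster_grid: %d x %d cells, pixel %g m, origin (%g, %g)\n",
    nrow(x$values), ncol(x$values), x$pixel_size, x$origin[1], x$origin[2]))
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d NA\n", min(v), max(v),
                sum(!is.finite(x$values))))
  invisible(x)
}

#' Coordinates of pixel centres
#'
#' @param r a [raster_grid()].
#' @return list with vectors `x` (per column) and `y` (per row), metres.
#' @export
pixel_centers <- function(r) {
  stopifnot(inherits(r, "raster_grid"))
  list(
    x = r$origin[1] + (seq_len(ncol(r$values)) - 0.5) * r$pixel_size,
    y = r$origin[2] - (seq_len(nrow(r$values)) - 0.5) * r$pixel_size
  )
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange format (north-up, pixel-is-area,
#' `xllcorner`/`yllcorner` anchored at the lower-left outer corner).
#'
#' @param r a [raster_grid()].
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "raster_grid"))
  v <- r$values
  v[!is.finite(v)] <- r$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2] - nrow(v) * r$pixel_size),
    sprintf("cellsize %.10g", r$pixel_size),
    sprintf("NODATA_value %.10g", r$nodata)
  )
  body <- apply(v, 1L, function(row) paste(sprintf("%.6g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @return a [raster_grid()]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing ", paste(setdiff(need, names(hdr)),
         collapse = ", "), call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(
    m,
    origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
    pixel_size = hdr$cellsize, nodata = nodata
  )
}
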