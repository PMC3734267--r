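#' Gridded elevation and mask objects
#'
#' A `sivva_grid` is a light wrapper around a numeric (or logical) matrix on
#' a regular square grid. The convention throughout the package: row 1 is the
#' southernmost row, column 1 the westernmost; the centre of cell `[i, j]`
#' sits at `(xll + (j - 0.5) * cellsize, yll + (i - 0.5) * cellsize)`. The
#' ESRI ASCII reader flips its north-first rows into this order.
#'
#' @param values Matrix of cell values (`NA` allowed for nodata).
#' @param cellsize Positive cell edge length (same unit for x and y).
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @return A `sivva_grid` object.
#' @export
sivva_grid <- function(values, cellsize = 1, xll = 0, yll = 0) {
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0) {
    abort("`cellsize` must be a single positive number.")
  }
  structure(
    list(values = values, cellsize = cellsize, xll = xll, yll = yll),
    class = "sivva_grid"
  )
}

#' @exportS3Method base::print
print.sivva_grid <- function(x, ...) {
  cat(sprintf(
    "<sivva_grid> %d rows x %d cols, cellsize %g, origin (%g, %g), %d NA cell(s)\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
    sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.sivva_grid <- function(x) dim(x$values)

# x/y coordinates of all cell centres, as matrices conformable with values.
cell_centres <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  list(
    x = matrix(grid$xll + (seq_len(nc) - 0.5) * grid$cellsize, nr, nc, byrow = TRUE),
    y = matrix(grid$yll + (seq_len(nr) - 0.5) * grid$cellsize, nr, nc)
  )
}

check_registered <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      a$cellsize != b$cellsize || a$xll != b$xll || a$yll != b$yll) {
    abort("Grids are not co-registered (shape, cellsize or origin differ).")
  }
  invisible(TRUE)
}

#' Read and write ESRI ASCII grids
#'
#' Standard `.asc` layout: a header of `ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize` and optional `NODATA_value` lines, then `nrows`
#' whitespace-separated data rows from north to south. Rows are flipped on
#' read so that row 1 of the stored matrix is the southernmost row.
#'
#' @param path File path.
#' @param grid A `sivva_grid` to write.
#' @param nodata Value written in place of `NA` cells.
#' @return `read_ascii_grid()` returns a `sivva_grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) abort(paste0("Missing '", k, "' in ASCII grid header."))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort("ASCII grid data size does not match header dimensions.")
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE] # north-first file -> south-first matrix
  sivva_grid(m, cellsize = hdr$cellsize,
             xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "sivva_grid"))
  m <- grid$values
  m[is.na(m)] <- nodata
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
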