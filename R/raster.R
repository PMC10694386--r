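#' Categorical land-use raster
#'
#' A lightweight in-memory raster of integer land-cover codes on a regular
#' square grid. The grid is row-major with its origin at the top-left corner;
#' the centre of cell (row, col) is at
#' `x = origin[1] + (col - 0.5) * cell_size`,
#' `y = origin[2] - (row - 0.5) * cell_size`.
#'
#' @param codes Integer matrix of land-cover codes. `NA` marks nodata.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Numeric length-2: x of the left edge, y of the top edge, in
#'   metres.
#' @param nodata_code Integer written to files for nodata cells; internally
#'   nodata is `NA`.
#'
#' @return An object of class `lu_raster`.
#' @examples
#' r <- lu_raster(matrix(c(1L, 1L, 2L, 2L), 2, 2), cell_size = 30)
#' r
#' @export
lu_raster <- function(codes, cell_size, origin = c(0, 0), nodata_code = -9999L) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix", call. = FALSE)
  if (nrow(codes) < 1L || ncol(codes) < 1L) {
    stop("degenerate grid: raster must have at least one cell", call. = FALSE)
  }
  if (is.double(codes)) {
    if (any(codes != round(codes), na.rm = TRUE)) {
      stop("land-use codes must be integer-valued; got non-integer values",
           call. = FALSE)
    }
    storage.mode(codes) <- "integer"
  }
  if (!is.integer(codes)) stop("`codes` must be an integer matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number (metres)", call. = FALSE)
  }
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be numeric length 2", call. = FALSE)
  }
  codes[codes == nodata_code] <- NA_integer_
  structure(
    list(codes = codes, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata_code = as.integer(nodata_code)),
    class = "lu_raster"
  )
}

#' @export
print.lu_raster <- function(x, ...) {
  cc <- sort(unique(as.vector(x$codes)))
  cat(sprintf("<lu_raster> %d x %d cells, cell %g m, origin (%g, %g)\n",
              nrow(x$codes), ncol(x$codes), x$cell_size,
              x$origin[1], x$origin[2]))
  cat("  codes:", paste(cc, collapse = " "),
      if (anyNA(x$codes)) " (+ nodata)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.lu_raster <- function(x) dim(x$codes)

#' Cell area in square kilometres
#' @param x An `lu_raster`.
#' @return Scalar area of one cell (km^2).
#' @export
cell_area_km2 <- function(x) (x$cell_size / 1000)^2

#' Cell-centre coordinates
#'
#' @param x An `lu_raster`.
#' @return List with matrices `x` and `y` of cell-centre coordinates (metres).
#' @keywords internal
cell_centers <- function(x) {
  nr <- nrow(x$codes); nc <- ncol(x$codes); cs <- x$cell_size
  list(
    x = matrix(rep(x$origin[1] + (seq_len(nc) - 0.5) * cs, each = nr), nr, nc),
    y = matrix(rep(x$origin[2] - (seq_len(nr) - 0.5) * cs, times = nc), nr, nc)
  )
}

same_geometry <- function(a, b) {
  identical(dim(a$codes), dim(b$codes)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b)) {
    stop("raster geometry mismatch: grids must share dimensions, cell size and origin",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert a raster to a cell-level tibble
#'
#' One row per cell with row/col indices, cell-centre coordinates and the
#' land-cover code (nodata cells carry `NA`).
#'
#' @param x An `lu_raster` (or a value raster from the quality model).
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `code` (or `value`).
#' @method as_tibble lu_raster
#' @export
as_tibble.lu_raster <- function(x, ...) {
  ctr <- cell_centers(x)
  nr <- nrow(x$codes); nc <- ncol(x$codes)
  codes <- as.vector(x$codes)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = as.vector(ctr$x), y = as.vector(ctr$y),
    code = codes
  )
}

#' Continuous value raster (degradation / quality surfaces)
#'
#' Same geometry conventions as [lu_raster()], holding a numeric surface such
#' as the degradation index D or the quality index Q.
#'
#' @param values Numeric matrix; `NA` marks nodata.
#' @param cell_size,origin As in [lu_raster()].
#' @param what Short tag describing the surface (e.g. "degradation").
#' @return An object of class `value_raster`.
#' @export
value_raster <- function(values, cell_size, origin = c(0, 0), what = "value") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), what = what),
    class = "value_raster"
  )
}

#' @export
print.value_raster <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<value_raster: %s> %d x %d cells, cell %g m, range [%.4g, %.4g]\n",
              x$what, nrow(x$values), ncol(x$values), x$cell_size,
              rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.value_raster <- function(x) dim(x$values)

#' @rdname as_tibble.lu_raster
#' @method as_tibble value_raster
#' @export
as_tibble.value_raster <- function(x, ...) {
  geom <- lu_raster(matrix(0L, nrow(x$values), ncol(x$values)),
                    x$cell_size, x$origin)
  out <- as_tibble.lu_raster(geom)
  out$code <- NULL
  out$value <- as.vector(x$values)
  out
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------
# Plain-text format: 6 header lines (ncols, nrows, xllcorner, yllcorner,
# cellsize, nodata_value) followed by nrows lines of ncols values, first line
# the top row. No installed package reads this format, so it is parsed here.

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @param integer Require integer cell values (land-use codes). A file with
#'   fractional values is rejected when `TRUE`.
#' @return An [lu_raster()] (or [value_raster()] when `integer = FALSE`).
#' @export
read_ascii_grid <- function(path, integer = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("unknown format: missing ", paste(setdiff(need, names(hdr)), collapse = ", "),
         " header in ", path, call. = FALSE)
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("unreadable grid body: expected ", nr * nc, " values, got ",
         length(vals), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  origin <- c(xll, yll + nr * hdr$cellsize)
  if (integer) {
    if (any(m != round(m), na.rm = TRUE)) {
      stop("non-integer band: land-use raster must hold integer codes",
           call. = FALSE)
    }
    lu_raster(m, hdr$cellsize, origin, nodata_code = as.integer(nodata))
  } else {
    value_raster(m, hdr$cellsize, origin)
  }
}

#' Write an ESRI ASCII grid
#'
#' @param x An [lu_raster()] or [value_raster()].
#' @param path Output path.
#' @param digits Significant digits for continuous surfaces (fixed so reruns
#'   are byte-identical).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, digits = 10) {
  if (inherits(x, "lu_raster")) {
    m <- x$codes; nodata <- x$nodata_code
  } else if (inherits(x, "value_raster")) {
    m <- signif(x$values, digits); nodata <- -9999
  } else {
    stop("`x` must be an lu_raster or value_raster", call. = FALSE)
  }
  nr <- nrow(m); nc <- ncol(m); cs <- x$cell_size
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", nc), sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", x$origin[1]),
    sprintf("yllcorner %.10g", x$origin[2] - nr * cs),
    sprintf("cellsize %.10g", cs),
    sprintf("nodata_value %d", as.integer(nodata))
  )
  body <- apply(m, 1, function(row) {
    paste(format(row, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read or write a raster, dispatching on file extension
#'
#' Currently the ESRI ASCII grid (`.asc`/`.txt`) is the supported on-disk
#' format; both functions exist so pipeline code is format-agnostic.
#'
#' @param path File path.
#' @param integer Passed to [read_ascii_grid()].
#' @return [read_raster()]: an `lu_raster`; [write_raster()]: `path`.
#' @export
read_raster <- function(path, integer = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "txt", "grd")) return(read_ascii_grid(path, integer))
  stop("unknown raster format '.", ext, "': supported format is ESRI ASCII grid (.asc)",
       call. = FALSE)
}

#' @rdname read_raster
#' @param x Raster object to write.
#' @export
write_raster <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "txt", "grd")) return(write_ascii_grid(x, path))
  stop("unknown raster format '.", ext, "': supported format is ESRI ASCII grid (.asc)",
       call. = FALSE)
}

# ---- 2-D convolution via FFT ------------------------------------------------
# Zero-padded "same" convolution of a grid with a centred (2R+1)^2 kernel.
# Used by the degradation kernel engine and the landscape smoother.
conv2_same <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(k); kc <- ncol(k)
  pr <- stats::nextn(nr + kr - 1L, c(2, 3, 5))
  pc <- stats::nextn(nc + kc - 1L, c(2, 3, 5))
  X <- matrix(0, pr, pc); X[seq_len(nr), seq_len(nc)] <- x
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- k
  Z <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  ro <- (kr - 1L) %/% 2L; co <- (kc - 1L) %/% 2L
  Z[ro + seq_len(nr), co + seq_len(nc)]
}
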