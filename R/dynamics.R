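#' Cross-tabulated land-use transfer matrix
#'
#' Areas (km^2) moving from class i in the first epoch (rows) to class j in
#' the second (columns). Row sums equal first-epoch class areas, column sums
#' equal second-epoch class areas, and the grand total equals the analyzed
#' area; a cell must be valid (non-nodata) in both epochs to count.
#'
#' @param lu_a,lu_b [lu_raster()]s of identical geometry at the two epochs.
#' @param years Length of the period in years (> 0).
#' @param class_names Optional names for the class codes (named character
#'   vector keyed by code, or plain vector aligned with the sorted code
#'   union).
#' @return A `transfer_matrix`: the area matrix with attributes `codes`,
#'   `years`, `cell_area_km2`.
#' @examples
#' a <- lu_raster(matrix(c(1L, 1L, 2L, 2L), 2), cell_size = 1000)
#' b <- lu_raster(matrix(c(1L, 2L, 2L, 2L), 2), cell_size = 1000)
#' transfer_matrix(a, b, years = 10)
#' @export
transfer_matrix <- function(lu_a, lu_b, years = 1, class_names = NULL) {
  stopifnot(inherits(lu_a, "lu_raster"), inherits(lu_b, "lu_raster"))
  stop_if_geometry_differs(lu_a, lu_b)
  if (years <= 0) stop("`years` must be > 0", call. = FALSE)
  ok <- !is.na(lu_a$codes) & !is.na(lu_b$codes)
  codes <- sort(union(unique(lu_a$codes[ok]), unique(lu_b$codes[ok])))
  fa <- factor(lu_a$codes[ok], levels = codes)
  fb <- factor(lu_b$codes[ok], levels = codes)
  m <- table(fa, fb) * cell_area_km2(lu_a)
  m <- unclass(m)
  dn <- as.character(codes)
  if (!is.null(class_names)) {
    dn <- if (!is.null(names(class_names))) {
      unname(class_names[as.character(codes)])
    } else as.character(class_names)
  }
  dimnames(m) <- list(from = dn, to = dn)
  new_transfer_matrix(m, codes, years, cell_area_km2(lu_a))
}

new_transfer_matrix <- function(m, codes, years, cell_area = NA_real_) {
  structure(m, codes = as.integer(codes), years = as.numeric(years),
            cell_area_km2 = cell_area, class = "transfer_matrix")
}

#' Build a transfer matrix from pre-tabulated areas
#'
#' @param m Square numeric matrix of areas (km^2), rows = first epoch.
#' @param years Period length in years.
#' @param codes Optional integer codes; defaults to `1:n`.
#' @return A `transfer_matrix`.
#' @export
as_transfer_matrix <- function(m, years = 1, codes = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("`m` must be square", call. = FALSE)
  if (any(m < 0)) stop("transfer areas must be >= 0", call. = FALSE)
  if (is.null(codes)) codes <- seq_len(nrow(m))
  new_transfer_matrix(m, codes, years)
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> %d classes over %g years, total %.4f km^2\n",
              nrow(x), attr(x, "years"), sum(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Read / write a transfer matrix as CSV
#'
#' The CSV mirrors the printed-table layout: class names on rows and columns,
#' with an optional trailing "Total" row and column which is validated
#' against the cell sums (to `total_tol`, loose enough for tables printed at
#' 0.1 km^2 precision) and then dropped.
#'
#' @param path CSV path.
#' @param years Period length in years.
#' @param total_tol Largest tolerated absolute difference between a printed
#'   Total and the recomputed sum (km^2).
#' @return A `transfer_matrix`.
#' @export
read_transfer_csv <- function(path, years = 1, total_tol = 0.5) {
  df <- utils::read.csv(path, check.names = FALSE)
  rn <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  is_total_row <- grepl("^total", tolower(rn))
  is_total_col <- grepl("^total", tolower(colnames(m)))
  if (any(is_total_row)) {
    tot <- m[is_total_row, !is_total_col, drop = TRUE]
    body <- m[!is_total_row, !is_total_col, drop = FALSE]
    bad <- abs(colSums(body) - tot) > total_tol
    if (any(bad)) {
      stop("printed column Total disagrees with cell sums for: ",
           paste(colnames(body)[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (any(is_total_col)) {
    tot <- m[!is_total_row, is_total_col, drop = TRUE]
    body <- m[!is_total_row, !is_total_col, drop = FALSE]
    bad <- abs(rowSums(body) - tot) > total_tol
    if (any(bad)) {
      stop("printed row Total disagrees with cell sums for: ",
           paste(rownames(body)[bad], collapse = ", "), call. = FALSE)
    }
  }
  m <- m[!is_total_row, !is_total_col, drop = FALSE]
  if (nrow(m) != ncol(m)) stop("transfer CSV is not square", call. = FALSE)
  dimnames(m) <- list(from = rownames(m), to = colnames(m))
  new_transfer_matrix(m, seq_len(nrow(m)), years)
}

#' @rdname read_transfer_csv
#' @param x A `transfer_matrix`.
#' @param digits Decimal places written (4, lossless for km^2-scale tables).
#' @export
write_transfer_csv <- function(x, path, digits = 4) {
  m <- round(unclass(x), digits)
  df <- data.frame(class = rownames(m), m, Total = rowSums(m),
                   check.names = FALSE)
  df <- rbind(df, c(class = "Total",
                    as.list(c(colSums(m), Total = sum(m)))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Single land-use dynamic degree
#'
#' Annualized percentage rate of change of one class's area:
#' `K = (U_b - U_a) / U_a / T * 100` (% per year). Undefined (NA) when the
#' initial area is zero.
#'
#' @param u_a,u_b Class areas at the start and end of the period (same
#'   units). Vectorized.
#' @param years Period length in years (> 0).
#' @return Percent per year; `NA` where `u_a == 0`.
#' @examples
#' single_dynamic_degree(100, 120, 20)  # 1 %/yr
#' @export
single_dynamic_degree <- function(u_a, u_b, years) {
  if (years <= 0) stop("`years` must be > 0", call. = FALSE)
  if (any(u_a < 0 | u_b < 0, na.rm = TRUE)) {
    stop("areas must be >= 0", call. = FALSE)
  }
  out <- (u_b - u_a) / u_a / years * 100
  out[u_a == 0] <- NA_real_
  out
}

#' Integrated land-use dynamic degree
#'
#' Annualized percentage rate of overall land-use change:
#' `LC = sum_i(outflow_i) / (2 * sum_i(area_i)) / T * 100`, where
#' `outflow_i` is the off-diagonal sum of row i (area leaving class i) and
#' `area_i` the initial class area.
#'
#' @param m A `transfer_matrix`.
#' @return Percent per year (>= 0).
#' @export
integrated_dynamic_degree <- function(m) {
  stopifnot(inherits(m, "transfer_matrix"))
  if (nrow(m) == 0 || sum(m) == 0) stop("empty transfer matrix", call. = FALSE)
  mm <- unclass(m)
  outflow <- rowSums(mm) - diag(mm)
  sum(outflow) / (2 * sum(mm)) / attr(m, "years") * 100
}

#' Transition shares and per-class change report
#'
#' @param m A `transfer_matrix`.
#' @return A list of class `dynamics_report`:
#'   * `shares`: tibble of every ordered (from, to) pair with area and its
#'     percentage share of the from-class row total (`NA`, flagged by
#'     `undefined`, for empty rows);
#'   * `classes`: per-class tibble with initial/final areas, off-diagonal
#'     outflow and its share, the single dynamic degree in %/yr (`k_pct`)
#'     and as a fraction (`k_frac`);
#'   * `lc_pct` / `lc_frac`: the integrated dynamic degree.
#' @export
transition_shares <- function(m) {
  stopifnot(inherits(m, "transfer_matrix"))
  mm <- unclass(m)
  rt <- rowSums(mm)
  labs <- rownames(mm) %||% as.character(seq_len(nrow(mm)))
  shares <- tibble::tibble(
    from = rep(labs, times = ncol(mm)),
    to = rep(colnames(mm) %||% labs, each = nrow(mm)),
    area_km2 = as.vector(mm),
    row_total_km2 = rep(unname(rt), times = ncol(mm))
  ) |>
    dplyr::mutate(
      share_pct = ifelse(.data$row_total_km2 > 0,
                         100 * .data$area_km2 / .data$row_total_km2, NA_real_),
      undefined = .data$row_total_km2 == 0
    )
  years <- attr(m, "years")
  rt <- unname(rt)
  ct <- unname(colSums(mm))
  outflow <- rt - diag(mm)
  k <- single_dynamic_degree(rt, ct, years)
  classes <- tibble::tibble(
    class = labs,
    area_a_km2 = rt, area_b_km2 = ct,
    outflow_km2 = outflow,
    outflow_share_pct = ifelse(rt > 0, 100 * outflow / rt, NA_real_),
    k_pct = k, k_frac = k / 100
  )
  lc <- integrated_dynamic_degree(m)
  structure(list(shares = shares, classes = classes,
                 lc_pct = lc, lc_frac = lc / 100, years = years),
            class = "dynamics_report")
}

#' @export
print.dynamics_report <- function(x, ...) {
  cat(sprintf("<dynamics_report> %g years, integrated dynamic degree %.4f %%/yr\n",
              x$years, x$lc_pct))
  print(x$classes)
  invisible(x)
}

#' Look up one transition's share of its origin class
#'
#' Convenience accessor for reading a single percentage out of
#' [transition_shares()].
#'
#' @param m A `transfer_matrix`.
#' @param from,to Class labels (row/column names).
#' @return Percentage of the `from` row total moving to `to`.
#' @export
share_of <- function(m, from, to) {
  s <- transition_shares(m)$shares
  hit <- s$from == from & s$to == to
  if (!any(hit)) stop("no such transition: ", from, " -> ", to, call. = FALSE)
  unname(s$share_pct[hit])
}
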