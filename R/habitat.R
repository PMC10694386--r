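#' Threat (stressor) parameter table
#'
#' Validates a tibble of threat sources: land-cover classes that exert a
#' distance-decaying impact on surrounding habitat. Each threat has a maximum
#' impact distance `max_dist_km` (beyond which its impact is zero), a relative
#' weight in (0, 1], and a decay type.
#'
#' @param threats Data frame with columns `threat` (name), `code` (land-cover
#'   code acting as source), `max_dist_km` (> 0), `weight` ((0, 1]), `decay`
#'   ("linear" or "exponential").
#' @return The validated tibble, classed `threat_table`.
#' @seealso [poyang_threats()] for the packaged parameterization.
#' @export
threat_table <- function(threats) {
  threats <- tibble::as_tibble(threats)
  need <- c("threat", "code", "max_dist_km", "weight", "decay")
  miss <- setdiff(need, names(threats))
  if (length(miss)) {
    stop("threat table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(threats$max_dist_km <= 0)) {
    stop("`max_dist_km` must be > 0", call. = FALSE)
  }
  if (any(threats$weight <= 0 | threats$weight > 1)) {
    stop("threat `weight` must lie in (0, 1]", call. = FALSE)
  }
  bad <- setdiff(unique(threats$decay), c("linear", "exponential"))
  if (length(bad)) {
    stop("unknown decay type: ", paste(bad, collapse = ", "),
         "; use \"linear\" or \"exponential\"", call. = FALSE)
  }
  if (anyDuplicated(threats$threat)) stop("duplicate threat names", call. = FALSE)
  class(threats) <- c("threat_table", class(threats))
  threats
}

#' Habitat suitability and sensitivity table
#'
#' Validates the per-class habitat suitability H (column `habitat`) and the
#' per-(class, threat) sensitivity S, one column per threat name, all in
#' [0, 1]. Every land-cover code in the legend must have a row, and every
#' threat must have a sensitivity column.
#'
#' @param sens Data frame with columns `lucode`, `name`, `habitat`, and one
#'   numeric column per threat.
#' @param threats Optional [threat_table()] to validate the threat columns
#'   against.
#' @return The validated tibble, classed `sensitivity_table`.
#' @seealso [poyang_sensitivity()] for the packaged parameterization.
#' @export
sensitivity_table <- function(sens, threats = NULL) {
  sens <- tibble::as_tibble(sens)
  need <- c("lucode", "name", "habitat")
  miss <- setdiff(need, names(sens))
  if (length(miss)) {
    stop("sensitivity table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(sens$habitat < 0 | sens$habitat > 1)) {
    stop("habitat suitability must lie in [0, 1]", call. = FALSE)
  }
  scols <- setdiff(names(sens), need)
  for (sc in scols) {
    if (any(sens[[sc]] < 0 | sens[[sc]] > 1)) {
      stop("sensitivity to '", sc, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (anyDuplicated(sens$lucode)) stop("duplicate `lucode` rows", call. = FALSE)
  if (!is.null(threats)) {
    missing_cols <- setdiff(threats$threat, scols)
    if (length(missing_cols)) {
      stop("sensitivity table lacks a column for threat: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    unknown <- setdiff(threats$code, sens$lucode)
    if (length(unknown)) {
      stop("threat source code not in legend: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  class(sens) <- c("sensitivity_table", class(sens))
  sens
}

#' Distance-decay factor of a threat
#'
#' Impact of a threat source on a cell at distance `d`, relative to its
#' impact at distance zero. Linear decay falls to 0 at `d_max`; exponential
#' decay is `exp(-2.99 d / d_max)` (about 0.05 at `d_max`). Both are clamped
#' to 0 beyond `d_max`.
#'
#' @param d Distance(s), same units as `d_max` (>= 0).
#' @param d_max Maximum impact distance (> 0).
#' @param decay `"linear"` or `"exponential"`.
#' @return Decay factor(s) in [0, 1].
#' @examples
#' decay_factor(c(0, 3, 6, 7), 6, "linear")
#' decay_factor(6, 6, "exponential")  # exp(-2.99)
#' @export
decay_factor <- function(d, d_max, decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  if (any(d < 0)) stop("distance must be >= 0", call. = FALSE)
  if (d_max <= 0) stop("`d_max` must be > 0", call. = FALSE)
  out <- if (decay == "linear") {
    pmax(0, 1 - d / d_max)
  } else {
    exp(-2.99 * d / d_max)
  }
  out[d > d_max] <- 0
  out
}

#' Extract binary threat-presence layers
#'
#' @param lu An [lu_raster()].
#' @param threats A [threat_table()].
#' @return A named list (one element per threat) of lists with `presence`
#'   (0/1 matrix) and `n_sources` (count of source cells), classed
#'   `threat_layers`.
#' @export
extract_threat_layers <- function(lu, threats) {
  stopifnot(inherits(lu, "lu_raster"))
  threats <- threat_table(threats)
  layers <- lapply(seq_len(nrow(threats)), function(i) {
    pres <- (!is.na(lu$codes)) & lu$codes == threats$code[i]
    storage.mode(pres) <- "double"
    list(presence = pres, n_sources = sum(pres))
  })
  names(layers) <- threats$threat
  structure(layers, class = "threat_layers")
}

# Decay kernel for one threat on this grid: (2R+1)^2 matrix of decay factors
# at centre-to-centre distances, truncated at d_max.
decay_kernel <- function(cell_size, max_dist_km, decay) {
  dmax_m <- max_dist_km * 1000
  R <- floor(dmax_m / cell_size)
  off <- -R:R
  dmat <- cell_size * sqrt(outer(off^2, off^2, "+"))
  k <- matrix(decay_factor(as.vector(dmat), dmax_m, decay),
              nrow = length(off))
  k
}

#' Compute the habitat-degradation surface
#'
#' Accumulates, for every cell x of land-cover class j, the weighted,
#' distance-decayed impact of all threat-source cells:
#' `D_x = sum_r sum_y (w_r / sum(w)) * r_y * i_r(d_xy) * beta_x * S_jr`,
#' with `i_r` the [decay_factor()] of threat r, `d_xy` the Euclidean
#' centre-to-centre distance, `beta_x` the accessibility (1 when no
#' accessibility raster is given) and `S_jr` the sensitivity of class j to
#' threat r. The sum runs over source cells as such; setting
#' `per_source_mean = TRUE` divides each threat's contribution by its source
#' count instead.
#'
#' The default engine evaluates the per-threat sums as a single FFT
#' convolution of the presence grid with a truncated decay kernel, which is
#' exact to floating-point accuracy.
#'
#' @param lu An [lu_raster()].
#' @param threats A [threat_table()].
#' @param sens A [sensitivity_table()] covering every code in `lu`.
#' @param access Optional [value_raster()] of accessibility beta in [0, 1],
#'   same geometry as `lu`; default 1 everywhere.
#' @param layers Optional precomputed [extract_threat_layers()] result.
#' @param per_source_mean Average (rather than sum) over each threat's source
#'   cells. Off by default.
#' @return A [value_raster()] of D >= 0 (`NA` at nodata cells), with the
#'   land-use raster attached as attribute `"lu"`.
#' @export
compute_degradation <- function(lu, threats, sens, access = NULL,
                                layers = NULL, per_source_mean = FALSE) {
  stopifnot(inherits(lu, "lu_raster"))
  threats <- threat_table(threats)
  sens <- sensitivity_table(sens, threats)
  if (is.null(layers)) layers <- extract_threat_layers(lu, threats)
  if (!is.null(access)) {
    if (!identical(dim(access$values), dim(lu$codes))) {
      stop("accessibility raster geometry mismatch", call. = FALSE)
    }
    if (any(access$values < 0 | access$values > 1, na.rm = TRUE)) {
      stop("accessibility values must lie in [0, 1]", call. = FALSE)
    }
  }
  present <- unique(as.vector(lu$codes))
  present <- present[!is.na(present)]
  nolegend <- setdiff(present, sens$lucode)
  if (length(nolegend)) {
    stop("missing sensitivity row for land-use code: ",
         paste(nolegend, collapse = ", "), call. = FALSE)
  }
  row_of <- match(lu$codes, sens$lucode)   # NA at nodata
  wnorm <- threats$weight / sum(threats$weight)
  D <- matrix(0, nrow(lu$codes), ncol(lu$codes))
  for (i in seq_len(nrow(threats))) {
    lay <- layers[[threats$threat[i]]]
    if (lay$n_sources == 0) next
    k <- decay_kernel(lu$cell_size, threats$max_dist_km[i], threats$decay[i])
    impact <- conv2_same(lay$presence, k)
    impact[impact < 0] <- 0          # FFT round-off on empty neighbourhoods
    if (per_source_mean) impact <- impact / lay$n_sources
    S <- matrix(sens[[threats$threat[i]]][row_of],
                nrow(lu$codes), ncol(lu$codes))
    S[is.na(S)] <- 0
    D <- D + wnorm[i] * impact * S
  }
  if (!is.null(access)) D <- D * access$values
  D[is.na(lu$codes)] <- NA_real_
  out <- value_raster(D, lu$cell_size, lu$origin, what = "degradation")
  attr(out, "lu") <- lu
  out
}

#' Transform degradation into habitat quality
#'
#' `Q_x = H_j * (1 - D_x^z / (D_x^z + k^z))`: quality equals the class
#' suitability ceiling H when degradation is 0 and falls to H/2 at the
#' half-saturation point `D = k`.
#'
#' @param D A degradation [value_raster()] from [compute_degradation()].
#' @param lu The matching [lu_raster()] (defaults to the one attached to `D`).
#' @param sens A [sensitivity_table()] providing H per class.
#' @param k Half-saturation constant (> 0), or `"auto"` for half the maximum
#'   observed degradation (falling back to 0.5 on a degradation-free map).
#' @param z Shape exponent of the half-saturation transform (> 0).
#' @return A [value_raster()] of Q in [0, 1], with `lu` and the resolved `k`
#'   attached as attributes.
#' @export
compute_quality <- function(D, lu = attr(D, "lu"), sens, k = 0.5, z = 2.5) {
  stopifnot(inherits(D, "value_raster"), inherits(lu, "lu_raster"))
  sens <- sensitivity_table(sens)
  if (!identical(dim(D$values), dim(lu$codes))) {
    stop("degradation and land-use geometry mismatch", call. = FALSE)
  }
  if (identical(k, "auto")) {
    dmax <- suppressWarnings(max(D$values, na.rm = TRUE))
    k <- if (is.finite(dmax) && dmax > 0) dmax / 2 else 0.5
  }
  if (!is.numeric(k) || k <= 0) stop("`k` must be > 0 or \"auto\"", call. = FALSE)
  if (!is.numeric(z) || z <= 0) stop("`z` must be > 0", call. = FALSE)
  H <- matrix(sens$habitat[match(lu$codes, sens$lucode)],
              nrow(lu$codes), ncol(lu$codes))
  Dz <- D$values^z
  Q <- H * (1 - Dz / (Dz + k^z))
  Q[is.na(lu$codes)] <- NA_real_
  out <- value_raster(Q, lu$cell_size, lu$origin, what = "quality")
  attr(out, "lu") <- lu
  attr(out, "k") <- k
  out
}

#' Grading scheme for a continuous surface
#'
#' Ordered, contiguous intervals covering a range. Intervals are
#' left-closed/right-open; the topmost interval is closed at its upper bound.
#'
#' @param labels Character grade labels, lowest interval first.
#' @param breaks Numeric vector of length `length(labels) + 1`, strictly
#'   increasing.
#' @return A `grade_scheme` tibble with columns `label`, `lower`, `upper`.
#' @examples
#' quality_grades()
#' grade_scheme(c("lo", "hi"), c(0, 0.5, 1))
#' @export
grade_scheme <- function(labels, breaks) {
  if (length(breaks) != length(labels) + 1L) {
    stop("`breaks` must be one longer than `labels`", call. = FALSE)
  }
  if (any(diff(breaks) <= 0)) stop("`breaks` must be strictly increasing", call. = FALSE)
  structure(
    tibble::tibble(label = as.character(labels),
                   lower = breaks[-length(breaks)], upper = breaks[-1]),
    class = c("grade_scheme", class(tibble::tibble()))
  )
}

#' @rdname grade_scheme
#' @export
quality_grades <- function() {
  grade_scheme(c("awful", "poor", "fair", "good", "excellent"),
               c(0, 0.1, 0.5, 0.7, 0.8, 1))
}

#' @rdname grade_scheme
#' @param upper Top of the degradation range covered by the scheme.
#' @export
degradation_grades <- function(upper = 0.2) {
  grade_scheme(c("nil", "low", "moderate", "high", "severe"),
               c(0, 0.01, 0.05, 0.10, 0.15, upper))
}

#' @rdname grade_scheme
#' @param n Number of equal-width classes.
#' @param range Range to cover.
#' @export
equal_interval_grades <- function(n = 10, range = c(0, 1)) {
  grade_scheme(sprintf("c%02d", seq_len(n)),
               seq(range[1], range[2], length.out = n + 1))
}

#' Classify a continuous raster into grades
#'
#' @param values A [value_raster()] (quality or degradation).
#' @param scheme A [grade_scheme()] covering the observed range.
#' @return A `graded_raster`: list with `grades` (factor matrix stored as an
#'   integer matrix + levels), `areas` (tibble of per-grade cell counts, area
#'   in km^2 and percentage share summing to 100) and the input geometry.
#' @export
classify_raster <- function(values, scheme) {
  stopifnot(inherits(values, "value_raster"), inherits(scheme, "grade_scheme"))
  v <- values$values
  ok <- !is.na(v)
  lo <- scheme$lower[1]; hi <- scheme$upper[nrow(scheme)]
  if (any(v[ok] < lo) || any(v[ok] > hi)) {
    stop(sprintf("values outside scheme range [%g, %g]: observed [%g, %g]",
                 lo, hi, min(v[ok]), max(v[ok])), call. = FALSE)
  }
  breaks <- c(scheme$lower, hi)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  g <- matrix(NA_integer_, nrow(v), ncol(v))
  g[ok] <- idx[ok]
  area1 <- (values$cell_size / 1000)^2
  counts <- tabulate(g[ok], nbins = nrow(scheme))
  areas <- tibble::tibble(
    label = scheme$label,
    cells = counts,
    area_km2 = counts * area1,
    share_pct = if (sum(counts) > 0) 100 * counts / sum(counts) else 0 * counts
  )
  structure(
    list(grades = g, levels = scheme$label, areas = areas,
         cell_size = values$cell_size, origin = values$origin,
         what = values$what),
    class = "graded_raster"
  )
}

#' @export
print.graded_raster <- function(x, ...) {
  cat(sprintf("<graded_raster: %s> %d x %d cells, %d grades\n",
              x$what, nrow(x$grades), ncol(x$grades), length(x$levels)))
  print(x$areas)
  invisible(x)
}

#' Cross-tabulate grade shares within land-use classes
#'
#' @param grades A `graded_raster` from [classify_raster()].
#' @param lu The matching [lu_raster()].
#' @return A tibble with one row per (land-use code, grade): cell count, area
#'   (km^2) and the grade's percentage share of that land-use class (each
#'   class's shares sum to 100).
#' @export
summarize_by_landuse <- function(grades, lu) {
  stopifnot(inherits(grades, "graded_raster"), inherits(lu, "lu_raster"))
  if (!identical(dim(grades$grades), dim(lu$codes))) {
    stop("grade grid and land-use geometry mismatch", call. = FALSE)
  }
  ok <- !is.na(grades$grades) & !is.na(lu$codes)
  area1 <- (lu$cell_size / 1000)^2
  tab <- tibble::tibble(
    lucode = as.vector(lu$codes[ok]),
    grade = factor(grades$levels[grades$grades[ok]], levels = grades$levels)
  ) |>
    dplyr::count(.data$lucode, .data$grade, .drop = FALSE, name = "cells") |>
    dplyr::group_by(.data$lucode) |>
    dplyr::mutate(area_km2 = .data$cells * area1,
                  share_pct = 100 * .data$cells / sum(.data$cells)) |>
    dplyr::ungroup()
  tab
}
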