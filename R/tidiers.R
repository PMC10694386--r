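#' Tidy a transfer matrix into a long tibble
#'
#' @param x A `transfer_matrix`.
#' @param ... Unused.
#' @return One row per (from, to) pair with `area_km2` and the row-share
#'   percentage.
#' @method tidy transfer_matrix
#' @export
tidy.transfer_matrix <- function(x, ...) {
  transition_shares(x)$shares
}

#' @rdname tidy.transfer_matrix
#' @method glance transfer_matrix
#' @export
glance.transfer_matrix <- function(x, ...) {
  mm <- unclass(x)
  tibble::tibble(
    n_classes = nrow(mm),
    total_km2 = sum(mm),
    changed_km2 = sum(mm) - sum(diag(mm)),
    years = attr(x, "years"),
    lc_pct = integrated_dynamic_degree(x)
  )
}

#' Tidy a factor-detector result
#'
#' @param x A `factor_q`, `interaction_q`, `eco_f` or `detector_report`.
#' @param ... Unused.
#' @return A one-row tibble (or, for a report, the per-factor table).
#' @method tidy factor_q
#' @export
tidy.factor_q <- function(x, ...) {
  tibble::tibble(q = x$q, p_value = x$p_value, L = x$L, n = x$n,
                 method = x$method)
}

#' @rdname tidy.factor_q
#' @method tidy interaction_q
#' @export
tidy.interaction_q <- function(x, ...) {
  tibble::tibble(q1 = x$q1, q2 = x$q2, q12 = x$q12, category = x$category)
}

#' @rdname tidy.factor_q
#' @method tidy eco_f
#' @export
tidy.eco_f <- function(x, ...) {
  tibble::tibble(F = x$F, n_x1 = x$n_x1, n_x2 = x$n_x2,
                 ssw_x1 = x$ssw_x1, ssw_x2 = x$ssw_x2,
                 significant = x$significant)
}

#' @rdname tidy.factor_q
#' @method tidy detector_report
#' @export
tidy.detector_report <- function(x, ...) x$factor

#' @rdname tidy.factor_q
#' @method glance detector_report
#' @export
glance.detector_report <- function(x, ...) {
  tibble::tibble(
    n_factors = nrow(x$factor),
    best_factor = x$factor$factor[which.max(x$factor$q)],
    best_q = max(x$factor$q),
    best_pair_q12 = if (nrow(x$interaction)) max(x$interaction$q12) else NA_real_,
    n_significant = sum(x$factor$p_value < 0.05, na.rm = TRUE)
  )
}

#' Tidy a graded raster into its area table
#'
#' @param x A `graded_raster`.
#' @param ... Unused.
#' @return The per-grade area tibble.
#' @method tidy graded_raster
#' @export
tidy.graded_raster <- function(x, ...) x$areas
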