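#' Discretize a continuous covariate into ordered strata
#'
#' @param values Numeric vector.
#' @param method `"quantile"` (equal-frequency), `"equal-interval"`, or
#'   `"natural-breaks"` (1-D k-means on the values, the Jenks criterion).
#' @param n_bins Number of bins (>= 2); empty bins are dropped from the
#'   returned factor's levels.
#' @param seed Seed for the k-means initialisation of natural breaks.
#' @return An ordered factor of stratum labels, one per value.
#' @export
discretize_factor <- function(values,
                              method = c("quantile", "equal-interval",
                                         "natural-breaks"),
                              n_bins = 5, seed = 1L) {
  method <- match.arg(method)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  if (anyNA(values)) stop("missing values in factor to discretize", call. = FALSE)
  rng <- range(values)
  if (method != "equal-interval" && rng[1] == rng[2]) {
    stop("constant input cannot be discretized with method '", method, "'",
         call. = FALSE)
  }
  breaks <- switch(
    method,
    "equal-interval" = seq(rng[1], rng[2], length.out = n_bins + 1),
    "quantile" = unique(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
                                        names = FALSE, type = 7)),
    "natural-breaks" = {
      centers <- stats::quantile(values, probs = seq(0.5, n_bins - 0.5) / n_bins,
                                 names = FALSE)
      centers <- unique(centers)
      km <- withr::with_seed(seed, stats::kmeans(values, centers = centers,
                                                 iter.max = 100))
      mids <- sort(km$centers[, 1])
      c(rng[1], (mids[-1] + mids[-length(mids)]) / 2, rng[2])
    }
  )
  breaks <- unique(breaks)
  breaks[1] <- rng[1]; breaks[length(breaks)] <- rng[2]
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  f <- factor(idx, levels = sort(unique(idx)),
              labels = paste0("b", seq_along(sort(unique(idx)))))
  ordered(f)
}

# Core variance decomposition: population (divide-by-N) variances, so
# SSW = sum over strata of N_h * sigma_h^2 equals the within sum of squared
# deviations exactly.
sum_of_squares <- function(y, strata) {
  strata <- droplevels(factor(strata))
  n <- length(y)
  sums <- rowsum(y, strata)
  sq <- rowsum(y^2, strata)
  nh <- as.vector(table(strata))
  ssw <- sum(sq) - sum(sums^2 / nh)
  sst <- sum(y^2) - sum(y)^2 / n
  list(ssw = ssw, sst = sst, n = n, L = nlevels(strata),
       nh = nh, means = as.vector(sums) / nh)
}

#' Factor-detector q statistic
#'
#' `q = 1 - SSW/SST`: the fraction of the response's variance explained by a
#' categorical stratification (spatial stratified heterogeneity). q is 0 when
#' strata explain nothing and 1 when the response is constant within every
#' stratum.
#'
#' @param y Numeric response vector (length >= 2, non-constant).
#' @param strata Stratum labels aligned with `y`; empty strata are dropped,
#'   singleton strata contribute 0 to SSW.
#' @param significance `"permutation"` (default) or `"noncentral-F"`; `"none"`
#'   skips the p-value.
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutation draw.
#' @return A `factor_q` list: `q`, `p_value`, `L` (stratum count), `n`,
#'   `method`, `ssw`, `sst`.
#' @examples
#' factor_q(c(1, 1, 2, 2), c("a", "a", "b", "b"), significance = "none")$q
#' @export
factor_q <- function(y, strata,
                     significance = c("permutation", "noncentral-F", "none"),
                     n_perm = 999, seed = 1L) {
  significance <- match.arg(significance)
  if (length(y) != length(strata)) stop("`y` and `strata` lengths differ", call. = FALSE)
  if (anyNA(y) || anyNA(strata)) stop("missing values in `y` or `strata`", call. = FALSE)
  if (length(y) < 2) stop("need at least 2 observations", call. = FALSE)
  ss <- sum_of_squares(y, strata)
  if (ss$sst <= 0) {
    stop("constant response: q is undefined when SST = 0", call. = FALSE)
  }
  if (ss$L < 2) stop("need at least 2 nonempty strata", call. = FALSE)
  q <- 1 - ss$ssw / ss$sst
  q <- min(max(q, 0), 1)
  p <- switch(significance,
    "none" = NA_real_,
    "permutation" = q_significance(y, strata, q, method = "permutation",
                                   n_perm = n_perm, seed = seed),
    "noncentral-F" = q_significance(y, strata, q, method = "noncentral-F")
  )
  structure(list(q = q, p_value = p, L = ss$L, n = ss$n,
                 method = significance, ssw = ss$ssw, sst = ss$sst),
            class = "factor_q")
}

#' @export
print.factor_q <- function(x, ...) {
  cat(sprintf("<factor_q> q = %.4f (L = %d, n = %d), p = %s [%s]\n",
              x$q, x$L, x$n,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value),
              x$method))
  invisible(x)
}

#' Significance of a q statistic
#'
#' Permutation: the stratum labels are permuted `n_perm` times and the
#' p-value is the add-one-smoothed fraction of permuted q values at least as
#' large as the observed one (so a perfect q = 1 reports
#' `p = 1/(n_perm + 1)`, never 0). Noncentral-F: the transform
#' `F = (N - L)/(L - 1) * q/(1 - q)` is referred to a noncentral F
#' distribution with `(L - 1, N - L)` degrees of freedom and the
#' geodetector noncentrality
#' `lambda = (sum_h nh*mh^2 - (sum_h sqrt(nh)*mh)^2 / N) / sigma^2`.
#'
#' @inheritParams factor_q
#' @param q The observed q (as from [factor_q()]).
#' @param method `"permutation"` or `"noncentral-F"`.
#' @return A p-value in (0, 1].
#' @export
q_significance <- function(y, strata, q,
                           method = c("permutation", "noncentral-F"),
                           n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  ss <- sum_of_squares(y, strata)
  if (method == "noncentral-F") {
    N <- ss$n; L <- ss$L
    if (q >= 1) return(.Machine$double.xmin)
    Fv <- (N - L) / (L - 1) * q / (1 - q)
    sigma2 <- ss$sst / N
    lambda <- (sum(ss$nh * ss$means^2) -
                 sum(sqrt(ss$nh) * ss$means)^2 / N) / sigma2
    return(stats::pf(Fv, L - 1, N - L, ncp = lambda, lower.tail = FALSE))
  }
  # permutation: permuting labels is equivalent to permuting y; q >= q_obs
  # iff sum_h S_h^2 / n_h >= the observed value, with SST fixed
  if (q >= 1 - 1e-12) return(1 / (n_perm + 1))
  strata_f <- droplevels(factor(strata))
  nh <- as.vector(table(strata_f))
  obs_between <- sum(rowsum(y, strata_f)^2 / nh)
  withr::with_seed(seed, {
    perms <- replicate(n_perm, sample(y))
  })
  sums <- rowsum(perms, strata_f)
  between <- colSums(sums^2 / nh)
  (1 + sum(between >= obs_between - 1e-12)) / (n_perm + 1)
}

#' Interaction detector
#'
#' Computes q for each factor and for their overlay (the Cartesian product of
#' stratum labels), and classifies how the pair acts together relative to the
#' single factors. Because overlay refines both stratifications, exact
#' computation always gives `q12 >= max(q1, q2)`; the weaken categories are
#' retained in the taxonomy for completeness and signal numerical error if
#' ever produced.
#'
#' @param y Numeric response.
#' @param strata1,strata2 Stratum labels for the two factors.
#' @return An `interaction_q` list: `q1`, `q2`, `q12`, `category` (one of
#'   nonlinear-weaken, uni-weaken, bi-enhance, independent,
#'   nonlinear-enhance).
#' @examples
#' # XOR response: neither factor explains anything alone, the pair fully
#' f1 <- c("a", "a", "b", "b"); f2 <- c("a", "b", "a", "b")
#' interaction_detect(c(0, 1, 1, 0), f1, f2)
#' @export
interaction_detect <- function(y, strata1, strata2) {
  q1 <- factor_q(y, strata1, significance = "none")$q
  q2 <- factor_q(y, strata2, significance = "none")$q
  overlay <- interaction(factor(strata1), factor(strata2), drop = TRUE)
  if (nlevels(overlay) < 2) {
    stop("overlay stratification has fewer than 2 nonempty strata", call. = FALSE)
  }
  q12 <- factor_q(y, overlay, significance = "none")$q
  lo <- min(q1, q2); hi <- max(q1, q2); s <- q1 + q2
  category <- if (abs(q12 - s) <= 1e-9) {
    "independent"
  } else if (q12 > s) {
    "nonlinear-enhance"
  } else if (q12 >= hi) {
    "bi-enhance"
  } else if (q12 >= lo) {
    "uni-weaken"
  } else {
    "nonlinear-weaken"
  }
  structure(list(q1 = q1, q2 = q2, q12 = q12, category = category),
            class = "interaction_q")
}

#' @export
print.interaction_q <- function(x, ...) {
  cat(sprintf("<interaction_q> q1 = %.4f, q2 = %.4f, q12 = %.4f (%s)\n",
              x$q1, x$q2, x$q12, x$category))
  invisible(x)
}

#' Ecological detector
#'
#' Tests whether two stratifications of the same response differ
#' significantly in their within-strata sums of squares, via
#' `F = (N1 * (N2 - 1) * SSW1) / (N2 * (N1 - 1) * SSW2)` referred to an F
#' distribution with `(N1 - 1, N2 - 1)` degrees of freedom. The null of
#' equal within-strata sums of squares is rejected in either tail (the
#' variance-ratio test is two-sided), so a factor is flagged whether it
#' explains significantly more or significantly less than the other.
#'
#' @param y Numeric response.
#' @param strata1,strata2 Stratum labels of the two factors on the same `y`.
#' @param alpha Significance level.
#' @return An `eco_f` list: `F`, sample sizes, SSWs, stratum counts,
#'   `significant`.
#' @export
ecological_detect <- function(y, strata1, strata2, alpha = 0.05) {
  s1 <- sum_of_squares(y, strata1)
  s2 <- sum_of_squares(y, strata2)
  if (s2$ssw <= 0) {
    stop("SSW of the second factor is 0: F is undefined", call. = FALSE)
  }
  Fv <- (s1$n * (s2$n - 1) * s1$ssw) / (s2$n * (s1$n - 1) * s2$ssw)
  upper <- stats::pf(Fv, s1$n - 1, s2$n - 1, lower.tail = FALSE)
  p <- min(1, 2 * min(upper, 1 - upper))
  structure(
    list(F = Fv, n_x1 = s1$n, n_x2 = s2$n, ssw_x1 = s1$ssw, ssw_x2 = s2$ssw,
         l_1 = s1$L, l_2 = s2$L, alpha = alpha, p_value = p,
         significant = p < alpha),
    class = "eco_f"
  )
}

#' @export
print.eco_f <- function(x, ...) {
  cat(sprintf("<eco_f> F = %.4f (n1 = %d, n2 = %d), %ssignificant at %g\n",
              x$F, x$n_x1, x$n_x2, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Run the full detector battery on a zonal table
#'
#' Computes per-factor q with significance, the full pairwise interaction
#' matrix, and the full pairwise ecological matrix. Continuous factor columns
#' are discretized first; factor/character columns are used as-is.
#'
#' @param table Data frame: one row per zonal unit.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names; defaults to every
#'   column except `response` and an optional `unit` id.
#' @param n_bins,disc Discretization settings for continuous factors (passed
#'   to [discretize_factor()]).
#' @param significance,n_perm,seed Passed to [factor_q()].
#' @param alpha Level for the ecological detector.
#' @return A `detector_report` list of tibbles: `factor` (q, p per factor),
#'   `interaction` (per unordered pair: q1, q2, q12, category), `ecological`
#'   (per unordered pair: F, significant).
#' @examples
#' tab <- generate_zonal_table(
#'   zonal_design(300, c(4, 3), c(.5, .2), seed = 7))
#' run_detectors(tab, response = "y")
#' @export
run_detectors <- function(table, response = "y", factors = NULL,
                          n_bins = 5, disc = "quantile",
                          significance = "permutation", n_perm = 999,
                          seed = 1L, alpha = 0.05) {
  table <- tibble::as_tibble(table)
  if (!response %in% names(table)) {
    stop("missing response column: ", response, call. = FALSE)
  }
  if (is.null(factors)) factors <- setdiff(names(table), c(response, "unit"))
  miss <- setdiff(factors, names(table))
  if (length(miss)) {
    stop("missing factor columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(table) < 2) stop("need at least 2 zonal units", call. = FALSE)
  y <- table[[response]]
  strata <- lapply(factors, function(f) {
    v <- table[[f]]
    if (is.numeric(v)) discretize_factor(v, method = disc, n_bins = n_bins)
    else factor(v)
  })
  names(strata) <- factors
  fr <- purrr::map2_dfr(strata, factors, function(s, f) {
    r <- factor_q(y, s, significance = significance, n_perm = n_perm,
                  seed = seed)
    tibble::tibble(factor = f, q = r$q, p_value = r$p_value, L = r$L,
                   method = r$method)
  })
  pairs <- if (length(factors) >= 2) {
    utils::combn(factors, 2, simplify = FALSE)
  } else list()
  inter <- purrr::map_dfr(pairs, function(p) {
    r <- interaction_detect(y, strata[[p[1]]], strata[[p[2]]])
    tibble::tibble(factor1 = p[1], factor2 = p[2], q1 = r$q1, q2 = r$q2,
                   q12 = r$q12, category = r$category)
  })
  eco <- purrr::map_dfr(pairs, function(p) {
    r <- ecological_detect(y, strata[[p[1]]], strata[[p[2]]], alpha = alpha)
    tibble::tibble(factor1 = p[1], factor2 = p[2], F = r$F,
                   significant = r$significant)
  })
  structure(list(factor = fr, interaction = inter, ecological = eco,
                 response = response, alpha = alpha),
            class = "detector_report")
}

#' @export
print.detector_report <- function(x, ...) {
  cat("<detector_report> response:", x$response, "\n\nFactor detector:\n")
  print(x$factor)
  if (nrow(x$interaction)) {
    cat("\nInteraction detector:\n"); print(x$interaction)
  }
  if (nrow(x$ecological)) {
    cat("\nEcological detector (alpha = ", x$alpha, "):\n", sep = "")
    print(x$ecological)
  }
  invisible(x)
}
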