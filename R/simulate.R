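#' Configuration for a synthetic land-use landscape
#'
#' The generator draws a spatially autocorrelated latent Gaussian field
#' (white noise smoothed at `autocorr_scale`) and slices it at
#' proportion-matched quantiles, so class shares match `proportions` up to
#' integer rounding and patchiness is controlled by a single length scale.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in metres.
#' @param codes Integer vector of land-cover codes, one per class.
#' @param proportions Non-negative fractions summing to 1, aligned with
#'   `codes`.
#' @param autocorr_scale Smoothing scale of the latent field in metres;
#'   0 gives spatially independent cells.
#' @param seed Integer seed; every draw from this config is reproducible.
#' @return A `sim_config` object.
#' @examples
#' cfg <- sim_config(50, 50, 100, codes = 1:3, proportions = c(.5, .3, .2))
#' lu <- generate_landuse(cfg)
#' table(lu$codes) / length(lu$codes)
#' @export
sim_config <- function(rows, cols, cell_size = 30, codes, proportions,
                       autocorr_scale = 0, seed = 1L) {
  stopifnot(rows >= 1, cols >= 1, cell_size > 0, autocorr_scale >= 0)
  codes <- as.integer(codes)
  if (length(codes) != length(proportions)) {
    stop("`codes` and `proportions` must have the same length", call. = FALSE)
  }
  if (any(proportions < 0)) stop("proportions must be >= 0", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", sum(proportions), ")", call. = FALSE)
  }
  if (anyDuplicated(codes)) stop("duplicate class codes", call. = FALSE)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         cell_size = as.numeric(cell_size), codes = codes,
         proportions = as.numeric(proportions),
         autocorr_scale = as.numeric(autocorr_scale), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Derive a reproducible sub-seed so each generator consumes an independent
# stream from one user-facing seed. Kept below 2^31.
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 65537) %% 2147483647
}

#' Generate a synthetic categorical land-use raster
#'
#' @param cfg A [sim_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return An [lu_raster()] whose class shares match `cfg$proportions` up to
#'   integer rounding.
#' @export
generate_landuse <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$rows * cfg$cols
  latent <- withr::with_seed(sub_seed(seed, 1L), {
    z <- matrix(stats::rnorm(n), cfg$rows, cfg$cols)
    if (cfg$autocorr_scale > 0) {
      sd_cells <- cfg$autocorr_scale / cfg$cell_size
      r <- max(1L, ceiling(3 * sd_cells))
      off <- -r:r
      k1 <- stats::dnorm(off, sd = sd_cells)
      k <- outer(k1, k1)
      z <- conv2_same(z, k / sum(k))
    }
    z
  })
  # quantile slicing: the lowest round(n*p1) cells -> class 1, etc.
  counts <- diff(round(cumsum(c(0, cfg$proportions)) * n))
  ord <- order(latent)
  codes <- integer(n)
  codes[ord] <- rep(cfg$codes, times = counts)
  lu_raster(matrix(codes, cfg$rows, cfg$cols), cfg$cell_size)
}

#' Epoch-to-epoch class transition model
#'
#' @param prob_matrix Square row-stochastic matrix; entry (i, j) is the
#'   probability that a cell of class `codes[i]` becomes class `codes[j]`
#'   over one epoch.
#' @param codes Integer land-cover codes labelling rows/columns; defaults to
#'   the matrix dimnames or `1:n`.
#' @param seed Integer seed.
#' @return A `transition_model` object.
#' @export
transition_model <- function(prob_matrix, codes = NULL, seed = 1L) {
  if (!is.matrix(prob_matrix) || nrow(prob_matrix) != ncol(prob_matrix)) {
    stop("`prob_matrix` must be square", call. = FALSE)
  }
  if (any(prob_matrix < 0) || any(prob_matrix > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(prob_matrix)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("non-stochastic rows: row sums must equal 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  if (is.null(codes)) {
    codes <- if (!is.null(rownames(prob_matrix))) {
      as.integer(rownames(prob_matrix))
    } else seq_len(nrow(prob_matrix))
  }
  codes <- as.integer(codes)
  stopifnot(length(codes) == nrow(prob_matrix))
  structure(list(prob_matrix = prob_matrix, codes = codes,
                 seed = as.integer(seed)),
            class = "transition_model")
}

#' Evolve a land-use raster one epoch forward
#'
#' Each cell's new class is drawn independently from the transition-model row
#' of its current class. Geometry, nodata pattern and cell count are
#' preserved.
#'
#' @param base An [lu_raster()].
#' @param model A [transition_model()] indexing every code present in `base`.
#' @param seed Optional override of `model$seed`.
#' @return An [lu_raster()] with the same geometry as `base`.
#' @export
evolve_landuse <- function(base, model, seed = model$seed) {
  stopifnot(inherits(base, "lu_raster"), inherits(model, "transition_model"))
  present <- unique(as.vector(base$codes))
  present <- present[!is.na(present)]
  missing <- setdiff(present, model$codes)
  if (length(missing)) {
    stop("codes in raster missing from transition model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  new_codes <- base$codes
  withr::with_seed(sub_seed(seed, 2L), {
    for (i in seq_along(model$codes)) {
      idx <- which(base$codes == model$codes[i])
      if (!length(idx)) next
      p <- model$prob_matrix[i, ]
      if (length(which(p > 0)) == 1L) {
        new_codes[idx] <- model$codes[which(p > 0)]
      } else {
        new_codes[idx] <- sample(model$codes, length(idx),
                                 replace = TRUE, prob = p)
      }
    }
  })
  lu_raster(new_codes, base$cell_size, base$origin, base$nodata_code)
}

#' Design for a synthetic zonal factor/response table
#'
#' The response is built as a sum of per-factor stratum means plus Gaussian
#' noise, with the stratum-mean vectors rescaled so the population
#' between-strata variance of each factor is exactly
#' `between_fraction[f] * V`, where `V` is the total response variance. The
#' expected geographical-detector q of factor `f` therefore equals
#' `between_fraction[f]` by construction.
#'
#' @param n_units Number of zonal units (rows).
#' @param n_strata Integer vector: stratum count per factor.
#' @param between_fraction Numeric vector in `[0, 1)` aligned with
#'   `n_strata`: the analytic q of each factor. The sum must be < 1.
#' @param noise_sd Standard deviation of the within-stratum noise.
#' @param factor_names Optional names; defaults to `x1, x2, ...`.
#' @param seed Integer seed.
#' @return A `zonal_design` object.
#' @export
zonal_design <- function(n_units, n_strata, between_fraction,
                         noise_sd = 1, factor_names = NULL, seed = 1L) {
  stopifnot(length(n_strata) == length(between_fraction))
  if (any(between_fraction < 0 | between_fraction >= 1)) {
    stop("`between_fraction` entries must lie in [0, 1)", call. = FALSE)
  }
  if (sum(between_fraction) >= 1) {
    stop("sum of `between_fraction` must be < 1 so a noise variance exists",
         call. = FALSE)
  }
  if (any(n_strata < 2)) stop("each factor needs >= 2 strata", call. = FALSE)
  if (n_units < 2 * max(n_strata)) {
    stop("`n_units` must be at least twice the largest stratum count",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(factor_names)) factor_names <- paste0("x", seq_along(n_strata))
  structure(
    list(n_units = as.integer(n_units), n_strata = as.integer(n_strata),
         between_fraction = as.numeric(between_fraction),
         noise_sd = as.numeric(noise_sd), factor_names = factor_names,
         seed = as.integer(seed)),
    class = "zonal_design"
  )
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Generate a zonal factor/response table with known ground truth
#'
#' @param design A [zonal_design()].
#' @param seed Optional override of `design$seed`.
#' @return A tibble with columns `unit`, `y`, and one factor column (a
#'   factor) per designed factor. The attribute `"between_fraction"` carries
#'   the analytic q values.
#' @examples
#' d <- zonal_design(1000, n_strata = c(4, 3), between_fraction = c(.5, .2))
#' tab <- generate_zonal_table(d)
#' factor_q(tab$y, tab$x1)$q  # ~ 0.5
#' @export
generate_zonal_table <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "zonal_design"))
  n <- design$n_units
  b <- design$between_fraction
  sigma2 <- design$noise_sd^2
  total_b <- sum(b)
  # total variance V with noise variance sigma2 occupying the (1 - sum b) share
  V <- if (total_b < 1 && sigma2 > 0) sigma2 / (1 - total_b) else 1
  withr::with_seed(sub_seed(seed, 3L), {
    cols <- list(unit = seq_len(n))
    y <- stats::rnorm(n, sd = design$noise_sd)
    for (f in seq_along(design$n_strata)) {
      L <- design$n_strata[f]
      labels <- sample(rep_len(seq_len(L), n))      # balanced, shuffled
      base_means <- seq_len(L) - (L + 1) / 2        # equally spaced, centred
      mf <- base_means[labels]
      vf <- b[f] * V
      pv <- pop_var(mf)
      mf <- if (vf > 0 && pv > 0) (mf - mean(mf)) * sqrt(vf / pv) else mf * 0
      y <- y + mf
      cols[[design$factor_names[f]]] <-
        factor(labels, levels = seq_len(L),
               labels = paste0("s", seq_len(L)))
    }
    out <- tibble::as_tibble(cols)
    out <- tibble::add_column(out, y = y, .after = "unit")
    attr(out, "between_fraction") <-
      stats::setNames(b, design$factor_names)
    out
  })
}
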