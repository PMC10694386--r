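# Independent reference implementations used to check the package's
# vectorized code paths. Deliberately literal and slow.

# Degradation by explicit accumulation over threats and source cells.
# Vectorized only over target cells; the per-source loop is explicit.
oracle_degradation <- function(lu, threats, sens, beta = NULL,
                               per_source_mean = FALSE) {
  nr <- nrow(lu$codes); nc <- ncol(lu$codes); cs <- lu$cell_size
  wsum <- sum(threats$weight)
  rowm <- matrix(rep(seq_len(nr), nc), nr, nc)
  colm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  D <- matrix(0, nr, nc)
  for (ti in seq_len(nrow(threats))) {
    dmax <- threats$max_dist_km[ti] * 1000
    src <- which(!is.na(lu$codes) & lu$codes == threats$code[ti],
                 arr.ind = TRUE)
    if (!nrow(src)) next
    acc <- matrix(0, nr, nc)
    for (s in seq_len(nrow(src))) {
      d <- cs * sqrt((rowm - src[s, 1])^2 + (colm - src[s, 2])^2)
      i <- if (threats$decay[ti] == "linear") {
        pmax(0, 1 - d / dmax)
      } else {
        exp(-2.99 * d / dmax)
      }
      i[d > dmax] <- 0
      acc <- acc + i
    }
    if (per_source_mean) acc <- acc / nrow(src)
    S <- matrix(sens[[threats$threat[ti]]][match(lu$codes, sens$lucode)],
                nr, nc)
    S[is.na(S)] <- 0
    D <- D + (threats$weight[ti] / wsum) * acc * S
  }
  if (!is.null(beta)) D <- D * beta
  D[is.na(lu$codes)] <- NA_real_
  D
}

# Fully scalar quadruple loop (target row, target col, source row, source
# col) — only usable on tiny grids; ties the faster oracle to first
# principles.
oracle_degradation_scalar <- function(lu, threats, sens) {
  nr <- nrow(lu$codes); nc <- ncol(lu$codes); cs <- lu$cell_size
  wsum <- sum(threats$weight)
  D <- matrix(0, nr, nc)
  for (xr in seq_len(nr)) for (xc in seq_len(nc)) {
    j <- lu$codes[xr, xc]
    if (is.na(j)) { D[xr, xc] <- NA_real_; next }
    total <- 0
    for (ti in seq_len(nrow(threats))) {
      dmax <- threats$max_dist_km[ti] * 1000
      S <- sens[[threats$threat[ti]]][match(j, sens$lucode)]
      for (yr in seq_len(nr)) for (yc in seq_len(nc)) {
        cy <- lu$codes[yr, yc]
        if (is.na(cy) || cy != threats$code[ti]) next
        d <- cs * sqrt((xr - yr)^2 + (xc - yc)^2)
        if (d > dmax) next
        i <- if (threats$decay[ti] == "linear") 1 - d / dmax else exp(-2.99 * d / dmax)
        total <- total + (threats$weight[ti] / wsum) * i * S
      }
    }
    D[xr, xc] <- total
  }
  D
}

# Two-pass loop computation of q = 1 - SSW/SST.
oracle_q <- function(y, strata) {
  strata <- factor(strata)
  ybar <- mean(y)
  sst <- 0
  for (v in y) sst <- sst + (v - ybar)^2
  ssw <- 0
  for (h in levels(strata)) {
    yh <- y[strata == h]
    if (!length(yh)) next
    mh <- mean(yh)
    for (v in yh) ssw <- ssw + (v - mh)^2
  }
  1 - ssw / sst
}

# Cell-by-cell tally of the transfer cross-tabulation (areas in km^2).
oracle_transfer <- function(lu_a, lu_b) {
  codes <- sort(union(unique(as.vector(lu_a$codes)),
                      unique(as.vector(lu_b$codes))))
  codes <- codes[!is.na(codes)]
  m <- matrix(0, length(codes), length(codes),
              dimnames = list(as.character(codes), as.character(codes)))
  for (i in seq_along(lu_a$codes)) {
    a <- lu_a$codes[i]; b <- lu_b$codes[i]
    if (is.na(a) || is.na(b)) next
    m[as.character(a), as.character(b)] <-
      m[as.character(a), as.character(b)] + 1
  }
  m * (lu_a$cell_size / 1000)^2
}

# Random landscape over the packaged 10-code legend.
random_poyang_landscape <- function(rows, cols, cell_size = 500, seed = 1) {
  withr::with_seed(seed, {
    codes <- matrix(sample(1:10, rows * cols, replace = TRUE,
                           prob = c(.15, .1, .25, .03, .07, .2, .1, .03, .04, .03)),
                    rows, cols)
    lu_raster(codes, cell_size)
  })
}

random_strata <- function(n, L, seed) {
  withr::with_seed(seed, factor(sample(seq_len(L), n, replace = TRUE)))
}
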