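# Chromatogram similarity measures. Each of the four optimal measures is
# bound to a fixed missing-value strategy: distance correlation and weighted
# cross-correlation impute missing as zero, cosine similarity imputes missing
# as seeded near-zero noise, and mutual information uses pairwise-complete
# positions only. Pearson correlation (pairwise-complete) is provided for
# evaluation uses.

MEASURE_MV <- c(distance_correlation = "zeros",
                weighted_cross_correlation = "zeros",
                cosine = "near_zero_noise",
                mutual_information = "na_pairwise",
                pearson = "na_pairwise")

#' Specify a similarity measure and its missing-value strategy
#'
#' The missing-value strategy is determined by the measure and cannot be
#' overridden: distance correlation and weighted cross-correlation impute
#' zeros; cosine similarity imputes near-zero noise; mutual information (and
#' Pearson) use pairwise-complete positions.
#'
#' @param measure one of \code{"distance_correlation"},
#'   \code{"weighted_cross_correlation"}, \code{"cosine"},
#'   \code{"mutual_information"}, \code{"pearson"}.
#' @param L lag window for weighted cross-correlation (integer >= 0).
#' @param B bin count for mutual information (integer >= 2).
#' @param sigma near-zero-noise scale, relative to the chromatogram maximum.
#' @param seed integer seed for the noise stream.
#' @return list of class \code{"measure_spec"}.
#' @export
measure_spec <- function(measure = c("distance_correlation",
                                     "weighted_cross_correlation",
                                     "cosine", "mutual_information",
                                     "pearson"),
                         L = 1L, B = 10L, sigma = 1e-4, seed = 1L) {
  measure <- match.arg(measure)
  stopifnot(L >= 0L, B >= 2L, sigma > 0)
  structure(list(measure = measure, mv_strategy = unname(MEASURE_MV[measure]),
                 L = as.integer(L), B = as.integer(B), sigma = sigma,
                 seed = as.integer(seed)),
            class = "measure_spec")
}

# evaluate expr under a temporary RNG state so package randomness never
# disturbs the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Impute missing values in a chromatogram
#'
#' @param x numeric vector with \code{NA} for missing values.
#' @param strategy \code{"zeros"} (missing -> 0), \code{"near_zero_noise"}
#'   (missing -> independent half-normal draws scaled by
#'   \code{sigma * max(x)}), or \code{"na_pairwise"} (unchanged; downstream
#'   code uses pairwise-complete positions).
#' @param sigma relative noise scale for \code{near_zero_noise}.
#' @param seed integer seed; the same seed reproduces the same draws.
#' @return imputed numeric vector.
#' @export
impute <- function(x, strategy = c("zeros", "near_zero_noise", "na_pairwise"),
                   sigma = 1e-4, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(length(x) >= 1L)
  miss <- is.na(x)
  if (!any(miss) || strategy == "na_pairwise") return(x)
  if (strategy == "zeros") {
    x[miss] <- 0
    return(x)
  }
  if (all(miss))
    stop("near_zero_noise imputation undefined for an all-missing chromatogram")
  scale <- sigma * max(x, na.rm = TRUE)
  x[miss] <- with_seed(seed, abs(stats::rnorm(sum(miss), 0, scale)))
  x
}

#' Distance correlation between two chromatograms
#'
#' Szekely's distance correlation computed from doubly-centered pairwise
#' Euclidean distance matrices. Returns a value in [0, 1]; 0 if either
#' distance variance is zero (e.g. a constant chromatogram).
#'
#' @param x,y numeric vectors of equal length n >= 2 (zero-imputed upstream;
#'   \code{NA} not allowed here).
#' @return distance correlation in [0, 1].
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  stopifnot(n >= 2L)
  A <- dcenter(abs(outer(x, x, "-")))
  B <- dcenter(abs(outer(y, y, "-")))
  v2x <- mean(A * A); v2y <- mean(B * B)
  if (v2x <= 0 || v2y <= 0) return(0)
  v2xy <- mean(A * B)
  if (v2xy <= 0) return(0)
  sqrt(v2xy / sqrt(v2x * v2y))
}

dcenter <- function(d) {
  rm <- rowMeans(d); gm <- mean(d)
  d - outer(rm, rm, "+") + gm
}

#' Weighted cross-correlation between two chromatograms
#'
#' A lag-tolerant correlation: with raw cross-covariances
#' \eqn{c_k(x,y) = \sum_i x_i y_{i+k}} of the mean-centered vectors and
#' triangular lag weights \eqn{w_k = 1 - |k|/(L+1)},
#' \deqn{WCC = \frac{\sum_{k=-L}^{L} w_k c_k(x,y)}
#'   {\sqrt{\sum_k w_k c_k(x,x) \sum_k w_k c_k(y,y)}}.}
#' At \code{L = 0} this is the ordinary Pearson correlation. Chromatographic
#' peaks shifted by up to \code{L} fractions still score highly.
#'
#' @param x,y numeric vectors of equal length n > L (zero-imputed upstream).
#' @param L lag window (default 1 fraction).
#' @return value in [-1, 1]; 0 with a warning if the denominator is zero.
#' @export
weighted_cross_correlation <- function(x, y, L = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  stopifnot(L >= 0L, n > L)
  x <- x - mean(x); y <- y - mean(y)
  ck <- function(a, b, k) sum(a[seq_len(n - k)] * b[seq_len(n - k) + k])
  w <- 1 - abs(seq(-L, L)) / (L + 1)
  num <- sum(w * vapply(seq(-L, L), function(k)
    if (k >= 0) ck(x, y, k) else ck(y, x, -k), 0))
  dx <- sum(w * vapply(seq(-L, L), function(k) ck(x, x, abs(k)), 0))
  dy <- sum(w * vapply(seq(-L, L), function(k) ck(y, y, abs(k)), 0))
  if (dx <= 0 || dy <= 0) {
    warning("zero denominator in weighted cross-correlation; returning 0")
    return(0)
  }
  num / sqrt(dx * dy)
}

#' Cosine similarity between two chromatograms
#'
#' @param x,y numeric vectors of equal length (near-zero-noise-imputed
#'   upstream), each with nonzero norm.
#' @return \code{sum(x*y) / (||x|| ||y||)} in [-1, 1].
#' @export
cosine <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for zero-norm vector")
  sum(x * y) / (nx * ny)
}

#' Mutual information between two chromatograms
#'
#' Plug-in mutual information in nats over a \code{B x B} equal-width joint
#' histogram of the pairwise-complete values (positions where both
#' chromatograms are quantified). Fewer than \code{B} pairwise-complete
#' positions yields \code{NA}, the missing-feature marker.
#'
#' @param x,y numeric vectors of equal length; \code{NA} marks missing.
#' @param B number of equal-width bins per margin.
#' @return mutual information in nats (>= 0), or \code{NA}.
#' @export
mutual_information <- function(x, y, B = 10L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < B) return(NA_real_)
  bx <- equal_width_bins(x[ok], B)
  by <- equal_width_bins(y[ok], B)
  joint <- tabulate((bx - 1L) * B + by, nbins = B * B)
  n <- sum(ok)
  pj <- joint / n
  px <- tabulate(bx, B) / n
  py <- tabulate(by, B) / n
  pos <- pj > 0
  pij <- pj[pos]
  # marginal index of each joint cell: row = x bin, col = y bin
  ix <- ((which(pos) - 1L) %/% B) + 1L
  iy <- ((which(pos) - 1L) %% B) + 1L
  sum(pij * log(pij / (px[ix] * py[iy])))
}

equal_width_bins <- function(v, B) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  b <- floor((v - r[1]) / (r[2] - r[1]) * B) + 1L
  pmin.int(b, B)
}

#' Pearson correlation with pairwise-complete positions
#'
#' @param x,y numeric vectors; \code{NA} marks missing.
#' @return Pearson r over positions where both are quantified, or \code{NA}
#'   if fewer than 3 such positions.
#' @export
pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Similarity features for all protein pairs of one experiment
#'
#' Computes, for every unordered pair of proteins in the experiment, the
#' value of each requested measure under its bound missing-value strategy.
#' Pairs are alphabetized; the table is symmetric by construction. The
#' near-zero-noise stream is derived deterministically from each spec's seed
#' and the protein's position in alphabetical order, so results are
#' reproducible end-to-end for a fixed configuration seed.
#'
#' @param experiment an \code{\link{elution_matrix}} (preprocessed).
#' @param specs a \code{\link{measure_spec}} or list of them.
#' @return data frame with columns \code{protein_a}, \code{protein_b} and one
#'   numeric column per spec (named by measure). \code{NA} marks the
#'   missing-feature marker.
#' @export
pairwise_features <- function(experiment, specs) {
  if (inherits(specs, "measure_spec")) specs <- list(specs)
  prot <- sort(rownames(experiment))
  X <- unclass(experiment)[prot, , drop = FALSE]
  np <- length(prot)
  if (np < 2L) stop("need at least 2 proteins")
  idx <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
  out <- data.frame(protein_a = prot[idx[, 1L]], protein_b = prot[idx[, 2L]],
                    stringsAsFactors = FALSE)
  for (spec in specs) {
    M <- pair_matrix(X, spec)
    out[[spec$measure]] <- M[idx]
  }
  out
}

# full symmetric measure matrix over the rows of X (proteins x fractions)
pair_matrix <- function(X, spec) {
  switch(spec$measure,
         distance_correlation = dcor_matrix(X),
         weighted_cross_correlation = wcc_matrix(X, spec$L),
         cosine = cosine_matrix(X, spec$sigma, spec$seed),
         mutual_information = mi_matrix(X, spec$B),
         pearson = {
           suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
         })
}

dcor_matrix <- function(X) {
  X[is.na(X)] <- 0
  np <- nrow(X); n <- ncol(X)
  P <- matrix(0, np, n * n)
  for (i in seq_len(np))
    P[i, ] <- as.vector(dcenter(abs(outer(X[i, ], X[i, ], "-"))))
  V <- tcrossprod(P) / (n * n)  # V[i,j] = dCov^2(x_i, x_j)
  v <- diag(V)
  den <- sqrt(outer(v, v))
  M <- matrix(0, np, np)
  pos <- den > 0 & V > 0
  M[pos] <- sqrt(V[pos] / den[pos])
  M
}

wcc_matrix <- function(X, L) {
  X[is.na(X)] <- 0
  X <- X - rowMeans(X)
  n <- ncol(X)
  stopifnot(n > L)
  num <- tcrossprod(X)  # lag 0, weight 1
  for (k in seq_len(L)) {
    w <- 1 - k / (L + 1)
    Ck <- X[, seq_len(n - k), drop = FALSE] %*%
      t(X[, seq_len(n - k) + k, drop = FALSE])
    num <- num + w * (Ck + t(Ck))
  }
  d <- diag(num)
  den <- sqrt(outer(d, d))
  M <- matrix(0, nrow(X), nrow(X))
  pos <- den > 0
  M[pos] <- num[pos] / den[pos]
  M
}

cosine_matrix <- function(X, sigma, seed) {
  np <- nrow(X)
  for (i in seq_len(np)) {
    miss <- is.na(X[i, ])
    if (any(miss)) {
      if (all(miss))
        stop("near_zero_noise imputation undefined for an all-missing chromatogram")
      scale <- sigma * max(X[i, ], na.rm = TRUE)
      X[i, miss] <- with_seed(seed + i, abs(stats::rnorm(sum(miss), 0, scale)))
    }
  }
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("cosine similarity undefined for zero-norm vector")
  tcrossprod(X / nrm)
}

mi_matrix <- function(X, B) {
  np <- nrow(X)
  M <- matrix(NA_real_, np, np)
  for (i in seq_len(np - 1L)) {
    xi <- X[i, ]
    for (j in (i + 1L):np) {
      M[i, j] <- M[j, i] <- mutual_information(xi, X[j, ], B)
    }
  }
  diag(M) <- 0
  M
}
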