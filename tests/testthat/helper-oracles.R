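# Independent brute-force oracles. These deliberately take different
# computational paths from the package implementations they check.

# distance correlation via Szekely's S1/S2/S3 sum formula (no explicit
# double-centering)
bf_dcor <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-")); b <- abs(outer(y, y, "-"))
  dcov2 <- function(a, b) {
    S1 <- sum(a * b) / n^2
    S2 <- mean(a) * mean(b)
    S3 <- sum(rowSums(a) * rowSums(b)) / n^3
    S1 + S2 - 2 * S3
  }
  vx <- dcov2(a, a); vy <- dcov2(b, b)
  if (vx <= 0 || vy <= 0) return(0)
  v <- dcov2(a, b)
  if (v <= 0) return(0)
  sqrt(v / sqrt(vx * vy))
}

# plug-in mutual information by explicit triple-loop histogram counting
bf_mi <- function(x, y, B = 10L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < B) return(NA_real_)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  bin <- function(v) {
    lo <- min(v); hi <- max(v)
    if (lo == hi) return(rep(1L, length(v)))
    b <- floor((v - lo) / (hi - lo) * B) + 1L
    ifelse(b > B, B, b)
  }
  bx <- bin(x); by <- bin(y)
  mi <- 0
  for (i in seq_len(B)) for (j in seq_len(B)) {
    nij <- 0L
    for (k in seq_len(n)) if (bx[k] == i && by[k] == j) nij <- nij + 1L
    if (nij > 0L) {
      pij <- nij / n
      pi_ <- sum(bx == i) / n; pj_ <- sum(by == j) / n
      mi <- mi + pij * log(pij / (pi_ * pj_))
    }
  }
  mi
}

# cumulative precision by full recount at every rank
bf_precision <- function(labels) {
  vapply(seq_along(labels), function(r) {
    l <- labels[seq_len(r)]
    l <- l[!is.na(l)]
    if (!length(l)) NA_real_ else sum(l == "positive") / length(l)
  }, 0)
}

# AUROC by explicit positive x negative pair comparison
bf_auroc <- function(scores, labels) {
  if (!is.logical(labels)) labels <- labels == "positive"
  sp <- scores[labels]; sn <- scores[!labels]
  tot <- 0
  for (p in sp) for (q in sn) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# exhaustive pair labeling by per-pair membership scan
bf_label_enum <- function(complexes) {
  prot <- sort(unique(unlist(complexes)))
  pos <- character(0); neg <- character(0)
  if (length(prot) < 2L)
    return(list(positives = pos, negatives = neg))
  for (i in seq_len(length(prot) - 1L)) for (j in (i + 1L):length(prot)) {
    a <- prot[i]; b <- prot[j]
    together <- any(vapply(complexes, function(m) a %in% m && b %in% m,
                           TRUE))
    key <- paste(a, b, sep = "|")
    if (together) pos <- c(pos, key) else neg <- c(neg, key)
  }
  list(positives = pos, negatives = neg)
}

# exact hypergeometric upper tail from binomial coefficients
bf_hyper_upper <- function(k, m, n_bg, n_fg) {
  i <- k:min(m, n_fg)
  sum(choose(m, i) * choose(n_bg - m, n_fg - i)) / choose(n_bg, n_fg)
}

# a Gaussian elution peak
gauss_peak <- function(n, center, width = 2, amp = 100) {
  amp * exp(-(seq_len(n) - center)^2 / (2 * width^2))
}

tiny_elution <- function(vals, proteins, id = "e1") {
  elution_matrix(matrix(vals, nrow = length(proteins), byrow = TRUE,
                        dimnames = list(proteins, NULL)),
                 experiment_id = id)
}

labels_from_sets <- function(complexes) {
  label_pairs(complex_catalog(complexes))
}
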