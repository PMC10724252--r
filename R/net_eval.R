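# Network-level evaluation: Jaccard overlap between screens, neighbor-voting
# functional coherence and disease-gene connectivity, per-edge profile
# correlation (coexpression / colocalization), and saturation analysis.

#' Jaccard index between two networks
#'
#' @param a,b \code{\link{edge_list}} objects (alphabetized pairs).
#' @return \code{|a n b| / |a u b|} in [0, 1]; 0 by convention if both are
#'   empty (logged).
#' @export
jaccard <- function(a, b) {
  ka <- paste(a$protein_a, a$protein_b, sep = "|")
  kb <- paste(b$protein_a, b$protein_b, sep = "|")
  u <- union(ka, kb)
  if (!length(u)) {
    message("both networks empty; Jaccard defined as 0")
    return(0)
  }
  length(intersect(ka, kb)) / length(u)
}

#' Functional coherence of a network by neighbor voting
#'
#' Guilt-by-association evaluation: for each annotation term, the annotated
#' proteins are split into \code{folds} cross-validation folds; in each
#' fold the annotations of fold members are hidden, and every network
#' protein is scored by the proportion of its interaction partners that are
#' (non-hidden) term members. The ROC-AUC of this score for hidden term
#' members (positives) versus never-annotated network proteins (negatives)
#' is averaged over folds. A coherent network predicts a protein's function
#' from its neighbors, giving AUCs well above 0.5.
#'
#' Proteins with degree zero or with only hidden-annotated neighbors score
#' 0, not missing, so the ROC is always well-defined.
#'
#' @param network an \code{\link{edge_list}}.
#' @param annotations named list (term -> annotated proteins), e.g. from
#'   \code{\link{read_gmt}}.
#' @param folds cross-validation folds per term (default 3).
#' @param min_size,max_size term-size filter applied to the number of
#'   annotated proteins present in the network (defaults 10 and 100;
#'   \code{NULL} disables a bound).
#' @param seed integer seed for the fold split.
#' @return list of class \code{"coherence_result"}: \code{terms} (data frame
#'   with term, size, auc), \code{median_auc}, \code{fraction_below_0.5}.
#' @export
neighbor_voting_auc <- function(network, annotations, folds = 3L,
                                min_size = 10L, max_size = 100L, seed = 1L) {
  stopifnot(nrow(network) > 0L)
  proteins <- sort(unique(c(network$protein_a, network$protein_b)))
  np <- length(proteins)
  adj <- matrix(FALSE, np, np, dimnames = list(proteins, proteins))
  ia <- match(network$protein_a, proteins)
  ib <- match(network$protein_b, proteins)
  adj[cbind(ia, ib)] <- TRUE
  adj[cbind(ib, ia)] <- TRUE
  degree <- rowSums(adj)
  res <- data.frame(term = character(0), size = integer(0),
                    auc = numeric(0), stringsAsFactors = FALSE)
  skipped <- 0L
  for (term in names(annotations)) {
    ann <- intersect(annotations[[term]], proteins)
    if (!length(ann)) { skipped <- skipped + 1L; next }
    if (!is.null(min_size) && length(ann) < min_size) next
    if (!is.null(max_size) && length(ann) > max_size) next
    if (length(ann) < folds) next
    fold <- with_seed(seed + which(names(annotations) == term),
                      sample(rep_len(seq_len(folds), length(ann))))
    negatives <- setdiff(proteins, ann)
    if (!length(negatives)) next
    aucs <- numeric(folds)
    for (f in seq_len(folds)) {
      hidden <- ann[fold == f]
      visible <- ann[fold != f]
      vote <- as.numeric(adj[, visible, drop = FALSE] %*%
                           rep(1, length(visible)))
      score <- ifelse(degree > 0, vote / degree, 0)
      names(score) <- proteins
      aucs[f] <- auroc(c(score[hidden], score[negatives]),
                       c(rep(TRUE, length(hidden)),
                         rep(FALSE, length(negatives))))
    }
    res <- rbind(res, data.frame(term = term, size = length(ann),
                                 auc = mean(aucs), stringsAsFactors = FALSE))
  }
  if (skipped) message(skipped, " term(s) with no annotated network protein skipped")
  structure(list(terms = res,
                 median_auc = if (nrow(res)) stats::median(res$auc) else NA_real_,
                 fraction_below_0.5 = if (nrow(res)) mean(res$auc < 0.5)
                                      else NA_real_),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("Neighbor-voting coherence: %d terms, median AUC %.3f, %.1f%% below 0.5\n",
              nrow(x$terms), x$median_auc, 100 * x$fraction_below_0.5))
  invisible(x)
}

#' Disease-gene connectivity of a network
#'
#' Predicts withheld disease genes from a protein's network neighbors using
#' the same neighbor-voting cross-validation machinery as
#' \code{\link{neighbor_voting_auc}}, with disease gene sets as terms and no
#' term-size filter by default.
#'
#' @inheritParams neighbor_voting_auc
#' @param disease_annotations named list (disease -> gene set).
#' @return a \code{"coherence_result"}.
#' @export
disease_connectivity <- function(network, disease_annotations, folds = 3L,
                                 seed = 1L) {
  neighbor_voting_auc(network, disease_annotations, folds = folds,
                      min_size = NULL, max_size = NULL, seed = seed)
}

#' Per-edge profile correlation (coexpression / colocalization)
#'
#' For every network edge whose two proteins both appear in a profile matrix
#' (protein x condition; e.g. abundance across tissues, or subcellular
#' fractionation profiles), computes the Pearson correlation of their
#' profiles over pairwise-complete conditions. Edges with fewer than 3
#' shared conditions, or with a protein absent from the matrix, are skipped
#' and counted.
#'
#' @param network an \code{\link{edge_list}}.
#' @param profile_matrix numeric matrix with protein rownames.
#' @return list: \code{correlations} (per retained edge), \code{median},
#'   \code{fraction_negative}, \code{n_skipped}.
#' @export
pair_property_correlation <- function(network, profile_matrix) {
  rn <- rownames(profile_matrix)
  r <- rep(NA_real_, nrow(network))
  for (i in seq_len(nrow(network))) {
    a <- network$protein_a[i]; b <- network$protein_b[i]
    if (!(a %in% rn) || !(b %in% rn)) next
    r[i] <- pearson(profile_matrix[a, ], profile_matrix[b, ])
  }
  keep <- !is.na(r)
  list(correlations = r[keep],
       median = if (any(keep)) stats::median(r[keep]) else NA_real_,
       fraction_negative = if (any(keep)) mean(r[keep] < 0) else NA_real_,
       n_skipped = sum(!keep))
}

#' Saturation analysis of protein detection across experiments
#'
#' Samples the experiments in random order (repeated \code{repeats} times)
#' and counts the cumulative number of distinct proteins quantified in at
#' least one fraction at each step. A logarithmic curve
#' \eqn{count = a + b \log(step)} is fit by least squares over all repeats
#' and used to project detection at larger experiment counts.
#'
#' @param experiments list of \code{\link{elution_matrix}} objects (>= 2).
#' @param repeats number of random orderings.
#' @param seed integer seed.
#' @return list: \code{counts} (repeats x steps matrix), \code{a}, \code{b}
#'   (fit coefficients), and \code{projection}, a function of the
#'   experiment count n returning \code{a + b*log(n)}.
#' @export
saturation_curve <- function(experiments, repeats = 10L, seed = 1L) {
  stopifnot(length(experiments) >= 2L)
  n <- length(experiments)
  detected <- lapply(experiments, function(e)
    rownames(e)[rowSums(!is.na(e)) > 0L])
  counts <- matrix(0L, repeats, n)
  for (r in seq_len(repeats)) {
    ord <- with_seed(seed + r, sample(n))
    seen <- character(0)
    for (s in seq_len(n)) {
      seen <- union(seen, detected[[ord[s]]])
      counts[r, s] <- length(seen)
    }
  }
  step <- rep(seq_len(n), each = repeats)
  y <- as.vector(counts)
  fit <- stats::lm(y ~ log(step))
  a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
  list(counts = counts, a = a, b = b,
       projection = function(n_exp) a + b * log(n_exp))
}
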