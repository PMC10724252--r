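#' Label protein pairs from a complex catalog
#'
#' Builds the gold standard used to train and evaluate the pair classifier:
#' positive examples are intra-complex pairs (both proteins in the same
#' complex), negative examples are inter-complex pairs (both proteins
#' annotated to complexes, but never the same one). A pair that is
#' intra-complex in any complex is a positive, never a negative.
#'
#' @param catalog a \code{\link{complex_catalog}}.
#' @param universe optional character vector; labeling is restricted to
#'   catalog proteins present in it.
#' @param source_tag provenance tag (\code{"native"} or \code{"injected"}).
#' @return data frame of class \code{"labeled_pairs"} with columns
#'   \code{protein_a}, \code{protein_b} (alphabetized), \code{label}
#'   (factor positive/negative) and \code{complex_id} (smallest source
#'   complex id for positives, \code{NA} for negatives); attribute
#'   \code{origin} maps each positive pair to all its source complexes.
#' @export
label_pairs <- function(catalog, universe = NULL,
                        source_tag = c("native", "injected")) {
  source_tag <- match.arg(source_tag)
  members <- lapply(catalog, function(m)
    if (is.null(universe)) m else intersect(m, universe))
  proteins <- sort(unique(unlist(members)))
  if (length(proteins) < 2L)
    return(empty_labeled_pairs(source_tag))
  # positives with origin complexes
  origin <- list()
  for (cid in names(members)) {
    m <- sort(members[[cid]])
    if (length(m) < 2L) next
    comb <- utils::combn(m, 2L)
    keys <- paste(comb[1L, ], comb[2L, ], sep = "|")
    for (key in keys) origin[[key]] <- c(origin[[key]], cid)
  }
  pos_keys <- names(origin)
  # all pairs over the labeled-protein universe
  idx <- which(upper.tri(matrix(0, length(proteins), length(proteins))),
               arr.ind = TRUE)
  a <- proteins[idx[, 1L]]; b <- proteins[idx[, 2L]]
  keys <- paste(a, b, sep = "|")
  is_pos <- keys %in% pos_keys
  cid <- rep(NA_character_, length(keys))
  cid[is_pos] <- vapply(origin[keys[is_pos]], function(v) sort(v)[1L], "")
  df <- data.frame(protein_a = a, protein_b = b,
                   label = factor(ifelse(is_pos, "positive", "negative"),
                                  levels = c("negative", "positive")),
                   complex_id = cid, stringsAsFactors = FALSE)
  structure(df, origin = origin, source_tag = source_tag,
            class = c("labeled_pairs", "data.frame"))
}

empty_labeled_pairs <- function(source_tag = "native") {
  structure(data.frame(protein_a = character(0), protein_b = character(0),
                       label = factor(character(0),
                                      levels = c("negative", "positive")),
                       complex_id = character(0), stringsAsFactors = FALSE),
            origin = list(), source_tag = source_tag,
            class = c("labeled_pairs", "data.frame"))
}

#' Project a complex catalog into another species via one-to-one orthologs
#'
#' Members without a one-to-one ortholog are dropped; complexes shrinking
#' below two members are dropped; attrition counts are logged.
#'
#' @param catalog a \code{\link{complex_catalog}} in the source species.
#' @param map an \code{\link{ortholog_map}} (source -> target identifiers).
#' @return a \code{\link{complex_catalog}} in the target species.
#' @export
project_orthologs <- function(catalog, map) {
  projected <- lapply(catalog, function(m) {
    hit <- map[m]
    unname(hit[!is.na(hit)])
  })
  lost <- sum(vapply(catalog, length, 1L)) -
    sum(vapply(projected, length, 1L))
  message(lost, " member(s) without a one-to-one ortholog dropped")
  complex_catalog(projected, source = "custom")
}

#' Assign labeled pairs to cross-validation folds
#'
#' Complexes (not pairs) are randomly partitioned into \code{k} folds; each
#' positive pair inherits the fold of its source complex (the smallest
#' complex id when a pair belongs to several), so intra-complex information
#' never leaks between training and test folds. Negative pairs are
#' partitioned uniformly at random.
#'
#' @param labels a \code{\link{label_pairs}} result.
#' @param k number of folds (>= 2).
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return integer vector of fold ids (1..k), one per row of \code{labels}.
#' @export
split_folds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  cids <- sort(unique(labels$complex_id[!is.na(labels$complex_id)]))
  if (k > length(cids))
    stop("k (", k, ") exceeds the number of complexes (", length(cids), ")")
  with_seed(seed, {
    cfold <- stats::setNames(
      sample(rep_len(seq_len(k), length(cids))), cids)
    fold <- integer(nrow(labels))
    pos <- !is.na(labels$complex_id)
    fold[pos] <- cfold[labels$complex_id[pos]]
    fold[!pos] <- sample(rep_len(seq_len(k), sum(!pos)))
    fold
  })
}
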