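#' Remove flagged protein groups
#'
#' Drops rows flagged as reverse (decoy) hits, potential contaminants, or
#' identified only by modified peptides ("only identified by site"), the
#' standard MaxQuant quality-control step.
#'
#' @param matrix an \code{\link{elution_matrix}}.
#' @param flags data frame with logical columns \code{reverse},
#'   \code{contaminant}, \code{only_by_site} as produced by
#'   \code{\link{read_protein_groups}}, or \code{NULL} (nothing removed, with
#'   a warning).
#' @return the filtered \code{elution_matrix}; attribute \code{removed_flagged}
#'   carries the per-rule removal counts.
#' @export
filter_flagged <- function(matrix, flags) {
  if (is.null(flags)) {
    warning("no flag columns attached; nothing removed")
    attr(matrix, "removed_flagged") <-
      c(reverse = 0L, contaminant = 0L, only_by_site = 0L)
    return(matrix)
  }
  stopifnot(nrow(flags) == nrow(matrix))
  bad <- flags$reverse | flags$contaminant | flags$only_by_site
  counts <- c(reverse = sum(flags$reverse),
              contaminant = sum(flags$contaminant),
              only_by_site = sum(flags$only_by_site))
  if (all(bad)) warning("all rows flagged; returning empty matrix")
  out <- restore_elution(matrix[!bad, , drop = FALSE], matrix)
  attr(out, "removed_flagged") <- counts
  out
}

#' Collapse protein groups to gene symbols
#'
#' Maps protein-group identifiers to gene symbols and, where several groups
#' map to the same gene, retains only the chromatogram with the fewest
#' missing values. Ties are broken by larger total intensity, then
#' lexicographically smaller group identifier, so the result is deterministic
#' and invariant to input row order.
#'
#' @param matrix an \code{\link{elution_matrix}} keyed by protein-group ids.
#' @param gene_map named character vector or 2-column data frame
#'   (group id -> gene symbol). Unmapped rows are dropped (count logged).
#' @return \code{elution_matrix} with one row per gene; attributes
#'   \code{unmapped_dropped} (count) and \code{gene_map_used} (named vector,
#'   winning group id per gene).
#' @export
collapse_to_genes <- function(matrix, gene_map) {
  if (is.data.frame(gene_map))
    gene_map <- stats::setNames(trimws(as.character(gene_map[[2L]])),
                                trimws(as.character(gene_map[[1L]])))
  ids <- rownames(matrix)
  genes <- unname(gene_map[ids])
  mapped <- !is.na(genes) & nzchar(genes)
  if (!any(mapped)) stop("gene map covers no rows of the matrix")
  n_unmapped <- sum(!mapped)
  if (n_unmapped) message(n_unmapped, " unmapped protein group(s) dropped")
  sub <- matrix[mapped, , drop = FALSE]
  genes <- genes[mapped]
  n_missing <- rowSums(is.na(sub))
  total <- rowSums(sub, na.rm = TRUE)
  # deterministic winner per gene: fewest missing, then largest total
  # intensity, then smallest group id
  ord <- order(genes, n_missing, -total, rownames(sub))
  first <- !duplicated(genes[ord])
  win <- ord[first]
  out <- sub[win, , drop = FALSE]
  winners <- stats::setNames(rownames(out), genes[ord][first])
  rownames(out) <- genes[ord][first]
  out <- restore_elution(out, matrix)
  attr(out, "unmapped_dropped") <- n_unmapped
  attr(out, "gene_map_used") <- winners
  out
}

#' Filter sparsely quantified proteins
#'
#' Removes proteins quantified in fewer than \code{min_fractions} fractions
#' of the experiment (default 4, boundary inclusive: a protein seen in
#' exactly \code{min_fractions} fractions is retained).
#'
#' @param matrix an \code{\link{elution_matrix}}.
#' @param min_fractions minimum number of non-missing fractions (>= 1).
#' @return filtered \code{elution_matrix}; attribute \code{removed_sparse}
#'   carries the removal count.
#' @export
filter_min_fractions <- function(matrix, min_fractions = 4L) {
  stopifnot(min_fractions >= 1L)
  keep <- rowSums(!is.na(matrix)) >= min_fractions
  out <- restore_elution(matrix[keep, , drop = FALSE], matrix)
  attr(out, "removed_sparse") <- sum(!keep)
  out
}

#' Full chromatogram quality-control pipeline
#'
#' Applies, in fixed order: flagged-row removal, gene collapsing (optional),
#' and the minimum-fractions filter. The output is invariant to input row
#' order.
#'
#' @inheritParams filter_flagged
#' @inheritParams collapse_to_genes
#' @inheritParams filter_min_fractions
#' @return cleaned \code{elution_matrix}; attribute \code{provenance} is a
#'   named count vector satisfying
#'   \code{rows_in - rows_out == sum(removals)}.
#' @export
preprocess_experiment <- function(matrix, flags = NULL, gene_map = NULL,
                                  min_fractions = 4L) {
  rows_in <- nrow(matrix)
  m <- filter_flagged(matrix, flags)
  n_flagged <- rows_in - nrow(m)
  n_unmapped <- 0L; n_collapsed <- 0L
  if (!is.null(gene_map)) {
    before <- nrow(m)
    m <- collapse_to_genes(m, gene_map)
    n_unmapped <- attr(m, "unmapped_dropped")
    n_collapsed <- before - n_unmapped - nrow(m)
  }
  before <- nrow(m)
  m <- filter_min_fractions(m, min_fractions)
  n_sparse <- before - nrow(m)
  attr(m, "provenance") <- c(rows_in = rows_in, flagged = n_flagged,
                             unmapped = n_unmapped, collapsed = n_collapsed,
                             sparse = n_sparse, rows_out = nrow(m))
  m
}
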