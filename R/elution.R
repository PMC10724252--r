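#' Construct a CF-MS elution matrix
#'
#' An elution matrix holds one co-fractionation mass spectrometry (CF-MS)
#' experiment: a protein-by-fraction matrix of quantified intensities, where
#' each row is a protein "chromatogram" (elution profile). Missing values are
#' encoded as \code{NA} and are distinct from numeric zero: \code{NA} means
#' the protein was not quantified in that fraction, while \code{0} is a
#' quantified zero.
#'
#' @param intensities numeric matrix, proteins in rows, fractions in columns.
#'   Values must be non-negative or \code{NA}.
#' @param proteins character vector of protein/gene identifiers, one per row.
#'   Duplicates are not allowed. Defaults to existing rownames.
#' @param experiment_id single string naming the experiment.
#' @param species single string naming the species.
#' @param quant_type \code{"intensity"} or \code{"ratio"}.
#' @return a numeric matrix of class \code{"elution_matrix"} with
#'   \code{experiment_id}, \code{species} and \code{quant_type} attributes.
#' @examples
#' m <- elution_matrix(rbind(A = c(1, NA, 3), B = c(0, 2, 1)),
#'                     experiment_id = "e1", species = "human")
#' n_fractions(m)
#' @export
elution_matrix <- function(intensities, proteins = rownames(intensities),
                           experiment_id = "experiment1", species = "unknown",
                           quant_type = c("intensity", "ratio")) {
  quant_type <- match.arg(quant_type)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (ncol(intensities) < 1L) stop("elution matrix needs at least 1 fraction")
  if (is.null(proteins)) stop("protein identifiers are required")
  proteins <- trimws(as.character(proteins))
  if (anyDuplicated(proteins))
    stop("duplicate protein identifiers: ",
         paste(unique(proteins[duplicated(proteins)]), collapse = ", "))
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  rownames(intensities) <- proteins
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("fraction", seq_len(ncol(intensities)))
  structure(intensities,
            experiment_id = as.character(experiment_id),
            species = as.character(species),
            quant_type = quant_type,
            class = c("elution_matrix", "matrix", "array"))
}

#' @rdname elution_matrix
#' @param x an \code{elution_matrix}.
#' @export
is_elution_matrix <- function(x) inherits(x, "elution_matrix")

#' @rdname elution_matrix
#' @export
n_fractions <- function(x) ncol(x)

#' @rdname elution_matrix
#' @export
experiment_id <- function(x) attr(x, "experiment_id")

# rebuild class/attrs after base subsetting stripped them
restore_elution <- function(new, old) {
  structure(new,
            experiment_id = attr(old, "experiment_id"),
            species = attr(old, "species"),
            quant_type = attr(old, "quant_type"),
            class = c("elution_matrix", "matrix", "array"))
}

#' @export
print.elution_matrix <- function(x, ...) {
  cat(sprintf("CF-MS elution matrix '%s' (%s): %d proteins x %d fractions\n",
              attr(x, "experiment_id"), attr(x, "species"), nrow(x), ncol(x)))
  cat(sprintf("  missing values: %.1f%%\n", 100 * mean(is.na(x))))
  invisible(x)
}
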