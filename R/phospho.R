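# Phosphosite-level meta-analysis: Phospho(STY) Sites table parsing, site
# filtering, cross-experiment detection counts, fraction-count
# prioritization, residue-class proportions, hypergeometric kinase-substrate
# enrichment, and stoichiometry chromatograms with parent-peak assignment.

#' Read a MaxQuant Phospho(STY) Sites table
#'
#' Parses the tab-separated \code{Phospho(STY) Sites.txt} dialect: columns
#' \code{Protein}, \code{Position}, \code{Amino acid},
#' \code{Localization prob}, \code{Delta score}, the \code{Reverse} and
#' \code{Potential contaminant} flags, and per-fraction intensity columns.
#' The reader does not filter; see \code{\link{filter_sites}}.
#'
#' @param path file path.
#' @param intensity_column_prefix prefix of intensity columns.
#' @param zeros_are_missing convert numeric 0 to \code{NA}.
#' @param experiment_id experiment label attached to the table.
#' @return data frame of class \code{"phospho_sites"}: columns
#'   \code{protein}, \code{position}, \code{residue}, \code{loc_prob},
#'   \code{delta_score}, \code{reverse}, \code{contaminant}; attribute
#'   \code{intensities} is the aligned site x fraction matrix and
#'   \code{experiment_id} the experiment label.
#' @export
read_phospho_sites <- function(path, intensity_column_prefix = "Intensity ",
                               zeros_are_missing = TRUE,
                               experiment_id = basename(path)) {
  tab <- read_tsv_checked(path)
  need <- c("Protein", "Position", "Amino acid")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         " in '", path, "'")
  int_cols <- grep(paste0("^", quote_regex(intensity_column_prefix)),
                   names(tab), value = TRUE)
  if (!length(int_cols))
    stop("format error: no intensity columns in '", path, "'")
  mat <- matrix(NA_real_, nrow(tab), length(int_cols),
                dimnames = list(NULL, int_cols))
  for (j in seq_along(int_cols))
    mat[, j] <- parse_intensity_column(tab[[int_cols[j]]], path, int_cols[j])
  if (zeros_are_missing) mat[!is.na(mat) & mat == 0] <- NA_real_
  residue <- toupper(trimws(tab[["Amino acid"]]))
  if (!all(residue %in% c("S", "T", "Y")))
    stop("format error: phosphosite residue must be S, T or Y")
  get_flag <- function(col) {
    if (col %in% names(tab)) trimws(as.character(tab[[col]])) == "+"
    else {
      warning("flag column '", col, "' absent from '", path,
              "'; treating all rows as unflagged")
      rep(FALSE, nrow(tab))
    }
  }
  get_num <- function(col, default) {
    if (col %in% names(tab)) suppressWarnings(as.numeric(tab[[col]]))
    else rep(default, nrow(tab))
  }
  df <- data.frame(protein = trimws(tab[["Protein"]]),
                   position = as.integer(tab[["Position"]]),
                   residue = residue,
                   loc_prob = get_num("Localization prob", NA_real_),
                   delta_score = get_num("Delta score", NA_real_),
                   reverse = get_flag("Reverse"),
                   contaminant = get_flag("Potential contaminant"),
                   stringsAsFactors = FALSE)
  structure(df, intensities = mat, experiment_id = experiment_id,
            class = c("phospho_sites", "data.frame"))
}

#' @rdname read_phospho_sites
#' @param sites a \code{"phospho_sites"} object.
#' @export
write_phospho_sites <- function(sites, path) {
  df <- data.frame(Protein = sites$protein, Position = sites$position,
                   `Amino acid` = sites$residue,
                   `Localization prob` = sites$loc_prob,
                   `Delta score` = sites$delta_score,
                   Reverse = ifelse(sites$reverse, "+", ""),
                   `Potential contaminant` = ifelse(sites$contaminant, "+", ""),
                   check.names = FALSE, stringsAsFactors = FALSE)
  mat <- attr(sites, "intensities")
  for (j in seq_len(ncol(mat))) {
    col <- format(mat[, j], trim = TRUE, scientific = FALSE, digits = 15)
    col[is.na(mat[, j])] <- ""
    df[[colnames(mat)[j]]] <- col
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove flagged phosphosites
#'
#' Drops sites from reversed (decoy) peptides or potential contaminants.
#'
#' @param sites a \code{\link{read_phospho_sites}} result.
#' @return filtered \code{"phospho_sites"}; attribute \code{removed_flagged}
#'   carries the removal count.
#' @export
filter_sites <- function(sites) {
  bad <- sites$reverse | sites$contaminant
  if (all(bad)) warning("all phosphosites flagged; returning empty table")
  keep <- which(!bad)
  out <- as.data.frame(sites)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            intensities = attr(sites, "intensities")[keep, , drop = FALSE],
            experiment_id = attr(sites, "experiment_id"),
            removed_flagged = sum(bad),
            class = c("phospho_sites", "data.frame"))
}

site_key <- function(protein, position, residue) {
  paste(protein, position, residue, sep = "|")
}

#' Cross-experiment phosphosite detection counts
#'
#' Site identity across experiments is (protein, position, residue).
#' \code{n_fractions} counts non-missing intensity cells over all
#' experiments; \code{n_experiments} counts experiments with at least one
#' detected fraction.
#'
#' @param site_tables list of \code{"phospho_sites"} tables, one per
#'   experiment.
#' @return data frame: \code{protein}, \code{position}, \code{residue},
#'   \code{n_fractions}, \code{n_experiments}, one row per unique site.
#' @export
detection_counts <- function(site_tables) {
  if (inherits(site_tables, "phospho_sites"))
    site_tables <- list(site_tables)
  acc <- new.env(parent = emptyenv())
  for (tab in site_tables) {
    ints <- attr(tab, "intensities")
    nfr <- rowSums(!is.na(ints))
    keys <- site_key(tab$protein, tab$position, tab$residue)
    # aggregate duplicate rows within one experiment before counting it
    per_key <- tapply(nfr, keys, sum)
    for (key in names(per_key)) {
      prev <- acc[[key]]
      if (is.null(prev)) prev <- c(0L, 0L)
      acc[[key]] <- c(prev[1L] + per_key[[key]],
                      prev[2L] + (per_key[[key]] > 0L))
    }
  }
  keys <- sort(ls(acc))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  counts <- t(vapply(keys, function(k) acc[[k]], c(0, 0)))
  data.frame(protein = parts[, 1L], position = as.integer(parts[, 2L]),
             residue = parts[, 3L],
             n_fractions = as.integer(counts[, 1L]),
             n_experiments = as.integer(counts[, 2L]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Prioritize phosphosites by detection depth
#'
#' Sites detected in at least \code{min_fractions} fractions (default 5,
#' boundary inclusive) across all experiments are retained as candidate
#' regulatory sites.
#'
#' @param counts a \code{\link{detection_counts}} result.
#' @param min_fractions detection threshold.
#' @return subset of \code{counts}.
#' @export
prioritize <- function(counts, min_fractions = 5L) {
  counts[counts$n_fractions >= min_fractions, , drop = FALSE]
}

#' Residue-class proportions of phosphosites
#'
#' Fractions of phosphoserine (pS), phosphothreonine (pT) and
#' phosphotyrosine (pY) among unique sites (a site detected in several
#' experiments is counted once).
#'
#' @param sites data frame with \code{protein}, \code{position},
#'   \code{residue} columns (e.g. a \code{\link{detection_counts}} result),
#'   or a list of \code{"phospho_sites"} tables.
#' @return named numeric vector \code{c(pS=, pT=, pY=)} summing to 1.
#' @export
residue_proportions <- function(sites) {
  if (is.list(sites) && !is.data.frame(sites))
    sites <- detection_counts(sites)
  keys <- unique(site_key(sites$protein, sites$position, sites$residue))
  if (!length(keys)) stop("no phosphosites")
  res <- vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 3L)
  n <- length(res)
  c(pS = sum(res == "S") / n, pT = sum(res == "T") / n,
    pY = sum(res == "Y") / n)
}

#' Kinase-substrate enrichment by the hypergeometric test
#'
#' Tests, for each kinase, whether its annotated substrates are enriched
#' among a foreground set of phosphosites (e.g. sites detected in five or
#' more fractions) relative to a background (e.g. all sites ever detected).
#' The p-value is the hypergeometric upper tail P(X >= k) with the
#' background as population, the kinase's background substrates as
#' successes, and the foreground size as draws. Benjamini-Hochberg q-values
#' are reported across kinases.
#'
#' @param foreground,background data frames with \code{protein},
#'   \code{position}, \code{residue}; foreground must be a subset of
#'   background.
#' @param kinase_map named list: kinase -> character vector of substrate
#'   keys \code{"protein|position|residue"} (see internal key format of
#'   \code{\link{detection_counts}}).
#' @return data frame: \code{kinase}, \code{n_substrates_background},
#'   \code{overlap}, \code{expected}, \code{p_value}, \code{q_value}.
#'   Kinases with no background substrates are skipped (logged).
#' @export
ksea_hypergeometric <- function(foreground, background, kinase_map) {
  fg <- unique(site_key(foreground$protein, foreground$position,
                        foreground$residue))
  bg <- unique(site_key(background$protein, background$position,
                        background$residue))
  if (!all(fg %in% bg))
    stop("foreground must be a subset of background")
  rows <- list()
  skipped <- 0L
  for (kin in names(kinase_map)) {
    subs_bg <- intersect(kinase_map[[kin]], bg)
    if (!length(subs_bg)) { skipped <- skipped + 1L; next }
    k <- length(intersect(subs_bg, fg))
    m <- length(subs_bg)
    p <- stats::phyper(k - 1L, m, length(bg) - m, length(fg),
                       lower.tail = FALSE)
    rows[[kin]] <- data.frame(kinase = kin, n_substrates_background = m,
                              overlap = k,
                              expected = length(fg) * m / length(bg),
                              p_value = p, stringsAsFactors = FALSE)
  }
  if (skipped) message(skipped, " kinase(s) with no background substrates skipped")
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(kinase = character(0),
                      n_substrates_background = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Phosphosite stoichiometry chromatogram with parent-peak assignment
#'
#' Computes the per-fraction ratio of phosphosite (modified) to parent
#' protein (unmodified) intensity, and flags which chromatographic peak of
#' the parent protein the phosphosite co-elutes with: parent peaks are local
#' maxima of the 3-point moving-average-smoothed parent chromatogram with
#' prominence at least \code{min_prominence} of its maximum, and the flag is
#' the index (by fraction order) of the parent peak nearest to the
#' phosphosite's intensity maximum. This enables detecting phosphosites
#' specific to one of several assembly states of the parent.
#'
#' @param site_intensity numeric per-fraction phosphosite intensity
#'   (\code{NA} = missing).
#' @param parent_intensity numeric per-fraction parent-protein intensity of
#'   the same experiment and length.
#' @param smooth_window moving-average window for parent peak detection.
#' @param min_prominence minimum peak height relative to the smoothed
#'   maximum.
#' @return list: \code{stoichiometry} (per-fraction ratio, \code{NA} where
#'   either is missing), \code{parent_peaks} (fraction indices),
#'   \code{peak_flag} (index into \code{parent_peaks}, or \code{NA} if the
#'   site and parent share no fraction, logged).
#' @export
stoichiometry_profile <- function(site_intensity, parent_intensity,
                                  smooth_window = 3L, min_prominence = 0.1) {
  if (length(site_intensity) != length(parent_intensity))
    stop("site and parent chromatograms must have equal length")
  ratio <- ifelse(!is.na(site_intensity) & !is.na(parent_intensity),
                  site_intensity / parent_intensity, NA_real_)
  peaks <- find_peaks(parent_intensity, smooth_window, min_prominence)
  if (all(is.na(site_intensity)) || !any(!is.na(site_intensity) &
                                           !is.na(parent_intensity))) {
    message("no overlapping fractions; peak flag undefined")
    flag <- NA_integer_
  } else {
    site_max <- which.max(ifelse(is.na(site_intensity), -Inf, site_intensity))
    flag <- if (length(peaks)) which.min(abs(peaks - site_max))
            else NA_integer_
  }
  list(stoichiometry = ratio, parent_peaks = peaks, peak_flag = flag)
}

# local maxima of the moving-average-smoothed chromatogram, missing treated
# as zero, prominence filter relative to the smoothed maximum
find_peaks <- function(x, smooth_window = 3L, min_prominence = 0.1) {
  x[is.na(x)] <- 0
  n <- length(x)
  if (n < 2L) return(if (n == 1L && x > 0) 1L else integer(0))
  half <- (smooth_window - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), 0)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1L) sm[i] > sm[i - 1L] else sm[i] > sm[i + 1L]
    right <- if (i < n) sm[i] >= sm[i + 1L] else TRUE
    is_peak[i] <- left && right
  }
  peaks <- which(is_peak & sm >= min_prominence * max(sm))
  peaks
}
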