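#' Read a MaxQuant proteinGroups table as an elution matrix
#'
#' Parses the tab-separated \code{proteinGroups.txt} dialect: one row per
#' protein group, one intensity column per chromatographic fraction, plus the
#' MaxQuant quality-flag columns (\code{Reverse}, \code{Potential contaminant},
#' \code{Only identified by site}). The reader does not filter anything; flags
#' are attached for \code{\link{filter_flagged}}.
#'
#' MaxQuant writes 0 for not-quantified values, whereas the simulator and the
#' downstream similarity measures need missing to be distinguishable from a
#' quantified zero. With \code{zeros_are_missing = TRUE} (the default for this
#' dialect) numeric zeros are converted to \code{NA}; empty cells and literal
#' \code{"NA"} always parse as missing.
#'
#' @param path path to a tab-separated protein-groups file.
#' @param intensity_column_prefix prefix identifying intensity columns
#'   (default \code{"Intensity "}); fraction order is the column order.
#' @param id_column identifier column; the first of the candidates present is
#'   used.
#' @param zeros_are_missing convert numeric 0 to \code{NA} (MaxQuant
#'   convention).
#' @param experiment_id,species,quant_type metadata passed to
#'   \code{\link{elution_matrix}}.
#' @return a list with elements \code{matrix} (an \code{elution_matrix}) and
#'   \code{flags} (data frame with logical columns \code{reverse},
#'   \code{contaminant}, \code{only_by_site}, one row per protein group).
#' @export
read_protein_groups <- function(path, intensity_column_prefix = "Intensity ",
                                id_column = c("Majority protein IDs",
                                              "Protein IDs", "Protein"),
                                zeros_are_missing = TRUE,
                                experiment_id = basename(path),
                                species = "unknown",
                                quant_type = "intensity") {
  tab <- read_tsv_checked(path)
  idc <- intersect(id_column, names(tab))
  if (length(idc) == 0L)
    stop("format error: no identifier column found in '", path,
         "' (looked for: ", paste(id_column, collapse = ", "), ")")
  ids <- trimws(tab[[idc[1L]]])
  int_cols <- grep(paste0("^", quote_regex(intensity_column_prefix)),
                   names(tab), value = TRUE)
  if (length(int_cols) == 0L)
    stop("format error: no intensity columns with prefix '",
         intensity_column_prefix, "' in '", path, "'")
  mat <- matrix(NA_real_, nrow(tab), length(int_cols),
                dimnames = list(NULL, int_cols))
  for (j in seq_along(int_cols)) {
    raw <- tab[[int_cols[j]]]
    val <- parse_intensity_column(raw, path, int_cols[j])
    mat[, j] <- val
  }
  if (zeros_are_missing) mat[!is.na(mat) & mat == 0] <- NA_real_
  flags <- extract_flags(tab, path)
  list(matrix = elution_matrix(mat, proteins = ids,
                               experiment_id = experiment_id,
                               species = species, quant_type = quant_type),
       flags = flags)
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "",
                    na.strings = character(0), comment.char = "")
}

quote_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

parse_intensity_column <- function(raw, path, column) {
  raw <- trimws(as.character(raw))
  missing <- raw == "" | raw == "NA"
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!missing & is.na(val))
  if (length(bad))
    stop("format error: non-numeric intensity at row ", bad[1L],
         ", column '", column, "' of '", path, "'")
  val[missing] <- NA_real_
  val
}

extract_flags <- function(tab, path) {
  flag_cols <- c(reverse = "Reverse", contaminant = "Potential contaminant",
                 only_by_site = "Only identified by site")
  out <- list()
  for (nm in names(flag_cols)) {
    col <- flag_cols[[nm]]
    if (col %in% names(tab)) {
      out[[nm]] <- trimws(as.character(tab[[col]])) == "+"
    } else {
      warning("flag column '", col, "' absent from '", path,
              "'; treating all rows as unflagged")
      out[[nm]] <- rep(FALSE, nrow(tab))
    }
  }
  as.data.frame(out)
}

#' Write an elution matrix in the proteinGroups dialect
#'
#' Inverse of \code{\link{read_protein_groups}}. Missing values are written
#' as empty cells, so the missing-vs-zero distinction survives a round trip
#' (read back with \code{zeros_are_missing = FALSE}).
#'
#' @param matrix an \code{\link{elution_matrix}}.
#' @param path output path.
#' @param flags optional flag data frame (as from the reader); written as
#'   the three MaxQuant flag columns.
#' @export
write_protein_groups <- function(matrix, path, flags = NULL) {
  df <- data.frame(`Majority protein IDs` = rownames(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(flags))
    flags <- data.frame(reverse = rep(FALSE, nrow(matrix)),
                        contaminant = FALSE, only_by_site = FALSE)
  df[["Reverse"]] <- ifelse(flags$reverse, "+", "")
  df[["Potential contaminant"]] <- ifelse(flags$contaminant, "+", "")
  df[["Only identified by site"]] <- ifelse(flags$only_by_site, "+", "")
  vals <- unclass(matrix)
  cn <- colnames(vals)
  if (!all(startsWith(cn, "Intensity"))) cn <- paste0("Intensity ", cn)
  for (j in seq_len(ncol(vals))) {
    col <- format(vals[, j], trim = TRUE, scientific = FALSE, digits = 15)
    col[is.na(vals[, j])] <- ""
    df[[cn[j]]] <- col
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a protein-complex catalog
#'
#' A catalog maps complex identifiers to member sets. Member sets are
#' deduplicated, complexes with fewer than two members are dropped, and
#' redundant entries (two complexes with identical member sets) are collapsed
#' to the first occurrence.
#'
#' @param complexes named list of character vectors (complex id -> members).
#' @param source provenance tag.
#' @return named list of class \code{"complex_catalog"}.
#' @export
complex_catalog <- function(complexes,
                            source = c("custom", "corum_like", "ecocyc_like")) {
  source <- match.arg(source)
  if (is.null(names(complexes)) || any(names(complexes) == ""))
    stop("complexes must be a named list")
  complexes <- lapply(complexes, function(m) unique(trimws(as.character(m))))
  small <- vapply(complexes, length, 1L) < 2L
  if (any(small))
    message(sum(small), " complex(es) with <2 members dropped")
  complexes <- complexes[!small]
  # redundant entries removed: identical member sets collapse to one
  keys <- vapply(complexes, function(m) paste(sort(m), collapse = "\r"), "")
  dup <- duplicated(keys)
  if (any(dup))
    message(sum(dup), " redundant complex(es) (identical member sets) removed")
  structure(complexes[!dup], source = source,
            class = c("complex_catalog", "list"))
}

#' Read a protein-complex catalog
#'
#' Supports two tab-separated dialects: \code{"corum_like"}
#' (CORUM \code{coreComplexes.txt}: a complex id/name column plus a
#' semicolon-delimited subunit column) and \code{"ecocyc_like"}
#' (EcoCyc \code{protcplxs.col}: one complex per row, the first column the
#' complex name, subsequent non-empty columns the members).
#'
#' @param path file path.
#' @param dialect \code{"corum_like"} or \code{"ecocyc_like"}.
#' @return a \code{\link{complex_catalog}}.
#' @export
read_complexes <- function(path, dialect = c("corum_like", "ecocyc_like")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("config error: unknown complex dialect"))
  if (dialect == "corum_like") {
    tab <- read_tsv_checked(path)
    idc <- intersect(c("ComplexID", "Complex id", "ComplexName", "Complex name"),
                     names(tab))
    sub <- intersect(c("subunits(Gene name)", "subunits(UniProt IDs)",
                       "Subunits", "subunits"), names(tab))
    if (length(idc) == 0L || length(sub) == 0L)
      stop("format error: corum_like file needs a complex-id column and a ",
           "subunit column; found: ", paste(names(tab), collapse = ", "))
    members <- strsplit(as.character(tab[[sub[1L]]]), ";", fixed = TRUE)
    names(members) <- make.unique(as.character(tab[[idc[1L]]]))
    complex_catalog(members, source = "corum_like")
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    members <- lapply(parts, function(p) {
      p <- trimws(p[-1L])
      p[nzchar(p)]
    })
    names(members) <- vapply(parts, function(p) trimws(p[1L]), "")
    complex_catalog(members, source = "ecocyc_like")
  }
}

#' @rdname read_complexes
#' @param catalog a \code{\link{complex_catalog}}.
#' @export
write_complexes <- function(catalog, path) {
  df <- data.frame(ComplexID = names(catalog),
                   Subunits = vapply(catalog, paste, "", collapse = ";"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[2L] <- "subunits(Gene name)"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GMT annotation sets
#'
#' Standard GMT: one term per line, tab-separated as
#' \code{term<TAB>description<TAB>member...}. Empty member sets are dropped.
#'
#' @param path file path.
#' @return named list (term id -> character vector of annotated proteins)
#'   with a \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stop("format error: GMT line ", bad[1L], " has fewer than 3 fields")
  terms <- lapply(parts, function(p) unique(trimws(p[-(1:2)])))
  names(terms) <- vapply(parts, function(p) trimws(p[1L]), "")
  attr(terms, "descriptions") <- vapply(parts, function(p) p[2L], "")
  terms[vapply(terms, length, 1L) > 0L]
}

#' @rdname read_gmt
#' @param terms named list of member vectors.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(t)
    paste(c(t, t, terms[[t]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Alphabetized protein-pair edge lists
#'
#' Edges are unordered protein pairs stored in alphabetized orientation
#' (\code{protein_a < protein_b}), each pair exactly once, no self-loops.
#'
#' @param protein_a,protein_b character vectors of endpoints.
#' @param score optional numeric per-edge score.
#' @return data frame of class \code{"edge_list"} with columns
#'   \code{protein_a}, \code{protein_b} and optionally \code{score}.
#' @export
edge_list <- function(protein_a, protein_b, score = NULL) {
  a <- trimws(as.character(protein_a)); b <- trimws(as.character(protein_b))
  keep <- a != b
  if (any(!keep)) message(sum(!keep), " self-loop(s) dropped")
  a <- a[keep]; b <- b[keep]
  if (!is.null(score)) score <- score[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  dup <- duplicated(paste(df$protein_a, df$protein_b, sep = "\r"))
  df <- df[!dup, , drop = FALSE]
  # canonical row order: reading a shuffled list equals reading a sorted one
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("edge_list", "data.frame")
  df
}

pair_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, sep = "|")
}

#' @rdname edge_list
#' @param path file path for a 2-3 column tab-separated edge list.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(edge_list(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop("format error: edge-list line ", bad[1L], " has ", nf[bad[1L]],
         " fields (expected 2 or 3)")
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  score <- if (all(nf == 3L)) as.numeric(vapply(parts, `[`, "", 3L)) else NULL
  edge_list(a, b, score)
}

#' @rdname edge_list
#' @param edges an \code{edge_list}.
#' @export
write_edge_list <- function(edges, path) {
  cols <- c("protein_a", "protein_b", intersect("score", names(edges)))
  utils::write.table(as.data.frame(edges)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a one-to-one ortholog map
#'
#' Two-column tab-separated table: source-species identifier, target-species
#' identifier. Under the \code{one_to_one_only} policy (the only one
#' supported), any source mapping to several targets or target mapped from
#' several sources is dropped entirely, so the returned map is injective in
#' both directions.
#'
#' @param path file path.
#' @return named character vector (source -> target) of class
#'   \code{"ortholog_map"}.
#' @export
read_ortholog_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop("format error: ortholog-map line ", bad[1L], " has fewer than 2 fields")
  src <- trimws(vapply(parts, `[`, "", 1L))
  tgt <- trimws(vapply(parts, `[`, "", 2L))
  ortholog_map(src, tgt)
}

#' @rdname read_ortholog_map
#' @param source,target parallel identifier vectors.
#' @export
ortholog_map <- function(source, target) {
  keep <- !(source %in% source[duplicated(source)]) &
          !(target %in% target[duplicated(target)])
  if (any(!keep))
    message(sum(!keep), " non-one-to-one ortholog row(s) dropped")
  structure(stats::setNames(target[keep], source[keep]),
            policy = "one_to_one_only", class = "ortholog_map")
}

#' @rdname read_ortholog_map
#' @param map an \code{ortholog_map}.
#' @param path output path.
#' @export
write_ortholog_map <- function(map, path) {
  writeLines(paste(names(map), unname(unclass(map)), sep = "\t"), path)
  invisible(path)
}
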