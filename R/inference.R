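# Supervised interactome inference: feature-tier assembly, cross-validated
# random-forest scoring of protein pairs, ranked-list precision, precision
# and top-k thresholding, labeled-pair data augmentation, and cross-species
# classifier transfer.

MEASURE_ORDER <- c("distance_correlation", "weighted_cross_correlation",
                   "cosine", "mutual_information")

#' Feature tier rule: measures per experiment
#'
#' The number of similarity measures computed per CF-MS experiment depends on
#' how many experiments exist for the species: more than ten experiments,
#' one measure (distance correlation); six to ten, two measures (adding
#' weighted cross-correlation); five or fewer, all four optimal measures.
#' Measures are returned in descending order of optimality.
#'
#' @param n_experiments number of CF-MS experiments for the species.
#' @return character vector of measure names.
#' @export
tiered_measures <- function(n_experiments) {
  stopifnot(n_experiments >= 1L)
  if (n_experiments > 10L) MEASURE_ORDER[1L]
  else if (n_experiments >= 6L) MEASURE_ORDER[1:2]
  else MEASURE_ORDER
}

#' Assemble a per-pair feature table across experiments
#'
#' Computes one feature column per (experiment, measure) combination. The
#' pair universe is the union over experiments of all pairs of co-detected
#' proteins; a pair gets the missing-feature marker (\code{NA}) in columns
#' of experiments where either protein is absent.
#'
#' @param experiments list of \code{\link{elution_matrix}} objects
#'   (preprocessed).
#' @param measures character vector of measure names; default applies the
#'   tier rule (\code{\link{tiered_measures}}) to \code{length(experiments)}.
#' @param L,B,sigma measure parameters (see \code{\link{measure_spec}}).
#' @param seed integer seed for the near-zero-noise stream.
#' @return data frame of class \code{"cf_features"}: columns
#'   \code{protein_a}, \code{protein_b}, then one numeric column per
#'   (experiment, measure) named \code{<experiment>.<measure>}; attribute
#'   \code{manifest} records the experiment and measure of each column.
#' @export
feature_table <- function(experiments, measures = NULL, L = 1L, B = 10L,
                          sigma = 1e-4, seed = 1L) {
  stopifnot(length(experiments) >= 1L)
  if (is.null(measures)) measures <- tiered_measures(length(experiments))
  stopifnot(all(measures %in% c(MEASURE_ORDER, "pearson")))
  exp_ids <- vapply(experiments, function(e) attr(e, "experiment_id"), "")
  if (anyDuplicated(exp_ids)) exp_ids <- make.unique(exp_ids)
  per_exp <- vector("list", length(experiments))
  for (i in seq_along(experiments)) {
    specs <- lapply(measures, function(m)
      measure_spec(m, L = L, B = B, sigma = sigma,
                   seed = seed + 7919L * i))
    per_exp[[i]] <- pairwise_features(experiments[[i]], specs)
  }
  keys <- unique(unlist(lapply(per_exp, function(f)
    paste(f$protein_a, f$protein_b, sep = "|"))))
  keys <- sort(keys)
  ab <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(protein_a = ab[, 1L], protein_b = ab[, 2L],
                    stringsAsFactors = FALSE)
  manifest <- data.frame(column = character(0), experiment = character(0),
                         measure = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(experiments)) {
    f <- per_exp[[i]]
    m <- match(keys, paste(f$protein_a, f$protein_b, sep = "|"))
    for (meas in measures) {
      col <- paste(exp_ids[i], meas, sep = ".")
      out[[col]] <- f[[meas]][m]
      manifest <- rbind(manifest,
                        data.frame(column = col, experiment = exp_ids[i],
                                   measure = meas, stringsAsFactors = FALSE))
    }
  }
  structure(out, manifest = manifest,
            class = c("cf_features", "data.frame"))
}

feature_columns <- function(features) {
  setdiff(names(features), c("protein_a", "protein_b"))
}

# zero-fill missing-feature markers just before model fitting; median fill
# available behind a flag
fill_features <- function(mat, fill = c("zero", "median")) {
  fill <- match.arg(fill)
  if (fill == "zero") {
    mat[is.na(mat)] <- 0
  } else {
    for (j in seq_len(ncol(mat))) {
      med <- stats::median(mat[, j], na.rm = TRUE)
      if (is.na(med)) med <- 0
      mat[is.na(mat[, j]), j] <- med
    }
  }
  stopifnot(!anyNA(mat))
  mat
}

#' Cross-validated random-forest scoring of protein pairs
#'
#' The central fitting function. Labeled pairs are split into \code{k}
#' cross-validation folds at the level of complexes
#' (\code{\link{split_folds}}); for each fold a random forest is trained on
#' the out-of-fold labeled pairs and scores the pairs assigned to that fold,
#' so no labeled pair is ever scored by a model that saw it (or its
#' complex) in training. Unlabeled pairs are scored by the mean over the
#' \code{k} fold models. The result is the full ranked interaction list with
#' cumulative precision over labeled pairs.
#'
#' @param features a \code{\link{feature_table}}.
#' @param labels a \code{\link{label_pairs}} result; labeled pairs absent
#'   from the feature table are ignored.
#' @param k number of cross-validation folds.
#' @param n_trees trees per random forest.
#' @param seed integer root seed; fold split, forest fitting and any
#'   subsampling derive from it, making the ranking reproducible.
#' @param negative_ratio optional: subsample negatives to this multiple of
#'   the positive count before training (default: train on all).
#' @param fill missing-feature fill applied immediately before fitting.
#' @param extra_train optional list(x = numeric matrix, y = factor) of
#'   additional training-only rows (used by \code{\link{augment_training}});
#'   never scored.
#' @return an object of class \code{"ranked_network"}: a data frame with
#'   columns \code{protein_a}, \code{protein_b}, \code{score}, \code{label}
#'   (\code{NA} for unlabeled pairs) and \code{precision} (cumulative, over
#'   labeled pairs), ordered by decreasing score with ties broken by
#'   alphabetized pair. Attributes: \code{models} (fold forests),
#'   \code{audit} (seeds, fold sizes, hyperparameters).
#' @export
train_score_cv <- function(features, labels, k = 5L, n_trees = 100L,
                           seed = 1L, negative_ratio = NULL,
                           fill = "zero", extra_train = NULL) {
  fcols <- feature_columns(features)
  X <- fill_features(as.matrix(features[, fcols, drop = FALSE]), fill)
  fkey <- paste(features$protein_a, features$protein_b, sep = "|")
  lkey <- paste(labels$protein_a, labels$protein_b, sep = "|")
  present <- lkey %in% fkey
  lab <- labels[present, , drop = FALSE]
  class(lab) <- c("labeled_pairs", "data.frame")
  attr(lab, "origin") <- attr(labels, "origin")
  if (!nrow(lab) || length(unique(lab$label)) < 2L)
    stop("need labeled pairs of both classes among the feature rows")
  li <- match(paste(lab$protein_a, lab$protein_b, sep = "|"), fkey)
  fold <- split_folds(lab, k = k, seed = seed + 1L)
  if (!is.null(negative_ratio)) {
    keep <- subsample_negatives(lab$label, negative_ratio, seed + 2L)
  } else keep <- rep(TRUE, nrow(lab))

  score <- rep(NA_real_, nrow(features))
  unlab_idx <- setdiff(seq_len(nrow(features)), li)
  unlab_acc <- rep(0, length(unlab_idx))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f & keep)
    te <- which(fold == f)
    ytr <- factor(lab$label[tr], levels = c("negative", "positive"))
    if (length(unique(ytr)) < 2L)
      stop("training fold ", f, " contains a single class; use fewer folds")
    rf <- with_seed(seed + 100L + f,
                    randomForest::randomForest(x = rbind(X[li[tr], , drop = FALSE],
                                                         if (!is.null(extra_train)) extra_train$x),
                                               y = if (is.null(extra_train)) ytr
                                                   else factor(c(as.character(ytr),
                                                                 as.character(extra_train$y)),
                                                               levels = c("negative", "positive")),
                                               ntree = n_trees))
    models[[f]] <- rf
    if (length(te))
      score[li[te]] <- predict_prob(rf, X[li[te], , drop = FALSE])
    if (length(unlab_idx))
      unlab_acc <- unlab_acc + predict_prob(rf, X[unlab_idx, , drop = FALSE])
  }
  score[unlab_idx] <- unlab_acc / k

  lab_vec <- rep(NA_character_, nrow(features))
  lab_vec[li] <- as.character(lab$label)
  audit <- list(seed = seed, k = k, n_trees = n_trees,
                fill = fill,
                mtry = if (length(models)) models[[1L]]$mtry else NA,
                n_labeled = nrow(lab),
                n_positive = sum(lab$label == "positive"),
                n_negative = sum(lab$label == "negative"),
                fold_sizes = as.integer(table(factor(fold, levels = seq_len(k)))),
                n_extra_train = if (is.null(extra_train)) 0L
                                else nrow(extra_train$x),
                feature_columns = fcols)
  make_ranked_network(features$protein_a, features$protein_b, score, lab_vec,
                      models = models, audit = audit)
}

subsample_negatives <- function(label, ratio, seed) {
  stopifnot(ratio > 0)
  n_pos <- sum(label == "positive")
  neg <- which(label == "negative")
  n_keep <- min(length(neg), floor(ratio * n_pos))
  keep <- rep(TRUE, length(label))
  drop <- with_seed(seed, sample(neg, length(neg) - n_keep))
  keep[drop] <- FALSE
  keep
}

predict_prob <- function(rf, x) {
  unname(stats::predict(rf, x, type = "prob")[, "positive"])
}

make_ranked_network <- function(a, b, score, label, models = NULL,
                                audit = list()) {
  ord <- order(-score, a, b)
  df <- data.frame(protein_a = a[ord], protein_b = b[ord],
                   score = score[ord], label = label[ord],
                   stringsAsFactors = FALSE)
  df$precision <- precision_curve(df$label)
  rownames(df) <- NULL
  structure(df, models = models, audit = audit,
            class = c("ranked_network", "data.frame"))
}

#' Cumulative precision along a ranked interaction list
#'
#' At rank r, precision is TP/(TP+FP) among the labeled pairs within the top
#' r; unlabeled pairs do not change the value. Before the first labeled pair
#' the precision is undefined (\code{NA}).
#'
#' @param labels character vector in rank order: \code{"positive"},
#'   \code{"negative"} or \code{NA} (unlabeled).
#' @return numeric vector of cumulative precisions.
#' @export
precision_curve <- function(labels) {
  tp <- cumsum(!is.na(labels) & labels == "positive")
  n_lab <- cumsum(!is.na(labels))
  prec <- ifelse(n_lab > 0, tp / n_lab, NA_real_)
  prec
}

#' Threshold a ranked network at a target precision
#'
#' Retains the top k ranks, where k is the deepest rank whose cumulative
#' precision meets the target (default 50%). Returns an empty network if the
#' target is never reached.
#'
#' @param ranked a \code{\link{train_score_cv}} result (or any data frame
#'   with \code{protein_a}, \code{protein_b}, \code{score},
#'   \code{precision}).
#' @param target_precision value in (0, 1].
#' @return an \code{\link{edge_list}} with scores.
#' @export
threshold_network <- function(ranked, target_precision = 0.5) {
  stopifnot(target_precision > 0, target_precision <= 1)
  ok <- which(!is.na(ranked$precision) &
                ranked$precision >= target_precision)
  if (!length(ok))
    return(edge_list(character(0), character(0)))
  k <- max(ok)
  edge_list(ranked$protein_a[seq_len(k)], ranked$protein_b[seq_len(k)],
            ranked$score[seq_len(k)])
}

#' Threshold a ranked network at the top k interactions
#'
#' @param ranked as in \code{\link{threshold_network}}.
#' @param k number of top-ranked pairs to retain (e.g. 5000 or 10000).
#' @return an \code{\link{edge_list}} with scores.
#' @export
threshold_topk <- function(ranked, k) {
  stopifnot(k >= 1L)
  if (k > nrow(ranked)) {
    warning("k exceeds list length; returning the whole list")
    k <- nrow(ranked)
  }
  idx <- seq_len(k)
  edge_list(ranked$protein_a[idx], ranked$protein_b[idx], ranked$score[idx])
}

#' Area under the ROC curve
#'
#' Exact rank-based (Mann-Whitney) AUROC with average ranks for ties.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical, or character \code{"positive"}/\code{"negative"};
#'   \code{NA} entries are dropped.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  if (!is.logical(labels)) labels <- labels == "positive"
  ok <- !is.na(labels) & !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("need both classes to compute AUROC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Augment a scarce training set with external labeled pairs
#'
#' For species with few known complexes, a random fraction of labeled pairs
#' from external CF-MS experiments is injected into the training data, in
#' proportion to the number of native labeled pairs
#' (\code{floor(proportion * n_labeled)}). Each external experiment is
#' mapped uniformly at random onto one of the target experiments, so
#' injected feature vectors occupy the same columns as native ones. Injected
#' examples are used only during model training and are discarded
#' afterwards: they never appear in the scored output and never influence
#' the precision curve.
#'
#' @param features_target target-species \code{\link{feature_table}}.
#' @param labels_target target-species \code{\link{label_pairs}} result.
#' @param external_pool data frame of external labeled feature rows:
#'   columns \code{protein_a}, \code{protein_b}, \code{label},
#'   \code{experiment}, plus one column per measure (see
#'   \code{\link{simulate_external_pool}}).
#' @param proportion injected fraction of the native labeled-pair count
#'   (default 0.33).
#' @param seed,k,n_trees,fill as in \code{\link{train_score_cv}}.
#' @return a \code{"ranked_network"} over target pairs only; the audit
#'   attribute records \code{n_injected} and the experiment mapping.
#' @export
augment_training <- function(features_target, labels_target, external_pool,
                             proportion = 0.33, seed = 1L, k = 5L,
                             n_trees = 100L, fill = "zero") {
  if (proportion < 0) stop("proportion must be non-negative")
  manifest <- attr(features_target, "manifest")
  measures <- unique(manifest$measure)
  if (!all(measures %in% names(external_pool)))
    stop("external pool lacks measures required by the target manifest: ",
         paste(setdiff(measures, names(external_pool)), collapse = ", "))
  fkey <- paste(features_target$protein_a, features_target$protein_b,
                sep = "|")
  lkey <- paste(labels_target$protein_a, labels_target$protein_b, sep = "|")
  n_target_labeled <- sum(lkey %in% fkey)
  n_inject <- floor(proportion * n_target_labeled)
  pool_pairs <- unique(external_pool[, c("protein_a", "protein_b", "label")])
  if (n_inject > nrow(pool_pairs))
    stop("external pool too small: ", nrow(pool_pairs), " labeled pairs, ",
         n_inject, " requested")
  target_exps <- unique(manifest$experiment)
  ext_exps <- sort(unique(external_pool$experiment))
  sel <- with_seed(seed + 31L, sample(nrow(pool_pairs), n_inject))
  # map external experiments at random onto target experiments, then pick
  # one source experiment per target column
  ext_to_target <- with_seed(seed + 32L,
    sample(target_exps, length(ext_exps), replace = TRUE))
  source_for_target <- with_seed(seed + 33L, vapply(target_exps, function(te) {
    cand <- ext_exps[ext_to_target == te]
    if (!length(cand)) cand <- ext_exps
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, ""))
  inj <- pool_pairs[sel, , drop = FALSE]
  inj_key <- paste(inj$protein_a, inj$protein_b, sep = "|")
  xcols <- feature_columns(features_target)
  xmat <- matrix(NA_real_, n_inject, length(xcols),
                 dimnames = list(NULL, xcols))
  pool_key <- paste(external_pool$protein_a, external_pool$protein_b,
                    sep = "|")
  for (j in seq_along(xcols)) {
    te <- manifest$experiment[manifest$column == xcols[j]]
    meas <- manifest$measure[manifest$column == xcols[j]]
    src <- source_for_target[[te]]
    rows <- match(paste(inj_key, src), paste(pool_key, external_pool$experiment))
    xmat[, j] <- external_pool[[meas]][rows]
  }
  xmat <- fill_features(xmat, fill)
  extra <- list(x = xmat,
                y = factor(inj$label, levels = c("negative", "positive")))
  net <- train_score_cv(features_target, labels_target, k = k,
                        n_trees = n_trees, seed = seed, fill = fill,
                        extra_train = extra)
  aud <- attr(net, "audit")
  aud$n_injected <- n_inject
  aud$proportion <- proportion
  aud$experiment_mapping <- stats::setNames(ext_to_target, ext_exps)
  attr(net, "audit") <- aud
  net
}

#' Train a transferable pair classifier on external-species data
#'
#' For target species without a usable training set of protein complexes, a
#' random forest is trained entirely on labeled pairs from external (e.g.
#' human and mouse) experiments. Each external labeled pair is assigned a
#' seeded random tuple of \code{target_replicate_count} external experiments
#' that supply its feature vector, matching the replicate structure of the
#' target species.
#'
#' @param external_pool data frame as in \code{\link{augment_training}}.
#' @param target_replicate_count number of experiments (replicates) acquired
#'   in the target species.
#' @param measures measures to use (default: all measure columns present in
#'   the pool).
#' @param n_trees,seed,fill as in \code{\link{train_score_cv}}.
#' @return object of class \code{"cf_transfer_model"}.
#' @export
transfer_train <- function(external_pool, target_replicate_count,
                           measures = NULL, n_trees = 100L, seed = 1L,
                           fill = "zero") {
  stopifnot(target_replicate_count >= 1L)
  if (is.null(measures))
    measures <- intersect(MEASURE_ORDER, names(external_pool))
  stopifnot(length(measures) >= 1L)
  ext_exps <- sort(unique(external_pool$experiment))
  replace <- length(ext_exps) < target_replicate_count
  if (replace)
    warning("fewer external experiments (", length(ext_exps),
            ") than target replicates (", target_replicate_count,
            "); sampling with replacement")
  pairs <- unique(external_pool[, c("protein_a", "protein_b", "label")])
  pool_key <- paste(external_pool$protein_a, external_pool$protein_b,
                    external_pool$experiment)
  assign <- with_seed(seed + 41L, t(vapply(seq_len(nrow(pairs)), function(i)
    sample(ext_exps, target_replicate_count, replace = replace),
    character(target_replicate_count))))
  if (target_replicate_count == 1L) assign <- matrix(assign, ncol = 1L)
  xcols <- as.vector(t(outer(paste0("rep", seq_len(target_replicate_count)),
                             measures, paste, sep = ".")))
  X <- matrix(NA_real_, nrow(pairs), length(xcols),
              dimnames = list(NULL, xcols))
  pk <- paste(pairs$protein_a, pairs$protein_b)
  for (r in seq_len(target_replicate_count)) {
    rows <- match(paste(pk, assign[, r]), pool_key)
    for (m in seq_along(measures)) {
      X[, (r - 1L) * length(measures) + m] <-
        external_pool[[measures[m]]][rows]
    }
  }
  X <- fill_features(X, fill)
  y <- factor(pairs$label, levels = c("negative", "positive"))
  if (length(unique(y)) < 2L)
    stop("external pool must contain both classes")
  rf <- with_seed(seed + 42L,
                  randomForest::randomForest(x = X, y = y, ntree = n_trees))
  structure(list(forest = rf, replicate_count = target_replicate_count,
                 measures = measures, fill = fill,
                 audit = list(seed = seed, n_trees = n_trees,
                              mtry = rf$mtry, n_training_pairs = nrow(pairs),
                              sampled_with_replacement = replace)),
            class = "cf_transfer_model")
}

#' Score target-species pairs with a transferred classifier
#'
#' @param model a \code{\link{transfer_train}} result.
#' @param features_target target \code{\link{feature_table}}; must have
#'   exactly \code{model$replicate_count} experiments, each with the model's
#'   measures.
#' @param labels optional \code{\link{label_pairs}} result used to annotate
#'   the ranking and compute precision/AUROC.
#' @return a \code{"ranked_network"}; if labels are given, the audit carries
#'   the transfer AUROC over all scored labeled pairs.
#' @export
transfer_score <- function(model, features_target, labels = NULL) {
  manifest <- attr(features_target, "manifest")
  target_exps <- unique(manifest$experiment)
  if (length(target_exps) != model$replicate_count)
    stop("target feature table has ", length(target_exps),
         " experiments; the model expects ", model$replicate_count)
  xcols <- character(0)
  for (r in seq_along(target_exps)) {
    for (m in model$measures) {
      col <- manifest$column[manifest$experiment == target_exps[r] &
                               manifest$measure == m]
      if (length(col) != 1L)
        stop("target features lack measure '", m, "' for experiment '",
             target_exps[r], "'")
      xcols <- c(xcols, col)
    }
  }
  X <- fill_features(as.matrix(features_target[, xcols, drop = FALSE]),
                     model$fill)
  colnames(X) <- as.vector(t(outer(paste0("rep", seq_along(target_exps)),
                                   model$measures, paste, sep = ".")))
  score <- predict_prob(model$forest, X)
  lab_vec <- rep(NA_character_, nrow(features_target))
  aud <- model$audit
  if (!is.null(labels)) {
    fkey <- paste(features_target$protein_a, features_target$protein_b,
                  sep = "|")
    lkey <- paste(labels$protein_a, labels$protein_b, sep = "|")
    m <- match(fkey, lkey)
    lab_vec <- as.character(labels$label)[m]
    aud$auroc <- auroc(score, lab_vec)
  }
  make_ranked_network(features_target$protein_a, features_target$protein_b,
                      score, lab_vec, models = list(model$forest),
                      audit = aud)
}
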