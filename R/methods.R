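#' @export
print.ranked_network <- function(x, ...) {
  aud <- attr(x, "audit")
  cat("Ranked CF-MS interaction network\n")
  cat(sprintf("  %d scored pairs (%d labeled: %d positive, %d negative)\n",
              nrow(x), sum(!is.na(x$label)),
              sum(x$label == "positive", na.rm = TRUE),
              sum(x$label == "negative", na.rm = TRUE)))
  if (!is.null(aud$k))
    cat(sprintf("  %d-fold cross-validated random forest, %d trees, seed %d\n",
                aud$k, aud$n_trees, aud$seed))
  at50 <- threshold_network(x, 0.5)
  cat(sprintf("  network size at 50%% precision: %d interactions\n",
              nrow(at50)))
  invisible(x)
}

#' @export
summary.ranked_network <- function(object, target_precision = 0.5, ...) {
  lab <- object$label
  labeled <- !is.na(lab)
  net <- threshold_network(object, target_precision)
  res <- list(n_pairs = nrow(object),
              n_labeled = sum(labeled),
              auroc = if (length(unique(lab[labeled])) == 2L)
                auroc(object$score, lab) else NA_real_,
              target_precision = target_precision,
              n_at_threshold = nrow(net),
              audit = attr(object, "audit"))
  class(res) <- "summary.ranked_network"
  res
}

#' @export
print.summary.ranked_network <- function(x, ...) {
  cat("Ranked CF-MS interaction network\n")
  cat(sprintf("  pairs scored: %d (labeled: %d)\n", x$n_pairs, x$n_labeled))
  if (!is.na(x$auroc))
    cat(sprintf("  AUROC over labeled pairs: %.3f\n", x$auroc))
  cat(sprintf("  interactions at %.0f%% precision: %d\n",
              100 * x$target_precision, x$n_at_threshold))
  invisible(x)
}

#' Plot the cumulative precision curve of a ranked network
#'
#' @param x a \code{"ranked_network"}.
#' @param target_precision horizontal reference line (default 0.5).
#' @param ... passed to \code{plot}.
#' @export
plot.ranked_network <- function(x, target_precision = 0.5, ...) {
  ok <- !is.na(x$precision)
  graphics::plot(which(ok), x$precision[ok], type = "l",
                 xlab = "Rank", ylab = "Cumulative precision",
                 ylim = c(0, 1), ...)
  graphics::abline(h = target_precision, lty = 2, col = "grey40")
  invisible(x)
}

#' Score new pairs with the fold models of a fitted ranking
#'
#' Averages the predictions of the cross-validation fold forests over a new
#' feature table, mirroring how unlabeled pairs were scored during fitting.
#'
#' @param object a \code{"ranked_network"} from \code{\link{train_score_cv}}.
#' @param newdata a \code{\link{feature_table}} with the same feature
#'   columns.
#' @param ... ignored.
#' @return numeric vector of scores, one per row of \code{newdata}.
#' @export
predict.ranked_network <- function(object, newdata, ...) {
  models <- attr(object, "models")
  if (is.null(models)) stop("no fold models stored in this object")
  fcols <- attr(object, "audit")$feature_columns
  if (is.null(fcols)) fcols <- feature_columns(newdata)
  X <- fill_features(as.matrix(newdata[, fcols, drop = FALSE]),
                     attr(object, "audit")$fill %||% "zero")
  rowMeans(vapply(models, function(m) predict_prob(m, X),
                  numeric(nrow(X))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
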