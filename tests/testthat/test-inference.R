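# small perfectly-separable feature fixture: positives at 1, negatives at 0
separable_fixture <- function(n_complex = 6L, seed = 1) {
  set.seed(seed)
  cx <- lapply(seq_len(n_complex), function(i)
    paste0("P", (3 * i - 2):(3 * i)))
  names(cx) <- paste0("C", seq_len(n_complex))
  lp <- labels_from_sets(cx)
  extra <- paste0("Q", 1:4)   # unlabeled proteins
  prot <- c(sort(unique(c(lp$protein_a, lp$protein_b))), extra)
  idx <- which(upper.tri(matrix(0, length(prot), length(prot))),
               arr.ind = TRUE)
  ft <- data.frame(protein_a = pmin(prot[idx[, 1]], prot[idx[, 2]]),
                   protein_b = pmax(prot[idx[, 1]], prot[idx[, 2]]),
                   stringsAsFactors = FALSE)
  key <- paste(ft$protein_a, ft$protein_b, sep = "|")
  pos <- key %in% paste(lp$protein_a, lp$protein_b,
                        sep = "|")[lp$label == "positive"]
  ft$e1.distance_correlation <- ifelse(pos, 1, 0) + runif(nrow(ft), 0, 0.01)
  list(features = structure(ft,
                            manifest = data.frame(
                              column = "e1.distance_correlation",
                              experiment = "e1",
                              measure = "distance_correlation"),
                            class = c("cf_features", "data.frame")),
       labels = lp)
}

test_that("feature tier rule yields 1, 2 or 4 measures per experiment", {
  expect_equal(tiered_measures(12L), "distance_correlation")
  expect_equal(tiered_measures(7L),
               c("distance_correlation", "weighted_cross_correlation"))
  expect_equal(tiered_measures(3L),
               c("distance_correlation", "weighted_cross_correlation",
                 "cosine", "mutual_information"))
  expect_equal(tiered_measures(6L), tiered_measures(10L))
  expect_equal(tiered_measures(11L), tiered_measures(100L))
})

test_that("feature table column count follows the tier rule manifest", {
  set.seed(20)
  mk <- function(id) {
    vals <- matrix(runif(4 * 8, 1, 100), 4, 8,
                   dimnames = list(paste0("P", 1:4), NULL))
    elution_matrix(vals, experiment_id = id)
  }
  exps <- lapply(paste0("e", 1:3), mk)
  ft <- feature_table(exps, seed = 1L)
  expect_equal(length(cfnet:::feature_columns(ft)), 3L * 4L)
  expect_equal(nrow(attr(ft, "manifest")), 12L)
  ft2 <- feature_table(exps, measures = "distance_correlation", seed = 1L)
  expect_equal(length(cfnet:::feature_columns(ft2)), 3L)
})

test_that("perfectly separable features rank all positives first, deterministically", {
  fx <- separable_fixture()
  net <- train_score_cv(fx$features, fx$labels, k = 3L, seed = 5L)
  lab <- net$label
  first_neg <- which(lab == "negative")[1]
  expect_true(all(which(lab == "positive") < first_neg))
  n_pos <- sum(lab == "positive", na.rm = TRUE)
  labeled_prec <- net$precision[!is.na(lab)]
  expect_true(all(labeled_prec[seq_len(n_pos)] == 1))
  # same seed and inputs reproduce the ranking bit-identically
  net2 <- train_score_cv(fx$features, fx$labels, k = 3L, seed = 5L)
  expect_identical(as.data.frame(net), as.data.frame(net2))
})

test_that("missing-feature markers are filled before fitting and never reach the learner", {
  fx <- separable_fixture()
  fx$features$e1.distance_correlation[3] <- NA
  expect_silent(net <- train_score_cv(fx$features, fx$labels, k = 3L,
                                      seed = 5L))
  filled <- cfnet:::fill_features(matrix(c(1, NA, 3)), "zero")
  expect_identical(filled[2], 0)
  expect_identical(cfnet:::fill_features(matrix(c(1, NA, 3)), "median")[2], 2)
})

test_that("single-class training folds raise an informative error", {
  fx <- separable_fixture(n_complex = 2L)
  lp <- fx$labels[fx$labels$label == "positive", ]
  class(lp) <- class(fx$labels)
  expect_error(train_score_cv(fx$features, lp, k = 2L, seed = 1L),
               "both classes")
})

test_that("precision curves match hand values and the recount oracle", {
  expect_equal(precision_curve(c("positive", "positive", "negative",
                                 "positive")),
               c(1, 1, 2/3, 3/4))
  expect_equal(precision_curve(c("positive", NA, "negative")),
               c(1, 1, 1/2))
  expect_true(all(is.na(precision_curve(c(NA, NA)))))
  set.seed(21)
  for (i in 1:20) {
    labs <- sample(c("positive", "negative", NA), 30, replace = TRUE)
    expect_equal(precision_curve(labs), bf_precision(labs))
  }
})

test_that("precision thresholding keeps the deepest qualifying rank", {
  rk <- data.frame(protein_a = letters[1:6], protein_b = LETTERS[1:6],
                   score = 6:1,
                   precision = c(1, 1, 2/3, 3/4, 1/2, 2/5))
  expect_equal(nrow(threshold_network(rk, 0.5)), 5L)
  expect_equal(nrow(threshold_network(rk, 3/4)), 4L)
  # target 1.0 keeps the longest prefix of perfect precision
  rk2 <- rk; rk2$precision <- c(1, 1, 2/3, 1/2, 2/5, 1/3)
  expect_equal(nrow(threshold_network(rk2, 1)), 2L)
  expect_equal(nrow(threshold_network(rk2, 0.99)), 2L)
  expect_equal(nrow(threshold_network(rk, 1.0)), 2L)
  # never reached -> empty
  rk3 <- rk; rk3$precision <- rep(0.2, 6)
  expect_equal(nrow(threshold_network(rk3, 0.5)), 0L)
  # linear-scan oracle on random precision sequences
  set.seed(22)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    prec <- runif(n)
    rkr <- data.frame(protein_a = paste0("a", 1:n),
                      protein_b = paste0("b", 1:n),
                      score = n:1, precision = prec)
    k_oracle <- 0L
    for (r in seq_len(n)) if (prec[r] >= 0.5) k_oracle <- r
    expect_equal(nrow(threshold_network(rkr, 0.5)), k_oracle)
  }
})

test_that("top-k thresholding is deterministic under input permutation", {
  fx <- separable_fixture()
  net <- train_score_cv(fx$features, fx$labels, k = 3L, seed = 5L)
  expect_equal(nrow(threshold_topk(net, 3L)), 3L)
  expect_warning(all_edges <- threshold_topk(net, nrow(net) + 10L),
                 "exceeds")
  expect_equal(nrow(all_edges), nrow(net))
  # permuting the feature rows leaves the ranking unchanged (alphabetized
  # tie-breaking)
  perm <- sample(nrow(fx$features))
  ftp <- fx$features[perm, ]
  attr(ftp, "manifest") <- attr(fx$features, "manifest")
  class(ftp) <- class(fx$features)
  netp <- train_score_cv(ftp, fx$labels, k = 3L, seed = 5L)
  expect_equal(as.data.frame(netp), as.data.frame(net))
})

test_that("rank-based AUROC matches the pair-counting oracle and pROC", {
  set.seed(23)
  for (i in 1:10) {
    n <- 40
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.3, .7))
    if (length(unique(labs)) < 2) next
    sc <- rnorm(n) + labs
    sc[1:5] <- round(sc[1:5])  # ties
    expect_equal(auroc(sc, labs), bf_auroc(sc, labs), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  labs <- c(rep(TRUE, 15), rep(FALSE, 25))
  sc <- rnorm(40) + labs
  expect_equal(auroc(sc, labs),
               as.numeric(pROC::auc(pROC::roc(labs, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("augmentation injects floor(proportion x labeled) pairs and discards them", {
  fx <- separable_fixture()
  n_lab <- nrow(fx$labels)
  pool <- do.call(rbind, lapply(1:4, function(e) {
    data.frame(protein_a = paste0("EXT:A", 1:50),
               protein_b = paste0("EXT:B", 1:50),
               label = rep(c("positive", "negative"), 25),
               experiment = sprintf("ext%02d", e),
               distance_correlation = rep(c(1, 0), 25) + runif(50, 0, .01),
               stringsAsFactors = FALSE)
  }))
  net <- augment_training(fx$features, fx$labels, pool, proportion = 0.33,
                          seed = 5L)
  expect_equal(attr(net, "audit")$n_injected, floor(0.33 * n_lab))
  # scored output pair set identical with and without augmentation
  base <- train_score_cv(fx$features, fx$labels, k = 5L, seed = 5L)
  expect_setequal(paste(net$protein_a, net$protein_b),
                  paste(base$protein_a, base$protein_b))
  expect_false(any(grepl("^EXT:", c(net$protein_a, net$protein_b))))
  # 300 labeled pairs at 33% -> 99 injected (arithmetic contract)
  expect_equal(floor(0.33 * 300), 99L)
  expect_error(augment_training(fx$features, fx$labels, pool[1:8, ],
                                proportion = 0.9, seed = 1L), "too small")
  expect_error(augment_training(fx$features, fx$labels, pool,
                                proportion = -1, seed = 1L), "non-negative")
})

test_that("transfer training builds replicate-width feature vectors", {
  set.seed(24)
  pool <- do.call(rbind, lapply(1:5, function(e) {
    lab <- rep(c("positive", "negative"), each = 25)
    data.frame(protein_a = paste0("X", 1:50), protein_b = paste0("Y", 1:50),
               label = lab, experiment = sprintf("ext%02d", e),
               distance_correlation = ifelse(lab == "positive", 1, 0) +
                 runif(50, 0, .01),
               stringsAsFactors = FALSE)
  }))
  model <- transfer_train(pool, target_replicate_count = 2L, seed = 9L)
  expect_equal(ncol(model$forest$importance), 1L)
  expect_equal(nrow(model$forest$importance), 2L)  # 2 replicates x 1 measure
  expect_warning(transfer_train(pool, target_replicate_count = 7L,
                                seed = 9L),
                 "with replacement")
  # scoring requires matching replicate structure
  fx <- separable_fixture()
  model1 <- transfer_train(pool, target_replicate_count = 1L, seed = 9L)
  scored <- transfer_score(model1, fx$features, labels = fx$labels)
  expect_gt(attr(scored, "audit")$auroc, 0.9)  # separable in both domains
  expect_error(transfer_score(model, fx$features), "expects 2")
})
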