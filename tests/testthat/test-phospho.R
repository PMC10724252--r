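write_phospho_fixture <- function(path, df, ints) {
  header <- c("Protein", "Position", "Amino acid", "Localization prob",
              "Delta score", "Reverse", "Potential contaminant",
              paste0("Intensity F", seq_len(ncol(ints))))
  lines <- paste(header, collapse = "\t")
  for (i in seq_len(nrow(df)))
    lines <- c(lines, paste(c(df$protein[i], df$position[i], df$residue[i],
                              df$loc_prob[i], df$delta[i], df$rev[i],
                              df$con[i], ints[i, ]), collapse = "\t"))
  writeLines(lines, path)
}

test_that("phospho reader parses sites and filter removes flagged rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  df <- data.frame(protein = c("P1", "REV__P2", "CON__P3", "P4"),
                   position = c(21, 10, 5, 99),
                   residue = c("S", "T", "Y", "S"),
                   loc_prob = c(0.99, 0.5, 0.8, 0.7),
                   delta = c(40, 10, 5, 20),
                   rev = c("", "+", "", ""), con = c("", "", "+", ""))
  write_phospho_fixture(f, df, matrix(as.character(1:8), 4, 2))
  sites <- read_phospho_sites(f)
  expect_equal(nrow(sites), 4L)
  kept <- filter_sites(sites)
  expect_equal(kept$protein, c("P1", "P4"))
  expect_equal(attr(kept, "removed_flagged"), 2L)
  expect_equal(nrow(attr(kept, "intensities")), 2L)
  # clean table -> identity; all flagged -> empty with warning
  clean <- filter_sites(kept)
  expect_equal(nrow(clean), 2L)
  all_bad <- sites
  all_bad$reverse <- TRUE
  expect_warning(none <- filter_sites(all_bad), "all phosphosites")
  expect_equal(nrow(none), 0L)
  # round trip
  out <- withr::local_tempfile(fileext = ".txt")
  write_phospho_sites(kept, out)
  back <- read_phospho_sites(out)
  expect_equal(back$protein, kept$protein)
  expect_equal(attr(back, "intensities")[, ], attr(kept, "intensities")[, ],
               ignore_attr = TRUE)
})

mk_sites <- function(protein, position, residue, ints, id) {
  df <- data.frame(protein = protein, position = position, residue = residue,
                   loc_prob = 0.9, delta_score = 40, reverse = FALSE,
                   contaminant = FALSE, stringsAsFactors = FALSE)
  structure(df, intensities = ints, experiment_id = id,
            class = c("phospho_sites", "data.frame"))
}

test_that("detection counts aggregate fractions and experiments per site", {
  e1 <- mk_sites("P1", 21, "S",
                 matrix(c(5, NA, NA, NA, 3, NA, NA, NA, 7, NA), 1, 10), "e1")
  counts <- detection_counts(e1)
  expect_equal(counts$n_fractions, 3L)
  expect_equal(counts$n_experiments, 1L)
  e2 <- mk_sites(c("P1", "P9"), c(21, 4), c("S", "Y"),
                 rbind(c(1, 2, NA, NA), c(NA, NA, NA, 8)), "e2")
  counts2 <- detection_counts(list(e1, e2))
  p1 <- counts2[counts2$protein == "P1", ]
  expect_equal(p1$n_fractions, 5L)       # 3 + 2 across experiments
  expect_equal(p1$n_experiments, 2L)
  # brute-force recount on random fixtures
  set.seed(40)
  tabs <- lapply(1:3, function(e) {
    n <- 12
    ints <- matrix(runif(n * 6), n, 6)
    ints[runif(n * 6) < 0.5] <- NA
    mk_sites(paste0("P", sample(4, n, TRUE)), sample(3, n, TRUE) * 10,
             sample(c("S", "T", "Y"), n, TRUE), ints, paste0("e", e))
  })
  got <- detection_counts(tabs)
  for (r in seq_len(nrow(got))) {
    nf <- 0L; ne <- 0L
    for (tab in tabs) {
      hit <- tab$protein == got$protein[r] & tab$position == got$position[r] &
        tab$residue == got$residue[r]
      cells <- sum(!is.na(attr(tab, "intensities")[hit, , drop = FALSE]))
      nf <- nf + cells
      ne <- ne + (cells > 0L)
    }
    expect_equal(got$n_fractions[r], nf)
    expect_equal(got$n_experiments[r], ne)
  }
})

test_that("prioritization threshold at 5 fractions is inclusive", {
  counts <- data.frame(protein = c("A", "B", "C"), position = 1:3,
                       residue = c("S", "T", "Y"),
                       n_fractions = c(6L, 3L, 5L), n_experiments = 1L)
  expect_equal(prioritize(counts)$protein, c("A", "C"))
  expect_equal(nrow(prioritize(counts, 1L)), 3L)
  # pure threshold filter: idempotent
  expect_equal(prioritize(prioritize(counts)), prioritize(counts))
})

test_that("residue proportions count unique sites once and sum to 1", {
  counts <- data.frame(protein = c("A", "A", "B", "C"),
                       position = c(1, 2, 1, 1),
                       residue = c("S", "S", "T", "Y"))
  expect_equal(residue_proportions(counts),
               c(pS = 0.5, pT = 0.25, pY = 0.25))
  expect_equal(residue_proportions(data.frame(protein = "A", position = 1,
                                              residue = "S")),
               c(pS = 1, pT = 0, pY = 0))
  set.seed(41)
  rnd <- data.frame(protein = paste0("P", 1:50), position = sample(500, 50),
                    residue = sample(c("S", "T", "Y"), 50, TRUE))
  expect_equal(sum(residue_proportions(rnd)), 1)
  expect_error(residue_proportions(rnd[0, ]), "no phosphosites")
})

test_that("kinase enrichment matches the closed-form hypergeometric", {
  bg <- data.frame(protein = paste0("P", 1:100), position = 1, residue = "S")
  fg <- bg[1:10, ]
  subs <- paste0("P", c(1:5, 30:44), "|1|S")  # 20 in bg, 5 in fg
  res <- ksea_hypergeometric(fg, bg, list(K1 = subs))
  expect_equal(res$overlap, 5L)
  expect_equal(res$expected, 10 * 20 / 100)
  expect_equal(res$p_value, bf_hyper_upper(5L, 20L, 100L, 10L),
               tolerance = 1e-12)
  # kinase with zero background substrates skipped
  expect_message(res2 <- ksea_hypergeometric(fg, bg,
                                             list(K1 = subs,
                                                  K0 = "Q9|9|Y")),
                 "skipped")
  expect_equal(res2$kinase, "K1")
  # degenerate foreground = background -> p = 1 for every kinase
  res3 <- ksea_hypergeometric(bg, bg, list(K1 = subs))
  expect_equal(res3$p_value, 1)
  # BH q-values monotone in p
  set.seed(42)
  kmap <- lapply(1:8, function(i)
    paste0("P", sample(100, sample(5:30, 1)), "|1|S"))
  names(kmap) <- paste0("K", 1:8)
  res4 <- ksea_hypergeometric(fg, bg, kmap)
  expect_true(all(res4$p_value > 0 & res4$p_value <= 1))
  ord <- order(res4$p_value)
  expect_true(all(diff(res4$q_value[ord]) >= -1e-12))
  expect_error(ksea_hypergeometric(data.frame(protein = "ZZ", position = 1,
                                              residue = "S"), bg, kmap),
               "subset")
})

test_that("stoichiometry profiles divide elementwise and flag the co-eluting peak", {
  parent <- c(gauss_peak(40, 12, 2, 100) + gauss_peak(40, 30, 2, 80))
  site <- parent * 0.25
  site[20:40] <- NA                       # detected only around peak 1
  prof <- stoichiometry_profile(site, parent)
  expect_equal(length(prof$parent_peaks), 2L)
  expect_equal(prof$parent_peaks, c(12, 30), tolerance = 1)
  expect_equal(prof$peak_flag, 1L)
  ok <- !is.na(site)
  expect_equal(prof$stoichiometry[ok], (site / parent)[ok])
  # site specific to the second peak
  site2 <- parent * 0.5
  site2[1:20] <- NA
  expect_equal(stoichiometry_profile(site2, parent)$peak_flag, 2L)
  # single-peak parent -> flag always 1
  p1 <- gauss_peak(30, 10)
  expect_equal(stoichiometry_profile(p1 * 0.1, p1)$peak_flag, 1L)
  # no overlap -> undefined flag, logged
  expect_message(
    und <- stoichiometry_profile(rep(NA_real_, 30), p1), "no overlapping")
  expect_true(is.na(und$peak_flag))
  expect_error(stoichiometry_profile(1:3, 1:4), "equal length")
})
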