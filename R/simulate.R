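# Synthetic CF-MS study generator. Complex members share a chromatographic
# co-peak per experiment (with per-member jitter); monomers elute
# independently; log-normal amplitudes, multiplicative noise, a small
# additive background, detection-limit and random-dropout missingness.
# Ground truth (catalog, peak parameters, labels) is exported so every
# downstream module is testable without external data.

#' Configure the synthetic CF-MS study generator
#'
#' Defaults describe a modest desk-scale study: 200 proteins, 20
#' disjoint complexes with geometric-tailed sizes (2 to 10 members), 3
#' replicate experiments of 50 fractions. Peak centers are uniform over
#' fractions; complex members jitter around the complex co-peak by
#' \code{jitter_sd} fractions; Gaussian peak widths ~ |N(width_mean,
#' width_sd)| fractions; amplitudes log-normal. Noise is multiplicative
#' log-normal plus a small additive background; missingness combines a
#' detection-limit quantile with random dropout.
#'
#' @param n_proteins,n_complexes study size.
#' @param complex_size_min,complex_size_geom_p,complex_size_cap complex-size
#'   distribution: \code{min + Geometric(p)}, capped.
#' @param n_experiments,n_fractions per-study design (\code{n_fractions >= 4}
#'   so defaults pass the minimum-fractions filter).
#' @param jitter_sd member peak-center jitter (fractions).
#' @param width_mean,width_sd Gaussian peak width (fractions).
#' @param amplitude_meanlog,amplitude_sdlog log-normal amplitude.
#' @param noise_sd multiplicative log-normal noise sd.
#' @param additive_floor scale of the additive background.
#' @param detection_quantile values below this quantile of the generated
#'   intensities are set missing (abundance bias of CF-MS).
#' @param dropout additional random missingness rate.
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_proteins = 200L, n_complexes = 20L,
                       complex_size_min = 2L, complex_size_geom_p = 0.4,
                       complex_size_cap = 10L,
                       n_experiments = 3L, n_fractions = 50L,
                       jitter_sd = 2, width_mean = 2.5, width_sd = 0.8,
                       amplitude_meanlog = log(1e6), amplitude_sdlog = 1,
                       noise_sd = 1, additive_floor = 100,
                       detection_quantile = 0.3, dropout = 0.25,
                       seed = 1L) {
  stopifnot(n_fractions >= 4L, n_proteins >= 2L, n_complexes >= 1L,
            detection_quantile >= 0, detection_quantile <= 1,
            dropout >= 0, dropout <= 1, !missing(seed) || is.numeric(seed))
  structure(as.list(environment()), class = "sim_config")
}

# complex membership and per-study structure, drawn once per study seed
sim_structure <- function(config) {
  with_seed(config$seed, {
    sizes <- pmin(config$complex_size_min +
                    stats::rgeom(config$n_complexes,
                                 config$complex_size_geom_p),
                  config$complex_size_cap)
    if (sum(sizes) > config$n_proteins)
      stop("complex members exceed n_proteins; reduce n_complexes or sizes")
    proteins <- sprintf("P%04d", seq_len(config$n_proteins))
    shuffled <- sample(proteins)
    complexes <- list()
    at <- 1L
    for (i in seq_len(config$n_complexes)) {
      complexes[[sprintf("CPX%03d", i)]] <-
        sort(shuffled[at:(at + sizes[i] - 1L)])
      at <- at + sizes[i]
    }
    list(proteins = proteins, complexes = complexes,
         monomers = sort(shuffled[at:config$n_proteins]),
         monomer_fraction = 1 - (at - 1L) / config$n_proteins)
  })
}

#' Simulate one CF-MS experiment
#'
#' @param config a \code{\link{sim_config}}.
#' @param experiment_index 1-based experiment index; peaks are redrawn per
#'   experiment while complex membership is fixed by the study seed.
#' @return list: \code{matrix} (an \code{\link{elution_matrix}}) and
#'   \code{truth} (per-protein peak center/width/amplitude and complex id).
#' @export
simulate_experiment <- function(config, experiment_index = 1L) {
  structure_ <- sim_structure(config)
  sim_experiment_internal(config, experiment_index, structure_)
}

sim_experiment_internal <- function(config, experiment_index, structure_) {
  np <- config$n_proteins; nf <- config$n_fractions
  proteins <- structure_$proteins
  with_seed(config$seed + 1000L * experiment_index, {
    center <- numeric(np); width <- numeric(np); amp <- numeric(np)
    cid <- rep(NA_character_, np)
    names(center) <- names(width) <- names(amp) <- names(cid) <- proteins
    for (cx in names(structure_$complexes)) {
      members <- structure_$complexes[[cx]]
      co_peak <- stats::runif(1L, 1, nf)
      center[members] <- co_peak + stats::rnorm(length(members), 0,
                                                config$jitter_sd)
      cid[members] <- cx
    }
    mono <- structure_$monomers
    center[mono] <- stats::runif(length(mono), 1, nf)
    width[proteins] <- abs(stats::rnorm(np, config$width_mean,
                                        config$width_sd))
    width[width < 0.5] <- 0.5
    amp[proteins] <- stats::rlnorm(np, config$amplitude_meanlog,
                                   config$amplitude_sdlog)
    f <- seq_len(nf)
    signal <- t(vapply(proteins, function(p)
      amp[p] * exp(-(f - center[p])^2 / (2 * width[p]^2)), numeric(nf)))
    noise <- matrix(stats::rlnorm(np * nf, 0, config$noise_sd), np, nf)
    bg <- matrix(stats::runif(np * nf, 0, config$additive_floor), np, nf)
    vals <- signal * noise + bg
    miss <- matrix(FALSE, np, nf)
    if (config$detection_quantile > 0) {
      lim <- stats::quantile(vals, config$detection_quantile)
      miss <- vals < lim
    }
    if (config$dropout > 0)
      miss <- miss | matrix(stats::runif(np * nf) < config$dropout, np, nf)
    vals[miss] <- NA_real_
    rownames(vals) <- proteins
    list(matrix = elution_matrix(vals, proteins = proteins,
                                 experiment_id = sprintf("sim%02d",
                                                         experiment_index),
                                 species = "synthetic"),
         truth = data.frame(protein = proteins, complex_id = unname(cid),
                            peak_center = unname(center),
                            peak_width = unname(width),
                            amplitude = unname(amp),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a full CF-MS study with ground truth
#'
#' Experiments share complex membership but redraw peak positions.
#' Annotation terms are generated from the true complexes plus random terms
#' for null testing.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_random_terms random annotation terms added to the complex-derived
#'   ones.
#' @return list: \code{experiments} (list of \code{\link{elution_matrix}}),
#'   \code{catalog} (\code{\link{complex_catalog}}), \code{labels}
#'   (\code{\link{label_pairs}} on the truth), \code{annotations} (named
#'   list, complexes plus random terms), \code{truth} (per-experiment peak
#'   parameters and \code{monomer_fraction}).
#' @export
simulate_study <- function(config, n_random_terms = 10L) {
  structure_ <- sim_structure(config)
  sims <- lapply(seq_len(config$n_experiments), function(i)
    sim_experiment_internal(config, i, structure_))
  catalog <- complex_catalog(structure_$complexes, source = "custom")
  labels <- label_pairs(catalog)
  annotations <- structure_$complexes
  names(annotations) <- paste0("TERM_", names(annotations))
  if (n_random_terms > 0L) {
    rand <- with_seed(config$seed + 77L, {
      lapply(seq_len(n_random_terms), function(i)
        sort(sample(structure_$proteins,
                    sample(5:min(30L, config$n_proteins), 1L))))
    })
    names(rand) <- sprintf("RAND_%03d", seq_len(n_random_terms))
    annotations <- c(annotations, rand)
  }
  list(experiments = lapply(sims, `[[`, "matrix"),
       catalog = catalog, labels = labels, annotations = annotations,
       truth = list(per_experiment = lapply(sims, `[[`, "truth"),
                    monomer_fraction = structure_$monomer_fraction))
}

#' Simulate an external labeled feature pool
#'
#' Simulates an independent study in a disjoint protein namespace and
#' exports, for each of its experiments, similarity features for its
#' labeled pairs in the long pool format consumed by
#' \code{\link{augment_training}} and \code{\link{transfer_train}}.
#'
#' @param config a \code{\link{sim_config}} describing the external study;
#'   \code{n_experiments} is overridden by \code{n_external_experiments}.
#' @param n_external_experiments number of external experiments.
#' @param measures measure columns to export (default distance correlation
#'   only, the most informative single feature).
#' @param namespace identifier prefix keeping the pool disjoint from any
#'   target study.
#' @return data frame: \code{protein_a}, \code{protein_b}, \code{label},
#'   \code{experiment}, plus one column per measure.
#' @export
simulate_external_pool <- function(config, n_external_experiments = 30L,
                                   measures = "distance_correlation",
                                   namespace = "EXT") {
  cfg <- config
  cfg$n_experiments <- n_external_experiments
  cfg$seed <- config$seed + 500000L
  structure_ <- sim_structure(cfg)
  catalog <- complex_catalog(structure_$complexes, source = "custom")
  labels <- label_pairs(catalog)
  labeled_prot <- sort(unique(c(labels$protein_a, labels$protein_b)))
  rows <- vector("list", n_external_experiments)
  for (i in seq_len(n_external_experiments)) {
    sim <- sim_experiment_internal(cfg, i, structure_)
    X <- unclass(sim$matrix)[labeled_prot, , drop = FALSE]
    specs <- lapply(measures, function(m)
      measure_spec(m, seed = cfg$seed + 7919L * i))
    fx <- pairwise_features(
      restore_elution(X, sim$matrix), specs)
    key_f <- paste(fx$protein_a, fx$protein_b, sep = "|")
    key_l <- paste(labels$protein_a, labels$protein_b, sep = "|")
    m <- match(key_l, key_f)
    df <- data.frame(protein_a = paste0(namespace, ":", labels$protein_a),
                     protein_b = paste0(namespace, ":", labels$protein_b),
                     label = as.character(labels$label),
                     experiment = sprintf("ext%02d", i),
                     stringsAsFactors = FALSE)
    for (meas in measures) df[[meas]] <- fx[[meas]][m]
    rows[[i]] <- df
  }
  do.call(rbind, rows)
}

#' Simulate a Phospho(STY)-dialect phosphosite table for an experiment
#'
#' A random subset of proteins receive S/T/Y phosphosites whose intensity
#' follows the parent chromatogram restricted to the neighborhood of one
#' parent peak (enabling the peak-specificity analysis), scaled by a random
#' stoichiometry and with heavier missingness than the parent.
#'
#' @param experiment an \code{\link{elution_matrix}} (the parent profiles).
#' @param sites_per_protein_rate Poisson rate of sites per protein.
#' @param residue_probs probabilities for (S, T, Y).
#' @param extra_dropout additional per-fraction missingness for sites.
#' @param peak_window fractions around the chosen parent peak retained.
#' @param seed integer seed.
#' @return a \code{"phospho_sites"} object (see
#'   \code{\link{read_phospho_sites}}); attribute \code{truth} records each
#'   site's assigned parent-peak index and stoichiometry.
#' @export
simulate_phospho <- function(experiment, sites_per_protein_rate = 0.3,
                             residue_probs = c(S = 0.60, T = 0.25, Y = 0.15),
                             extra_dropout = 0.3, peak_window = 5L,
                             seed = 1L) {
  stopifnot(abs(sum(residue_probs) - 1) < 1e-8)
  proteins <- rownames(experiment)
  nf <- ncol(experiment)
  with_seed(seed, {
    n_sites <- stats::rpois(length(proteins), sites_per_protein_rate)
    total <- sum(n_sites)
    protein <- character(total); position <- integer(total)
    residue <- character(total); loc_prob <- numeric(total)
    delta_score <- numeric(total); peak_idx_v <- integer(total)
    stoich_v <- numeric(total)
    mat <- matrix(NA_real_, total, nf,
                  dimnames = list(NULL, paste0("Intensity ", seq_len(nf))))
    at <- 0L
    for (i in seq_along(proteins)) {
      if (n_sites[i] == 0L) next
      parent <- unclass(experiment)[proteins[i], ]
      peaks <- find_peaks(parent)
      if (!length(peaks)) next
      positions <- sample(500L, min(n_sites[i], 500L))
      for (s in seq_len(length(positions))) {
        at <- at + 1L
        pk <- sample.int(length(peaks), 1L)
        stoich <- stats::rbeta(1L, 2, 5)
        val <- ifelse(abs(seq_len(nf) - peaks[pk]) <= peak_window,
                      parent * stoich, NA_real_)
        val[stats::runif(nf) < extra_dropout] <- NA_real_
        protein[at] <- proteins[i]; position[at] <- positions[s]
        residue[at] <- sample(c("S", "T", "Y"), 1L, prob = residue_probs)
        loc_prob[at] <- stats::rbeta(1L, 8, 2)
        delta_score[at] <- stats::rexp(1L, 1 / 40)
        peak_idx_v[at] <- pk; stoich_v[at] <- stoich
        mat[at, ] <- val
      }
    }
    idx <- seq_len(at)
    df <- data.frame(protein = protein[idx], position = position[idx],
                     residue = residue[idx], loc_prob = loc_prob[idx],
                     delta_score = delta_score[idx],
                     reverse = rep(FALSE, at), contaminant = rep(FALSE, at),
                     stringsAsFactors = FALSE)
    structure(df, intensities = mat[idx, , drop = FALSE],
              experiment_id = attr(experiment, "experiment_id"),
              truth = data.frame(parent_peak = peak_idx_v[idx],
                                 stoichiometry = stoich_v[idx]),
              class = c("phospho_sites", "data.frame"))
  })
}
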