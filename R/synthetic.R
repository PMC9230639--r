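#' Define a synthetic paired-cohort scenario
#'
#' The full generative configuration for [generate_cohort()]: two cohorts
#' measured in both omes, a log-normal landscape of baseline abundances,
#' negative-binomial read counts with a common dispersion, log-normal protein
#' intensities with intensity-dependent (MNAR) missingness, and planted
#' per-set fold-changes that may differ between omes.
#'
#' @param n_case,n_control samples per group.
#' @param n_background_genes genes carrying no planted effect
#'   (both multipliers 1).
#' @param sets data frame with columns `name`, `size`, `transcript_fc`,
#'   `protein_fc`: planted case/control multipliers per functional set.
#' @param nb_dispersion common negative-binomial dispersion of the counts
#'   (0 gives Poisson).
#' @param mean_log_expression,sd_log_expression log-normal parameters of the
#'   baseline transcript abundance landscape.
#' @param library_size_range integer pair: sequencing depths drawn uniformly
#'   in this range.
#' @param mean_log_intensity,sd_log_intensity normal parameters of baseline
#'   protein log-intensities (natural log of arbitrary MS intensity units).
#' @param protein_detection_midpoint log-intensity at which detection
#'   probability is 50%.
#' @param protein_detection_slope logistic scale (per log-intensity unit) of
#'   the detection curve; larger is shallower.
#' @param noise_sd_protein per-cell standard deviation added to protein
#'   log-intensities.
#' @param seed integer seed making the cohort fully reproducible.
#' @return object of class `synthetic_scenario` (a validated list).
#' @export
synthetic_scenario <- function(n_case = 20, n_control = 20,
                               n_background_genes = 1000,
                               sets = NULL,
                               nb_dispersion = 0.1,
                               mean_log_expression = 3,
                               sd_log_expression = 1.2,
                               library_size_range = c(50000L, 80000L),
                               mean_log_intensity = 20,
                               sd_log_intensity = 2,
                               protein_detection_midpoint = 18,
                               protein_detection_slope = 1,
                               noise_sd_protein = 0.5,
                               seed = 1L) {
  if (is.null(sets)) {
    sets <- data.frame(name = character(0), size = integer(0),
                       transcript_fc = numeric(0), protein_fc = numeric(0))
  }
  stopifnot(n_case >= 2, n_control >= 2, n_background_genes >= 0,
            all(c("name", "size", "transcript_fc", "protein_fc") %in%
                  names(sets)),
            all(sets$size >= 1),
            all(sets$transcript_fc > 0), all(sets$protein_fc > 0),
            !anyDuplicated(sets$name),
            nb_dispersion >= 0, noise_sd_protein >= 0,
            length(library_size_range) == 2,
            library_size_range[1] > 0,
            library_size_range[2] >= library_size_range[1],
            protein_detection_slope > 0,
            n_background_genes + sum(sets$size) >= 1)
  structure(list(n_case = n_case, n_control = n_control,
                 n_background_genes = n_background_genes, sets = sets,
                 nb_dispersion = nb_dispersion,
                 mean_log_expression = mean_log_expression,
                 sd_log_expression = sd_log_expression,
                 library_size_range = as.integer(library_size_range),
                 mean_log_intensity = mean_log_intensity,
                 sd_log_intensity = sd_log_intensity,
                 protein_detection_midpoint = protein_detection_midpoint,
                 protein_detection_slope = protein_detection_slope,
                 noise_sd_protein = noise_sd_protein,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Default paper-shaped scenario
#'
#' A 20 vs 20 cohort with the functional-group structure of a PD-vs-control
#' lymphoblast study: respiratory Complexes I-IV with transcripts planted
#' down (0.8) and proteins up (2.0); Complex V and the ribosome down in both
#' omes (0.8/0.8); TCA-cycle proteins up with unchanged transcripts;
#' SLC25 carriers and TIMM/TOMM import machinery with transcripts down;
#' immune and sphingolipid sets up in both omes; plus a null background.
#' Set sizes follow the detected counts of the study's functional-group
#' tables.
#'
#' @param seed integer seed (default 1).
#' @param n_background_genes background size (default 1000).
#' @return a [synthetic_scenario()].
#' @export
default_paper_scenario <- function(seed = 1L, n_background_genes = 1000) {
  sets <- data.frame(
    name = c("CI", "CII", "CIII", "CIV", "CV", "TCA", "SLC25", "TIMM_TOMM",
             "RIBOSOME", "IMMUNE", "SPHINGOLIPID"),
    size = c(44L, 8L, 11L, 35L, 19L, 24L, 52L, 23L, 80L, 100L, 30L),
    transcript_fc = c(0.8, 0.8, 0.8, 0.8, 0.8, 1.0, 0.85, 0.85,
                      0.8, 1.3, 1.3),
    protein_fc = c(2.0, 2.0, 2.0, 2.0, 0.8, 1.8, 1.0, 1.5,
                   0.8, 1.5, 1.5),
    stringsAsFactors = FALSE)
  synthetic_scenario(n_case = 20, n_control = 20,
                     n_background_genes = n_background_genes,
                     sets = sets, seed = seed)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate one paired synthetic cohort
#'
#' Transcripts: per-gene baseline abundances are log-normal; each sample's
#' library size is uniform in the configured range; counts are negative
#' binomial around `library_size * relative_abundance * planted_fc` (case
#' samples only carry the fold-change) with the common dispersion.
#' Proteins: per-protein baseline log-intensities are normal; case samples
#' are shifted by `log(protein_fc)`; per-cell Gaussian noise is added; cells
#' are then masked as not-detected with probability
#' `1 - plogis((log_intensity - midpoint) / slope)`, so low-abundance
#' proteins are missing more often (missing-not-at-random). Gene-set
#' membership is returned as a `functional_group` collection. Everything is
#' reproducible from the scenario's seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `transcripts` and `proteins`
#'   ([expression_matrix()] each), `design` ([cohort_design()]) and `sets`
#'   ([gene_set_collection()]).
#' @export
generate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    n_set_genes <- sum(sc$sets$size)
    n_genes <- sc$n_background_genes + n_set_genes
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    set_of <- rep(NA_character_, n_genes)
    if (n_set_genes > 0) {
      set_of[seq_len(n_set_genes)] <- rep(sc$sets$name, sc$sets$size)
    }
    t_fc <- rep(1, n_genes)
    p_fc <- rep(1, n_genes)
    if (n_set_genes > 0) {
      t_fc[seq_len(n_set_genes)] <- rep(sc$sets$transcript_fc, sc$sets$size)
      p_fc[seq_len(n_set_genes)] <- rep(sc$sets$protein_fc, sc$sets$size)
    }

    n_samp <- sc$n_case + sc$n_control
    sample_ids <- c(sprintf("case_%02d", seq_len(sc$n_case)),
                    sprintf("ctrl_%02d", seq_len(sc$n_control)))
    is_case <- c(rep(TRUE, sc$n_case), rep(FALSE, sc$n_control))
    design <- cohort_design(stats::setNames(
      ifelse(is_case, "case", "control"), sample_ids))

    # transcripts
    baseline <- stats::rlnorm(n_genes, sc$mean_log_expression,
                              sc$sd_log_expression)
    rel <- baseline / sum(baseline)
    libs <- sample(seq(sc$library_size_range[1], sc$library_size_range[2]),
                   n_samp, replace = TRUE)
    mu <- outer(rel, libs)
    mu[, is_case] <- mu[, is_case] * t_fc
    counts <- matrix(
      if (sc$nb_dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / sc$nb_dispersion)
      } else {
        stats::rpois(length(mu), lambda = mu)
      },
      nrow = n_genes, dimnames = list(gene_ids, sample_ids))
    lengths_bp <- sample(500:5000, n_genes, replace = TRUE)
    transcripts <- expression_matrix(counts, "transcript",
                                     feature_length_bp = lengths_bp)

    # proteins
    base_int <- stats::rnorm(n_genes, sc$mean_log_intensity,
                             sc$sd_log_intensity)
    logint <- matrix(base_int, n_genes, n_samp)
    logint[, is_case] <- logint[, is_case] + log(p_fc)
    logint <- logint + stats::rnorm(length(logint), 0, sc$noise_sd_protein)
    p_detect <- stats::plogis((logint - sc$protein_detection_midpoint) /
                                sc$protein_detection_slope)
    detected <- matrix(stats::runif(length(logint)) < p_detect,
                       n_genes, n_samp)
    intens <- exp(logint)
    intens[!detected] <- NA
    dimnames(intens) <- list(gene_ids, sample_ids)
    proteins <- expression_matrix(intens, "protein")

    sets <- if (nrow(sc$sets)) {
      gene_set_collection(lapply(seq_len(nrow(sc$sets)), function(i) {
        list(name = sc$sets$name[i], category = "functional_group",
             members = gene_ids[!is.na(set_of) & set_of == sc$sets$name[i]])
      }))
    } else gene_set_collection(list())

    list(transcripts = transcripts, proteins = proteins,
         design = design, sets = sets)
  })
}
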