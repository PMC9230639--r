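#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in input order: sort p ascending, take
#' `q_(i) = min_{j >= i}(p_(j) * m / j)` capped at 1. Thin validated wrapper
#' over [stats::p.adjust()], which implements exactly this step-up rule.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-feature detection counts by group
#'
#' A protein is detected in a sample when its intensity is non-missing; a
#' transcript when its count is greater than zero.
#'
#' @param mat an [expression_matrix()].
#' @param design a [cohort_design()] covering all samples of `mat`.
#' @return data frame with columns `feature_id`, `n_case`, `n_control`.
#' @export
detection_counts <- function(mat, design) {
  check_design_covers(mat, design)
  detected <- if (mat$ome == "protein") !is.na(mat$values) else mat$values > 0
  case_cols <- intersect(colnames(mat$values), design_samples(design, "case"))
  ctrl_cols <- intersect(colnames(mat$values), design_samples(design, "control"))
  data.frame(feature_id = rownames(mat$values),
             n_case = as.integer(rowSums(detected[, case_cols, drop = FALSE])),
             n_control = as.integer(rowSums(detected[, ctrl_cols, drop = FALSE])),
             stringsAsFactors = FALSE)
}

de_direction <- function(fold_change, significant) {
  ifelse(!significant, "none", ifelse(fold_change > 1, "up",
                                      ifelse(fold_change < 1, "down", "none")))
}

#' Protein differential expression (t-tests on detected intensities)
#'
#' Features with zero detections in either cohort are excluded up front.
#' Fold-change is the linear ratio of detected case to detected control mean
#' intensities; the p-value comes from a two-sided t-test on log-transformed
#' detected intensities (Welch by default); q-values from [bh_adjust()] over
#' all features with at least 2 detected values in each group. Features with
#' fewer than 2 detections in a group are reported with `p = q = 1` and are
#' never significant.
#'
#' @param mat protein [expression_matrix()].
#' @param design a [cohort_design()].
#' @param alpha significance threshold on the q-value (default 0.05).
#' @param log_transform test on log intensities (default TRUE).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data frame, one row per retained feature: `feature_id`,
#'   `mean_case`, `mean_control`, `fold_change`, `p_value`, `q_value`,
#'   `significant`, `n_detected_case`, `n_detected_control`, `direction`.
#' @export
protein_de <- function(mat, design, alpha = 0.05, log_transform = TRUE,
                       var_equal = FALSE) {
  stopifnot(mat$ome == "protein")
  det <- detection_counts(mat, design)
  keep <- det$n_case > 0 & det$n_control > 0
  det <- det[keep, , drop = FALSE]
  vals <- mat$values[keep, , drop = FALSE]
  case_cols <- intersect(colnames(vals), design_samples(design, "case"))
  ctrl_cols <- intersect(colnames(vals), design_samples(design, "control"))

  mean_case <- rowMeans(vals[, case_cols, drop = FALSE], na.rm = TRUE)
  mean_ctrl <- rowMeans(vals[, ctrl_cols, drop = FALSE], na.rm = TRUE)
  fc <- mean_case / mean_ctrl

  testable <- det$n_case >= 2 & det$n_control >= 2
  p <- rep(NA_real_, nrow(vals))
  for (i in which(testable)) {
    x <- vals[i, case_cols]; x <- x[!is.na(x)]
    y <- vals[i, ctrl_cols]; y <- y[!is.na(y)]
    if (log_transform) { x <- log(x); y <- log(y) }
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      # constant in both groups: t undefined; identical means => no evidence
      p[i] <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else NA_real_
      if (is.na(p[i])) testable[i] <- FALSE
      next
    }
    p[i] <- stats::t.test(x, y, var.equal = var_equal)$p.value
  }
  q <- rep(1, nrow(vals))
  q[testable] <- bh_adjust(p[testable])
  p[!testable] <- 1
  significant <- testable & q <= alpha
  data.frame(feature_id = det$feature_id,
             mean_case = mean_case, mean_control = mean_ctrl,
             fold_change = fc, p_value = p, q_value = q,
             significant = significant,
             n_detected_case = det$n_case, n_detected_control = det$n_control,
             direction = de_direction(fc, significant),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' TMM scaling-factor normalization
#'
#' Trimmed mean of M-values relative to a reference sample (the sample whose
#' upper-quartile count fraction is closest to the mean of those fractions).
#' For each sample, genes with zero counts in either the sample or the
#' reference are dropped; log2 ratios (M) are trimmed by `logratio_trim`
#' (default 30%) and average log intensities (A) by `abs_trim` (default 5%),
#' and the factor is 2 to the precision-weighted mean of the doubly trimmed
#' M values. Factors are rescaled so their product is 1. The effective
#' library size of a sample is its raw library size times its factor.
#'
#' @param mat transcript [expression_matrix()] with at least 2 samples.
#' @param logratio_trim fraction trimmed from each tail of M (default 0.3).
#' @param abs_trim fraction trimmed from each tail of A (default 0.05).
#' @return named numeric vector of per-sample scaling factors with attribute
#'   `effective_lib_size`.
#' @export
tmm_factors <- function(mat, logratio_trim = 0.3, abs_trim = 0.05) {
  stopifnot(mat$ome == "transcript")
  y <- mat$values
  if (ncol(y) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(y)
  if (any(lib == 0)) stop("sample with all-zero counts")

  uq <- apply(y, 2, function(col) stats::quantile(col, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))

  f <- vapply(seq_len(ncol(y)), function(k) {
    if (k == ref) return(0)
    obs <- y[, k]; refc <- y[, ref]
    keep <- obs > 0 & refc > 0
    obs <- obs[keep]; refc <- refc[keep]
    # exact tie patterns in M and A matter at the trim boundaries, so keep
    # the canonical forms of both expressions
    m <- log2((obs / lib[k]) / (refc / lib[ref]))
    a <- (log2(obs / lib[k]) + log2(refc / lib[ref])) / 2
    w <- (lib[k] - obs) / (lib[k] * obs) + (lib[ref] - refc) / (lib[ref] * refc)
    n <- length(m)
    lom <- floor(n * logratio_trim) + 1
    him <- n + 1 - lom
    loa <- floor(n * abs_trim) + 1
    hia <- n + 1 - loa
    keep2 <- rank(m) >= lom & rank(m) <= him & rank(a) >= loa & rank(a) <= hia
    if (!any(keep2)) return(0)
    val <- sum(m[keep2] / w[keep2]) / sum(1 / w[keep2])
    if (!is.finite(val) || abs(val) < 1e-6) 0 else val
  }, 0)
  f <- 2^f
  f <- f / exp(mean(log(f)))  # geometric mean 1 => product 1
  names(f) <- colnames(y)
  attr(f, "effective_lib_size") <- lib * f
  f
}

#' Fragments per kilobase per million (FPKM)
#'
#' `fpkm[g, s] = count[g, s] / ((length_bp[g] / 1000) * (eff_lib[s] / 1e6))`
#' where the effective library size is the TMM-adjusted library size.
#'
#' @param mat transcript [expression_matrix()] with `feature_length_bp`.
#' @param factors optional precomputed [tmm_factors()]; computed if NULL.
#' @return numeric matrix of FPKM values, same dimnames as the counts.
#' @export
fpkm <- function(mat, factors = NULL) {
  stopifnot(mat$ome == "transcript")
  if (is.null(mat$feature_length_bp)) stop("feature lengths missing")
  if (is.null(factors)) factors <- tmm_factors(mat)
  eff <- attr(factors, "effective_lib_size")
  sweep(mat$values / (mat$feature_length_bp / 1000), 2, eff / 1e6, "/")
}

# Common negative-binomial dispersion by method of moments on normalized
# counts: per gene, pooled within-group moments give
# phi_g = (s^2 - mu) / mu^2; the common value is the mean over genes with
# positive mean, floored at zero.
estimate_common_dispersion <- function(scaled, case_cols, ctrl_cols) {
  phi_of <- function(block) {
    mu <- rowMeans(block)
    v <- apply(block, 1, stats::var)
    ok <- mu > 0
    (v[ok] - mu[ok]) / mu[ok]^2
  }
  phis <- c(phi_of(scaled[, case_cols, drop = FALSE]),
            phi_of(scaled[, ctrl_cols, drop = FALSE]))
  phis <- phis[is.finite(phis)]
  if (!length(phis)) return(0)
  max(0, mean(phis))
}

#' Exact test of a two-group count split conditional on the total
#'
#' Given equalized per-group count sums `z1` (over `n1` samples) and `z2`
#' (over `n2` samples) and a common negative-binomial dispersion `phi`, the
#' two-sided p-value is the sum of the conditional probabilities of all
#' splits no more probable than the observed one, conditioning on
#' `z1 + z2`. With `phi > 0` the group sums are negative binomial (size
#' `n_g / phi`); at `phi = 0` the conditional law is exactly
#' `Binomial(z1 + z2, n1 / (n1 + n2))`.
#'
#' @param z1,z2 nonnegative integer group sums.
#' @param n1,n2 samples per group.
#' @param phi common dispersion (>= 0).
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(z1, z2, n1, n2, phi) {
  tot <- z1 + z2
  if (tot == 0) return(1)
  ys <- 0:tot
  if (phi <= 0) {
    pr <- stats::dbinom(ys, tot, n1 / (n1 + n2))
  } else {
    mu <- tot / (n1 + n2)
    pr <- stats::dnbinom(ys, size = n1 / phi, mu = n1 * mu) *
      stats::dnbinom(tot - ys, size = n2 / phi, mu = n2 * mu)
    pr <- pr / sum(pr)
  }
  sum(pr[pr <= pr[z1 + 1] * (1 + 1e-7)])
}

#' Transcript differential expression (common-dispersion exact test)
#'
#' Counts are TMM-normalized to a common effective library size (the
#' geometric mean); a single common negative-binomial dispersion is estimated
#' by method of moments on the normalized counts (floored at 0, where the
#' test reduces to a conditional binomial exact test). For each gene the
#' normalized group sums are compared with a two-sided exact test conditional
#' on the gene's total. Fold-change is the ratio of normalized group means
#' with a pseudocount of 0.5 added to each mean (the pseudocount never enters
#' the test). A gene is significant when `q <= alpha` and its fold-change is
#' at least `fc_min` or at most `1 / fc_min`.
#'
#' @param mat transcript [expression_matrix()].
#' @param design a [cohort_design()].
#' @param alpha q-value threshold (default 0.05).
#' @param fc_min minimum linear fold-change, applied symmetrically
#'   (default 2).
#' @param dispersion optional fixed common dispersion, bypassing estimation.
#' @return data frame with the same columns as [protein_de()].
#' @export
transcript_de <- function(mat, design, alpha = 0.05, fc_min = 2,
                          dispersion = NULL) {
  stopifnot(mat$ome == "transcript")
  check_design_covers(mat, design)
  y <- mat$values
  case_cols <- intersect(colnames(y), design_samples(design, "case"))
  ctrl_cols <- intersect(colnames(y), design_samples(design, "control"))
  lib <- colSums(y)
  if (sum(lib[case_cols]) == 0 || sum(lib[ctrl_cols]) == 0) {
    stop("a group has zero total library size")
  }

  f <- tmm_factors(mat)
  eff <- attr(f, "effective_lib_size")
  target <- exp(mean(log(eff)))
  scaled <- sweep(y, 2, target / eff, "*")

  phi <- if (is.null(dispersion)) {
    estimate_common_dispersion(scaled, case_cols, ctrl_cols)
  } else dispersion

  n1 <- length(case_cols); n2 <- length(ctrl_cols)
  z1 <- round(rowSums(scaled[, case_cols, drop = FALSE]))
  z2 <- round(rowSums(scaled[, ctrl_cols, drop = FALSE]))
  p <- vapply(seq_len(nrow(y)),
              function(i) nb_exact_test(z1[i], z2[i], n1, n2, phi), 0)
  p <- pmin(p, 1)
  q <- bh_adjust(p)

  mean_case <- rowMeans(scaled[, case_cols, drop = FALSE])
  mean_ctrl <- rowMeans(scaled[, ctrl_cols, drop = FALSE])
  fc <- (mean_case + 0.5) / (mean_ctrl + 0.5)
  significant <- q <= alpha & (fc >= fc_min | fc <= 1 / fc_min)

  det <- detection_counts(mat, design)
  data.frame(feature_id = rownames(y),
             mean_case = mean_case, mean_control = mean_ctrl,
             fold_change = fc, p_value = p, q_value = q,
             significant = significant,
             n_detected_case = det$n_case, n_detected_control = det$n_control,
             direction = de_direction(fc, significant),
             stringsAsFactors = FALSE, row.names = NULL)
}
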