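#' Minimum per-group detection filter
#'
#' A feature is retained only when it was detected in at least
#' `min_per_group` case samples and `min_per_group` control samples.
#'
#' @param mat an [expression_matrix()].
#' @param design a [cohort_design()].
#' @param min_per_group minimum detections in each group (default 5).
#' @return character vector of retained feature ids.
#' @export
min_detection_filter <- function(mat, design, min_per_group = 5) {
  n_case <- length(design_samples(design, "case"))
  n_ctrl <- length(design_samples(design, "control"))
  if (min_per_group > min(n_case, n_ctrl)) {
    stop("min_per_group exceeds a group size")
  }
  det <- detection_counts(mat, design)
  det$feature_id[det$n_case >= min_per_group & det$n_control >= min_per_group]
}

#' Classify fold-changes into abundance direction classes
#'
#' `up` for fold-change strictly above `up_cut` (default 1.1, a 10% increase),
#' `down` for strictly below `down_cut` (default 0.9, a 10% decrease),
#' `unchanged` otherwise — boundary values are unchanged.
#'
#' @param fold_change positive numeric vector.
#' @param up_cut upper cut (default 1.1).
#' @param down_cut lower cut (default 0.9).
#' @return character vector in `{"up", "down", "unchanged"}`.
#' @export
classify_direction <- function(fold_change, up_cut = 1.1, down_cut = 0.9) {
  if (anyNA(fold_change) || any(fold_change <= 0)) {
    stop("fold-changes must be positive")
  }
  ifelse(fold_change > up_cut, "up",
         ifelse(fold_change < down_cut, "down", "unchanged"))
}

#' Two-sample proportion test with continuity correction
#'
#' Two-sided pooled z-test of `p1 = p2`: with pooled proportion
#' `ph = (x1 + x2) / (n1 + n2)`,
#' `z = (|x1/n1 - x2/n2| - c) / sqrt(ph (1 - ph) (1/n1 + 1/n2))` where the
#' continuity term `c = (1/n1 + 1/n2) / 2` (0 when `continuity = FALSE`) and
#' the numerator is floored at 0; `p = 2 * pnorm(-z)`. Equivalent to the
#' Yates-corrected chi-square test on the 2x2 table. Degenerate pooled
#' proportions (0 or 1) return p = 1.
#'
#' @param x1,x2 successes in each sample.
#' @param n1,n2 trials in each sample.
#' @param continuity apply the continuity correction (default TRUE).
#' @return the two-sided p-value.
#' @export
two_sample_prop_test <- function(x1, x2, n1, n2, continuity = TRUE) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  ph <- (x1 + x2) / (n1 + n2)
  if (ph <= 0 || ph >= 1) return(1)
  cc <- if (continuity) (1 / n1 + 1 / n2) / 2 else 0
  num <- max(0, abs(x1 / n1 - x2 / n2) - cc)
  z <- num / sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
  2 * stats::pnorm(-z)
}

#' Set-level direction test
#'
#' For one functional set in one ome: members with fold-change strictly above
#' 1 count as up, strictly below 1 as down (exactly 1 counts as neither).
#' The up and down counts are compared with a continuity-corrected
#' two-sample proportion test, each arm out of `n_up + n_down`.
#'
#' @param fold_changes positive numeric vector of the set's member
#'   fold-changes (after detection filtering).
#' @return list with `n_up`, `n_down`, `prop_p` (`NA` when no member moves).
#' @export
set_direction_test <- function(fold_changes) {
  stopifnot(all(fold_changes > 0))
  n_up <- sum(fold_changes > 1)
  n_down <- sum(fold_changes < 1)
  n <- n_up + n_down
  prop_p <- if (n == 0) NA_real_ else two_sample_prop_test(n_up, n_down, n, n)
  list(n_up = n_up, n_down = n_down, prop_p = prop_p)
}

#' Set-level magnitude test
#'
#' Mean fold-change of the up (> 1) and down (< 1) members, plus a two-sided
#' one-sample t-test of all member fold-changes against the null mean of 1
#' (on the linear scale by default, matching how average fold-changes are
#' reported; `log = TRUE` tests log fold-changes against 0).
#'
#' @param fold_changes positive numeric vector.
#' @param log test on the log scale.
#' @return list with `mean_fc_up`, `mean_fc_down` (`NaN` when a side is
#'   empty) and `magnitude_p` (`NA` for n < 2 or zero variance).
#' @export
set_magnitude_test <- function(fold_changes, log = FALSE) {
  stopifnot(all(fold_changes > 0))
  mean_up <- mean(fold_changes[fold_changes > 1])
  mean_down <- mean(fold_changes[fold_changes < 1])
  x <- if (log) log(fold_changes) else fold_changes
  mu0 <- if (log) 0 else 1
  p <- if (length(x) < 2 || stats::var(x) == 0) NA_real_
       else stats::t.test(x, mu = mu0)$p.value
  list(mean_fc_up = mean_up, mean_fc_down = mean_down, magnitude_p = p)
}

#' Global direction test
#'
#' Compares the number of significantly up- and downregulated features, each
#' against the full detected population, with the continuity-corrected
#' two-sample proportion test.
#'
#' @param n_up,n_down significant feature counts per direction.
#' @param n_total total detected features (both arms use this denominator).
#' @return the two-sided p-value.
#' @export
global_direction_test <- function(n_up, n_down, n_total) {
  if (n_total == 0) stop("no detected features")
  stopifnot(n_up + n_down <= 2 * n_total, n_up <= n_total, n_down <= n_total)
  two_sample_prop_test(n_up, n_down, n_total, n_total)
}

#' Build the per-set concordance table for one ome
#'
#' Applies the detection filter, intersects each set with the retained
#' features, and reports for each set the up/down counts with their mean
#' fold-changes, the set-level proportion test and the magnitude test —
#' one row per functional set.
#'
#' @param de differential result data frame ([protein_de()] /
#'   [transcript_de()] output: needs `feature_id`, `fold_change`,
#'   `n_detected_case`, `n_detected_control`).
#' @param sets a [gene_set_collection()].
#' @param ome label recorded in the output.
#' @param min_detect per-group detection minimum (default 5).
#' @return data frame: `set_name`, `ome`, `n_members_detected`, `n_up`,
#'   `n_down`, `mean_fc_up`, `mean_fc_down`, `prop_p`, `magnitude_p`.
#' @export
concordance_table <- function(de, sets, ome, min_detect = 5) {
  retained <- de$feature_id[de$n_detected_case >= min_detect &
                            de$n_detected_control >= min_detect]
  fc <- stats::setNames(de$fold_change, de$feature_id)
  rows <- lapply(sets, function(s) {
    members <- intersect(s$members, retained)
    fcs <- fc[members]
    if (length(fcs)) {
      d <- set_direction_test(fcs)
      m <- set_magnitude_test(fcs)
    } else {
      d <- list(n_up = 0L, n_down = 0L, prop_p = NA_real_)
      m <- list(mean_fc_up = NaN, mean_fc_down = NaN, magnitude_p = NA_real_)
    }
    data.frame(set_name = s$name, ome = ome,
               n_members_detected = length(members),
               n_up = d$n_up, n_down = d$n_down,
               mean_fc_up = m$mean_fc_up, mean_fc_down = m$mean_fc_down,
               prop_p = d$prop_p, magnitude_p = m$magnitude_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

set_call <- function(n_up, n_down, prop_p, alpha) {
  if (is.na(prop_p)) return("none")
  if (prop_p <= alpha && n_up > n_down) return("up")
  if (prop_p <= alpha && n_down > n_up) return("down")
  "mixed"
}

coupling_lookup <- function(transcript_call, protein_call) {
  if (transcript_call == "down" && protein_call == "up") {
    "discordant_t_down_p_up"
  } else if (transcript_call == "up" && protein_call == "down") {
    "discordant_t_up_p_down"
  } else if (transcript_call == "up" && protein_call == "up") {
    "concordant_up"
  } else if (transcript_call == "down" && protein_call == "down") {
    "concordant_down"
  } else "undetermined"
}

#' Classify transcript-protein coupling for one functional set
#'
#' Each ome's call is `up` when its set-level proportion test is significant
#' with more up than down members, `down` in the mirror case, and `mixed`
#' otherwise. The coupling class follows from the two calls: concordant when
#' they agree, discordant when they oppose, `undetermined` otherwise (or when
#' an ome's row is missing).
#'
#' @param transcript_row,protein_row single rows of [concordance_table()]
#'   output for the same set (either may be NULL / missing).
#' @param alpha significance threshold on the proportion test (default 0.05).
#' @return data frame row: `set_name`, `transcript_call`, `protein_call`,
#'   `coupling`.
#' @export
classify_coupling <- function(transcript_row, protein_row, alpha = 0.05) {
  missing_t <- is.null(transcript_row) || !nrow(transcript_row)
  missing_p <- is.null(protein_row) || !nrow(protein_row)
  if (missing_t && missing_p) stop("both ome rows missing")
  set_name <- if (!missing_t) transcript_row$set_name else protein_row$set_name
  t_call <- if (missing_t) "none" else {
    set_call(transcript_row$n_up, transcript_row$n_down,
             transcript_row$prop_p, alpha)
  }
  p_call <- if (missing_p) "none" else {
    set_call(protein_row$n_up, protein_row$n_down, protein_row$prop_p, alpha)
  }
  coupling <- if (missing_t || missing_p) "undetermined"
              else coupling_lookup(t_call, p_call)
  data.frame(set_name = set_name, transcript_call = t_call,
             protein_call = p_call, coupling = coupling,
             stringsAsFactors = FALSE)
}

#' Coupling classification for every set present in either ome
#'
#' @param conc_transcript,conc_protein [concordance_table()] outputs.
#' @param alpha proportion-test significance threshold (default 0.05).
#' @return data frame of [classify_coupling()] rows, one per set.
#' @export
coupling_table <- function(conc_transcript, conc_protein, alpha = 0.05) {
  sets <- union(conc_transcript$set_name, conc_protein$set_name)
  out <- lapply(sets, function(nm) {
    classify_coupling(conc_transcript[conc_transcript$set_name == nm, ],
                      conc_protein[conc_protein$set_name == nm, ],
                      alpha = alpha)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assemble the run-level concordance summary
#'
#' Per ome: total detected features, significant up/down counts,
#' whole-number percentages, and the global direction test p-value; plus the
#' per-set concordance tables and the coupling table.
#'
#' @param de_transcript,de_protein differential result tables.
#' @param sets a [gene_set_collection()].
#' @param alpha coupling-call significance threshold (default 0.05).
#' @param min_detect detection-filter minimum (default 5).
#' @return list with elements `global` (data frame, one row per ome),
#'   `concordance_transcript`, `concordance_protein`, `coupling`.
#' @export
build_summary <- function(de_transcript, de_protein, sets, alpha = 0.05,
                          min_detect = 5) {
  global_row <- function(de, ome) {
    n_total <- nrow(de)
    n_up <- sum(de$direction == "up")
    n_down <- sum(de$direction == "down")
    data.frame(ome = ome, n_detected = n_total,
               n_sig_up = n_up, n_sig_down = n_down,
               pct_up = round(100 * n_up / n_total),
               pct_down = round(100 * n_down / n_total),
               global_p = global_direction_test(n_up, n_down, n_total),
               stringsAsFactors = FALSE)
  }
  conc_t <- concordance_table(de_transcript, sets, "transcript", min_detect)
  conc_p <- concordance_table(de_protein, sets, "protein", min_detect)
  list(global = rbind(global_row(de_transcript, "transcript"),
                      global_row(de_protein, "protein")),
       concordance_transcript = conc_t,
       concordance_protein = conc_p,
       coupling = coupling_table(conc_t, conc_p, alpha = alpha))
}
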