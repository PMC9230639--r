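#' Binomial over-representation analysis against a detected-feature reference
#'
#' For each gene set: `k` = hits in the query list, `K` = hits in the
#' reference, `N` = reference size, `n` = list size; expected hits
#' `n * K / N` and `fold_enrichment = k / expected`. The p-value is the
#' one-sided binomial tail under `X ~ Binomial(n, K/N)` in the requested
#' direction: upper tail `P(X >= k)` for the over-representation analysis,
#' lower tail `P(X <= k)` for the under-representation analysis (whose hits
#' have fold enrichment below 1). The two directions are separate analyses —
#' the tail is never chosen from the observed counts, which would invalidate
#' the one-sided p-value. Sets are intersected with the reference before
#' testing; sets with no reference hits are skipped with a message.
#'
#' @param list_ids character vector of query feature ids (must be a subset
#'   of `reference_ids`).
#' @param reference_ids character vector: all features detected in the
#'   experiment.
#' @param sets a [gene_set_collection()].
#' @param correct_fdr add a BH `fdr` column (the analysis is also run
#'   uncorrected, in which case the column is absent).
#' @param direction `"over"` (default) or `"under"`: which one-sided
#'   analysis to run.
#' @param test `"binomial"` (default) or `"hypergeometric"` for the exact
#'   sampling-without-replacement tail.
#' @return data frame with columns `term`, `category`, `n`, `N`, `K`, `k`,
#'   `expected`, `fold_enrichment`, `p_value` (and `fdr` when requested),
#'   plus a list column `members` holding each set's reference-restricted
#'   membership (used by [merge_redundant_terms()]).
#' @export
binomial_ora <- function(list_ids, reference_ids, sets, correct_fdr = TRUE,
                         direction = c("over", "under"),
                         test = c("binomial", "hypergeometric")) {
  test <- match.arg(test)
  direction <- match.arg(direction)
  list_ids <- unique(list_ids)
  reference_ids <- unique(reference_ids)
  if (!all(list_ids %in% reference_ids)) {
    stop("query list is not a subset of the reference list")
  }
  n <- length(list_ids)
  N <- length(reference_ids)

  rows <- if (n == 0) list() else lapply(sets, function(s) {
    ref_members <- intersect(s$members, reference_ids)
    K <- length(ref_members)
    if (K == 0) {
      message("skipping set '", s$name, "': no members in the reference")
      return(NULL)
    }
    k <- length(intersect(s$members, list_ids))
    expected <- n * K / N
    fe <- k / expected
    p <- if (test == "binomial") {
      if (direction == "over") stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
      else stats::pbinom(k, n, K / N)
    } else {
      if (direction == "over") stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      else stats::phyper(k, K, N - K, n)
    }
    data.frame(term = s$name, category = s$category, n = n, N = N, K = K,
               k = k, expected = expected, fold_enrichment = fe, p_value = p,
               members = I(list(ref_members)), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), category = character(0),
                      n = integer(0), N = integer(0), K = integer(0),
                      k = integer(0), expected = numeric(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      members = I(list()))
  }
  rownames(out) <- NULL
  if (correct_fdr && nrow(out)) out$fdr <- bh_adjust(out$p_value)
  if (correct_fdr && !nrow(out)) out$fdr <- numeric(0)
  out
}

# Connected components by union-find; edges where Jaccard >= threshold.
single_linkage_components <- function(members, jaccard_min) {
  n <- length(members)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    inter <- length(intersect(members[[i]], members[[j]]))
    uni <- length(union(members[[i]], members[[j]]))
    if (uni > 0 && inter / uni >= jaccard_min) {
      parent[find(j)] <- find(i)
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Merge redundant enrichment terms by membership overlap
#'
#' Single-linkage clustering of terms whose reference-restricted member sets
#' have Jaccard similarity at least `jaccard_min`; each cluster becomes one
#' merged row named after its most significant member, reporting the mean,
#' minimum and maximum fold enrichment over members and the mean significance
#' (mean FDR when present, else mean p).
#'
#' @param rows output of [binomial_ora()] (must carry the `members` column).
#' @param jaccard_min Jaccard threshold for linking two terms (default 0.5).
#' @return data frame: `merged_name`, `member_terms` (list column),
#'   `n_members`, `mean_fold_enrichment`, `min_fold_enrichment`,
#'   `max_fold_enrichment`, `mean_significance`.
#' @export
merge_redundant_terms <- function(rows, jaccard_min = 0.5) {
  if (!nrow(rows)) {
    return(data.frame(merged_name = character(0),
                      member_terms = I(list()), n_members = integer(0),
                      mean_fold_enrichment = numeric(0),
                      min_fold_enrichment = numeric(0),
                      max_fold_enrichment = numeric(0),
                      mean_significance = numeric(0)))
  }
  stopifnot("members" %in% names(rows))
  comp <- single_linkage_components(rows$members, jaccard_min)
  sig <- if ("fdr" %in% names(rows)) rows$fdr else rows$p_value
  out <- lapply(unique(comp), function(cid) {
    idx <- which(comp == cid)
    best <- idx[which.min(rows$p_value[idx])]
    data.frame(merged_name = rows$term[best],
               member_terms = I(list(rows$term[idx])),
               n_members = length(idx),
               mean_fold_enrichment = mean(rows$fold_enrichment[idx]),
               min_fold_enrichment = min(rows$fold_enrichment[idx]),
               max_fold_enrichment = max(rows$fold_enrichment[idx]),
               mean_significance = mean(sig[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$mean_significance, out$merged_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove enrichment terms irrelevant to the cell type
#'
#' Drops rows whose term name matches any of the supplied patterns
#' (case-insensitive regular expressions); removals are reported with a
#' message.
#'
#' @param rows enrichment rows (any data frame with a `term` or
#'   `merged_name` column).
#' @param blocklist character vector of patterns; empty means no filtering.
#' @return the filtered rows.
#' @export
filter_relevance <- function(rows, blocklist = character(0)) {
  if (!length(blocklist) || !nrow(rows)) return(rows)
  nm <- if ("term" %in% names(rows)) rows$term else rows$merged_name
  hit <- Reduce(`|`, lapply(blocklist, function(p) {
    grepl(p, nm, ignore.case = TRUE)
  }))
  if (any(hit)) {
    message("removed ", sum(hit), " term(s): ", paste(nm[hit], collapse = ", "))
  }
  rows[!hit, , drop = FALSE]
}
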