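# Small programmatic fixtures shared across test files.

make_counts <- function(values, n_features, n_samples, lengths = NULL) {
  m <- matrix(values, n_features, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_features)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, "transcript", feature_length_bp = lengths)
}

make_intensities <- function(values, n_features, n_samples) {
  m <- matrix(values, n_features, n_samples,
              dimnames = list(sprintf("p%03d", seq_len(n_features)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, "protein")
}

balanced_design <- function(n_case, n_control) {
  ids <- c(sprintf("s%02d", seq_len(n_case)),
           sprintf("s%02d", n_case + seq_len(n_control)))
  cohort_design(stats::setNames(
    c(rep("case", n_case), rep("control", n_control)), ids))
}

simple_sets <- function(...) {
  defs <- list(...)
  gene_set_collection(lapply(names(defs), function(nm) {
    list(name = nm, category = "functional_group", members = defs[[nm]])
  }))
}

# Brute-force BH step-up (explicit min over every suffix), independent of
# stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, 0)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
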