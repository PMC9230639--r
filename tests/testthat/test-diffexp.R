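test_that("bh_adjust implements the step-up rule and validates input", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:5) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p))         # m/j >= 1 everywhere
    expect_equal(q, bh_oracle(p))
  }
})

test_that("detection counts distinguish protein missingness from true zeros", {
  d <- balanced_design(5, 5)
  vals <- matrix(1, 2, 10, dimnames = list(c("p001", "p002"),
                                           names(d)))
  vals[1, c(1, 3)] <- NA       # 3 of 5 case samples detected
  vals[2, 6:10] <- NA          # zero control detections
  prot <- expression_matrix(vals, "protein")
  det <- detection_counts(prot, d)
  expect_equal(det$n_case, c(3L, 5L))
  expect_equal(det$n_control, c(5L, 0L))

  counts <- make_counts(c(1, 0), 2, 10)[["values"]]
  counts[2, 6:10] <- 0
  tr <- expression_matrix(counts, "transcript")
  det_t <- detection_counts(tr, balanced_design(5, 5))
  expect_equal(det_t$n_control[2], 0L)

  # zero detections in a group excludes the feature from protein DE
  de <- protein_de(prot, d)
  expect_false("p002" %in% de$feature_id)
})

test_that("protein DE computes linear fold-changes and Welch t-tests", {
  d <- balanced_design(3, 3)
  vals <- matrix(c(15, 15, 15, 10, 10, 10,      # exact 1.5-fold, zero var
                   2, 4, 6, 2, 4, 6),           # identical groups
                 2, 6, byrow = TRUE,
                 dimnames = list(c("p001", "p002"), names(d)))
  de <- protein_de(expression_matrix(vals, "protein"), d)
  expect_equal(de$fold_change[1], 1.5)
  expect_equal(de$p_value[2], 1)              # identical case/control values
  expect_false(de$significant[2])

  # under 2 detections in a group: reported but p = q = 1, never significant
  vals2 <- vals
  vals2[1, 2:3] <- NA
  de2 <- protein_de(expression_matrix(vals2, "protein"), d)
  expect_equal(de2$p_value[1], 1)
  expect_equal(de2$q_value[1], 1)
  expect_false(de2$significant[1])

  # planted 2-fold shift, n = 20/20, low noise: detected as upregulated
  set.seed(42)
  d20 <- balanced_design(20, 20)
  base <- exp(rnorm(50, 8, 0.1))
  m <- matrix(rep(base, 40), 50, 40,
              dimnames = list(sprintf("p%03d", 1:50), names(d20)))
  m <- m * exp(matrix(rnorm(2000, 0, 0.1), 50, 40))
  m[1, 1:20] <- m[1, 1:20] * 2
  de3 <- protein_de(expression_matrix(m, "protein"), d20)
  expect_true(de3$significant[1])
  expect_identical(de3$direction[1], "up")
  expect_true(all(de3$q_value >= de3$p_value))
})

test_that("TMM factors satisfy their defining symmetries", {
  set.seed(3)
  counts <- matrix(rnbinom(200 * 6, mu = 50, size = 10), 200, 6,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("s%02d", 1:6)))
  m <- expression_matrix(counts, "transcript")

  # identical libraries: all factors 1
  same <- expression_matrix(counts[, c(1, 1, 1)] |>
                              `colnames<-`(c("a", "b", "c")), "transcript")
  expect_equal(unclass(tmm_factors(same))[1:3], c(a = 1, b = 1, c = 1))

  # pure depth scaling of one of several identical libraries: factors stay
  # equal after rescaling, effective sizes keep the x2
  ident <- counts[, c(1, 1, 1, 1)]
  colnames(ident) <- sprintf("s%02d", 1:4)
  doubled <- ident
  doubled[, 1] <- ident[, 1] * 2L
  f <- tmm_factors(expression_matrix(doubled, "transcript"))
  expect_equal(max(abs(f - f[[2]])), 0, tolerance = 1e-9)
  eff <- attr(f, "effective_lib_size")
  expect_equal(eff[[1]] / eff[[2]], 2, tolerance = 1e-9)

  # product is 1 for arbitrary input
  expect_equal(prod(tmm_factors(m)), 1, tolerance = 1e-12)

  expect_error(tmm_factors(expression_matrix(
    cbind(counts[, 1:2], zero = 0L), "transcript")), "all-zero")
})

test_that("TMM factors match the canonical edgeR implementation", {
  set.seed(9)
  counts <- matrix(rnbinom(500 * 8, mu = 80, size = 5), 500, 8,
                   dimnames = list(sprintf("g%03d", 1:500),
                                   sprintf("s%02d", 1:8)))
  counts[sample(length(counts), 200)] <- 0L
  f <- tmm_factors(expression_matrix(counts, "transcript"))
  expect_equal(unname(unclass(f))[1:8],
               unname(edgeR::calcNormFactors(counts)),
               tolerance = 1e-10)
})

test_that("FPKM follows its defining formula", {
  # two identical samples of total 1e6 reads: factors 1, eff lib 1e6
  counts <- matrix(c(10, 10, 999990, 999990), 2, 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m <- expression_matrix(counts, "transcript",
                         feature_length_bp = c(2000, 1000))
  fk <- fpkm(m)
  expect_equal(fk["g1", "s1"], 5)
  # doubling gene length halves FPKM
  m2 <- expression_matrix(counts, "transcript",
                          feature_length_bp = c(4000, 1000))
  expect_equal(fpkm(m2)["g1", "s1"], 2.5)
  # zero count maps to zero
  counts0 <- counts; counts0[1, 1] <- 0
  m0 <- expression_matrix(counts0, "transcript",
                          feature_length_bp = c(2000, 1000))
  expect_equal(fpkm(m0)["g1", "s1"], 0)
  expect_error(fpkm(expression_matrix(counts, "transcript")), "length")
})

test_that("exact split test is symmetric-null and reduces to binomial", {
  # equal counts and equal library sizes: no evidence, p = 1
  d <- balanced_design(3, 3)
  counts <- matrix(rep(c(5, 10, 20, 40), 6), 4, 6,
                   dimnames = list(sprintf("g%03d", 1:4), names(d)))
  de <- transcript_de(expression_matrix(counts, "transcript"), d)
  expect_equal(de$p_value, rep(1, 4))
  expect_equal(de$fold_change, rep(1, 4))

  # dispersion 0 equals the exact binomial split (same two-sided rule)
  set.seed(5)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    tot <- sample(1:50, 1)
    z1 <- rbinom(1, tot, n1 / (n1 + n2)); z2 <- tot - z1
    expect_equal(nb_exact_test(z1, z2, n1, n2, phi = 0),
                 binom.test(z1, tot, n1 / (n1 + n2))$p.value)
  }
})

test_that("transcript significance needs both the q-value and the 2-fold cut", {
  set.seed(8)
  d <- balanced_design(10, 10)
  # strong but modest shift (x1.5): huge counts make q tiny while FC < 2
  counts <- matrix(rnbinom(50 * 20, mu = 1000, size = 1e6), 50, 20,
                   dimnames = list(sprintf("g%03d", 1:50), names(d)))
  counts[1, 1:10] <- rnbinom(10, mu = 1500, size = 1e6)
  de <- transcript_de(expression_matrix(counts, "transcript"), d,
                      dispersion = 0)
  expect_lt(de$q_value[1], 0.01)
  expect_lt(de$fold_change[1], 2)
  expect_false(de$significant[1])
  expect_identical(de$direction[1], "none")

  # same shift at x4 passes both gates
  counts[2, 1:10] <- rnbinom(10, mu = 4000, size = 1e6)
  de2 <- transcript_de(expression_matrix(counts, "transcript"), d,
                       dispersion = 0)
  expect_true(de2$significant[2])
  expect_identical(de2$direction[2], "up")
})

test_that("transcript test is stable under integer rescaling of one sample", {
  set.seed(21)
  d <- balanced_design(5, 5)
  counts <- matrix(rnbinom(300 * 10, mu = 60, size = 8), 300, 10,
                   dimnames = list(sprintf("g%03d", 1:300), names(d)))
  de1 <- transcript_de(expression_matrix(counts, "transcript"), d,
                       dispersion = 0.1)
  scaled <- counts
  scaled[, 3] <- counts[, 3] * 3L
  de2 <- transcript_de(expression_matrix(scaled, "transcript"), d,
                       dispersion = 0.1)
  # effective-size compensation keeps fold-changes and calls close
  expect_equal(de2$fold_change, de1$fold_change, tolerance = 0.05)
  expect_gt(cor(-log10(de1$p_value + 1e-300), -log10(de2$p_value + 1e-300)),
            0.98)
})
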