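test_that("detection filter is inclusive at the boundary", {
  d <- balanced_design(6, 6)
  vals <- matrix(1, 3, 12, dimnames = list(sprintf("p%03d", 1:3), names(d)))
  vals[1, 1:2] <- NA               # 4 case detections, 6 control
  vals[2, 1] <- NA; vals[2, 7] <- NA  # 5 and 5
  prot <- expression_matrix(vals, "protein")
  kept <- min_detection_filter(prot, d, min_per_group = 5)
  expect_false("p001" %in% kept)
  expect_true("p002" %in% kept)
  expect_setequal(min_detection_filter(prot, d, min_per_group = 0),
                  sprintf("p%03d", 1:3))
  expect_error(min_detection_filter(prot, d, min_per_group = 7),
               "group size")
})

test_that("direction classes use strict 1.1/0.9 cuts", {
  expect_identical(classify_direction(c(0.85, 1.1, 0.9, 1.1000001, 2.4)),
                   c("down", "unchanged", "unchanged", "up", "up"))
  expect_error(classify_direction(c(1.2, 0)), "positive")
  expect_error(classify_direction(-1), "positive")
  # exactly one class per feature, counts partition the input
  set.seed(2)
  fc <- exp(rnorm(500, 0, 0.3))
  cl <- classify_direction(fc)
  expect_equal(sum(cl == "up") + sum(cl == "down") + sum(cl == "unchanged"),
               500)
})

test_that("two-sample proportion test matches the Yates chi-square oracle", {
  for (n1 in c(5, 11, 26, 44, 60)) for (n2 in c(7, 26, 60)) {
    for (x1 in unique(round(seq(0, n1, length.out = 5)))) {
      for (x2 in unique(round(seq(0, n2, length.out = 5)))) {
        ph <- (x1 + x2) / (n1 + n2)
        if (ph <= 0 || ph >= 1) {
          expect_equal(two_sample_prop_test(x1, x2, n1, n2), 1)
          next
        }
        tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2)
        oracle <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
        expect_equal(two_sample_prop_test(x1, x2, n1, n2), oracle,
                     tolerance = 1e-12)
      }
    }
  }
  # swapping the two samples leaves p unchanged
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(2:60, 1); n2 <- sample(2:60, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    expect_equal(two_sample_prop_test(x1, x2, n1, n2),
                 two_sample_prop_test(x2, x1, n2, n1))
  }
  expect_equal(two_sample_prop_test(4, 4, 9, 9), 1)  # zero numerator
})

test_that("set-level direction test counts strict movers only", {
  r <- set_direction_test(c(rep(1.2, 5), rep(0.8, 5)))
  expect_equal(r$n_up, 5)
  expect_equal(r$n_down, 5)
  expect_equal(r$prop_p, 1)

  # FC exactly 1 sits in neither arm
  r2 <- set_direction_test(c(1, 1, 1.3))
  expect_equal(r2$n_up, 1)
  expect_equal(r2$n_down, 0)

  expect_true(is.na(set_direction_test(c(1, 1))$prop_p))
})

test_that("magnitude test is a one-sample t against unit fold-change", {
  expect_true(is.na(set_magnitude_test(c(1, 1, 1))$magnitude_p))
  expect_true(is.na(set_magnitude_test(2)$magnitude_p))
  expect_equal(set_magnitude_test(c(0.8, 1.2))$magnitude_p, 1)

  # closed-form t with df = 3
  fc <- c(1.2, 1.3, 1.4, 1.5)
  t_stat <- (mean(fc) - 1) / (sd(fc) / sqrt(4))
  r <- set_magnitude_test(fc)
  expect_equal(r$magnitude_p, 2 * pt(-abs(t_stat), df = 3))
  expect_equal(r$mean_fc_up, 1.35)
  expect_true(is.nan(r$mean_fc_down))

  # log-scale option tests log fold-changes against zero
  r_log <- set_magnitude_test(c(0.5, 2), log = TRUE)
  expect_equal(r_log$magnitude_p, 1)
})

test_that("global direction test uses the detected population as denominator", {
  expect_equal(global_direction_test(10, 10, 500), 1)
  expect_error(global_direction_test(1, 1, 0), "no detected")
  # more up than down against a large population is detected
  expect_lt(global_direction_test(590, 49, 2776), 1e-50)
})

test_that("coupling classification follows the fixed lookup", {
  row <- function(set, up, down, p) {
    data.frame(set_name = set, ome = "x", n_members_detected = up + down,
               n_up = up, n_down = down, mean_fc_up = 1.5, mean_fc_down = 0.7,
               prop_p = p, magnitude_p = 0.5)
  }
  expect_identical(
    classify_coupling(row("CI", 3, 20, 0.001), row("CI", 19, 7, 0.002))$coupling,
    "discordant_t_down_p_up")
  expect_identical(
    classify_coupling(row("CV", 3, 16, 1e-4), row("CV", 2, 10, 0.03))$coupling,
    "concordant_down")
  expect_identical(
    classify_coupling(row("up", 20, 3, 0.001), row("up", 2, 10, 0.03))$coupling,
    "discordant_t_up_p_down")
  expect_identical(
    classify_coupling(row("im", 20, 3, 0.001), row("im", 10, 2, 0.03))$coupling,
    "concordant_up")
  # both non-significant: undetermined
  expect_identical(
    classify_coupling(row("ns", 6, 5, 0.9), row("ns", 5, 6, 0.8))$coupling,
    "undetermined")
  # missing ome row: undetermined, call 'none'
  res <- classify_coupling(row("solo", 3, 20, 0.001), NULL)
  expect_identical(res$coupling, "undetermined")
  expect_identical(res$protein_call, "none")
  # empty set (NA prop_p): call 'none'
  expect_identical(
    classify_coupling(row("na", 0, 0, NA), row("na", 10, 2, 0.03))$transcript_call,
    "none")
})

test_that("concordance tables respect the detection filter", {
  de <- data.frame(feature_id = sprintf("f%02d", 1:6),
                   fold_change = c(1.5, 1.2, 0.7, 0.8, 1.01, 1),
                   n_detected_case = c(6, 6, 6, 4, 6, 6),
                   n_detected_control = c(6, 6, 6, 6, 6, 6))
  sets <- simple_sets(S = sprintf("f%02d", 1:6))
  tab <- concordance_table(de, sets, "protein", min_detect = 5)
  # f04 filtered out; f06 (FC exactly 1) in neither arm
  expect_equal(tab$n_members_detected, 5)
  expect_equal(tab$n_up, 3)
  expect_equal(tab$n_down, 1)
  expect_equal(tab$mean_fc_up, mean(c(1.5, 1.2, 1.01)))
  expect_equal(tab$mean_fc_down, 0.7)
  expect_equal(tab$prop_p, two_sample_prop_test(3, 1, 4, 4))
})

test_that("run summary reports counts, percentages and global tests", {
  de_mock <- function(n, n_up, n_down) {
    data.frame(feature_id = sprintf("m%04d", seq_len(n)),
               fold_change = 1,
               n_detected_case = 6, n_detected_control = 6,
               direction = c(rep("up", n_up), rep("down", n_down),
                             rep("none", n - n_up - n_down)))
  }
  sets <- simple_sets(S = "m0001")
  s <- build_summary(de_mock(100, 4, 4), de_mock(100, 21, 2), sets,
                     min_detect = 5)
  expect_equal(s$global$pct_up, c(4, 21))
  expect_equal(s$global$global_p[1], 1)
  expect_lt(s$global$global_p[2], 0.001)
  expect_identical(s$coupling$set_name, "S")

  # degenerate run: nothing significant
  s0 <- build_summary(de_mock(50, 0, 0), de_mock(50, 0, 0), sets)
  expect_equal(s0$global$pct_up, c(0, 0))
  expect_equal(s0$global$global_p, c(1, 1))
})
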