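# Brute-force oracle for the detection-call rule: a probe is EXCLUDED when
# every group has 2 or 3 Absent calls out of 3; otherwise retained.
call_rule_oracle <- function(g1, g2) {
  !(sum(g1 == "A") >= 2 && sum(g2 == "A") >= 2)
}

test_that("detection-call filter matches the exclusion-sentence oracle on
           all 729 call-pattern pairs", {
  pats <- expand.grid(a1 = c("P", "M", "A"), a2 = c("P", "M", "A"),
                      a3 = c("P", "M", "A"), b1 = c("P", "M", "A"),
                      b2 = c("P", "M", "A"), b3 = c("P", "M", "A"),
                      stringsAsFactors = FALSE)
  expect_identical(nrow(pats), 729L)
  call <- as.matrix(pats)
  rownames(call) <- sprintf("pat%03d", seq_len(nrow(call)))
  sig <- matrix(100, nrow(call), 6L, dimnames = dimnames(call))
  mat <- toy_matrix(sig, call)
  kept <- detection_call_filter(mat)
  oracle <- vapply(seq_len(nrow(pats)), function(i)
    call_rule_oracle(call[i, 1:3], call[i, 4:6]), FALSE)
  expect_setequal(kept, rownames(call)[oracle])
  # stricter reading: only Present calls keep a probe eligible
  kept_strict <- detection_call_filter(
    mat, filter_params(marginal = "absent"))
  oracle_strict <- vapply(seq_len(nrow(pats)), function(i)
    sum(call[i, 1:3] == "P") >= 2 || sum(call[i, 4:6] == "P") >= 2, FALSE)
  expect_setequal(kept_strict, rownames(call)[oracle_strict])
})

test_that("detection-call filter edge cases follow the published rule", {
  call <- rbind(allA = rep("A", 6),
                ppa = c("P", "P", "A", "A", "A", "A"),
                onegrp = c("A", "A", "A", "P", "P", "P"))
  sig <- matrix(100, 3, 6, dimnames = list(rownames(call), NULL))
  kept <- detection_call_filter(toy_matrix(sig, call))
  expect_false("allA" %in% kept)
  expect_true(all(c("ppa", "onegrp") %in% kept))
})

test_that("intensity filter keeps induced genes and drops dim ones", {
  sig <- rbind(dim = rep(49.9, 6),
               induced = c(10, 10, 10, 500, 500, 500),
               bright = rep(200, 6))
  mat <- toy_matrix(sig)
  kept <- intensity_filter(mat, toy_condition)
  expect_setequal(kept, c("induced", "bright"))
  all_kept <- intensity_filter(mat, toy_condition,
                               filter_params(intensity_floor = 0))
  expect_setequal(all_kept, rownames(sig))
})

test_that("welch_t agrees with the textbook formula and stats::t.test", {
  # hand-computed closed form for a fixed example
  x <- c(10, 11, 12); y <- c(14, 15, 16)
  res <- welch_t(x, y)
  se2 <- var(x) / 3 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  # identical vectors
  expect_identical(welch_t(x, x)[c("statistic", "p_value")],
                   list(statistic = 0, p_value = 1))
  # p decreases monotonically as the shift grows
  ps <- vapply(c(1, 5, 25, 125), function(d) welch_t(x, x + d)$p_value, 0)
  expect_true(all(diff(ps) < 0))
  # random-input agreement with the independent implementation
  set.seed(99)
  for (i in 1:200) {
    a <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ref <- t.test(a, b)
    got <- welch_t(a, b)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  }
  # symmetry: p invariant, t flips sign
  expect_equal(welch_t(y, x)$statistic, -res$statistic)
  expect_equal(welch_t(y, x)$p_value, res$p_value)
})

test_that("fold-change thresholds are strict inequalities", {
  sig <- rbind(boundary = c(99, 100, 101, 149, 150, 151),
               up = c(99, 100, 101, 299, 300, 301),
               down = c(299, 300, 301, 99, 100, 101))
  de <- call_de(toy_matrix(sig), toy_condition)
  expect_false("boundary" %in% c(de$up$probe_id, de$down$probe_id))
  expect_identical(de$up$probe_id, "up")
  expect_identical(de$down$probe_id, "down")
  expect_identical(attr(de$up, "label"), "IQISPFLI-up")
})

test_that("planted up-regulated genes land in the up list only", {
  planted <- data.frame(probe_id = sprintf("probe_%05d", 1:20),
                        condition = "IQI.SPF.LI", direction = "up",
                        log2_effect = 2)
  des <- simulation_design(
    conditions = data.frame(strain = "IQI", flora = "SPF", tissue = "LI"),
    n_probes = 1000L, planted = planted, seed = 13L)
  sim <- simulate_expression(des)
  de <- call_de(sim$matrix, toy_condition)
  expect_gte(sum(planted$probe_id %in% de$up$probe_id), 19L)
  expect_identical(sum(planted$probe_id %in% de$down$probe_id), 0L)
  # lists never overlap and are sorted as printed
  expect_length(intersect(de$up$probe_id, de$down$probe_id), 0L)
  expect_false(is.unsorted(rev(de$up$fold_change)))
  expect_false(is.unsorted(de$down$fold_change))
})

test_that("null-design p-filter pass rate shows the small-sample
           conservatism of Welch's test", {
  des <- simulation_design(
    conditions = data.frame(strain = "IQI", flora = "SPF", tissue = "LI"),
    n_probes = 4000L, seed = 17L)
  mat <- simulate_expression(des)$matrix
  keep <- intersect(detection_call_filter(mat),
                    intensity_filter(mat, toy_condition))
  sig <- log2(SummarizedExperiment::assay(mat, "signal")[keep, ] + 1)
  cd <- SummarizedExperiment::colData(mat)
  ps <- vapply(seq_along(keep), function(i)
    welch_t(sig[i, cd$treatment == "JTX"],
            sig[i, cd$treatment == "control"])$p_value, 0)
  rate <- mean(ps < 0.1)
  # at n = 3 the Welch test rejects below its nominal level
  expect_gt(rate, 0.06)
  expect_lt(rate, 0.10)
})

test_that("dropping the intensity filter never shrinks the lists", {
  des <- synthetic_study_design(seed = 31L, n_probes = 800L, n_planted = 15L)
  mat <- simulate_expression(des)$matrix
  with_floor <- call_de(mat, toy_condition)
  no_floor <- call_de(mat, toy_condition, filter_params(intensity_floor = 0))
  expect_true(all(with_floor$up$probe_id %in% no_floor$up$probe_id))
  expect_true(all(with_floor$down$probe_id %in% no_floor$down$probe_id))
})
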