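# Independent O(m^2) oracle for module matching: double loop over the two
# single-site match tables, re-deriving the constraints from scratch.
module_oracle <- function(ma, mb, dmin, dmax, same_strand = TRUE,
                          order_fixed = TRUE, same_motif = FALSE) {
  n <- 0L
  for (i in seq_len(nrow(ma))) {
    for (j in seq_len(nrow(mb))) {
      if (ma$sequence_id[i] != mb$sequence_id[j]) next
      d <- mb$offset[j] - ma$offset[i]
      sp <- if (order_fixed) d else abs(d)
      if (sp < dmin || sp > dmax) next
      if (same_strand && ma$strand[i] != mb$strand[j]) next
      if (same_motif && d == 0 && ma$strand[i] == mb$strand[j]) next
      n <- n + 1L
    }
  }
  n
}

test_that("a degenerate one-hot matrix finds exact matches only", {
  p <- gaaa_pwm()
  hit <- scan_pwm(c(s1 = "CCGAAACC"), p, threshold = 1.0)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$offset, 2L)
  expect_identical(hit$strand, "+")
  # the reverse complement gives the mirrored minus-strand match
  rc <- scan_pwm(c(s1 = "GGTTTCGG"), p, threshold = 1.0)
  expect_identical(nrow(rc), 1L)
  expect_identical(rc$offset, 2L)
  expect_identical(rc$strand, "-")
  # matrix longer than the sequence: silently empty
  expect_identical(nrow(scan_pwm(c(s = "GA"), p, 0.5)), 0L)
})

test_that("scanning reverse-complemented input mirrors coordinates and
           flips strands", {
  seqs <- random_sequences(10, 120, seed = 41)
  p <- irf_standin_pwm()
  fwd <- scan_pwm(seqs, p, threshold = 0.8)
  rc <- vapply(seqs, function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  names(rc) <- names(seqs)
  rev <- scan_pwm(rc, p, threshold = 0.8)
  L <- length(p)
  key_fwd <- with(fwd, paste(sequence_id, offset, strand))
  key_mirr <- with(rev, paste(sequence_id, 120 - offset - L,
                              ifelse(strand == "+", "-", "+")))
  expect_setequal(key_mirr, key_fwd)
  expect_equal(sort(rev$score), sort(fwd$score), tolerance = 1e-12)
})

test_that("raising the threshold never increases match counts", {
  seqs <- random_sequences(20, 200, seed = 8)
  p <- irf_standin_pwm()
  counts <- vapply(c(0.7, 0.8, 0.9, 0.99),
                   function(th) nrow(scan_pwm(seqs, p, th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("spacing constraints bound module matches exactly", {
  s <- c(s1 = paste0("CC", "GAAA", "CCCCCC", "GAAA", "CC"))  # 10 bp apart
  p <- gaaa_pwm()
  m_in <- match_module(s, tandem_module(p, c(5, 50)), threshold = 1.0)
  expect_identical(nrow(m_in), 1L)
  expect_identical(m_in$spacing, 10L)
  m_out <- match_module(s, tandem_module(p, c(11, 50)), threshold = 1.0)
  expect_identical(nrow(m_out), 0L)
  # the single physical site never pairs with itself
  m_self <- match_module(c(s1 = "CCGAAACC"), tandem_module(p, c(1, 50)), 1.0)
  expect_identical(nrow(m_self), 0L)
  expect_error(module_model(p, p, distance_range = c(0, 10)), "d_min >= 1")
})

test_that("match_module equals brute-force pair enumeration on random
           promoters", {
  seqs <- random_sequences(100, 150, seed = 77)
  pa <- gaaa_pwm()
  pb <- pwm_matrix("TTCC", consensus_pwm("TTCC"))
  ma <- scan_pwm(seqs, pa, 1.0)
  mb <- scan_pwm(seqs, pb, 1.0)
  mod <- module_model(pa, pb, distance_range = c(5, 60),
                      strand_rule = "same", order_fixed = TRUE)
  got <- match_module(seqs, mod, threshold = 1.0)
  expect_identical(nrow(got), module_oracle(ma, mb, 5, 60))
  # same-motif tandem model against the oracle
  tand <- tandem_module(pa, c(1, 80))
  got2 <- match_module(seqs, tand, threshold = 1.0)
  expect_identical(nrow(got2),
                   module_oracle(ma, ma, 1, 80, same_motif = TRUE))
  # unordered variant
  mod3 <- module_model(pa, pb, distance_range = c(5, 60),
                       strand_rule = "same", order_fixed = FALSE)
  got3 <- match_module(seqs, mod3, threshold = 1.0)
  expect_identical(nrow(got3),
                   module_oracle(ma, mb, 5, 60, order_fixed = FALSE))
})

test_that("match counts are additive over disjoint promoter subsets", {
  mod <- tandem_module(irf_standin_pwm())
  sim <- simulate_promoters(promoter_plant_spec(
    30L, module = mod, plant_rate = 1, seed = 19L))
  seqs <- as.character(sim$promoters$seqs)
  whole <- count_module_matches(seqs, mod)
  part1 <- count_module_matches(seqs[1:15], mod)
  part2 <- count_module_matches(seqs[16:30], mod)
  expect_identical(whole$total, part1$total + part2$total)
  expect_identical(nrow(count_module_matches(c(a = "CCCC"), mod)$matches), 0L)
})

test_that("framework discovery ranks the planted module first among decoys", {
  p <- irf_standin_pwm()
  mod <- tandem_module(p, c(12, 16))
  sim <- simulate_promoters(promoter_plant_spec(
    30L, module = mod, plant_rate = 1, seed = 23L))
  decoys <- lapply(1:10, function(i)
    random_pwm(paste0("decoy", i), 8L, seed = 100 + i))
  lib <- c(list(IRF = p), setNames(decoys, paste0("decoy", 1:10)))
  ranked <- discover_frameworks(sim$promoters, lib, threshold = 0.85,
                                min_support = 0.8, spacing_tol = 2L)
  expect_gt(nrow(ranked), 0L)
  expect_identical(c(ranked$motif_a[[1L]], ranked$motif_b[[1L]]),
                   c("IRF", "IRF"))
  expect_gte(ranked$support_frac[[1L]], 0.8)
})

test_that("background-only promoters support no high-recurrence framework", {
  p <- irf_standin_pwm()
  sim <- simulate_promoters(promoter_plant_spec(30L, seed = 29L))
  decoys <- lapply(1:3, function(i)
    random_pwm(paste0("d", i), 8L, seed = 200 + i))
  lib <- c(list(IRF = p), setNames(decoys, paste0("d", 1:3)))
  ranked <- discover_frameworks(sim$promoters, lib, threshold = 0.85,
                                min_support = 0.8, spacing_tol = 2L)
  expect_identical(nrow(ranked), 0L)
  # degenerate q = 0 reports every pair in the library
  all_pairs <- discover_frameworks(sim$promoters, lib, threshold = 0.85,
                                   min_support = 0, spacing_tol = 2L)
  expect_identical(nrow(all_pairs), 10L)   # all i <= j pairs of 4 motifs
  expect_error(discover_frameworks(sim$promoters, list()), "empty")
})
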