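test_that("expression tables round-trip through TSV", {
  des <- simulation_design(
    conditions = data.frame(strain = "IQI", flora = "SPF", tissue = "LI"),
    n_probes = 10L, seed = 42L)
  mat <- simulate_expression(des)$matrix
  tsv <- withr::local_tempfile(fileext = ".tsv")
  stsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(mat, tsv, stsv)
  back <- read_expression_table(tsv, stsv)
  expect_equal(SummarizedExperiment::assay(back, "signal"),
               SummarizedExperiment::assay(mat, "signal"))
  expect_identical(SummarizedExperiment::assay(back, "call"),
                   SummarizedExperiment::assay(mat, "call"))
  cd <- SummarizedExperiment::colData(back)
  expect_identical(as.integer(table(cd$treatment)), c(3L, 3L))
})

test_that("malformed expression input is rejected with named errors", {
  sig <- matrix(100, 2, 6, dimnames = list(c("a", "b"), NULL))
  call <- matrix("P", 2, 6, dimnames = dimnames(sig))
  call[1, 1] <- "X"
  samples <- data.frame(
    sample_id = paste0("s", 1:6), strain = "IQI", flora = "SPF",
    tissue = "LI", treatment = rep(c("control", "JTX"), each = 3),
    replicate = rep(1:3, 2))
  expect_error(expression_matrix(sig, call, samples), "invalid detection call")
  call[1, 1] <- "P"
  sig[2, 2] <- -1
  expect_error(expression_matrix(sig, call, samples), "non-negative")
  sig[2, 2] <- 100
  rownames(sig) <- rownames(call) <- c("a", "a")
  expect_error(expression_matrix(sig, call, samples), "duplicate probe_id")
})

test_that("packaged gene-list fixtures parse to the published row counts", {
  lists <- jtx_gene_lists()
  expect_identical(vapply(lists, nrow, 0L),
                   c("SPFLI-up" = 27L, "BALBLI-down" = 22L,
                     "GFLI-down" = 31L, "GFSI-down" = 42L))
  expect_identical(attr(lists[["SPFLI-up"]], "direction"), "up")
  expect_identical(attr(lists[["GFSI-down"]], "direction"), "down")
  # order preserved as printed: strongest fold change first
  expect_identical(lists[["SPFLI-up"]]$symbol[1:2], c("Ifit3", "Usp18"))
  expect_identical(lists[["GFSI-down"]]$probe_id[[1L]], "103842_at")
})

test_that("gene-list reader validates its input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# direction: up", f)
  expect_error(read_gene_list(f), "no records")
  writeLines(c("# direction: up",
               "probe_id\tgene_name\tsymbol\tentrez\tfold_change\tp_value",
               "x_at\tgene\tGx\t1\tnot_a_number\t0.05"), f)
  expect_error(read_gene_list(f))
  lists <- jtx_gene_lists("SPFLI-up")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_gene_list(lists[[1L]], out)
  back <- read_gene_list(out)
  expect_equal(as.data.frame(back), as.data.frame(lists[[1L]]))
  expect_identical(attr(back, "label"), "SPFLI-up")
})

test_that("FASTA ingestion is lossless and rejects bad alphabets", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">prom1 gene=Irf7 span=-500..-480", "ACGTACGTACGTACGTACGT",
               ">prom2", "GGGCCCNNNA"), fa)
  ps <- read_promoter_fasta(fa, label = "demo")
  expect_length(ps, 2L)
  expect_identical(Biostrings::width(ps$seqs), c(20L, 10L))
  expect_identical(ps$info$gene_symbol, c("Irf7", "prom2"))
  expect_identical(ps$info$span_start, c(-500L, -500L))
  expect_identical(ps$info$span_end[[1L]], -480L)
  out <- withr::local_tempfile(fileext = ".fa")
  write_promoter_fasta(ps, out)
  back <- read_promoter_fasta(out)
  expect_identical(as.character(back$seqs), as.character(ps$seqs))
  writeLines(c(">bad", "ACGTR"), fa)  # IUPAC R: parseable, not ACGTN
  expect_error(read_promoter_fasta(fa), "bad")
})

test_that("BED export uses 0-based half-open coordinates and round-trips", {
  m <- data.frame(sequence_id = "prom1", offset = 5L, length = 12L,
                  strand = "+", score = 0.9, name = "mod")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(m, bed)
  line <- strsplit(readLines(bed)[[1L]], "\t")[[1L]]
  expect_identical(line[1:3], c("prom1", "5", "17"))
  expect_identical(line[[6L]], "+")
  back <- read_bed(bed)
  expect_identical(back$start, 5L)
  expect_identical(back$end, 17L)
  expect_identical(back$strand, "+")
  # intervals always inside the sequence for real scans
  seqs <- random_sequences(5, 80, seed = 9)
  hits <- scan_pwm(seqs, gaaa_pwm(), 1.0)
  if (nrow(hits)) {
    write_bed(hits, bed)
    b <- read_bed(bed)
    expect_true(all(b$start >= 0 & b$start < b$end & b$end <= 80))
    expect_identical(nrow(b), nrow(hits))
  }
})

test_that("PWM blocks round-trip and are properly normalised", {
  pwms <- read_pwm(system.file("extdata", "irf_like_standin.pwm",
                               package = "ifnmodmap"))
  expect_named(pwms, "IRF_like_standin")
  p <- pwms[[1L]]
  expect_true(all(abs(rowSums(p$prob) - 1) < 1e-9))
  expect_gte(nrow(p$prob), 4L)
  f <- withr::local_tempfile(fileext = ".pwm")
  write_pwm(p, f)
  back <- read_pwm(f)[[1L]]
  expect_equal(back$prob, p$prob, tolerance = 1e-9)
  expect_error(pwm_matrix("short", consensus_pwm("GA")), "length >= 4")
})
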