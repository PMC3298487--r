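# Shared helpers: tiny in-code fixtures used across test files.

# A one-condition expression matrix with hand-chosen signals and calls.
# `signal` and `call` are probes x 6 matrices (3 control + 3 JTX columns).
toy_matrix <- function(signal, call = NULL) {
  signal <- as.matrix(signal)
  if (is.null(rownames(signal)))
    rownames(signal) <- sprintf("p%02d", seq_len(nrow(signal)))
  if (is.null(call))
    call <- matrix("P", nrow(signal), 6L, dimnames = dimnames(signal))
  samples <- data.frame(
    sample_id = paste0("s", 1:6), strain = "IQI", flora = "SPF",
    tissue = "LI", treatment = rep(c("control", "JTX"), each = 3L),
    replicate = rep(1:3, 2L), stringsAsFactors = FALSE)
  expression_matrix(signal, call, samples)
}

toy_condition <- list(strain = "IQI", flora = "SPF", tissue = "LI")

# Degenerate exact-match motif used for constructed scanning cases.
gaaa_pwm <- function() pwm_matrix("GAAA", consensus_pwm("GAAA"))

irf_standin_pwm <- function() {
  read_pwm(system.file("extdata", "irf_like_standin.pwm",
                       package = "ifnmodmap", mustWork = TRUE))[[1L]]
}

# Random promoter-like sequences for property tests.
random_sequences <- function(n, len, seed) {
  set.seed(seed)
  out <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
  names(out) <- sprintf("rs%03d", seq_len(n))
  out
}

# Informative decoy PWMs around a random consensus (real library matrices
# are specific; a near-flat decoy would match background constantly).
random_pwm <- function(name, len, seed) {
  set.seed(seed)
  cons <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  m <- matrix(0.05, nrow = len, ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_len(len), match(cons, colnames(m)))] <- 0.85
  pwm_matrix(name, m)
}
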