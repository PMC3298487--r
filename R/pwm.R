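DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' A `PwmMatrix` stores per-position base probabilities for a binding-site
#' motif, together with the pseudocount used to regularise them and the
#' background base frequencies against which log-odds are taken. Rows are
#' positions, columns the bases A, C, G, T.
#'
#' @param name motif name, e.g. `"V$IRFF"`.
#' @param prob numeric matrix (length x 4) of per-position base
#'   probabilities or counts; columns in A, C, G, T order. Counts are
#'   normalised per row.
#' @param pseudocount small positive value added to each probability before
#'   renormalisation; guards against `log(0)` for one-hot columns.
#' @param background base frequencies (A, C, G, T), must sum to 1.
#' @return An object of class `PwmMatrix`.
#' @examples
#' m <- pwm_matrix("GAAA", consensus_pwm("GAAA"))
#' nrow(m$prob)
#' @export
pwm_matrix <- function(name, prob, pseudocount = 0.01,
                       background = rep(0.25, 4)) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4L)
    stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(prob) < 4L)
    stop("PWM must have length >= 4, got ", nrow(prob))
  if (any(prob < 0) || any(!is.finite(prob)))
    stop("PWM entries must be finite and non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0))
    stop("background frequencies must be positive and sum to 1")
  raw <- prob / rowSums(prob)                   # counts -> probabilities
  prob <- (raw + pseudocount) / (1 + 4 * pseudocount)
  dimnames(raw) <- dimnames(prob) <- list(NULL, DNA_BASES)
  structure(list(name = name, prob = prob, prob_raw = raw,
                 pseudocount = pseudocount,
                 background = stats::setNames(as.numeric(background),
                                              DNA_BASES)),
            class = "PwmMatrix")
}

#' @export
print.PwmMatrix <- function(x, ...) {
  cat(sprintf("PwmMatrix '%s' (%d bp)\n", x$name, nrow(x$prob)))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' @export
length.PwmMatrix <- function(x) nrow(x$prob)

#' Build a one-hot probability matrix from a consensus string
#'
#' Degenerate helper mainly used in examples and tests: the returned matrix
#' puts all probability mass on the consensus base at each position (before
#' pseudocount regularisation by [pwm_matrix()]).
#'
#' @param consensus string over A, C, G, T.
#' @return A length x 4 numeric matrix.
#' @export
consensus_pwm <- function(consensus) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% DNA_BASES)) stop("consensus must be over ACGT")
  m <- matrix(0, nrow = length(bases), ncol = 4,
              dimnames = list(NULL, DNA_BASES))
  m[cbind(seq_along(bases), match(bases, DNA_BASES))] <- 1
  m
}

# Majority-base consensus of a PwmMatrix (display only).
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$prob, 1L, which.max)], collapse = "")
}

# Log2-odds score matrix (positions x 4) of a PwmMatrix.
pwm_log_odds <- function(pwm) {
  sweep(log2(pwm$prob), 2L, log2(pwm$background), `-`)
}

# Reverse complement of a PwmMatrix: reverse positions, swap A<->T, C<->G.
pwm_reverse_complement <- function(pwm) {
  rc <- pwm$prob[rev(seq_len(nrow(pwm$prob))), c("T", "G", "C", "A"),
                 drop = FALSE]
  colnames(rc) <- DNA_BASES
  out <- pwm
  out$prob <- rc
  out
}

#' Read position weight matrices from a plain-text file
#'
#' The format is a minimal motif block format: a header line `>NAME`
#' followed by one row per position with four whitespace-separated numbers
#' (A, C, G, T). Several blocks per file are allowed; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @inheritParams pwm_matrix
#' @return A named list of [PwmMatrix][pwm_matrix] objects.
#' @export
read_pwm <- function(path, pseudocount = 0.01, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || !startsWith(lines[[1L]], ">"))
    stop("PWM file must start with a '>NAME' header: ", path)
  idx <- cumsum(startsWith(lines, ">"))
  out <- lapply(split(lines, idx), function(block) {
    name <- sub("^>\\s*", "", block[[1L]])
    rows <- strsplit(block[-1L], "\\s+")
    if (!length(rows)) stop("PWM block '", name, "' has no rows")
    mat <- do.call(rbind, lapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(r))
      if (length(v) != 4L || anyNA(v))
        stop("PWM block '", name, "' has a malformed row")
      v
    }))
    pwm_matrix(name, mat, pseudocount = pseudocount, background = background)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write position weight matrices to a plain-text file
#'
#' Inverse of [read_pwm()]; the raw (pre-pseudocount) probabilities are
#' written, so a write/read round trip reproduces the matrices exactly up
#' to printed precision.
#'
#' @param pwms a `PwmMatrix` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "PwmMatrix")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    utils::write.table(format(p$prob_raw, digits = 12), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
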