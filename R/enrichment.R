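#' Appearance ratio of a promoter module
#'
#' Total module matches divided by the number of promoter sequences
#' scanned. A sequence can carry several matches, so the ratio may exceed
#' one. Vectorised over both arguments.
#'
#' @param matches non-negative integer count(s) of module matches.
#' @param n_sequences positive integer count(s) of promoter sequences.
#' @return Numeric ratio(s).
#' @examples
#' appearance_ratio(31, 26)
#' @export
appearance_ratio <- function(matches, n_sequences) {
  if (any(n_sequences <= 0)) stop("n_sequences must be >= 1")
  if (any(matches < 0)) stop("matches must be non-negative")
  matches / n_sequences
}

#' Enrichment of a module across gene-list promoter sets
#'
#' Summarises per-list appearance ratios of one framework as mean and
#' sample SD (n - 1) and tests them against the genome-wide background
#' ratio, treated as a fixed constant, with a two-sided one-sample t-test
#' (df = number of lists - 1). Ratios are kept at full precision; rounding
#' to the three decimals of presentation tables is left to the caller.
#'
#' @param matches integer vector of module-match counts, one per gene list.
#' @param n_sequences integer vector of promoter-sequence counts per list.
#' @param background_matches,background_sequences background counts over
#'   all annotated promoters.
#' @param module module name carried into the result.
#' @param sets optional labels of the gene lists.
#' @return A list of class `EnrichmentResult`: per-list `ratio`,
#'   `mean_ratio`, `sd_ratio`, `background_ratio`, `statistic`, `df`,
#'   `p_value`.
#' @export
enrichment_summary <- function(matches, n_sequences, background_matches,
                               background_sequences, module = "",
                               sets = NULL) {
  if (length(matches) != length(n_sequences))
    stop("matches and n_sequences must have equal length")
  if (length(matches) < 2L)
    stop("need >= 2 gene lists (SD undefined otherwise)")
  if (background_sequences <= 0)
    stop("background_sequences must be positive")
  ratio <- appearance_ratio(matches, n_sequences)
  bg <- appearance_ratio(background_matches, background_sequences)
  n <- length(ratio)
  m <- mean(ratio)
  s <- stats::sd(ratio)
  if (s == 0) {
    t <- if (m == bg) 0 else sign(m - bg) * Inf
    p <- if (m == bg) 1 else 0
  } else {
    t <- (m - bg) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1)
  }
  if (!is.null(sets)) names(ratio) <- sets
  structure(list(module = module, matches = matches,
                 n_sequences = n_sequences, ratio = ratio,
                 mean_ratio = m, sd_ratio = s,
                 background_matches = background_matches,
                 background_sequences = background_sequences,
                 background_ratio = bg, statistic = t, df = n - 1,
                 p_value = p),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("%s: %.3f +/- %.3f vs background %.3f (p = %.4g)\n",
              x$module, x$mean_ratio, x$sd_ratio, x$background_ratio,
              x$p_value))
  invisible(x)
}

#' Enrichment table over several modules
#'
#' Applies [enrichment_summary()] to every module of a long-format count
#' table (`module`, `set`, `matches`, `sequences`; background rows have
#' `set = "background"`), e.g. the output of [jtx_module_counts()] or of
#' repeated [count_module_matches()] calls.
#'
#' @param counts count data frame as described above.
#' @return Data frame with one row per module: `mean_ratio`, `sd_ratio`,
#'   `background_ratio`, `p_value`, ordered as in the input.
#' @export
enrichment_table <- function(counts) {
  req <- c("module", "set", "matches", "sequences")
  if (!all(req %in% names(counts)))
    stop("counts must have columns: ", paste(req, collapse = ", "))
  mods <- unique(counts$module)
  rows <- lapply(mods, function(m) {
    sub <- counts[counts$module == m, , drop = FALSE]
    bg <- sub[sub$set == "background", , drop = FALSE]
    fg <- sub[sub$set != "background", , drop = FALSE]
    if (nrow(bg) != 1L)
      stop("module '", m, "' needs exactly one background row")
    r <- enrichment_summary(fg$matches, fg$sequences, bg$matches,
                            bg$sequences, module = m, sets = fg$set)
    data.frame(module = m, n_lists = length(r$ratio),
               mean_ratio = r$mean_ratio, sd_ratio = r$sd_ratio,
               background_ratio = r$background_ratio,
               statistic = r$statistic, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
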