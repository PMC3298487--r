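# Encode a DNA string as integer codes 1..4 (A,C,G,T), NA for N.
encode_dna <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1L]]
  code <- match(chars, DNA_BASES)
  if (any(is.na(code) & chars != "N"))
    stop("non-ACGTN character in sequence")
  code
}

# Relative (min-max normalised) log-odds scores of every window of `code`
# for the log-odds matrix `lo`. N positions contribute 0 (the background
# log-odds). Returns numeric(0) when the matrix is longer than the
# sequence.
relative_scores <- function(code, lo) {
  L <- nrow(lo)
  n <- length(code)
  if (L > n) return(numeric(0))
  lo_na <- rbind(lo, 0)                       # row L+1 scores an N as 0
  code[is.na(code)] <- 0L
  idx <- function(i) {
    b <- code[i:(i + n - L)]
    b[b == 0L] <- NA
    v <- lo_na[cbind(rep.int(i, n - L + 1L), b)]
    v[is.na(v)] <- 0
    v
  }
  s <- numeric(n - L + 1L)
  for (i in seq_len(L)) s <- s + idx(i)
  mn <- sum(apply(lo, 1L, min))
  mx <- sum(apply(lo, 1L, max))
  if (mx == mn) rep(1, length(s)) else (s - mn) / (mx - mn)
}

#' Scan sequences for matches to a position weight matrix
#'
#' Scores every window on both strands with the relative log-odds score:
#' the window's summed log2-odds, shifted and scaled by the matrix-specific
#' attainable minimum and maximum so that 1 is a perfect site and 0 the
#' worst possible window (the matrix-similarity idea of classical motif
#' scanners). `N` bases score as background. Positions with relative score
#' at or above `threshold` are reported; a minus-strand match is reported
#' by the 0-based offset of its leftmost base on the plus strand.
#'
#' @param subject a [PromoterSet][promoter_set], `DNAStringSet`, or named
#'   character vector of sequences.
#' @param pwm a [PwmMatrix][pwm_matrix].
#' @param threshold minimum relative score in (0, 1].
#' @return Data frame with `sequence_id`, `offset` (0-based), `length`,
#'   `strand`, `score` and `name` (the motif name).
#' @export
scan_pwm <- function(subject, pwm, threshold = 0.85) {
  stopifnot(inherits(pwm, "PwmMatrix"))
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]")
  seqs <- as_named_sequences(subject)
  lo_f <- pwm_log_odds(pwm)
  lo_r <- pwm_log_odds(pwm_reverse_complement(pwm))
  L <- nrow(lo_f)
  out <- lapply(names(seqs), function(id) {
    code <- encode_dna(seqs[[id]])
    s_f <- relative_scores(code, lo_f)
    s_r <- relative_scores(code, lo_r)
    h_f <- which(s_f >= threshold) - 1L     # 0-based offsets
    h_r <- which(s_r >= threshold) - 1L
    if (!length(h_f) && !length(h_r)) return(NULL)
    data.frame(
      sequence_id = rep(id, length(h_f) + length(h_r)),
      offset = c(h_f, h_r),
      length = L,
      strand = rep(c("+", "-"), times = c(length(h_f), length(h_r))),
      score = c(s_f[h_f + 1L], s_r[h_r + 1L]),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(sequence_id = character(), offset = integer(),
                      length = integer(), strand = character(),
                      score = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  res <- res[order(res$sequence_id, res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res$name <- pwm$name
  res
}

# Coerce the accepted subject types to a named list of character sequences.
as_named_sequences <- function(subject) {
  if (inherits(subject, "PromoterSet")) subject <- subject$seqs
  if (methods::is(subject, "DNAStringSet"))
    subject <- as.character(subject)
  if (is.null(names(subject)))
    names(subject) <- paste0("seq", seq_along(subject))
  as.list(subject)
}

#' Two-motif framework model
#'
#' A framework (promoter module) is an ordered pair of binding-site motifs
#' with a start-to-start spacing constraint and a strand rule. Spacing is
#' measured between the 5'-most bases of the two site matches in plus
#' -strand coordinates. When the two motifs are the same matrix the model
#' describes a tandem repeat; self-pairing of one physical site with itself
#' is excluded.
#'
#' @param motif_a,motif_b [PwmMatrix][pwm_matrix] objects.
#' @param distance_range integer `c(d_min, d_max)` start-to-start spacing
#'   bounds, inclusive.
#' @param strand_rule `"same"` (both sites on one strand), `"any"`, or
#'   `"convergent"` (upstream site on `+`, downstream on `-`).
#' @param order_fixed must `motif_a` lie 5' of `motif_b`? When `FALSE` the
#'   pair may occur in either order and spacing is taken as the absolute
#'   offset difference.
#' @param name model name; defaults to `"<a>-<b>"`.
#' @return A list of class `ModuleModel`.
#' @export
module_model <- function(motif_a, motif_b, distance_range = c(5L, 200L),
                         strand_rule = c("same", "any", "convergent"),
                         order_fixed = TRUE, name = NULL) {
  strand_rule <- match.arg(strand_rule)
  stopifnot(inherits(motif_a, "PwmMatrix"), inherits(motif_b, "PwmMatrix"))
  distance_range <- as.integer(distance_range)
  if (length(distance_range) != 2L || distance_range[1L] > distance_range[2L])
    stop("distance_range must be c(d_min, d_max) with d_min <= d_max")
  same <- identical(motif_a$prob, motif_b$prob)
  if (same && distance_range[1L] < 1L)
    stop("identical motifs need d_min >= 1 (no self-pairing)")
  if (is.null(name)) name <- paste0(motif_a$name, "-", motif_b$name)
  structure(list(name = name, motif_a = motif_a, motif_b = motif_b,
                 distance_range = distance_range, strand_rule = strand_rule,
                 order_fixed = order_fixed, same_motif = same),
            class = "ModuleModel")
}

#' Tandem-repeat framework preset
#'
#' The tandem module: two copies of one motif on the same strand in fixed
#' order, 5 to 50 bp apart start-to-start.
#'
#' @param pwm a [PwmMatrix][pwm_matrix].
#' @param distance_range spacing bounds (default `c(5, 50)`).
#' @return A [ModuleModel][module_model].
#' @export
tandem_module <- function(pwm, distance_range = c(5L, 50L)) {
  module_model(pwm, pwm, distance_range = distance_range,
               strand_rule = "same", order_fixed = TRUE,
               name = paste0(pwm$name, "-", pwm$name))
}

#' Locate framework matches in sequences
#'
#' Enumerates all pairs of single-motif matches satisfying the module's
#' spacing, strand and order constraints. Pairs whose two site spans are
#' identical to an already-reported pair are deduplicated, and a site is
#' never paired with itself under a same-motif model.
#'
#' @param subject sequences as in [scan_pwm()].
#' @param module a [ModuleModel][module_model].
#' @param threshold single-motif relative-score threshold.
#' @return Data frame with one row per module match: offsets, strands and
#'   scores of both sites, `spacing`, and the enclosing `span_start` /
#'   `span_end` (0-based half-open).
#' @export
match_module <- function(subject, module, threshold = 0.85) {
  stopifnot(inherits(module, "ModuleModel"))
  ma <- scan_pwm(subject, module$motif_a, threshold)
  mb <- if (module$same_motif) ma else scan_pwm(subject, module$motif_b,
                                                threshold)
  empty <- data.frame(sequence_id = character(), offset_a = integer(),
                      strand_a = character(), score_a = numeric(),
                      offset_b = integer(), strand_b = character(),
                      score_b = numeric(), spacing = integer(),
                      span_start = integer(), span_end = integer(),
                      name = character(), stringsAsFactors = FALSE)
  if (!nrow(ma) || !nrow(mb)) return(empty)
  out <- lapply(intersect(unique(ma$sequence_id), unique(mb$sequence_id)),
                function(id) {
    a <- ma[ma$sequence_id == id, , drop = FALSE]
    b <- mb[mb$sequence_id == id, , drop = FALSE]
    ia <- rep(seq_len(nrow(a)), times = nrow(b))
    ib <- rep(seq_len(nrow(b)), each = nrow(a))
    d <- b$offset[ib] - a$offset[ia]
    spacing <- if (module$order_fixed) d else abs(d)
    keep <- spacing >= module$distance_range[1L] &
      spacing <= module$distance_range[2L]
    keep <- keep & switch(module$strand_rule,
      same = a$strand[ia] == b$strand[ib],
      any = TRUE,
      convergent = ifelse(d >= 0,
                          a$strand[ia] == "+" & b$strand[ib] == "-",
                          b$strand[ib] == "+" & a$strand[ia] == "-"))
    if (module$same_motif) {
      # a physical site cannot pair with itself
      keep <- keep & !(a$offset[ia] == b$offset[ib] &
                         a$strand[ia] == b$strand[ib])
      if (!module$order_fixed) keep <- keep & d > 0   # unordered: count once
    }
    ia <- ia[keep]; ib <- ib[keep]
    if (!length(ia)) return(NULL)
    res <- data.frame(
      sequence_id = id,
      offset_a = a$offset[ia], strand_a = a$strand[ia], score_a = a$score[ia],
      offset_b = b$offset[ib], strand_b = b$strand[ib], score_b = b$score[ib],
      spacing = if (module$order_fixed) b$offset[ib] - a$offset[ia]
                else abs(b$offset[ib] - a$offset[ia]),
      span_start = pmin(a$offset[ia], b$offset[ib]),
      span_end = pmax(a$offset[ia] + a$length[ia],
                      b$offset[ib] + b$length[ib]),
      stringsAsFactors = FALSE)
    dup <- duplicated(res[c("offset_a", "strand_a", "offset_b", "strand_b")])
    res[!dup, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  res <- res[order(res$sequence_id, res$span_start, res$span_end), ,
             drop = FALSE]
  rownames(res) <- NULL
  res$name <- module$name
  res
}

#' Count framework matches over a promoter set
#'
#' Total number of module matches summed over all sequences (one sequence
#' may contribute several) together with the number of sequences scanned —
#' the two integers whose quotient is the appearance ratio.
#'
#' @inheritParams match_module
#' @param promoters a [PromoterSet][promoter_set] (or any [scan_pwm()]
#'   subject).
#' @return List with `total`, `n_sequences` and the `matches` data frame.
#' @export
count_module_matches <- function(promoters, module, threshold = 0.85) {
  seqs <- as_named_sequences(promoters)
  if (!length(seqs)) stop("empty promoter set")
  m <- match_module(promoters, module, threshold)
  list(total = nrow(m), n_sequences = length(seqs), matches = m)
}
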