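#' Per-position chance probability of a motif match
#'
#' Probability that a single window of background sequence scores at or
#' above `threshold` (relative score) for the matrix, computed by dynamic
#' programming over the discretised log-odds score distribution under the
#' matrix's background base frequencies. Per window per strand.
#'
#' @param pwm a [PwmMatrix][pwm_matrix].
#' @param threshold relative-score threshold in (0, 1].
#' @param bins number of discretisation bins for the score range.
#' @return A probability.
#' @export
pwm_match_prob <- function(pwm, threshold = 0.85, bins = 4000L) {
  lo <- pwm_log_odds(pwm)
  mins <- apply(lo, 1L, min)
  mn <- sum(mins)
  mx <- sum(apply(lo, 1L, max))
  if (mx == mn) return(1)
  step <- (mx - mn) / bins
  # integer-bin distribution of the shifted score sum under background:
  # each position contributes one of four point masses
  dist <- 1
  for (i in seq_len(nrow(lo))) {
    inc <- as.integer(round((lo[i, ] - mins[i]) / step))
    new <- numeric(length(dist) + max(inc))
    for (b in seq_len(4L)) {
      sh <- inc[[b]]
      rng <- seq_along(dist) + sh
      new[rng] <- new[rng] + dist * pwm$background[[b]]
    }
    dist <- new
  }
  cut <- (threshold * (mx - mn)) / step
  sum(dist[(seq_along(dist) - 1L) >= cut - 1e-9])
}

#' Discover enriched two-motif frameworks
#'
#' Searches a motif library for pairs of binding sites that recur with
#' consistent spacing across a promoter set. For every (unordered) motif
#' pair, single-site matches are enumerated, and the spacing window of
#' width `2 * spacing_tol + 1` (centred on an observed spacing, within
#' `distance_range`) supported by the largest number of promoters is
#' located. Pairs supported by at least `min_support` of the promoters are
#' reported, ranked by a chance-probability score: the binomial tail
#' probability of observing that many supporting promoters when matches
#' arise only from the background model (per-motif chance rates from
#' [pwm_match_prob()], Poisson-approximated over candidate site pairs).
#' Smaller scores indicate frameworks less explicable by chance.
#'
#' @param promoters a [PromoterSet][promoter_set] (or [scan_pwm()] subject).
#' @param motifs named list of [PwmMatrix][pwm_matrix] objects.
#' @param threshold single-site relative-score threshold.
#' @param min_support minimum fraction of promoters that must carry the
#'   framework (default 0.8).
#' @param spacing_tol half-width of the spacing window in bp (default 2).
#' @param distance_range admissible start-to-start spacings.
#' @return Data frame ranked by ascending chance probability with columns
#'   `motif_a`, `motif_b`, `spacing`, `support`, `support_frac`, `chance_p`.
#' @export
discover_frameworks <- function(promoters, motifs, threshold = 0.85,
                                min_support = 0.8, spacing_tol = 2L,
                                distance_range = c(5L, 200L)) {
  if (!length(motifs)) stop("empty motif library")
  if (is.null(names(motifs)))
    names(motifs) <- vapply(motifs, `[[`, "", "name")
  seqs <- as_named_sequences(promoters)
  n <- length(seqs)
  mean_len <- mean(vapply(seqs, nchar, 0L))
  scans <- lapply(motifs, function(m) scan_pwm(promoters, m, threshold))
  probs <- vapply(motifs, pwm_match_prob, 0, threshold = threshold)
  pairs <- expand.grid(a = seq_along(motifs), b = seq_along(motifs))
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$a[[k]]; j <- pairs$b[[k]]
    # per-promoter observed same-strand ordered spacings for this pair
    spacings <- lapply(names(seqs), function(id) {
      a <- scans[[i]][scans[[i]]$sequence_id == id, , drop = FALSE]
      b <- scans[[j]][scans[[j]]$sequence_id == id, , drop = FALSE]
      if (!nrow(a) || !nrow(b)) return(integer(0))
      ia <- rep(seq_len(nrow(a)), times = nrow(b))
      ib <- rep(seq_len(nrow(b)), each = nrow(a))
      d <- b$offset[ib] - a$offset[ia]
      ok <- a$strand[ia] == b$strand[ib] & d >= distance_range[1L] &
        d <= distance_range[2L]
      if (i == j) ok <- ok & d > 0
      unique(d[ok])
    })
    cand <- sort(unique(unlist(spacings)))
    if (!length(cand)) {
      if (min_support > 0) return(NULL)
      # degenerate q = 0: report the pair even without any co-occurrence
      return(data.frame(motif_a = names(motifs)[[i]],
                        motif_b = names(motifs)[[j]],
                        spacing = NA_integer_, support = 0L,
                        support_frac = 0, chance_p = 1,
                        stringsAsFactors = FALSE))
    }
    support <- vapply(cand, function(ctr) {
      sum(vapply(spacings, function(s)
        any(abs(s - ctr) <= spacing_tol), FALSE))
    }, 0L)
    best <- which.max(support)              # ties -> smallest spacing
    k_supp <- support[[best]]
    if (k_supp / n < min_support) return(NULL)
    w <- 2L * spacing_tol + 1L
    lambda <- 2 * mean_len * w * probs[[i]] * probs[[j]]
    p0 <- min(1, -expm1(-lambda))
    data.frame(motif_a = names(motifs)[[i]], motif_b = names(motifs)[[j]],
               spacing = cand[[best]], support = k_supp,
               support_frac = k_supp / n,
               chance_p = stats::pbinom(k_supp - 1L, n, p0,
                                        lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(motif_a = character(), motif_b = character(),
                      spacing = integer(), support = integer(),
                      support_frac = numeric(), chance_p = numeric(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$chance_p, -out$support), , drop = FALSE]
  rownames(out) <- NULL
  out
}
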