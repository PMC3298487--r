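#' Intersect two gene lists
#'
#' Returns the records of `a` whose key also appears in `b`, in the order
#' of `a`. The default key is the probe-set id, which is unambiguous;
#' joining by gene symbol is offered because results are usually narrated
#' by symbol.
#'
#' @param a,b [DEGeneList][de_gene_list] objects (or data frames with the
#'   key column).
#' @param key `"probe_id"` or `"symbol"`.
#' @return A data frame of the common records of `a`.
#' @export
intersect_lists <- function(a, b, key = c("probe_id", "symbol")) {
  key <- match.arg(key)
  if (is.null(a[[key]]) || is.null(b[[key]]))
    stop("key '", key, "' absent from one of the lists")
  as.data.frame(a)[a[[key]] %in% b[[key]], , drop = FALSE]
}

#' Count list memberships per gene
#'
#' For each key value occurring anywhere in the input collection, the
#' number of lists that contain it. Used to pick the core shared signature:
#' the genes present in at least `min_lists` of the condition lists.
#'
#' @param lists a (named) list of [DEGeneList][de_gene_list] objects.
#' @param key `"probe_id"` or `"symbol"`.
#' @return A data frame with columns `key` and `n_lists`, ordered by
#'   decreasing count then key.
#' @export
membership_counts <- function(lists, key = c("probe_id", "symbol")) {
  key <- match.arg(key)
  if (!length(lists)) stop("need >= 1 list")
  keys <- lapply(lists, function(l) {
    if (is.null(l[[key]])) stop("key '", key, "' absent from a list")
    unique(l[[key]])
  })
  tab <- table(unlist(keys, use.names = FALSE))
  out <- data.frame(key = names(tab), n_lists = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n_lists, out$key), , drop = FALSE]
}

#' Genes shared by at least a given number of lists
#'
#' Convenience filter over [membership_counts()]. With the four published
#' condition lists and `min_lists = 3` this selects the twelve-gene core
#' signature that fed the promoter-framework search.
#'
#' @inheritParams membership_counts
#' @param min_lists minimum number of lists a key must occur in.
#' @return Character vector of keys.
#' @export
shared_genes <- function(lists, min_lists = 3L, key = c("probe_id", "symbol")) {
  mc <- membership_counts(lists, key)
  mc$key[mc$n_lists >= min_lists]
}

#' Cross-condition concordance report
#'
#' Pairwise overlap counts over a collection of gene lists, with overlap
#' percentages relative to the smaller list of each pair (the "k of n
#' genes" phrasing), plus the per-gene membership counts.
#'
#' @inheritParams membership_counts
#' @return A list of class `ConcordanceReport` with components `overlap`
#'   (integer matrix), `percent` (one-decimal percentages), `sizes` and
#'   `membership` (the [membership_counts()] data frame).
#' @export
concordance_report <- function(lists, key = c("probe_id", "symbol")) {
  key <- match.arg(key)
  if (length(lists) < 2L) stop("need >= 2 lists")
  labs <- names(lists)
  if (is.null(labs))
    labs <- vapply(lists, function(l) attr(l, "label"), "")
  n <- length(lists)
  ov <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n))
    for (j in seq_len(n))
      ov[i, j] <- nrow(intersect_lists(lists[[i]], lists[[j]], key))
  sizes <- vapply(lists, nrow, 0L)
  pct <- round(100 * ov / outer(sizes, sizes, pmin), 1)
  structure(list(overlap = ov, percent = pct, sizes = sizes,
                 membership = membership_counts(lists, key)),
            class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat("Pairwise overlaps (count / % of smaller list):\n")
  print(x$overlap)
  print(x$percent)
  invisible(x)
}
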