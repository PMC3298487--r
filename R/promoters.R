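#' Promoter sequence set
#'
#' A `PromoterSet` couples a [Biostrings::DNAStringSet] of promoter
#' sequences with per-entry metadata: the owning gene symbol (several
#' promoters may map to one gene) and the TSS-relative span the sequence
#' covers. Spans use 0-based half-open internal coordinates with negative
#' positions upstream of the transcription start site; the default span
#' `-500..+101` covers a 601-bp promoter.
#'
#' @param seqs `DNAStringSet` (or named character vector) over A, C, G, T,
#'   N; names are sequence ids.
#' @param gene_symbol character vector of owning genes (recycled if length
#'   1); defaults to the sequence ids.
#' @param span_start integer TSS-relative start of each sequence (recycled).
#' @param label free-text set label, e.g. `"SPFLI-up"`.
#' @return An object of class `PromoterSet`.
#' @export
promoter_set <- function(seqs, gene_symbol = NULL, span_start = -500L,
                         label = "") {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("promoter sequences must be named")
  if (any(Biostrings::width(seqs) == 0L))
    stop("promoter sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(seqs)
  extra <- rowSums(freq[, setdiff(colnames(freq), c("A", "C", "G", "T", "N")),
                        drop = FALSE])
  if (any(extra > 0))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(seqs)[extra > 0], collapse = ", "))
  n <- length(seqs)
  if (is.null(gene_symbol)) gene_symbol <- names(seqs)
  gene_symbol <- rep_len(gene_symbol, n)
  span_start <- rep_len(as.integer(span_start), n)
  structure(list(seqs = seqs,
                 info = data.frame(sequence_id = names(seqs),
                                   gene_symbol = gene_symbol,
                                   span_start = span_start,
                                   span_end = span_start +
                                     Biostrings::width(seqs),
                                   stringsAsFactors = FALSE),
                 label = label),
            class = "PromoterSet")
}

#' @export
print.PromoterSet <- function(x, ...) {
  cat(sprintf("PromoterSet '%s': %d sequences, %d genes\n", x$label,
              length(x$seqs), length(unique(x$info$gene_symbol))))
  invisible(x)
}

#' @export
length.PromoterSet <- function(x) length(x$seqs)

#' Read promoters from a FASTA file
#'
#' Headers are parsed as `id [gene=SYMBOL] [span=START..END]`, the two
#' key=value fields being optional (gene defaults to the id, span to
#' `-500..` plus the sequence width). Ingestion is lossless; sequences with
#' characters outside A, C, G, T, N are rejected by name.
#'
#' @param path FASTA file path.
#' @param label set label attached to the result.
#' @return A [PromoterSet][promoter_set].
#' @export
read_promoter_fasta <- function(path, label = "") {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  field <- function(key) {
    m <- regmatches(headers, regexpr(paste0(key, "=[^\\s]+"), headers,
                                     perl = TRUE))
    out <- rep(NA_character_, length(headers))
    out[grepl(paste0(key, "="), headers)] <- sub(paste0(key, "="), "", m)
    out
  }
  gene <- field("gene")
  gene[is.na(gene)] <- ids[is.na(gene)]
  span <- field("span")
  start <- ifelse(is.na(span), -500L,
                  suppressWarnings(as.integer(sub("\\.\\..*$", "", span))))
  names(seqs) <- ids
  promoter_set(seqs, gene_symbol = gene, span_start = start, label = label)
}

#' Write a promoter set to FASTA
#'
#' @param promoters a [PromoterSet][promoter_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  stopifnot(inherits(promoters, "PromoterSet"))
  seqs <- promoters$seqs
  info <- promoters$info
  names(seqs) <- sprintf("%s gene=%s span=%d..%d", info$sequence_id,
                         info$gene_symbol, info$span_start, info$span_end)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Export motif or module matches as BED6
#'
#' Intervals are 0-based half-open on the promoter sequence (chrom = the
#' sequence id). For module matches the interval is the enclosing span of
#' the two site matches; the name column carries the module (or motif)
#' name and the score column the match score scaled to 0-1000.
#'
#' @param matches a match data frame from [scan_pwm()] or [match_module()].
#' @param path output BED file path.
#' @param name feature name to write; defaults to the `name` column of
#'   `matches` when present.
#' @return `path`, invisibly.
#' @export
write_bed <- function(matches, path, name = NULL) {
  if (nrow(matches) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (!is.null(matches$span_start)) {        # module matches
    start0 <- matches$span_start
    end0 <- matches$span_end
    strand <- matches$strand_a
    score <- (matches$score_a + matches$score_b) / 2
  } else {                                   # single-motif matches
    start0 <- matches$offset
    end0 <- matches$offset + matches$length
    strand <- matches$strand
    score <- matches$score
  }
  if (is.null(name)) name <- matches$name
  if (is.null(name)) name <- "match"
  gr <- GenomicRanges::GRanges(
    seqnames = matches$sequence_id,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand,
    name = rep_len(name, nrow(matches)),
    score = as.integer(round(pmin(pmax(score, 0), 1) * 1000)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 file of match locations
#'
#' Returns the 0-based half-open intervals written by [write_bed()].
#'
#' @param path BED file path.
#' @return A data frame with `sequence_id`, `start`, `end`, `name`,
#'   `score` (0-1000) and `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(sequence_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (is.null(gr$name)) NA_character_ else gr$name,
             score = if (is.null(gr$score)) NA_integer_ else gr$score,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
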