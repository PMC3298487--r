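#' Ordered differential-expression gene list
#'
#' A `DEGeneList` is a data frame of probe-set records in the layout of the
#' published tables — `probe_id`, `gene_name`, `symbol`, `entrez`,
#' `fold_change` (linear, treated mean / control mean) and `p_value` — with
#' a direction tag (`"up"` or `"down"`) and a condition label such as
#' `"SPFLI-up"` carried as attributes. Row order is meaningful and is
#' preserved by all operations.
#'
#' Direction implies a fold-change bound (`> 1.5` for up, `< 0.67` for
#' down); the bound is checked with a tolerance of half the printed
#' precision (0.005) because published tables round fold changes to two
#' decimals, so a boundary gene may print exactly 0.67.
#'
#' @param records data frame with the six columns above (missing annotation
#'   columns are filled with `NA`).
#' @param direction `"up"` or `"down"`.
#' @param label condition label, free text.
#' @param fc_up,fc_down the fold-change bounds the direction implies
#'   (defaults 1.5 and 0.67).
#' @return A data frame of class `DEGeneList`.
#' @export
de_gene_list <- function(records, direction = c("up", "down"), label = "",
                         fc_up = 1.5, fc_down = 0.67) {
  direction <- match.arg(direction)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("gene_name", "symbol"))
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  if (is.null(records[["entrez"]])) records[["entrez"]] <- NA_integer_
  req <- c("probe_id", "fold_change", "p_value")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("gene list lacks column(s): ", paste(miss, collapse = ", "))
  records <- records[c("probe_id", "gene_name", "symbol", "entrez",
                       "fold_change", "p_value")]
  if (anyDuplicated(records$probe_id))
    stop("duplicate probe_id within a gene list")
  if (any(!is.finite(records$fold_change)) || any(records$fold_change <= 0))
    stop("fold changes must be positive and finite")
  if (any(records$p_value < 0 | records$p_value > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  tol <- 0.005  # half of the 2-decimal precision of printed tables
  if (direction == "up" && any(records$fold_change <= fc_up - tol))
    stop("'up' list contains fold change <= ", fc_up)
  if (direction == "down" && any(records$fold_change >= fc_down + tol))
    stop("'down' list contains fold change >= ", fc_down)
  rownames(records) <- NULL
  structure(records, direction = direction, label = label,
            class = c("DEGeneList", "data.frame"))
}

#' @export
print.DEGeneList <- function(x, ...) {
  cat(sprintf("DEGeneList '%s' (%s, %d records)\n",
              attr(x, "label"), attr(x, "direction"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a gene list from TSV
#'
#' The file carries the six table columns (`probe_id`, `gene_name`,
#' `symbol`, `entrez`, `fold_change`, `p_value`) and two metadata comment
#' lines, `# direction: up|down` and `# label: <text>`, which arguments may
#' override. Row order is preserved as printed.
#'
#' @param path TSV file path.
#' @param direction,label optional overrides of the file metadata.
#' @return A [DEGeneList][de_gene_list].
#' @export
read_gene_list <- function(path, direction = NULL, label = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^#\\s*", key, ":"), "", hit[[1L]]))
    else NULL
  }
  if (is.null(direction)) direction <- get_meta("direction")
  if (is.null(label)) label <- get_meta("label")
  if (is.null(direction))
    stop("direction not given and no '# direction:' header in ", path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) <= 1L)
    stop("gene list file has no records: ", path)
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  if (!is.numeric(tab$fold_change))
    stop("non-numeric fold_change column in ", path)
  de_gene_list(tab, direction = direction,
               label = if (is.null(label)) "" else label)
}

#' Write a gene list to TSV
#'
#' Inverse of [read_gene_list()]: records as printed plus the direction and
#' label metadata as comment lines.
#'
#' @param x a [DEGeneList][de_gene_list].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "DEGeneList"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# direction: ", attr(x, "direction")),
               paste0("# label: ", attr(x, "label"))), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Packaged gene-list fixtures
#'
#' The four published condition lists ship with the package as TSV fixtures:
#' `SPFLI-up` (27 genes up in the large intestine of IQI SPF mice),
#' `BALBLI-down` (22 down in BALB/c SPF large intestine), `GFLI-down`
#' (31 down in IQI germ-free large intestine) and `GFSI-down` (42 down in
#' IQI germ-free small intestine). They are the reference surface for the
#' concordance computations.
#'
#' @param which optional character vector of labels to load (default: all
#'   four).
#' @return A named list of [DEGeneList][de_gene_list] objects.
#' @export
jtx_gene_lists <- function(which = c("SPFLI-up", "BALBLI-down",
                                     "GFLI-down", "GFSI-down")) {
  files <- c("SPFLI-up" = "table_spfli_up.tsv",
             "BALBLI-down" = "table_balbli_down.tsv",
             "GFLI-down" = "table_gfli_down.tsv",
             "GFSI-down" = "table_gfsi_down.tsv")
  which <- match.arg(which, names(files), several.ok = TRUE)
  out <- lapply(which, function(w) {
    path <- system.file("extdata", files[[w]], package = "ifnmodmap",
                        mustWork = TRUE)
    read_gene_list(path)
  })
  stats::setNames(out, which)
}

#' Packaged promoter-module count fixture
#'
#' Published module-match counts per gene-list promoter set for the four
#' top-ranked two-motif frameworks, plus the genome-wide background counts
#' over all annotated mouse promoters. Long format: `module`, `set`,
#' `matches`, `sequences`; the background rows have `set = "background"`.
#'
#' @return A data frame.
#' @export
jtx_module_counts <- function() {
  path <- system.file("extdata", "module_counts.tsv", package = "ifnmodmap",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
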