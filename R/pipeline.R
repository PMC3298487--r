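#' Run the full analysis chain
#'
#' Orchestrates the pipeline in one of two modes.
#'
#' In `"fixture"` mode the packaged published tables are the input: the
#' four condition gene lists feed the concordance report (pairwise
#' overlaps, shared-gene counts) and the packaged module-count matrix
#' feeds the enrichment table. No randomness is involved.
#'
#' In `"synthetic"` mode the generators produce an expression matrix with
#' planted bi-directional interferon-like effects and a promoter set with
#' a planted tandem framework; the gene lists are then derived with
#' [call_de()], their concordance computed, the planted module counted
#' against a background promoter set, and its enrichment summarised.
#' Everything is deterministic given `seed`.
#'
#' @param mode `"fixture"` or `"synthetic"`.
#' @param seed root seed (synthetic mode).
#' @param out_dir optional directory; when given, gene lists, the
#'   concordance overlap matrix, the enrichment table and a JSON summary
#'   (which records mode and seed) are written there.
#' @param n_probes,n_planted,log2_effect,n_promoters synthetic-mode sizes:
#'   probes simulated, planted genes, planted log2 effect, promoters per
#'   set.
#' @return A list of class `PipelineResult` with components `lists`,
#'   `concordance`, `enrichment` and `summary`.
#' @export
run_pipeline <- function(mode = c("fixture", "synthetic"), seed = 1L,
                         out_dir = NULL, n_probes = 2000L, n_planted = 20L,
                         log2_effect = 2, n_promoters = 30L) {
  mode <- match.arg(mode)
  if (mode == "fixture") {
    lists <- jtx_gene_lists()
    counts <- jtx_module_counts()
    conc <- concordance_report(lists)
    enr <- enrichment_table(counts)
    summary <- list(
      mode = mode,
      overlap_gfli_spfli = conc$overlap["GFLI-down", "SPFLI-up"],
      overlap_gfsi_gfli = conc$overlap["GFSI-down", "GFLI-down"],
      overlap_gfsi_spfli = conc$overlap["GFSI-down", "SPFLI-up"],
      overlap_spfli_balbli = conc$overlap["SPFLI-up", "BALBLI-down"],
      shared_in_3plus = length(shared_genes(lists, 3L)),
      enrichment_means = stats::setNames(round(enr$mean_ratio, 3),
                                         enr$module))
  } else {
    design <- synthetic_study_design(seed = seed, n_probes = n_probes,
                                     n_planted = n_planted,
                                     log2_effect = log2_effect)
    sim <- simulate_expression(design)
    conds <- design$conditions
    lists <- list()
    for (i in seq_len(nrow(conds))) {
      cond <- as.list(conds[i, ])
      de <- call_de(sim$matrix, cond)
      for (d in c("up", "down"))
        if (nrow(de[[d]]))
          lists[[attr(de[[d]], "label")]] <- de[[d]]
    }
    conc <- if (length(lists) >= 2L) concordance_report(lists) else NULL
    pwm <- read_pwm(system.file("extdata", "irf_like_standin.pwm",
                                package = "ifnmodmap", mustWork = TRUE))[[1L]]
    mod <- tandem_module(pwm)
    fg <- simulate_promoters(promoter_plant_spec(
      n_sequences = n_promoters, module = mod, plant_rate = 1,
      seed = substream_seed(seed, "promoters_fg")))
    bg <- simulate_promoters(promoter_plant_spec(
      n_sequences = 4L * n_promoters, module = mod, plant_rate = 0.1,
      seed = substream_seed(seed, "promoters_bg")))
    cf <- count_module_matches(fg$promoters, mod)
    cb <- count_module_matches(bg$promoters, mod)
    # split the foreground into two pseudo-lists so an SD is defined
    half <- seq_len(n_promoters %/% 2L)
    m1 <- sum(cf$matches$sequence_id %in%
                names(as_named_sequences(fg$promoters))[half])
    enr <- enrichment_summary(c(m1, cf$total - m1),
                              c(length(half), n_promoters - length(half)),
                              cb$total, cb$n_sequences, module = mod$name)
    summary <- list(mode = mode, seed = seed, n_probes = n_probes,
                    n_lists = length(lists),
                    list_sizes = vapply(lists, nrow, 0L),
                    module_matches = cf$total,
                    module_sequences = cf$n_sequences,
                    enrichment_mean = enr$mean_ratio,
                    background_ratio = enr$background_ratio,
                    enrichment_p = enr$p_value)
    enr <- data.frame(module = enr$module, n_lists = 2L,
                      mean_ratio = enr$mean_ratio, sd_ratio = enr$sd_ratio,
                      background_ratio = enr$background_ratio,
                      statistic = enr$statistic, p_value = enr$p_value,
                      stringsAsFactors = FALSE)
  }
  res <- structure(list(lists = lists, concordance = conc, enrichment = enr,
                        summary = summary),
                   class = "PipelineResult")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (l in lists) {
      fname <- paste0(gsub("[^A-Za-z0-9._-]", "", attr(l, "label")), ".tsv")
      write_gene_list(l, file.path(out_dir, fname))
    }
    if (!is.null(conc))
      utils::write.table(conc$overlap, file.path(out_dir, "overlaps.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("Pipeline result (", x$summary$mode, " mode)\n", sep = "")
  utils::str(x$summary, give.attr = FALSE)
  invisible(x)
}

#' Default synthetic study design with bi-directional planted genes
#'
#' Builds the [simulation_design()] used by the synthetic pipeline mode:
#' `n_planted` interferon-like probe sets planted up-regulated in the
#' IQI-SPF large-intestine block and down-regulated in the BALB/c-SPF and
#' IQI-GF blocks, mirroring the strain- and microbiota-dependent direction
#' flip of the target signature.
#'
#' @param seed root seed.
#' @param n_probes total probe sets.
#' @param n_planted planted signature size.
#' @param log2_effect planted effect size in log2 units.
#' @return A [simulation_design()].
#' @export
synthetic_study_design <- function(seed = 1L, n_probes = 2000L,
                                   n_planted = 20L, log2_effect = 2) {
  ids <- sprintf("probe_%05d", seq_len(n_planted))
  planted <- rbind(
    data.frame(probe_id = ids, condition = "IQI.SPF.LI", direction = "up",
               log2_effect = log2_effect, stringsAsFactors = FALSE),
    data.frame(probe_id = ids, condition = "BALB/c.SPF.LI",
               direction = "down", log2_effect = log2_effect,
               stringsAsFactors = FALSE),
    data.frame(probe_id = ids, condition = "IQI.GF.LI", direction = "down",
               log2_effect = log2_effect, stringsAsFactors = FALSE),
    data.frame(probe_id = ids, condition = "IQI.GF.SI", direction = "down",
               log2_effect = log2_effect, stringsAsFactors = FALSE))
  simulation_design(n_probes = n_probes, planted = planted, seed = seed)
}
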