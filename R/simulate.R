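#' Study-design description for the expression simulator
#'
#' Describes the synthetic counterpart of the array experiment: five
#' condition blocks (IQI-SPF large and small intestine, IQI-GF large and
#' small intestine, BALB/c-SPF large intestine), each with a water-control
#' and a treated group of three arrays. Signals follow a log-normal model:
#' per-probe log2 baselines are drawn once, a planted treatment effect is
#' added on the log2 scale in the treated group of the designated
#' condition, and i.i.d. Gaussian noise (SD `noise_sd` log2 units) is added
#' per array. Detection calls are Present when the linear signal clears
#' `call_threshold`, with a small symmetric misclassification rate.
#' Directions are planted per condition independently, so one probe can be
#' up-regulated in one condition block and down-regulated in another — the
#' bi-directional behaviour the cross-condition concordance analysis keys
#' on.
#'
#' @param conditions data frame with columns `strain`, `flora`, `tissue`;
#'   default is the five-block study layout.
#' @param n_replicates arrays per group (default 3).
#' @param n_probes number of probe sets (default 12488, the array size).
#' @param planted data frame of planted effects with columns `probe_id`,
#'   `condition` (a `strain.flora.tissue` label), `direction` (`up` /
#'   `down`), `log2_effect` (positive); `NULL` for an all-null design.
#' @param noise_sd per-array noise SD on the log2 scale (default 0.25).
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-probe
#'   log2 baselines (defaults 7 and 1.5).
#' @param call_threshold linear signal above which a call is Present
#'   (default 50, mirroring the intensity floor).
#' @param call_flip_rate symmetric P/A misclassification rate
#'   (default 0.02).
#' @param seed root seed; expanded into named substreams per stage.
#' @return A list of class `SimulationDesign`.
#' @export
simulation_design <- function(conditions = NULL, n_replicates = 3L,
                              n_probes = 12488L, planted = NULL,
                              noise_sd = 0.25, baseline_log2_mean = 7,
                              baseline_log2_sd = 1.5, call_threshold = 50,
                              call_flip_rate = 0.02, seed = 1L) {
  if (is.null(conditions))
    conditions <- data.frame(
      strain = c("IQI", "IQI", "IQI", "IQI", "BALB/c"),
      flora = c("SPF", "SPF", "GF", "GF", "SPF"),
      tissue = c("LI", "SI", "LI", "SI", "LI"),
      stringsAsFactors = FALSE)
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (n_probes <= 0L) stop("n_probes must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (call_flip_rate < 0 || call_flip_rate >= 0.5)
    stop("call_flip_rate must lie in [0, 0.5)")
  labels <- condition_label(conditions)
  if (!is.null(planted)) {
    req <- c("probe_id", "condition", "direction", "log2_effect")
    miss <- setdiff(req, names(planted))
    if (length(miss))
      stop("planted table lacks column(s): ", paste(miss, collapse = ", "))
    if (!all(planted$condition %in% labels))
      stop("planted condition labels must match the design conditions")
    if (!all(planted$direction %in% c("up", "down")))
      stop("planted directions must be 'up' or 'down'")
    if (any(!is.finite(planted$log2_effect) | planted$log2_effect <= 0))
      stop("log2 effects must be positive and finite")
  }
  structure(list(conditions = conditions, condition_labels = labels,
                 n_replicates = as.integer(n_replicates),
                 n_probes = as.integer(n_probes), planted = planted,
                 noise_sd = noise_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 call_threshold = call_threshold,
                 call_flip_rate = call_flip_rate, seed = as.integer(seed)),
            class = "SimulationDesign")
}

condition_label <- function(conditions) {
  paste(conditions$strain, conditions$flora, conditions$tissue, sep = ".")
}

#' Simulate an expression matrix with planted ground truth
#'
#' @param design a [simulation_design()].
#' @return List with `matrix` (a `SummarizedExperiment`, see
#'   [expression_matrix()]) and `truth` (the planted-effect table; empty
#'   data frame for an all-null design). The substream seeds used are
#'   recorded in the `"seeds"` attribute of the matrix metadata.
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  probes <- sprintf("probe_%05d", seq_len(design$n_probes))
  seeds <- c(baseline = substream_seed(design$seed, "baseline"),
             noise = substream_seed(design$seed, "noise"),
             calls = substream_seed(design$seed, "calls"))
  baseline <- with_seed(seeds[["baseline"]], {
    b <- stats::rnorm(design$n_probes, design$baseline_log2_mean,
                      design$baseline_log2_sd)
    if (!is.null(design$planted) && nrow(design$planted)) {
      # Planted signature probes are expressed genes: their baselines come
      # from the same normal truncated above the detection floor plus one
      # log2 unit, since a probe silenced below the floor in every group is
      # removed by the intensity rule regardless of any planted effect.
      idx <- match(unique(design$planted$probe_id), probes)
      lb <- log2(design$call_threshold) + 1
      lo <- stats::pnorm(lb, design$baseline_log2_mean,
                         design$baseline_log2_sd)
      u <- stats::runif(length(idx), lo, 1)
      b[idx] <- stats::qnorm(u, design$baseline_log2_mean,
                             design$baseline_log2_sd)
    }
    b
  })
  conds <- design$conditions
  labels <- design$condition_labels
  samples <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    expand.grid(replicate = seq_len(design$n_replicates),
                treatment = c("control", "JTX"),
                strain = conds$strain[[i]], flora = conds$flora[[i]],
                tissue = conds$tissue[[i]], stringsAsFactors = FALSE)
  }))
  samples$sample_id <- sprintf(
    "%s.%s.%s.%s.%d", gsub("/", "", samples$strain), samples$flora,
    samples$tissue, samples$treatment, samples$replicate)
  samples <- samples[c("sample_id", "strain", "flora", "tissue",
                       "treatment", "replicate")]
  effect <- matrix(0, nrow = design$n_probes, ncol = nrow(samples),
                   dimnames = list(probes, samples$sample_id))
  truth <- design$planted
  if (!is.null(truth) && nrow(truth)) {
    if (!all(truth$probe_id %in% probes))
      stop("planted probe_id outside the simulated probe set")
    jtx <- samples$treatment == "JTX"
    slab <- condition_label(samples)
    for (k in seq_len(nrow(truth))) {
      cols <- jtx & slab == truth$condition[[k]]
      sgn <- if (truth$direction[[k]] == "up") 1 else -1
      effect[truth$probe_id[[k]], cols] <-
        effect[truth$probe_id[[k]], cols] + sgn * truth$log2_effect[[k]]
    }
  } else {
    truth <- data.frame(probe_id = character(), condition = character(),
                        direction = character(), log2_effect = numeric(),
                        stringsAsFactors = FALSE)
  }
  noise <- with_seed(seeds[["noise"]],
                     matrix(stats::rnorm(length(effect), 0, design$noise_sd),
                            nrow = nrow(effect)))
  signal <- 2^(baseline + effect + noise)
  flips <- with_seed(seeds[["calls"]],
                     matrix(stats::runif(length(effect)) <
                              design$call_flip_rate, nrow = nrow(effect)))
  present <- (signal >= design$call_threshold) != flips
  call <- matrix(ifelse(present, "P", "A"), nrow = nrow(effect),
                 dimnames = dimnames(effect))
  mat <- expression_matrix(signal, call, samples)
  S4Vectors::metadata(mat)$seeds <- seeds
  S4Vectors::metadata(mat)$seed <- design$seed
  list(matrix = mat, truth = truth)
}

#' Planting specification for the promoter simulator
#'
#' Background sequence is i.i.d. with a given GC content; a chosen
#' fraction of sequences receives exactly one planted instance of a
#' two-motif framework at a uniformly drawn legal offset. Planted sites
#' are the consensus of each matrix by default (so they are matches by
#' construction at any reasonable threshold); `site_model = "sample"`
#' draws each site base-by-base from the matrix instead.
#'
#' @param n_sequences number of promoter sequences.
#' @param length sequence length in bp (default 601, a -500..+100
#'   TSS-relative window).
#' @param gc background GC content (default 0.5).
#' @param module a [ModuleModel][module_model] to plant.
#' @param plant_rate fraction of sequences receiving one instance, in
#'   \[0, 1\].
#' @param spacing fixed start-to-start spacing; `NULL` draws uniformly
#'   from the module's distance range per sequence.
#' @param site_model `"consensus"` or `"sample"`.
#' @param seed root seed.
#' @return A list of class `PromoterPlantSpec`.
#' @export
promoter_plant_spec <- function(n_sequences, length = 601L, gc = 0.5,
                                module = NULL, plant_rate = 0,
                                spacing = NULL,
                                site_model = c("consensus", "sample"),
                                seed = 1L) {
  site_model <- match.arg(site_model)
  if (plant_rate < 0 || plant_rate > 1)
    stop("plant_rate must lie in [0, 1]")
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
  if (plant_rate > 0 && is.null(module))
    stop("a module is required when plant_rate > 0")
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length), gc = gc, module = module,
                 plant_rate = plant_rate, spacing = spacing,
                 site_model = site_model, seed = as.integer(seed)),
            class = "PromoterPlantSpec")
}

# One planted site as a character vector of bases.
draw_site <- function(pwm, site_model) {
  if (site_model == "consensus")
    return(strsplit(pwm_consensus(pwm), "")[[1L]])
  apply(pwm$prob_raw, 1L, function(p) sample(DNA_BASES, 1L, prob = p))
}

#' Simulate promoter sequences with planted framework instances
#'
#' @param spec a [promoter_plant_spec()].
#' @return List with `promoters` (a [PromoterSet][promoter_set]) and
#'   `truth`, a data frame recording for every sequence whether a module
#'   instance was planted and, if so, its offsets, spacing and strand.
#' @export
simulate_promoters <- function(spec) {
  stopifnot(inherits(spec, "PromoterPlantSpec"))
  p_base <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
              T = (1 - spec$gc) / 2)
  seeds <- c(background = substream_seed(spec$seed, "background"),
             plant = substream_seed(spec$seed, "plant"))
  chars <- with_seed(seeds[["background"]],
                     sample(DNA_BASES, spec$n_sequences * spec$length,
                            replace = TRUE, prob = p_base))
  seqs <- matrix(chars, nrow = spec$n_sequences)
  ids <- sprintf("promoter_%04d", seq_len(spec$n_sequences))
  truth <- data.frame(sequence_id = ids, planted = FALSE,
                      offset_a = NA_integer_, offset_b = NA_integer_,
                      spacing = NA_integer_, strand = NA_character_,
                      stringsAsFactors = FALSE)
  n_plant <- round(spec$plant_rate * spec$n_sequences)
  if (n_plant > 0) {
    mod <- spec$module
    len_a <- nrow(mod$motif_a$prob)
    len_b <- nrow(mod$motif_b$prob)
    truth_rows <- with_seed(seeds[["plant"]], {
      chosen <- sort(sample.int(spec$n_sequences, n_plant))
      lapply(chosen, function(i) {
        rng <- mod$distance_range[1L]:mod$distance_range[2L]
        sp <- if (is.null(spec$spacing))
          rng[sample.int(length(rng), 1L)]   # safe for length-1 ranges
        else as.integer(spec$spacing)
        span <- max(len_a, sp + len_b)
        if (span > spec$length)
          stop("planted module does not fit in a ", spec$length,
               " bp sequence")
        off <- sample.int(spec$length - span + 1L, 1L) - 1L
        site_a <- draw_site(mod$motif_a, spec$site_model)
        site_b <- draw_site(mod$motif_b, spec$site_model)
        seqs[i, off + seq_len(len_a)] <<- site_a
        seqs[i, off + sp + seq_len(len_b)] <<- site_b
        list(i = i, offset_a = off, offset_b = off + sp, spacing = sp)
      })
    })
    for (tr in truth_rows) {
      truth$planted[[tr$i]] <- TRUE
      truth$offset_a[[tr$i]] <- tr$offset_a
      truth$offset_b[[tr$i]] <- tr$offset_b
      truth$spacing[[tr$i]] <- tr$spacing
      truth$strand[[tr$i]] <- "+"
    }
  }
  sequences <- apply(seqs, 1L, paste, collapse = "")
  names(sequences) <- ids
  list(promoters = promoter_set(sequences, label = "synthetic"),
       truth = truth)
}
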