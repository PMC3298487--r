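#' Parameters of the gene-list derivation
#'
#' Bundles the filtering and testing constants of the differential-expression
#' rule chain: a probe set survives when (i) at least one sample group has
#' `min_present_per_group` non-absent detection calls, (ii) the larger of the
#' two comparison-group mean signals reaches `intensity_floor` (linear MAS5
#' units), (iii) Welch's t on `test_scale` values gives `p < p_threshold`,
#' and (iv) the linear fold change is strictly above `fc_up` (up list) or
#' strictly below `fc_down` (down list). No multiple-testing correction is
#' applied anywhere in the chain; the lenient `p < 0.1` screen is deliberate
#' and fold change carries the remaining specificity burden.
#'
#' @param min_present_per_group minimum non-absent calls needed in at least
#'   one group (default 2 of 3 replicates).
#' @param intensity_floor minimum of the larger group-mean signal
#'   (default 50).
#' @param p_threshold Welch p-value cut-off (default 0.1).
#' @param fc_up,fc_down linear fold-change thresholds (defaults 1.5, 0.67).
#' @param test_scale scale on which the t-test runs: `"log2"` (on
#'   `log2(signal + 1)`, variance-stabilised; default) or `"linear"`.
#' @param marginal how Marginal calls count in the detection filter:
#'   `"not_absent"` (default; the filter counts absent calls, so an M keeps
#'   a probe eligible) or `"absent"` (stricter present-only reading).
#' @return A list of class `FilterParams`.
#' @export
filter_params <- function(min_present_per_group = 2L, intensity_floor = 50,
                          p_threshold = 0.1, fc_up = 1.5, fc_down = 0.67,
                          test_scale = c("log2", "linear"),
                          marginal = c("not_absent", "absent")) {
  test_scale <- match.arg(test_scale)
  marginal <- match.arg(marginal)
  if (!(0 < fc_down && fc_down < 1 && 1 < fc_up))
    stop("need 0 < fc_down < 1 < fc_up")
  if (!(0 < p_threshold && p_threshold < 1))
    stop("p_threshold must lie in (0, 1)")
  structure(list(min_present_per_group = as.integer(min_present_per_group),
                 intensity_floor = intensity_floor,
                 p_threshold = p_threshold, fc_up = fc_up, fc_down = fc_down,
                 test_scale = test_scale, marginal = marginal),
            class = "FilterParams")
}

#' Detection-call filter
#'
#' Implements the published exclusion rule: a probe set is excluded when
#' every sample group has 2 or 3 Absent calls (out of 3 replicates);
#' equivalently, it is retained when at least one group has at least
#' `min_present_per_group` non-absent calls. With `marginal = "absent"`,
#' Marginal calls are counted as absent and only Present calls keep a probe
#' eligible.
#'
#' @param mat expression matrix from [expression_matrix()].
#' @param params a [filter_params()] object.
#' @return Character vector of retained probe ids.
#' @export
detection_call_filter <- function(mat, params = filter_params()) {
  grp <- sample_groups(mat)
  if (any(table(grp) < 2L))
    stop("detection-call filter needs >= 2 samples per group")
  calls <- SummarizedExperiment::assay(mat, "call")
  eligible <- if (params$marginal == "absent") calls == "P" else calls != "A"
  keep <- Reduce(`|`, lapply(levels(grp), function(g) {
    rowSums(eligible[, grp == g, drop = FALSE]) >= params$min_present_per_group
  }))
  rownames(calls)[keep]
}

#' Signal-intensity filter
#'
#' Retains a probe set when the larger of the two comparison-group mean
#' signals reaches the floor, so that a gene strongly induced (or silenced)
#' by treatment is never discarded for being low in the other group.
#'
#' @param mat expression matrix.
#' @param condition list with `strain`, `flora`, `tissue` selecting the
#'   comparison block.
#' @param params a [filter_params()] object.
#' @return Character vector of retained probe ids.
#' @export
intensity_filter <- function(mat, condition, params = filter_params()) {
  sig <- SummarizedExperiment::assay(mat, "signal")
  ctrl <- condition_samples(mat, condition, "control")
  trt <- condition_samples(mat, condition, "JTX")
  m1 <- rowMeans(sig[, ctrl, drop = FALSE])
  m2 <- rowMeans(sig[, trt, drop = FALSE])
  rownames(sig)[pmax(m1, m2) >= params$intensity_floor]
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t with Welch-Satterthwaite degrees of freedom, computed
#' in closed form. Degenerate inputs (zero variance in both groups) give
#' `p = 1` when the means are equal and are flagged via the `degenerate`
#' field otherwise.
#'
#' @param x,y numeric replicate vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p_value`, `degenerate`.
#' @examples
#' welch_t(c(10, 11, 12), c(14, 15, 16))
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t needs >= 2 values per group")
  if (any(!is.finite(c(x, y)))) stop("welch_t needs finite values")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = nx + ny - 2, p_value = 1,
                  degenerate = FALSE))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, df = NA_real_,
                p_value = 0, degenerate = TRUE))
  }
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

# Row-wise Welch t over two column blocks of a matrix. Returns a data frame
# with p (NA where degenerate with unequal means -> caller drops + warns).
welch_t_rows <- function(m1, m2) {
  n1 <- ncol(m1); n2 <- ncol(m2)
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  v1 <- rowSums((m1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((m2 - mu2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- v1 == 0 & v2 == 0
  p[zero & mu1 == mu2] <- 1
  p[zero & mu1 != mu2] <- NA_real_          # degenerate, flagged upstream
  data.frame(statistic = t, df = df, p_value = p, degenerate = zero & mu1 != mu2)
}

#' Derive the up- and down-regulated gene lists for one condition
#'
#' Runs the full rule chain for a (strain, flora, tissue) block: detection
#' -call filter over all groups of the matrix, intensity filter over the
#' control/treated pair, Welch's t on the configured scale, then the strict
#' fold-change thresholds on linear group means. The up list is ordered by
#' descending fold change and the down list by ascending fold change,
#' matching the published table order.
#'
#' @param mat expression matrix.
#' @param condition list with `strain`, `flora`, `tissue`.
#' @param params a [filter_params()] object.
#' @param label_prefix prefix for the condition labels (e.g. `"SPFLI"`
#'   yields `"SPFLI-up"` / `"SPFLI-down"`); derived from the condition when
#'   omitted.
#' @return List with components `up` and `down`, each a
#'   [DEGeneList][de_gene_list].
#' @export
call_de <- function(mat, condition, params = filter_params(),
                    label_prefix = NULL) {
  if (is.null(label_prefix))
    label_prefix <- paste0(condition$strain, condition$flora, condition$tissue)
  keep <- intersect(detection_call_filter(mat, params),
                    intensity_filter(mat, condition, params))
  sig <- SummarizedExperiment::assay(mat, "signal")[keep, , drop = FALSE]
  ctrl <- condition_samples(mat, condition, "control")
  trt <- condition_samples(mat, condition, "JTX")
  test_mat <- if (params$test_scale == "log2") log2(sig + 1) else sig
  res <- welch_t_rows(test_mat[, trt, drop = FALSE],
                      test_mat[, ctrl, drop = FALSE])
  if (any(res$degenerate)) {
    warning(sum(res$degenerate),
            " zero-variance probe set(s) with unequal means excluded")
  }
  fc <- rowMeans(sig[, trt, drop = FALSE]) /
    rowMeans(sig[, ctrl, drop = FALSE])
  ok <- !res$degenerate & !is.na(res$p_value) &
    res$p_value < params$p_threshold
  rd <- as.data.frame(SummarizedExperiment::rowData(mat))[keep, , drop = FALSE]
  build <- function(sel, direction) {
    ids <- keep[sel]
    ord <- order(fc[sel], decreasing = (direction == "up"))
    n <- length(ids)
    rec <- data.frame(probe_id = ids,
                      gene_name = if (!is.null(rd$gene_name))
                        rd$gene_name[sel] else rep(NA_character_, n),
                      symbol = if (!is.null(rd$symbol))
                        rd$symbol[sel] else rep(NA_character_, n),
                      entrez = if (!is.null(rd$entrez))
                        rd$entrez[sel] else rep(NA_integer_, n),
                      fold_change = fc[sel],
                      p_value = res$p_value[sel],
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
    de_gene_list(rec, direction = direction,
                 label = paste0(label_prefix, "-", direction),
                 fc_up = params$fc_up, fc_down = params$fc_down)
  }
  list(up = build(ok & fc > params$fc_up, "up"),
       down = build(ok & fc < params$fc_down, "down"))
}
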