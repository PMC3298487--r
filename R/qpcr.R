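#' Read a threshold-cycle (Ct) table from TSV
#'
#' Expected columns: `sample_id`, `group` (e.g. `control` / `JTX`), `gene`,
#' `ct` (threshold cycle, > 0). The reference gene used for normalisation
#' (GAPDH for the SYBR chemistry, Irf1 for the TaqMan runs) is named at
#' quantification time, not in the file.
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("sample_id", "group", "gene", "ct")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0))
    stop("Ct values must be positive and finite")
  tab
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Group Ct values are averaged per gene; the normalised difference
#' `(Ct_target - Ct_reference)` is compared between treated and control,
#' and the fold change is `efficiency^(-ddCt)`. The classical method
#' assumes perfect doubling per cycle (`efficiency = 2`); other measured
#' amplification efficiencies can be supplied.
#'
#' @param ct Ct table as from [read_ct_table()].
#' @param target target gene name.
#' @param reference reference (normaliser) gene name.
#' @param treated,control group labels.
#' @param efficiency amplification factor per cycle (default 2).
#' @return The linear fold change (treated relative to control), with the
#'   reference gene recorded in the `"reference"` attribute.
#' @examples
#' ct <- data.frame(sample_id = rep(1:4, 2), group = rep(c("control", "JTX"),
#'                  each = 2, times = 2),
#'                  gene = rep(c("Irf7", "Gapdh"), each = 4),
#'                  ct = c(25, 25, 24, 24, 20, 20, 20, 20))
#' ddct_fold_change(ct, "Irf7", "Gapdh")  # one cycle earlier -> 2-fold
#' @export
ddct_fold_change <- function(ct, target, reference, treated = "JTX",
                             control = "control", efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must exceed 1")
  mean_ct <- function(gene, group) {
    v <- ct$ct[ct$gene == gene & ct$group == group]
    if (!length(v))
      stop("no Ct values for gene '", gene, "' in group '", group, "'")
    mean(v)
  }
  ddct <- (mean_ct(target, treated) - mean_ct(reference, treated)) -
    (mean_ct(target, control) - mean_ct(reference, control))
  structure(efficiency^(-ddct), reference = reference)
}

#' Time of the peak response in a sampled time course
#'
#' The peak is the sampled time point at which the group mean is maximal;
#' ties resolve to the earliest such time. A maximum attained at the final
#' time point is flagged as right-censored — the true peak may lie beyond
#' the sampling window.
#'
#' @param tc time-course data frame with columns `time` (hours, strictly
#'   increasing within group), `group`, and `mean` (non-negative measured
#'   quantity; a `se` column may be present and is ignored here).
#' @param group which group to summarise.
#' @return List with `time` (peak time), `peak` (the maximal mean) and
#'   `censored` (logical).
#' @export
time_to_peak <- function(tc, group) {
  sub <- tc[tc$group == group, , drop = FALSE]
  if (nrow(sub) < 3L) stop("need >= 3 time points")
  sub <- sub[order(sub$time), , drop = FALSE]
  if (any(duplicated(sub$time)))
    stop("time points must be strictly increasing")
  if (any(sub$mean < 0)) stop("measured values must be non-negative")
  i <- which.max(sub$mean)                  # which.max takes the first tie
  list(time = sub$time[[i]], peak = sub$mean[[i]],
       censored = i == nrow(sub))
}

#' Two-group comparison by Student's pooled-variance t-test
#'
#' Two-sided pooled t in closed form; zero pooled variance with equal
#' means gives `p = 1` by convention.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group")
  sp2 <- ((n1 - 1) * stats::var(values_a) + (n2 - 1) * stats::var(values_b)) /
    (n1 + n2 - 2)
  d <- mean(values_a) - mean(values_b)
  if (sp2 == 0) {
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                df = n1 + n2 - 2, p_value = if (d == 0) 1 else 0))
  }
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, df = n1 + n2 - 2,
       p_value = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

#' Fisher's least-significant-difference test after one-way ANOVA
#'
#' All pairwise group comparisons using the pooled ANOVA mean-square error
#' and its residual degrees of freedom, without multiplicity adjustment
#' (the classical protected-LSD procedure; the protecting omnibus F is
#' also returned).
#'
#' @param values numeric response vector.
#' @param groups group factor (>= 2 levels, >= 2 values each).
#' @return List with `anova_p` (omnibus F-test p) and `pairs`, a data
#'   frame of pairwise `estimate` (mean difference) and `p_value`.
#' @export
fisher_lsd <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("need >= 2 values per group")
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfr <- an["Residuals", "Df"]
  lv <- levels(groups)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  combs <- utils::combn(lv, 2L)
  pairs <- data.frame(
    group_a = combs[1L, ], group_b = combs[2L, ],
    estimate = means[combs[1L, ]] - means[combs[2L, ]],
    stringsAsFactors = FALSE)
  se <- sqrt(mse * (1 / ns[combs[1L, ]] + 1 / ns[combs[2L, ]]))
  t <- pairs$estimate / se
  pairs$p_value <- 2 * stats::pt(-abs(t), dfr)
  rownames(pairs) <- NULL
  list(anova_p = an["groups", "Pr(>F)"], pairs = pairs)
}

#' Read a time-course table from TSV
#'
#' Columns: `time` (hours), `group`, `mean`, and optionally `se`.
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
read_time_course <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("time", "group", "mean")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("time-course table lacks column(s): ", paste(miss, collapse = ", "))
  tab
}
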