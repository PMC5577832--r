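# Single-probe differential methylation: two-group ANOVA per probe,
# direction/effect-size summaries, volcano export and a sample-level PCA
# for quality control.
#
# Tests run on beta values, not M-values: the effect-size cutoffs this
# workflow uses (0.3 for regions, 0.15 for large single-probe effects) are
# defined on the beta scale.

# Vectorised two-group one-way ANOVA over matrix rows. Equivalent to the
# squared pooled-variance t statistic: F = t^2 with df (1, n1+n2-2).
.row_anova <- function(values, groups) {
  case <- values[, groups == "CASE", drop = FALSE]
  ctrl <- values[, groups == "CTRL", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples (have ",
                             n1, " CASE, ", n2, " CTRL)")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  ss1 <- rowSums((case - m1)^2); ss2 <- rowSums((ctrl - m2)^2)
  delta <- m1 - m2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  denom <- sp2 * (1 / n1 + 1 / n2)
  f <- ifelse(denom > 0, delta^2 / denom, ifelse(delta == 0, 0, Inf))
  p <- ifelse(is.finite(f),
              stats::pf(f, 1, n1 + n2 - 2, lower.tail = FALSE), 0)
  # zero total variance (all values identical): define F=0, p=1
  p[denom == 0 & delta == 0] <- 1
  data.frame(F_stat = f, p_value = p, mean_case = m1, mean_ctrl = m2,
             delta = delta, row.names = rownames(values))
}

#' Two-group one-way ANOVA for a single probe
#'
#' For two groups the one-way ANOVA F statistic equals the square of the
#' pooled-variance t statistic, with df (1, n1+n2−2). If the total variance
#' of the pooled data is zero the probe is untestable and `(F=0, p=1)` is
#' returned.
#'
#' @param case_values,ctrl_values Numeric beta values, at least 2 per
#'   group, no missing values.
#' @return Named list with `F_stat`, `p_value`, `mean_case`, `mean_ctrl`
#'   and `delta` (= mean_case − mean_ctrl).
#' @examples
#' probe_anova(c(0.8, 0.7, 0.9), c(0.2, 0.3, 0.1))
#' @export
probe_anova <- function(case_values, ctrl_values) {
  if (anyNA(case_values) || anyNA(ctrl_values)) {
    stop("probe_anova does not accept missing values")
  }
  vals <- matrix(c(case_values, ctrl_values), nrow = 1,
                 dimnames = list("probe", NULL))
  colnames(vals) <- paste0("s", seq_len(ncol(vals)))
  groups <- c(rep("CASE", length(case_values)), rep("CTRL", length(ctrl_values)))
  res <- .row_anova(vals, groups)
  as.list(res[1, ])
}

#' Call differentially methylated positions (DMPs)
#'
#' Runs the per-probe two-group ANOVA over every testable probe of a beta
#' matrix and attaches the manifest annotation. A probe is flagged
#' significant when its non-adjusted p-value is strictly below
#' `p_threshold`; no multiple-testing correction enters the call, but a
#' Benjamini–Hochberg column (`p_adj_bh`) is emitted for reference.
#'
#' Probes with a missing beta in any sample are excluded (with a message);
#' probes absent from the annotation are kept with empty annotation fields.
#'
#' @param bm A [beta_matrix()].
#' @param annotations A `probe_annotation` data frame from
#'   [read_manifest()], or `NULL` to proceed unannotated.
#' @param p_threshold Significance threshold on the non-adjusted p
#'   (default 0.001, strict `<`).
#' @return Data frame of class `dmp_result`: one row per tested probe with
#'   columns `probe_id`, `F_stat`, `p_value`, `p_adj_bh`, `mean_case`,
#'   `mean_ctrl`, `delta`, `direction` (`HYPER` = higher in cases), the
#'   annotation columns, and logical `significant`.
#' @export
call_dmps <- function(bm, annotations = NULL, p_threshold = 0.001) {
  stopifnot(inherits(bm, "beta_matrix"))
  vals <- bm$values
  keep <- !apply(is.na(vals), 1, any)
  if (any(!keep)) {
    message("call_dmps: excluded ", sum(!keep),
            " probe(s) with missing values")
    vals <- vals[keep, , drop = FALSE]
  }
  res <- .row_anova(vals, bm$groups)
  out <- data.frame(probe_id = rownames(vals), res,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(out$delta > 0, "HYPER",
                          ifelse(out$delta < 0, "HYPO", NA_character_))
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations)
    idx <- match(out$probe_id, ann$probe_id)
    n_unann <- sum(is.na(idx))
    if (n_unann > 0) {
      message("call_dmps: ", n_unann,
              " probe(s) not in the annotation; kept with empty annotation")
    }
    out$chrom <- ifelse(is.na(idx), "", ann$chrom[idx])
    out$position <- ifelse(is.na(idx), NA_integer_, ann$position[idx])
    out$genes <- ifelse(is.na(idx), "", ann$genes[idx])
    out$island_name <- ifelse(is.na(idx), "", ann$island_name[idx])
    out$relation <- ifelse(is.na(idx), "", ann$relation[idx])
  } else {
    out$chrom <- ""; out$position <- NA_integer_
    out$genes <- ""; out$island_name <- ""; out$relation <- ""
  }
  out$significant <- out$p_value < p_threshold
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("dmp_result", "data.frame")
  out
}

#' Summarise a DMP call
#'
#' Counts significant probes by direction, the distinct genic regions they
#' map to, and the large-effect subset. "Genic regions" counts distinct
#' gene symbols covered by significant probes of each direction (multi-gene
#' annotations are split); `n_*_annotation_strings` counts distinct
#' unsplit annotation strings instead, for comparison. Large effect means
#' |delta| strictly greater than `effect_threshold`.
#'
#' @param dmps A `dmp_result` from [call_dmps()].
#' @param p_threshold Significance threshold (default: the one stored in
#'   `dmps`, else 0.001).
#' @param effect_threshold Beta-difference threshold for the large-effect
#'   count (default 0.15, strict `>`).
#' @return A list of class `dmp_summary` with counts `n_tested`,
#'   `n_significant`, `n_hyper`, `n_hypo`, `n_hyper_genic_regions`,
#'   `n_hypo_genic_regions`, `n_hyper_large_effect`, `n_hypo_large_effect`,
#'   `n_hyper_annotation_strings`, `n_hypo_annotation_strings`, plus the
#'   thresholds used.
#' @export
summarize_dmps <- function(dmps, p_threshold = NULL, effect_threshold = 0.15) {
  p_threshold <- p_threshold %||% attr(dmps, "p_threshold") %||% 0.001
  sig <- dmps[dmps$p_value < p_threshold, , drop = FALSE]
  hyper <- sig[sig$delta > 0, , drop = FALSE]
  hypo <- sig[sig$delta < 0, , drop = FALSE]
  distinct_genes <- function(x) length(unique(unlist(split_genes(x$genes))))
  distinct_strings <- function(x) length(unique(x$genes[nzchar(x$genes)]))
  out <- list(
    n_tested = nrow(dmps),
    n_significant = nrow(sig),
    n_hyper = nrow(hyper),
    n_hypo = nrow(hypo),
    n_hyper_genic_regions = distinct_genes(hyper),
    n_hypo_genic_regions = distinct_genes(hypo),
    n_hyper_large_effect = sum(abs(hyper$delta) > effect_threshold),
    n_hypo_large_effect = sum(abs(hypo$delta) > effect_threshold),
    n_hyper_annotation_strings = distinct_strings(hyper),
    n_hypo_annotation_strings = distinct_strings(hypo),
    p_threshold = p_threshold,
    effect_threshold = effect_threshold
  )
  class(out) <- "dmp_summary"
  out
}

#' @export
print.dmp_summary <- function(x, ...) {
  cat(sprintf(
    paste0("DMP summary (p < %g, |delta| > %g):\n",
           "  %d significant of %d tested\n",
           "  %d hypermethylated (%d genic regions, %d large-effect)\n",
           "  %d hypomethylated (%d genic regions, %d large-effect)\n"),
    x$p_threshold, x$effect_threshold, x$n_significant, x$n_tested,
    x$n_hyper, x$n_hyper_genic_regions, x$n_hyper_large_effect,
    x$n_hypo, x$n_hypo_genic_regions, x$n_hypo_large_effect))
  invisible(x)
}

#' Principal component analysis of samples
#'
#' PCA of the samples-by-probes matrix after per-probe mean centering, for
#' sample-level quality control. Probes with missing values are excluded.
#'
#' @param bm A [beta_matrix()].
#' @param n_components Number of components to return (default 2); must
#'   not exceed n_samples − 1.
#' @return List with `scores` (samples × components), `var_explained`
#'   (fraction of total variance per returned component) and `groups`.
#' @export
sample_pca <- function(bm, n_components = 2) {
  stopifnot(inherits(bm, "beta_matrix"))
  vals <- bm$values
  vals <- vals[!apply(is.na(vals), 1, any), , drop = FALSE]
  n <- ncol(vals)
  if (n < 2) stop("sample_pca needs at least 2 samples")
  if (n_components > n - 1) {
    stop("n_components (", n_components, ") exceeds n_samples - 1 (", n - 1, ")")
  }
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       var_explained = var_frac[seq_len(n_components)],
       groups = bm$groups)
}

#' Volcano-plot table for a DMP call
#'
#' One record per probe: beta difference on x, −log10 non-adjusted p on y,
#' and the significance flag at the strict `p < p_threshold` rule.
#'
#' @param dmps A `dmp_result`.
#' @param p_threshold Threshold for the flag (default: stored value, else
#'   0.001).
#' @return Data frame with `probe_id`, `delta`, `neg_log10_p`,
#'   `significant`.
#' @export
volcano_table <- function(dmps, p_threshold = NULL) {
  p_threshold <- p_threshold %||% attr(dmps, "p_threshold") %||% 0.001
  data.frame(probe_id = dmps$probe_id,
             delta = dmps$delta,
             neg_log10_p = -log10(dmps$p_value),
             significant = dmps$p_value < p_threshold,
             stringsAsFactors = FALSE)
}
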