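# Two-group differential expression (pooled t-test + fold change) and the
# methylation-expression concordance join.

#' Guess the scale of an expression matrix
#'
#' Heuristic: non-negative values whose 99th percentile is at most 20 are
#' taken as log2 intensities; anything else as linear.
#'
#' @param values Numeric vector or matrix.
#' @return `"log2"` or `"linear"`.
#' @export
detect_expression_scale <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("no non-missing expression values")
  if (min(v) >= 0 && stats::quantile(v, 0.99) <= 20) "log2" else "linear"
}

#' Two-sample t-test with fold change for one gene
#'
#' Two-sided pooled-variance (Student) t-test. The fold change is the
#' linear-scale case/control ratio: `2^(mean_case − mean_ctrl)` for log2
#' data, `mean_case / mean_ctrl` for linear data (a zero control mean on
#' the linear scale is an error).
#'
#' @param case_values,ctrl_values Numeric vectors, at least 2 per group.
#' @param scale `"log2"`, `"linear"` or `"auto"` (heuristic on the pooled
#'   values, see [detect_expression_scale()]).
#' @return List with `fold_change`, `t_stat`, `p_value`, `mean_case`,
#'   `mean_ctrl`, `direction` (`UP` iff fold change > 1) and the `scale`
#'   used.
#' @export
de_ttest <- function(case_values, ctrl_values,
                     scale = c("auto", "log2", "linear")) {
  scale <- match.arg(scale)
  if (length(case_values) < 2 || length(ctrl_values) < 2) {
    stop("each group needs at least 2 values")
  }
  if (anyNA(case_values) || anyNA(ctrl_values)) {
    stop("de_ttest does not accept missing values")
  }
  if (scale == "auto") {
    scale <- detect_expression_scale(c(case_values, ctrl_values))
  }
  n1 <- length(case_values); n2 <- length(ctrl_values)
  m1 <- mean(case_values); m2 <- mean(ctrl_values)
  sp2 <- (sum((case_values - m1)^2) + sum((ctrl_values - m2)^2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    t_stat <- (m1 - m2) / se
  }
  p <- if (is.finite(t_stat)) {
    2 * stats::pt(abs(t_stat), n1 + n2 - 2, lower.tail = FALSE)
  } else 0
  fc <- if (scale == "log2") {
    2^(m1 - m2)
  } else {
    if (m2 == 0) stop("control mean is zero on the linear scale; fold change undefined")
    m1 / m2
  }
  list(fold_change = fc, t_stat = t_stat, p_value = p,
       mean_case = m1, mean_ctrl = m2,
       direction = if (fc > 1) "UP" else "DOWN", scale = scale)
}

#' Differential expression for a set of genes
#'
#' Runs [de_ttest()] per gene of an expression matrix. When a gene symbol
#' maps to several matrix rows, the row with the largest inter-quartile
#' range is used by default (`collapse = "iqr"`), or rows are averaged
#' (`collapse = "mean"`).
#'
#' @param em An `expression_matrix` from [read_expression_matrix()].
#' @param genes Genes to test (default: all distinct row ids).
#' @param scale Passed to [de_ttest()]; `"auto"` resolves once on the
#'   whole matrix.
#' @param collapse `"iqr"` or `"mean"`.
#' @return Data frame with `gene`, `fold_change`, `t_stat`, `p_value`,
#'   `direction`; genes absent from the matrix are dropped with a message.
#' @export
call_de <- function(em, genes = NULL, scale = c("auto", "log2", "linear"),
                    collapse = c("iqr", "mean")) {
  stopifnot(inherits(em, "expression_matrix"))
  scale <- match.arg(scale)
  collapse <- match.arg(collapse)
  if (scale == "auto") scale <- detect_expression_scale(em$values)
  row_gene <- toupper(rownames(em$values))
  genes <- unique(toupper(genes %||% row_gene))
  missing <- setdiff(genes, row_gene)
  if (length(missing) > 0) {
    message("call_de: ", length(missing),
            " gene(s) absent from the expression matrix")
    genes <- setdiff(genes, missing)
  }
  case_cols <- em$groups == "CASE"
  rows <- lapply(genes, function(g) {
    idx <- which(row_gene == g)
    v <- if (length(idx) == 1) {
      em$values[idx, ]
    } else if (collapse == "iqr") {
      iqrs <- apply(em$values[idx, , drop = FALSE], 1, stats::IQR, na.rm = TRUE)
      em$values[idx[which.max(iqrs)], ]
    } else {
      colMeans(em$values[idx, , drop = FALSE], na.rm = TRUE)
    }
    if (anyNA(v)) return(NULL)
    r <- de_ttest(v[case_cols], v[!case_cols], scale = scale)
    data.frame(gene = g, fold_change = r$fold_change, t_stat = r$t_stat,
               p_value = r$p_value, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), fold_change = numeric(0),
                      t_stat = numeric(0), p_value = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Methylation-expression concordance table
#'
#' Inner-joins (on uppercased gene symbol) a table of differentially
#' methylated genes with a differential-expression table. Expression is
#' flagged significant at `p < de_p` (strict). The `concordant` flag
#' records the canonical repressive pairing — hypermethylated & down-
#' regulated or hypomethylated & up-regulated — purely descriptively:
#' discordant pairings are reported as-is, with no causal claim.
#'
#' @param meth Data frame with columns `gene` and `direction`
#'   (`HYPER`/`HYPO`); one row per gene (duplicates deduplicated, a gene
#'   listed with both directions is marked `MIXED` and never concordant).
#' @param de Output of [call_de()].
#' @param de_p Expression significance threshold (default 0.05).
#' @return Data frame `gene`, `meth_direction`, `fold_change`,
#'   `de_p_value`, `de_direction`, `de_significant`, `concordant`, with
#'   attribute `n_meth_unmatched` = methylation genes absent from the
#'   expression table.
#' @export
concordance_table <- function(meth, de, de_p = 0.05) {
  stopifnot(all(c("gene", "direction") %in% names(meth)),
            all(c("gene", "fold_change", "p_value", "direction") %in% names(de)))
  mg <- toupper(meth$gene)
  dir_by_gene <- tapply(meth$direction, mg, function(d) {
    u <- unique(d)
    if (length(u) == 1) u else "MIXED"
  })
  meth_u <- data.frame(gene = names(dir_by_gene),
                       meth_direction = unname(dir_by_gene),
                       stringsAsFactors = FALSE)
  de$gene <- toupper(de$gene)
  joined <- merge(meth_u, de, by = "gene")
  n_unmatched <- nrow(meth_u) - nrow(joined)
  if (n_unmatched > 0) {
    message("concordance_table: ", n_unmatched,
            " methylation gene(s) absent from the expression table")
  }
  out <- data.frame(gene = joined$gene,
                    meth_direction = joined$meth_direction,
                    fold_change = joined$fold_change,
                    de_p_value = joined$p_value,
                    de_direction = joined$direction,
                    de_significant = joined$p_value < de_p,
                    stringsAsFactors = FALSE)
  out$concordant <- (out$meth_direction == "HYPER" & out$de_direction == "DOWN") |
    (out$meth_direction == "HYPO" & out$de_direction == "UP")
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_meth_unmatched") <- n_unmatched
  out
}
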