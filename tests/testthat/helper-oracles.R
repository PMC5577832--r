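# Independent oracles and small fixture builders shared by the tests.
# Every oracle here recomputes its quantity from first principles (explicit
# enumeration, base combinatorics, or a from-scratch statistic) and never
# calls the package code path it is used to check.

# Exact one-sided hypergeometric tail P(X >= k) by explicit enumeration of
# binomial coefficients (no phyper).
fisher_enum_p <- function(k, K, n, B) {
  lo <- max(0, n + K - B)
  hi <- min(n, K)
  if (k > hi) return(0)
  j <- max(k, lo):hi
  sum(exp(lchoose(K, j) + lchoose(B - K, n - j) - lchoose(B, n)))
}

# From-scratch Hotelling T2 (plain solve(), no pseudoinverse) used only
# inside the permutation oracle.
.oracle_t2 <- function(X, is_case) {
  X1 <- X[, is_case, drop = FALSE]
  X2 <- X[, !is_case, drop = FALSE]
  n1 <- ncol(X1); n2 <- ncol(X2)
  d <- rowMeans(X1) - rowMeans(X2)
  S <- (tcrossprod(X1 - rowMeans(X1)) + tcrossprod(X2 - rowMeans(X2))) /
    (n1 + n2 - 2)
  n1 * n2 / (n1 + n2) * sum(d * solve(S, d))
}

# Exact permutation p of the T2 statistic over all balanced relabelings
# (choose(n, n1) assignments of the CASE label).
perm_t2_p <- function(X, n_case) {
  n <- ncol(X)
  obs <- .oracle_t2(X, seq_len(n) <= n_case)
  labelings <- utils::combn(n, n_case, simplify = FALSE)
  stats <- vapply(labelings, function(idx) {
    .oracle_t2(X, seq_len(n) %in% idx)
  }, numeric(1))
  mean(stats >= obs - 1e-12)
}

# Exact permutation p of the two-group F statistic (univariate).
perm_f_p <- function(x, n_case) {
  n <- length(x)
  fstat <- function(is_case) {
    m1 <- mean(x[is_case]); m2 <- mean(x[!is_case])
    ss <- sum((x[is_case] - m1)^2) + sum((x[!is_case] - m2)^2)
    if (ss == 0) return(if (m1 == m2) 0 else Inf)
    (m1 - m2)^2 / ((ss / (n - 2)) * (1 / sum(is_case) + 1 / sum(!is_case)))
  }
  obs <- fstat(seq_len(n) <= n_case)
  labelings <- utils::combn(n, n_case, simplify = FALSE)
  stats <- vapply(labelings, function(idx) fstat(seq_len(n) %in% idx),
                  numeric(1))
  mean(stats >= obs - 1e-12)
}

# Minimal probe-annotation builder for hand-made layouts.
make_ann <- function(probe_id, position, chrom = "chr1", genes = "",
                     island_name = "", relation = NULL) {
  if (is.null(relation)) {
    relation <- ifelse(nzchar(island_name), "Island", "OpenSea")
  }
  ann <- data.frame(probe_id = probe_id, chrom = chrom,
                    position = as.integer(position), genes = genes,
                    island_name = island_name, relation = relation,
                    stringsAsFactors = FALSE)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

# Beta matrix from a numeric matrix plus group sizes (CASE columns first).
make_bm <- function(values, n_case, probe_ids = NULL) {
  if (is.null(probe_ids)) probe_ids <- paste0("p", seq_len(nrow(values)))
  n <- ncol(values)
  sample_ids <- c(paste0("case_", seq_len(n_case)),
                  paste0("ctrl_", seq_len(n - n_case)))
  dimnames(values) <- list(probe_ids, sample_ids)
  beta_matrix(values, stats::setNames(rep(c("CASE", "CTRL"),
                                          c(n_case, n - n_case)), sample_ids))
}

# A small in-code gene-set library.
make_library <- function(sets, names = NULL) {
  structure(list(sets = sets,
                 term_names = stats::setNames(names %||% names(sets),
                                              names(sets))),
            class = "gene_set_library")
}

`%||%` <- wsmeth:::`%||%`
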