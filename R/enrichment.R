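# Gene-set enrichment with a combined score. Each term gets a one-sided
# Fisher exact overlap p, a z-score measuring how far the term's p-value
# rank deviates from its expected rank under random input lists of the same
# size, and the combined score c = ln(p) * z used for prioritisation.
# The natural log is used ("log" base is a ranking rescale only).

# One-sided (greater) Fisher exact p for overlap k between a list of size n
# and a term of size K in a background of size B: hypergeometric upper tail.
.fisher_p <- function(k, K, n, B) {
  stats::phyper(k - 1, K, B - K, n, lower.tail = FALSE)
}

# Deterministic rank of terms by ascending p, ties broken by term id.
.rank_terms <- function(p, term_ids) {
  r <- integer(length(p))
  r[order(p, term_ids)] <- seq_along(p)
  r
}

#' One-sided Fisher exact test for a gene-set overlap
#'
#' Both gene sets are intersected with the background first (dropped genes
#' are counted in a message). The p-value is the hypergeometric upper tail
#' \eqn{P(X \ge k)} for the 2x2 table
#' (k, n−k; K−k, B−n−K+k).
#'
#' @param input_genes Character vector of query gene symbols.
#' @param term_genes Character vector of term gene symbols.
#' @param background Character vector: the gene universe.
#' @return List with `k` (overlap), `K` (term size in background), `n`
#'   (input size in background), `p_value` and `overlapping_genes`.
#' @export
fisher_overlap <- function(input_genes, term_genes, background) {
  background <- unique(toupper(background))
  if (length(background) == 0) stop("background gene universe is empty")
  input0 <- unique(toupper(input_genes))
  input <- intersect(input0, background)
  if (length(input) < length(input0)) {
    message("fisher_overlap: dropped ", length(input0) - length(input),
            " input gene(s) outside the background")
  }
  term <- intersect(unique(toupper(term_genes)), background)
  ov <- intersect(input, term)
  list(k = length(ov), K = length(term), n = length(input),
       p_value = .fisher_p(length(ov), length(term), length(input),
                           length(background)),
       overlapping_genes = sort(ov))
}

# Term-by-background logical membership matrix.
.membership <- function(library, background) {
  M <- vapply(library$sets, function(g) background %in% toupper(g),
              logical(length(background)))
  t(matrix(M, nrow = length(background),
           dimnames = list(background, names(library$sets))))
}

#' Rank-deviation z-scores for a gene-set library
#'
#' For each term, the expected rank (by ascending Fisher p, ties broken by
#' term id) under random input lists of size `input_size` drawn uniformly
#' from the background is estimated; the z-score is
#' `(observed_rank − mean_null_rank) / sd_null_rank`, so a negative z means
#' the term ranked better than expected. When the number of possible input
#' sets `choose(|background|, input_size)` is at most `exhaustive_limit`,
#' the null is enumerated exhaustively (population sd); otherwise `n_null`
#' seeded random draws are used (sample sd). A term with zero null rank sd
#' gets z = 0 with a warning.
#'
#' @param library A `gene_set_library`.
#' @param input_size Size of the (background-intersected) input list.
#' @param observed_ranks Integer vector of observed term ranks, named by
#'   term id.
#' @param background Gene universe (default: union of library genes).
#' @param n_null Number of null draws when sampling (default 1000, min 100).
#' @param seed RNG seed for the sampled null.
#' @param exhaustive_limit Enumerate all input sets when their count is at
#'   most this (default 1e5).
#' @return Named numeric vector of z-scores (one per term).
#' @export
rank_zscore <- function(library, input_size, observed_ranks,
                        background = NULL, n_null = 1000, seed = NULL,
                        exhaustive_limit = 1e5) {
  background <- unique(toupper(background %||% unlist(library$sets)))
  B <- length(background)
  term_ids <- names(library$sets)
  Tn <- length(term_ids)
  if (input_size > B) stop("input_size (", input_size,
                           ") exceeds background size (", B, ")")
  if (Tn == 0) return(stats::setNames(numeric(0), character(0)))
  M <- .membership(library, background)
  Ksz <- rowSums(M)
  rank_of_set <- function(idx) {
    k <- rowSums(M[, idx, drop = FALSE])
    .rank_terms(.fisher_p(k, Ksz, length(idx), B), term_ids)
  }
  n_sets <- suppressWarnings(choose(B, input_size))
  if (is.finite(n_sets) && n_sets <= exhaustive_limit) {
    sets <- utils::combn(B, input_size, simplify = FALSE)
    ranks <- matrix(vapply(sets, rank_of_set, integer(Tn)), nrow = Tn)
    mu <- rowMeans(ranks)
    sdv <- sqrt(rowMeans((ranks - mu)^2))  # population sd: full enumeration
  } else {
    if (n_null < 100) stop("n_null must be at least 100")
    ranks <- with_local_seed(seed, {
      matrix(vapply(seq_len(n_null), function(i) {
        rank_of_set(sample.int(B, input_size))
      }, integer(Tn)), nrow = Tn)
    })
    mu <- rowMeans(ranks)
    sdv <- apply(ranks, 1, stats::sd)
  }
  obs <- observed_ranks[term_ids]
  z <- numeric(Tn)
  zero_sd <- sdv == 0
  if (any(zero_sd)) {
    warning("rank_zscore: ", sum(zero_sd),
            " term(s) with zero null rank sd; z set to 0")
  }
  z[!zero_sd] <- (obs[!zero_sd] - mu[!zero_sd]) / sdv[!zero_sd]
  stats::setNames(z, term_ids)
}

#' Gene-set enrichment with combined score
#'
#' Scores every library term against a gene list: one-sided Fisher exact
#' overlap p ([fisher_overlap()]), rank-deviation z ([rank_zscore()]) and
#' combined score `c = ln(p) * z`. Terms with `p < p_cut` (strict) are
#' returned sorted by descending `|c|`, ties by ascending p then term id.
#' With a fixed `seed` the output is fully reproducible.
#'
#' @param gene_list Character vector of query gene symbols.
#' @param library A `gene_set_library` from [read_gmt()].
#' @param background Gene universe (default: union of all library genes).
#' @param p_cut Fisher-p filter (default 0.05, strict `<`).
#' @param n_null,seed,exhaustive_limit Passed to [rank_zscore()].
#' @return Data frame of class `enrichment_result`: `term_id`,
#'   `term_name`, `overlap_k`, `term_size`, `input_size`, `p_value`, `z`,
#'   `combined_score`, `overlapping_genes` (";"-joined), sorted as above.
#' @export
enrich <- function(gene_list, library, background = NULL, p_cut = 0.05,
                   n_null = 1000, seed = NULL, exhaustive_limit = 1e5) {
  stopifnot(inherits(library, "gene_set_library"))
  background <- unique(toupper(background %||% unlist(library$sets)))
  if (length(background) == 0) stop("background gene universe is empty")
  input <- intersect(unique(toupper(gene_list)), background)
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      overlap_k = integer(0), term_size = integer(0),
                      input_size = integer(0), p_value = numeric(0),
                      z = numeric(0), combined_score = numeric(0),
                      overlapping_genes = character(0),
                      stringsAsFactors = FALSE)
  if (length(input) == 0) {
    warning("enrich: gene list is empty after background intersection")
    class(empty) <- c("enrichment_result", "data.frame")
    return(empty)
  }
  term_ids <- names(library$sets)
  if (length(term_ids) == 0) {
    class(empty) <- c("enrichment_result", "data.frame")
    return(empty)
  }
  M <- .membership(library, background)
  Ksz <- rowSums(M)
  k <- rowSums(M[, input, drop = FALSE])
  p <- .fisher_p(k, Ksz, length(input), length(background))
  obs_rank <- stats::setNames(.rank_terms(p, term_ids), term_ids)
  z <- rank_zscore(library, length(input), obs_rank, background = background,
                   n_null = n_null, seed = seed,
                   exhaustive_limit = exhaustive_limit)
  cs <- log(p) * z
  ov <- vapply(term_ids, function(id) {
    paste(sort(intersect(input, toupper(library$sets[[id]]))), collapse = ";")
  }, character(1))
  out <- data.frame(term_id = term_ids,
                    term_name = unname(library$term_names[term_ids]),
                    overlap_k = as.integer(k),
                    term_size = as.integer(Ksz),
                    input_size = length(input),
                    p_value = p, z = unname(z), combined_score = unname(cs),
                    overlapping_genes = unname(ov),
                    stringsAsFactors = FALSE)
  out <- out[out$p_value < p_cut, , drop = FALSE]
  out <- out[order(-abs(out$combined_score), out$p_value, out$term_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
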