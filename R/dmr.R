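# Region-level differential methylation. Windows of `window_size` adjacent
# eligible probes (gene-associated probes in CpG islands, shores or shelves,
# never spanning two island units) are tested with two-group MANOVA. For two
# groups all classical MANOVA statistics (Wilks, Pillai, Hotelling-Lawley,
# Roy) coincide, so the test is implemented as Hotelling's T-squared with
# its exact F transform. A window is significant when its non-adjusted p is
# strictly below the threshold AND it contains a run of at least
# `min_adjacent_exceeding` consecutive probes whose |group mean difference|
# is >= `min_abs_delta` (inclusive). Significant windows of one island unit
# that overlap or touch are merged into a DMR.

#' Parameters for DMR calling
#'
#' @param window_size Number of adjacent probes per window (default 3).
#' @param p_threshold Non-adjusted p threshold, strict `<` (default 0.001).
#' @param min_abs_delta Minimum absolute beta difference, inclusive `>=`
#'   (default 0.3).
#' @param min_adjacent_exceeding How many consecutive probes within a
#'   window must reach `min_abs_delta` (default 2).
#' @return A validated list of class `dmr_params`.
#' @export
dmr_params <- function(window_size = 3, p_threshold = 0.001,
                       min_abs_delta = 0.3, min_adjacent_exceeding = 2) {
  stopifnot(window_size >= 2,
            min_adjacent_exceeding >= 1,
            min_adjacent_exceeding <= window_size,
            p_threshold > 0, p_threshold <= 1,
            min_abs_delta >= 0)
  structure(list(window_size = as.integer(window_size),
                 p_threshold = p_threshold,
                 min_abs_delta = min_abs_delta,
                 min_adjacent_exceeding = as.integer(min_adjacent_exceeding)),
            class = "dmr_params")
}

#' Probes eligible for region-level testing
#'
#' Region testing is restricted to probes mapping in CpG-rich regions
#' (island, shore or shelf — i.e. relation other than `OpenSea`) that are
#' associated to at least one gene. The result is sorted by chromosome,
#' position, then probe id (probe id breaks position ties
#' deterministically).
#'
#' @param annotations A `probe_annotation` data frame.
#' @return The filtered, ordered annotation data frame.
#' @export
eligible_probes <- function(annotations) {
  ann <- as.data.frame(annotations)
  keep <- ann$relation %in% c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf") &
    nzchar(ann$genes)
  ann <- ann[keep, , drop = FALSE]
  ann <- ann[order(ann$chrom, ann$position, ann$probe_id), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Build sliding windows over eligible probes
#'
#' Windows are runs of `window_size` consecutive eligible probes that share
#' one island unit (same chromosome and manifest island name), sliding with
#' step 1. Island units with fewer than `window_size` eligible probes yield
#' no windows; windows never span two island units.
#'
#' @param eligible Output of [eligible_probes()].
#' @param params A [dmr_params()].
#' @return Data frame with one row per window: `window_id`, `chrom`,
#'   `island_name`, `probe_ids` (";"-joined, ordered by position) and
#'   `start_idx` (index of the window's first probe within `eligible`).
#' @export
make_windows <- function(eligible, params = dmr_params()) {
  w <- params$window_size
  if (nrow(eligible) == 0) {
    return(data.frame(window_id = integer(0), chrom = character(0),
                      island_name = character(0), probe_ids = character(0),
                      start_idx = integer(0), stringsAsFactors = FALSE))
  }
  unit <- paste(eligible$chrom, eligible$island_name, sep = "\r")
  runs <- rle(unit)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  rows <- list()
  for (r in seq_along(runs$lengths)) {
    L <- runs$lengths[r]
    if (L < w) next
    starts <- run_start[r]:(run_end[r] - w + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = eligible$chrom[starts],
      island_name = eligible$island_name[starts],
      probe_ids = vapply(starts, function(s) {
        paste(eligible$probe_id[s:(s + w - 1L)], collapse = ";")
      }, character(1)),
      start_idx = starts,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(window_id = integer(0), chrom = character(0),
                      island_name = character(0), probe_ids = character(0),
                      start_idx = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- data.frame(window_id = seq_len(nrow(out)), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hotelling's T-squared test for one window
#'
#' Two-group MANOVA statistic
#' \deqn{T^2 = \frac{n_1 n_2}{n_1+n_2}\, d' S^{-1} d}
#' with `d` the per-probe mean-difference vector (CASE − CTRL) and `S` the
#' pooled within-group covariance, transformed exactly to
#' \deqn{F = T^2\,\frac{n-p-1}{p(n-2)} \sim F_{p,\,n-p-1}}
#' where `p` is the window size and `n = n1+n2`. A numerically singular `S`
#' is inverted by Moore–Penrose pseudoinverse (singular values below
#' `1e-10` of the largest are dropped) with a warning.
#'
#' @param window_betas Numeric matrix, window probes in rows, samples in
#'   columns.
#' @param groups `"CASE"`/`"CTRL"` vector named by (or aligned with) the
#'   columns of `window_betas`.
#' @return List of class `window_test` with `T2`, `F_stat`, `df1`, `df2`,
#'   `p_value`, `deltas` (named, CASE − CTRL) and `singular` flag.
#' @export
hotelling_t2 <- function(window_betas, groups) {
  stopifnot(is.matrix(window_betas))
  if (!is.null(names(groups)) && !is.null(colnames(window_betas))) {
    groups <- groups[colnames(window_betas)]
  }
  p <- nrow(window_betas)
  case <- window_betas[, groups == "CASE", drop = FALSE]
  ctrl <- window_betas[, groups == "CTRL", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl); n <- n1 + n2
  if (n < p + 2) {
    stop("Hotelling's T2 with ", p, " probes needs at least ", p + 2,
         " samples (have ", n, ")")
  }
  if (anyNA(case) || anyNA(ctrl)) stop("window contains missing values")
  d <- rowMeans(case) - rowMeans(ctrl)
  S <- (tcrossprod(case - rowMeans(case)) +
          tcrossprod(ctrl - rowMeans(ctrl))) / (n - 2)
  sv <- svd(S)
  tol <- 1e-10 * max(sv$d, 0)
  pos <- sv$d > tol
  singular <- !all(pos)
  if (singular) {
    warning("pooled covariance is numerically singular; using pseudoinverse")
  }
  if (!any(pos)) {
    quad <- if (all(d == 0)) 0 else Inf
  } else {
    dv <- crossprod(sv$u[, pos, drop = FALSE], d)
    quad <- sum(dv^2 / sv$d[pos])
  }
  T2 <- n1 * n2 / n * quad
  df1 <- p; df2 <- n - p - 1
  F_stat <- T2 * df2 / (p * (n - 2))
  p_value <- if (is.finite(F_stat)) {
    stats::pf(F_stat, df1, df2, lower.tail = FALSE)
  } else 0
  if (T2 == 0) p_value <- 1
  structure(list(T2 = T2, F_stat = F_stat, df1 = df1, df2 = df2,
                 p_value = p_value, deltas = d, singular = singular),
            class = "window_test")
}

# Dual significance rule for one tested window: p strictly below threshold
# and a run of >= min_adjacent_exceeding consecutive probes (in position
# order) with |delta| >= min_abs_delta.
.window_significant <- function(p_value, deltas, params) {
  if (!(p_value < params$p_threshold)) return(FALSE)
  exceeds <- abs(deltas) >= params$min_abs_delta
  r <- rle(exceeds)
  any(r$values & r$lengths >= params$min_adjacent_exceeding)
}

#' Call differentially methylated regions (DMRs)
#'
#' Tests every sliding window (see [make_windows()]) with
#' [hotelling_t2()], applies the dual significance rule — non-adjusted
#' `p < p_threshold` and at least `min_adjacent_exceeding` consecutive
#' probes with `|delta| >= min_abs_delta` — and merges significant windows
#' of the same island unit whose probe ranges overlap or touch into one
#' DMR. The DMR p-value is the minimum member-window p. DMR direction is
#' `HYPER`/`HYPO` when all member-probe deltas reaching `min_abs_delta`
#' share one sign, else `MIXED`.
#'
#' @param bm A [beta_matrix()].
#' @param annotations A `probe_annotation` data frame.
#' @param params A [dmr_params()].
#' @return List with `windows` (per-window test table, all windows) and
#'   `dmrs` (merged significant regions: `chrom`, `start`, `end`,
#'   `n_probes`, `probe_ids`, `genes`, `island_name`, `relations`,
#'   `p_value`, `direction`).
#' @export
call_dmrs <- function(bm, annotations, params = dmr_params()) {
  stopifnot(inherits(bm, "beta_matrix"))
  elig <- eligible_probes(annotations)
  present <- elig$probe_id %in% rownames(bm$values)
  if (any(!present)) {
    message("call_dmrs: ", sum(!present),
            " eligible probe(s) absent from the beta matrix; skipped")
    elig <- elig[present, , drop = FALSE]
  }
  complete <- !apply(is.na(bm$values[elig$probe_id, , drop = FALSE]), 1, any)
  if (any(!complete)) {
    message("call_dmrs: excluded ", sum(!complete),
            " eligible probe(s) with missing values")
    elig <- elig[complete, , drop = FALSE]
  }
  windows <- make_windows(elig, params)
  w <- params$window_size
  empty_dmrs <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), n_probes = integer(0),
                           probe_ids = character(0), genes = character(0),
                           island_name = character(0), relations = character(0),
                           p_value = numeric(0), direction = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(windows) == 0) {
    return(list(windows = cbind(windows, T2 = numeric(0), F_stat = numeric(0),
                                p_value = numeric(0), deltas = character(0),
                                significant = logical(0)),
                dmrs = empty_dmrs))
  }
  T2 <- F_stat <- p_value <- numeric(nrow(windows))
  deltas_str <- character(nrow(windows))
  significant <- logical(nrow(windows))
  delta_list <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    ids <- elig$probe_id[windows$start_idx[i]:(windows$start_idx[i] + w - 1L)]
    ht <- hotelling_t2(bm$values[ids, , drop = FALSE], bm$groups)
    T2[i] <- ht$T2; F_stat[i] <- ht$F_stat; p_value[i] <- ht$p_value
    delta_list[[i]] <- ht$deltas
    deltas_str[i] <- paste(sprintf("%.6g", ht$deltas), collapse = ";")
    significant[i] <- .window_significant(ht$p_value, ht$deltas, params)
  }
  windows$T2 <- T2; windows$F_stat <- F_stat; windows$p_value <- p_value
  windows$deltas <- deltas_str; windows$significant <- significant

  sig <- windows[windows$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(list(windows = windows, dmrs = empty_dmrs))

  # merge overlapping / touching significant windows within an island unit
  sig <- sig[order(sig$chrom, sig$island_name, sig$start_idx), , drop = FALSE]
  unit <- paste(sig$chrom, sig$island_name, sep = "\r")
  dmr_rows <- list()
  i <- 1L
  while (i <= nrow(sig)) {
    j <- i
    lo <- sig$start_idx[i]; hi <- sig$start_idx[i] + w - 1L
    while (j + 1L <= nrow(sig) && unit[j + 1L] == unit[i] &&
           sig$start_idx[j + 1L] <= hi + 1L) {
      j <- j + 1L
      hi <- max(hi, sig$start_idx[j] + w - 1L)
    }
    member_idx <- lo:hi
    member <- elig[member_idx, , drop = FALSE]
    deltas <- unlist(delta_list[match(
      sig$window_id[i:j], windows$window_id)])
    probe_delta <- stats::setNames(rep(NA_real_, nrow(member)), member$probe_id)
    probe_delta[names(deltas)] <- deltas
    exceeding <- probe_delta[!is.na(probe_delta) &
                               abs(probe_delta) >= params$min_abs_delta]
    direction <- if (length(exceeding) == 0) {
      "MIXED"
    } else if (all(exceeding > 0)) {
      "HYPER"
    } else if (all(exceeding < 0)) {
      "HYPO"
    } else "MIXED"
    dmr_rows[[length(dmr_rows) + 1L]] <- data.frame(
      chrom = member$chrom[1],
      start = min(member$position),
      end = max(member$position),
      n_probes = nrow(member),
      probe_ids = paste(member$probe_id, collapse = ";"),
      genes = paste(sort(unique(unlist(split_genes(member$genes)))),
                    collapse = ";"),
      island_name = member$island_name[1],
      relations = paste(unique(member$relation), collapse = ";"),
      p_value = min(sig$p_value[i:j]),
      direction = direction,
      stringsAsFactors = FALSE
    )
    i <- j + 1L
  }
  dmrs <- do.call(rbind, dmr_rows)
  dmrs <- dmrs[order(dmrs$p_value, dmrs$chrom, dmrs$start), , drop = FALSE]
  rownames(dmrs) <- NULL
  list(windows = windows, dmrs = dmrs)
}
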