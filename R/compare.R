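# Cross-platform / cross-dataset replication of a DMP list: intersect with
# another array's probe universe, re-test in a second two-group dataset and
# count replication at tiered thresholds with direction concordance.

#' Intersect a probe list with an array probe universe
#'
#' Order-preserving: the returned probes keep the input order.
#'
#' @param probe_ids Character vector (e.g. significant DMP probes).
#' @param universe_probe_ids Character vector of probes assayed by the
#'   other platform.
#' @return The subset of `probe_ids` present in the universe.
#' @export
intersect_universe <- function(probe_ids, universe_probe_ids) {
  probe_ids[probe_ids %in% universe_probe_ids]
}

#' Replicate a DMP list in a second dataset
#'
#' Re-tests each probe of `subset_ids` with the two-group ANOVA in a
#' second beta matrix and reports tiered replication counts: strict
#' (`p < p_strict`), loose (`p < p_loose`) and, among the loose-replicated
#' probes, how many change in the same direction as the reference
#' (`sign(delta_second) == sign(reference delta)`). A per-probe
#' case/control within-group variance ratio in the second dataset is
#' reported descriptively (immortalised or otherwise noisier material
#' often shows inflated group variance).
#'
#' @param subset_ids Probe ids to re-test (typically the output of
#'   [intersect_universe()]); probes absent from `other_bm` are dropped
#'   and counted.
#' @param other_bm A [beta_matrix()] for the second dataset (at least 2
#'   samples per group).
#' @param reference_deltas Numeric vector of reference mean differences,
#'   named by probe id, covering `subset_ids`.
#' @param p_strict,p_loose Tier thresholds (defaults 0.001 and 0.05,
#'   strict `<`).
#' @return List of class `replication_report`: counts `n_input`,
#'   `n_in_universe`, `n_replicated_strict`, `n_replicated_loose`,
#'   `n_concordant_direction`, and `probes` (per-probe data frame with
#'   `p_value`, `delta`, `reference_delta`, `concordant`, `var_ratio`).
#' @export
replicate_dmps <- function(subset_ids, other_bm, reference_deltas,
                           p_strict = 0.001, p_loose = 0.05) {
  stopifnot(inherits(other_bm, "beta_matrix"))
  n_input <- length(subset_ids)
  present <- subset_ids %in% rownames(other_bm$values)
  if (any(!present)) {
    message("replicate_dmps: ", sum(!present),
            " probe(s) absent from the second dataset; dropped")
  }
  ids <- subset_ids[present]
  missing_ref <- setdiff(ids, names(reference_deltas))
  if (length(missing_ref) > 0) {
    stop("no reference delta for probe(s): ",
         paste(utils::head(missing_ref, 3), collapse = ", "))
  }
  vals <- other_bm$values[ids, , drop = FALSE]
  complete <- !apply(is.na(vals), 1, any)
  if (any(!complete)) {
    message("replicate_dmps: excluded ", sum(!complete),
            " probe(s) with missing values in the second dataset")
    ids <- ids[complete]
    vals <- vals[complete, , drop = FALSE]
  }
  if (length(ids) == 0) {
    probes <- data.frame(probe_id = character(0), p_value = numeric(0),
                         delta = numeric(0), reference_delta = numeric(0),
                         concordant = logical(0), var_ratio = numeric(0),
                         stringsAsFactors = FALSE)
    out <- list(n_input = n_input, n_in_universe = 0L,
                n_replicated_strict = 0L, n_replicated_loose = 0L,
                n_concordant_direction = 0L, probes = probes)
    class(out) <- "replication_report"
    return(out)
  }
  res <- .row_anova(vals, other_bm$groups)
  case <- vals[, other_bm$groups == "CASE", drop = FALSE]
  ctrl <- vals[, other_bm$groups == "CTRL", drop = FALSE]
  var_case <- apply(case, 1, stats::var)
  var_ctrl <- apply(ctrl, 1, stats::var)
  ref <- reference_deltas[ids]
  probes <- data.frame(probe_id = ids,
                       p_value = res$p_value,
                       delta = res$delta,
                       reference_delta = unname(ref),
                       concordant = sign(res$delta) == sign(ref),
                       var_ratio = ifelse(var_ctrl > 0, var_case / var_ctrl, NA_real_),
                       stringsAsFactors = FALSE, row.names = NULL)
  loose <- probes$p_value < p_loose
  out <- list(
    n_input = n_input,
    n_in_universe = length(ids),
    n_replicated_strict = sum(probes$p_value < p_strict),
    n_replicated_loose = sum(loose),
    n_concordant_direction = sum(loose & probes$concordant),
    probes = probes
  )
  stopifnot(out$n_replicated_strict <= out$n_replicated_loose,
            out$n_replicated_loose <= out$n_in_universe,
            out$n_in_universe <= out$n_input,
            out$n_concordant_direction <= out$n_replicated_loose)
  class(out) <- "replication_report"
  out
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf(paste0("Replication report: %d input probes, %d testable in the ",
                     "second dataset\n  %d at the strict tier, %d at the loose ",
                     "tier (%d direction-concordant)\n"),
              x$n_input, x$n_in_universe, x$n_replicated_strict,
              x$n_replicated_loose, x$n_concordant_direction))
  invisible(x)
}
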