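# Single-config pipeline driver: DMP -> DMR -> enrichment -> differential
# expression -> concordance -> cross-dataset replication, with a run
# manifest recording versions, seed and input checksums.

.default_config <- function() {
  list(
    paths = list(betas = NULL, samples = NULL, manifest = NULL,
                 manifest_dialect = "generic", gmt = NULL,
                 expr = NULL, expr_samples = NULL,
                 universe = NULL, betas2 = NULL, samples2 = NULL),
    thresholds = list(dmp_p = 0.001, dmr_p = 0.001, min_abs_delta = 0.3,
                      effect_threshold = 0.15, enrich_p = 0.05, de_p = 0.05),
    window_size = 3,
    min_adjacent_exceeding = 2,
    seed = 1,
    out_dir = "wsmeth_out"
  )
}

# Deep-merge user config over defaults; unknown keys are a schema error.
.merge_config <- function(user, defaults, prefix = "") {
  for (key in names(user)) {
    path <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("config schema violation: unknown field '", path, "'")
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) {
        stop("config schema violation: field '", path, "' must be a mapping")
      }
      defaults[[key]] <- .merge_config(user[[key]], defaults[[key]], path)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  for (f in c("dmp_p", "dmr_p", "enrich_p", "de_p")) {
    v <- cfg$thresholds[[f]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      stop("config schema violation: field 'thresholds.", f,
           "' must be in (0, 1]")
    }
  }
  if (!is.numeric(cfg$thresholds$min_abs_delta) ||
      cfg$thresholds$min_abs_delta < 0) {
    stop("config schema violation: field 'thresholds.min_abs_delta' must be >= 0")
  }
  if (!is.numeric(cfg$window_size) || cfg$window_size < 2) {
    stop("config schema violation: field 'window_size' must be >= 2")
  }
  for (f in c("betas", "samples", "manifest")) {
    if (is.null(cfg$paths[[f]])) {
      stop("config schema violation: required field 'paths.", f, "' is missing")
    }
    if (!file.exists(cfg$paths[[f]])) {
      stop("config schema violation: field 'paths.", f, "' points to a ",
           "missing file: ", cfg$paths[[f]])
    }
  }
  invisible(cfg)
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML mapping with blocks `paths` (betas,
#' samples, manifest, optional manifest_dialect/gmt/expr/expr_samples/
#' universe/betas2/samples2), `thresholds` (dmp_p, dmr_p, min_abs_delta,
#' effect_threshold, enrich_p, de_p), plus `window_size`,
#' `min_adjacent_exceeding`, `seed` and `out_dir`. Unset fields take the
#' documented defaults; unknown fields are a fatal schema error naming the
#' field path.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The validated, default-completed config list.
#' @export
load_config <- function(config) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a file path or a list")
  }
  cfg <- .merge_config(user, .default_config())
  .validate_config(cfg)
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes, in order: DMP calling (with summary, volcano table and sample
#' PCA), DMR calling (windows, merged regions, BED export), gene-set
#' enrichment of the hyper- and hypomethylated DMP gene lists and of the
#' DMR gene list (if a GMT library is configured), differential expression
#' and the methylation-expression concordance join (if an expression
#' matrix is configured), and cross-dataset replication (if a probe
#' universe and second dataset are configured). Optional stages whose
#' inputs are absent are skipped with a logged notice. Any stage failure
#' aborts with the stage name.
#'
#' All tables are written under `out_dir` together with
#' `run_manifest.json` (package and R versions, seed, thresholds, input
#' MD5 checksums), which is sufficient to reproduce every output
#' byte-identically.
#'
#' @param config Path to a YAML config or an equivalent list (see
#'   [load_config()]).
#' @return Invisibly, a list with the stage results and the vector of
#'   written file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_paths <- character(0)
  emit <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    write_table(x, p)
    out_paths[[name]] <<- p
    p
  }
  results <- list()

  inputs <- .run_stage("load", {
    list(manifest = read_manifest(cfg$paths$manifest,
                                  dialect = cfg$paths$manifest_dialect),
         betas = read_beta_matrix(cfg$paths$betas, cfg$paths$samples))
  })

  results$dmp <- .run_stage("dmp", {
    dmps <- call_dmps(inputs$betas, inputs$manifest,
                      p_threshold = cfg$thresholds$dmp_p)
    summ <- summarize_dmps(dmps, cfg$thresholds$dmp_p,
                           cfg$thresholds$effect_threshold)
    emit(dmps, "dmps.tsv")
    emit(volcano_table(dmps), "volcano.tsv")
    n_samp <- ncol(inputs$betas$values)
    pca <- sample_pca(inputs$betas, n_components = min(2, n_samp - 1))
    emit(data.frame(sample_id = rownames(pca$scores), pca$scores,
                    group = unname(pca$groups[rownames(pca$scores)]),
                    check.names = FALSE), "pca.tsv")
    jsonlite::write_json(unclass(summ),
                         file.path(cfg$out_dir, "dmp_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out_paths[["dmp_summary.json"]] <- file.path(cfg$out_dir, "dmp_summary.json")
    list(dmps = dmps, summary = summ, pca = pca)
  })

  results$dmr <- .run_stage("dmr", {
    params <- dmr_params(window_size = cfg$window_size,
                         p_threshold = cfg$thresholds$dmr_p,
                         min_abs_delta = cfg$thresholds$min_abs_delta,
                         min_adjacent_exceeding = cfg$min_adjacent_exceeding)
    res <- call_dmrs(inputs$betas, inputs$manifest, params)
    emit(res$windows, "windows.tsv")
    emit(res$dmrs, "dmrs.tsv")
    write_dmr_bed(res$dmrs, file.path(cfg$out_dir, "dmrs.bed"))
    out_paths[["dmrs.bed"]] <- file.path(cfg$out_dir, "dmrs.bed")
    res
  })

  meth_gene_dirs <- local({
    sig <- results$dmp$dmps[results$dmp$dmps$significant, , drop = FALSE]
    g <- split_genes(sig$genes)
    data.frame(gene = unlist(g) %||% character(0),
               direction = rep(sig$direction, lengths(g)) %||% character(0),
               stringsAsFactors = FALSE)
  })

  if (!is.null(cfg$paths$gmt)) {
    results$enrich <- .run_stage("enrich", {
      gsl <- read_gmt(cfg$paths$gmt)
      lists <- list(
        hyper = unique(meth_gene_dirs$gene[meth_gene_dirs$direction == "HYPER"]),
        hypo = unique(meth_gene_dirs$gene[meth_gene_dirs$direction == "HYPO"]),
        dmr = unique(unlist(split_genes(results$dmr$dmrs$genes))))
      res <- lapply(names(lists), function(nm) {
        er <- enrich(lists[[nm]], gsl, p_cut = cfg$thresholds$enrich_p,
                     seed = cfg$seed)
        emit(er, paste0("enrich_", nm, ".tsv"))
        er
      })
      stats::setNames(res, names(lists))
    })
  } else {
    message("run_pipeline: no GMT library configured; enrichment skipped")
  }

  if (!is.null(cfg$paths$expr)) {
    results$de <- .run_stage("de", {
      expr_sheet <- cfg$paths$expr_samples %||% cfg$paths$samples
      em <- read_expression_matrix(cfg$paths$expr, expr_sheet)
      # test the genes highlighted by enrichment when available, else all
      # differentially methylated genes
      genes <- if (!is.null(results$enrich)) {
        unique(unlist(lapply(results$enrich, function(er) {
          unlist(split_genes(er$overlapping_genes))
        })))
      } else {
        unique(meth_gene_dirs$gene)
      }
      de <- call_de(em, genes = genes)
      emit(de, "de.tsv")
      concord <- concordance_table(meth_gene_dirs, de,
                                   de_p = cfg$thresholds$de_p)
      emit(concord, "concord.tsv")
      list(de = de, concordance = concord)
    })
  } else {
    message("run_pipeline: no expression matrix configured; DE/concordance skipped")
  }

  if (!is.null(cfg$paths$universe) && !is.null(cfg$paths$betas2) &&
      !is.null(cfg$paths$samples2)) {
    results$compare <- .run_stage("compare", {
      universe <- read_probe_universe(cfg$paths$universe)
      bm2 <- read_beta_matrix(cfg$paths$betas2, cfg$paths$samples2)
      sig <- results$dmp$dmps[results$dmp$dmps$significant, , drop = FALSE]
      subset_ids <- intersect_universe(sig$probe_id, universe)
      rep <- replicate_dmps(subset_ids, bm2,
                            stats::setNames(sig$delta, sig$probe_id))
      emit(rep$probes, "replication.tsv")
      jsonlite::write_json(rep[c("n_input", "n_in_universe",
                                 "n_replicated_strict", "n_replicated_loose",
                                 "n_concordant_direction")],
                           file.path(cfg$out_dir, "replication_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      out_paths[["replication_summary.json"]] <-
        file.path(cfg$out_dir, "replication_summary.json")
      rep
    })
  } else {
    message("run_pipeline: no probe universe / second dataset configured; ",
            "replication skipped")
  }

  input_files <- unlist(Filter(Negate(is.null),
                               cfg$paths[setdiff(names(cfg$paths),
                                                 "manifest_dialect")]))
  manifest <- list(
    package = "wsmeth",
    package_version = as.character(utils::packageVersion("wsmeth")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    thresholds = cfg$thresholds,
    window_size = cfg$window_size,
    min_adjacent_exceeding = cfg$min_adjacent_exceeding,
    input_md5 = as.list(tools::md5sum(input_files))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out_paths[["run_manifest.json"]] <- file.path(cfg$out_dir, "run_manifest.json")

  invisible(list(config = cfg, results = results, paths = out_paths))
}
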