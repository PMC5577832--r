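# Synthetic-data generator. Emulates the statistical structure the analysis
# assumes: an island-clustered probe manifest with shore/shelf flanks and
# gene annotations, two-group beta matrices whose per-probe baselines follow
# the characteristic bimodal (mostly-unmethylated / mostly-methylated)
# distribution, spiked single-probe and regional effects with a ground-truth
# registry, and a matched log2 expression matrix with direction-aware
# differential-expression spikes. Every randomised operation takes an
# explicit seed and leaves global RNG state untouched.

# relation layout of one island block, by probe count
.island_relations <- function(k) {
  if (k >= 5) c("N_Shelf", "N_Shore", rep("Island", k - 4), "S_Shore", "S_Shelf")
  else if (k == 4) c("N_Shore", "Island", "Island", "S_Shore")
  else if (k == 3) c("N_Shore", "Island", "S_Shore")
  else rep("Island", k)
}

#' Generate a synthetic probe-annotation manifest
#'
#' Islands are laid consecutively along synthetic chromosomes; each island
#' block carries shore/shelf flanks assigned positionally and all its
#' probes share one island name (`"chrN:start-end"` over the island core).
#' Each island draws 1–2 gene symbols from a pool and a fraction
#' `annotated_frac` of its probes carry them; open-sea probes (no island,
#' relation `OpenSea`) are interleaved between blocks and carry a gene
#' with probability 0.5.
#'
#' @param n_islands Number of CpG-island blocks.
#' @param probes_per_island Probes per block (island core plus flanks).
#' @param n_opensea Open-sea probes interleaved between blocks.
#' @param gene_pool_size Size of the gene-symbol pool.
#' @param annotated_frac Fraction of island-block probes carrying the
#'   island's gene annotation (default 0.9).
#' @param n_chrom Number of chromosomes to spread blocks over (default:
#'   up to 4).
#' @param seed RNG seed.
#' @return A `probe_annotation` data frame (see [read_manifest()]).
#' @export
generate_manifest <- function(n_islands, probes_per_island, n_opensea = 0,
                              gene_pool_size = 100, annotated_frac = 0.9,
                              n_chrom = NULL, seed = NULL) {
  stopifnot(n_islands >= 0, probes_per_island >= 0, n_opensea >= 0,
            gene_pool_size >= 1, annotated_frac >= 0, annotated_frac <= 1)
  gene_pool <- sprintf("SYNG%04d", seq_len(gene_pool_size))
  n_chrom <- n_chrom %||% max(1L, min(4L, max(n_islands, 1L)))
  with_local_seed(seed, {
    k <- probes_per_island
    islands_per_chrom <- if (n_islands > 0) ceiling(n_islands / n_chrom) else 1L
    # spread open-sea probes evenly over the gaps before each island block
    os_share <- if (n_islands > 0) {
      diff(floor(seq(0, n_opensea, length.out = n_islands + 1)))
    } else c(n_opensea)
    n_slots <- length(os_share)
    slot_chrom <- if (n_islands > 0) {
      paste0("chr", (seq_len(n_islands) - 1L) %/% islands_per_chrom + 1L)
    } else "chr1"
    # walk the layout once with scalar cursors, then expand vectorised
    cursor <- stats::setNames(rep(1e6, n_chrom), paste0("chr", seq_len(n_chrom)))
    os_start <- numeric(n_slots)
    isl_start <- numeric(n_islands)
    for (i in seq_len(n_slots)) {
      ch <- slot_chrom[i]
      os_start[i] <- cursor[ch]
      cursor[ch] <- cursor[ch] + 5000 * os_share[i] + 20000
      if (i <= n_islands && k > 0) {
        isl_start[i] <- cursor[ch]
        cursor[ch] <- cursor[ch] + 150 * k + 20000
      }
    }
    # open-sea probes
    os_chrom <- rep(slot_chrom, os_share)
    os_pos <- as.integer(unlist(lapply(seq_len(n_slots), function(i) {
      if (os_share[i] == 0) return(integer(0))
      os_start[i] + 5000 * (seq_len(os_share[i]) - 1)
    })) %||% integer(0))
    n_os <- length(os_chrom)
    os_genes <- ifelse(stats::runif(n_os) < 0.5,
                       sample(gene_pool, n_os, replace = TRUE), "")
    # island-block probes
    if (n_islands > 0 && k > 0) {
      rel <- .island_relations(k)
      core <- which(rel == "Island")
      core_lo <- if (length(core)) min(core) else 1L
      core_hi <- if (length(core)) max(core) else k
      isl_chrom <- rep(slot_chrom[seq_len(n_islands)], each = k)
      isl_pos <- as.integer(rep(isl_start, each = k) + 150 * (seq_len(k) - 1L))
      island_name <- sprintf("%s:%d-%d", slot_chrom[seq_len(n_islands)],
                             as.integer(isl_start + 150 * (core_lo - 1L)),
                             as.integer(isl_start + 150 * (core_hi - 1L)))
      two_genes <- stats::runif(n_islands) >= 0.8
      g1 <- sample(gene_pool, n_islands, replace = TRUE)
      g2 <- sample(gene_pool, n_islands, replace = TRUE)
      island_genes <- ifelse(two_genes & g1 != g2,
                             paste(pmin(g1, g2), pmax(g1, g2), sep = ";"), g1)
      annotated <- stats::runif(n_islands * k) < annotated_frac
      isl_genes <- ifelse(annotated, rep(island_genes, each = k), "")
      isl_df <- data.frame(chrom = isl_chrom, position = isl_pos,
                           genes = isl_genes,
                           island_name = rep(island_name, each = k),
                           relation = rep(rel, n_islands),
                           stringsAsFactors = FALSE)
    } else {
      isl_df <- NULL
    }
    os_df <- if (n_os > 0) {
      data.frame(chrom = os_chrom, position = os_pos, genes = os_genes,
                 island_name = "", relation = "OpenSea",
                 stringsAsFactors = FALSE)
    } else NULL
    ann <- rbind(os_df, isl_df) %||% data.frame(
      chrom = character(0), position = integer(0), genes = character(0),
      island_name = character(0), relation = character(0),
      stringsAsFactors = FALSE)
    ann <- data.frame(probe_id = sprintf("cg%08d", seq_len(nrow(ann))), ann,
                      stringsAsFactors = FALSE)
    ann <- ann[order(ann$chrom, ann$position, ann$probe_id), , drop = FALSE]
    rownames(ann) <- NULL
    class(ann) <- c("probe_annotation", "data.frame")
    ann
  })
}

# Maximal runs of >= run_length consecutive eligible probes per island unit.
# Returns a data.frame of candidate spike sites (unit key, start index into
# the eligible table, run length).
.dmr_spike_sites <- function(elig, run_length) {
  if (nrow(elig) == 0) return(NULL)
  unit <- paste(elig$chrom, elig$island_name, sep = "\r")
  runs <- rle(unit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- runs$lengths >= run_length & vapply(
    starts, function(s) nzchar(elig$island_name[s]), logical(1))
  if (!any(ok)) return(NULL)
  data.frame(island_name = elig$island_name[starts[ok]],
             chrom = elig$chrom[starts[ok]],
             start = starts[ok], length = runs$lengths[ok],
             stringsAsFactors = FALSE)
}

#' Generate a two-group beta matrix with spiked effects
#'
#' Per-probe baseline means are drawn from a bimodal mixture (half
#' `Beta(1.5, 10)`, mostly unmethylated; half `Beta(10, 1.5)`, mostly
#' methylated). Sample values are `baseline + group effect + N(0, within_sd)`
#' clipped to \[0, 1\]; the CASE group carries the spiked effect, so a
#' positive delta means hypermethylated in cases. Spiked probes get their
#' baseline redrawn uniformly inside the range that keeps both group means
#' in \[0.05, 0.95\], so the requested delta is not attenuated by clipping.
#'
#' Single-probe (DMP) spikes are placed on probes outside spiked islands;
#' regional (DMR) spikes shift `run_length` consecutive region-eligible
#' probes of one island unit by a common delta. All injected effects are
#' recorded in the returned ground-truth registry.
#'
#' Two noise models are available. `"gaussian"` (the default) adds
#' homoscedastic `N(0, within_sd)` noise and clips to \[0, 1\].
#' `"beta"` draws each value from `Beta(m*c, (1-m)*c)` around the probe's
#' group mean `m` with concentration `c = concentration`, giving the
#' heteroscedastic, boundary-respecting noise real beta values show
#' (variance shrinks near 0 and 1, no clipping); it is the model used for
#' null-calibration scenes, where the homoscedastic clipped model would
#' mildly violate the variance assumptions of the downstream F tests at
#' boundary probes. Baseline means are kept in \[0.03, 0.97\].
#'
#' @param manifest A `probe_annotation` data frame.
#' @param n_case,n_ctrl Samples per group (default 3 and 3).
#' @param within_sd Within-group Gaussian noise sd on the beta scale
#'   (default 0.03; `"gaussian"` model only).
#' @param noise_model `"gaussian"` or `"beta"`.
#' @param concentration Beta noise concentration `c` (default 150, giving
#'   sd about 0.04 at mid-methylation; `"beta"` model only).
#' @param dmp_spikes List `(n, delta_range)`: number of single-probe
#'   spikes and the |delta| range (default 20 spikes in 0.15–0.45).
#' @param dmr_spikes List `(n, delta, run_length)`: number of spiked
#'   islands, |delta| (>= 0.3 to be recoverable at the default region
#'   filter) and run length (default 5 islands, 0.35, 3 probes).
#' @param seed RNG seed.
#' @return List with `betas` (a [beta_matrix()]) and `truth` (class
#'   `synthetic_truth`: `spiked_dmp_probes` — data frame `probe_id,
#'   gene, delta`; `spiked_dmr_islands` — data frame `island_name, chrom,
#'   probe_ids, genes, delta`; `spiked_de_genes`; `seed`).
#' @export
generate_betas <- function(manifest, n_case = 3, n_ctrl = 3, within_sd = 0.03,
                           dmp_spikes = list(n = 20, delta_range = c(0.15, 0.45)),
                           dmr_spikes = list(n = 5, delta = 0.35, run_length = 3),
                           noise_model = c("gaussian", "beta"),
                           concentration = 150, seed = NULL) {
  stopifnot(inherits(manifest, "data.frame"), n_case >= 2, n_ctrl >= 2)
  noise_model <- match.arg(noise_model)
  n_dmp <- dmp_spikes$n %||% 0L
  n_dmr <- dmr_spikes$n %||% 0L
  dmr_delta <- dmr_spikes$delta %||% 0.35
  run_length <- dmr_spikes$run_length %||% 3L
  if (n_dmr > 0 && abs(dmr_delta) < 0) stop("dmr delta must be non-negative")
  p <- nrow(manifest)
  with_local_seed(seed, {
    comp <- stats::runif(p) < 0.5
    baseline <- ifelse(comp, stats::rbeta(p, 1.5, 10), stats::rbeta(p, 10, 1.5))
    baseline <- pmin(pmax(baseline, 0.03), 0.97)
    effect <- numeric(p)
    names(effect) <- manifest$probe_id
    names(baseline) <- manifest$probe_id

    # regional spikes on runs of eligible probes within one island unit
    dmr_truth <- NULL
    spiked_island_names <- character(0)
    if (n_dmr > 0) {
      elig <- eligible_probes(manifest)
      sites <- .dmr_spike_sites(elig, run_length)
      if (is.null(sites) || nrow(sites) < n_dmr) {
        stop("infeasible DMR spike request: need ", n_dmr, " island(s) with >= ",
             run_length, " consecutive eligible probes, found ",
             if (is.null(sites)) 0 else nrow(sites))
      }
      pick <- sites[sample.int(nrow(sites), n_dmr), , drop = FALSE]
      dmr_rows <- list()
      for (i in seq_len(n_dmr)) {
        offset <- sample.int(pick$length[i] - run_length + 1L, 1) - 1L
        ids <- elig$probe_id[(pick$start[i] + offset):
                               (pick$start[i] + offset + run_length - 1L)]
        d <- sample(c(-1, 1), 1) * abs(dmr_delta)
        effect[ids] <- d
        genes <- sort(unique(unlist(split_genes(
          elig$genes[elig$probe_id %in% ids]))))
        dmr_rows[[i]] <- data.frame(island_name = pick$island_name[i],
                                    chrom = pick$chrom[i],
                                    probe_ids = paste(ids, collapse = ";"),
                                    genes = paste(genes, collapse = ";"),
                                    delta = d, stringsAsFactors = FALSE)
      }
      dmr_truth <- do.call(rbind, dmr_rows)
      spiked_island_names <- dmr_truth$island_name
    }

    # single-probe spikes outside spiked islands
    dmp_truth <- NULL
    if (n_dmp > 0) {
      candidates <- which(!(manifest$island_name %in% spiked_island_names) &
                            effect == 0)
      if (length(candidates) < n_dmp) {
        stop("infeasible DMP spike request: ", n_dmp, " spikes but only ",
             length(candidates), " candidate probes")
      }
      idx <- sample(candidates, n_dmp)
      rng <- dmp_spikes$delta_range %||% c(0.15, 0.45)
      d <- sample(c(-1, 1), n_dmp, replace = TRUE) *
        stats::runif(n_dmp, rng[1], rng[2])
      effect[idx] <- d
      dmp_truth <- data.frame(probe_id = manifest$probe_id[idx],
                              gene = manifest$genes[idx],
                              delta = d, stringsAsFactors = FALSE)
    }

    # keep spiked group means clear of the [0,1] boundary
    spiked <- which(effect != 0)
    for (i in spiked) {
      d <- effect[i]
      lo <- 0.05 + max(0, -d)
      hi <- 0.95 - max(0, d)
      baseline[i] <- stats::runif(1, lo, hi)
    }

    sample_ids <- c(paste0("case_", seq_len(n_case)),
                    paste0("ctrl_", seq_len(n_ctrl)))
    groups <- stats::setNames(rep(c("CASE", "CTRL"), c(n_case, n_ctrl)),
                              sample_ids)
    mean_mat <- outer(baseline, rep(1, n_case + n_ctrl)) +
      outer(effect, as.numeric(groups == "CASE"))
    if (noise_model == "gaussian") {
      vals <- mean_mat + matrix(stats::rnorm(p * (n_case + n_ctrl), 0, within_sd),
                                nrow = p)
      vals <- pmin(pmax(vals, 0), 1)
    } else {
      m <- pmin(pmax(mean_mat, 0.01), 0.99)
      vals <- matrix(stats::rbeta(length(m), m * concentration,
                                  (1 - m) * concentration), nrow = p)
    }
    dimnames(vals) <- list(manifest$probe_id, sample_ids)

    empty_dmp <- data.frame(probe_id = character(0), gene = character(0),
                            delta = numeric(0), stringsAsFactors = FALSE)
    empty_dmr <- data.frame(island_name = character(0), chrom = character(0),
                            probe_ids = character(0), genes = character(0),
                            delta = numeric(0), stringsAsFactors = FALSE)
    truth <- structure(list(
      spiked_dmp_probes = dmp_truth %||% empty_dmp,
      spiked_dmr_islands = dmr_truth %||% empty_dmr,
      spiked_de_genes = data.frame(gene = character(0), log2_fc = numeric(0),
                                   stringsAsFactors = FALSE),
      seed = seed), class = "synthetic_truth")
    list(betas = beta_matrix(vals, groups), truth = truth)
  })
}

#' Generate a two-group log2 expression matrix
#'
#' Baseline log2 intensities per gene are uniform in \[6, 10\] with
#' `N(0, noise_sd)` sample noise. Spiked genes are shifted in the CASE
#' group by their log2 fold change. When a methylation ground truth is
#' supplied, the spiked genes are the genes of the spiked methylation
#' effects and each gene's expression direction agrees with the canonical
#' repressive pairing (hypermethylated -> down-regulated) with probability
#' `concordance_fraction`, else opposes it.
#'
#' @param gene_pool Character vector of gene symbols (matrix rows).
#' @param n_case,n_ctrl Samples per group (default 10 and 10).
#' @param de_spikes List `(genes, log2_fc)` of extra spiked genes;
#'   `log2_fc` is recycled (default magnitude 1).
#' @param noise_sd Sample noise sd on the log2 scale (default 0.25).
#' @param concordance_with Optional `synthetic_truth` from
#'   [generate_betas()].
#' @param concordance_fraction Probability a methylation-linked spike is
#'   direction-concordant (default 1).
#' @param seed RNG seed.
#' @return List with `expr` (an `expression_matrix`) and `truth` (the
#'   input truth, or a fresh one, with `spiked_de_genes` filled:
#'   `gene, log2_fc`).
#' @export
generate_expression <- function(gene_pool, n_case = 10, n_ctrl = 10,
                                de_spikes = NULL, noise_sd = 0.25,
                                concordance_with = NULL,
                                concordance_fraction = 1, seed = NULL) {
  gene_pool <- unique(toupper(gene_pool))
  g <- length(gene_pool)
  stopifnot(g > 0, n_case >= 2, n_ctrl >= 2)
  with_local_seed(seed, {
    shift <- stats::setNames(numeric(g), gene_pool)
    de_rows <- list()
    if (!is.null(concordance_with)) {
      stopifnot(inherits(concordance_with, "synthetic_truth"))
      meth_genes <- rbind(
        data.frame(gene = unlist(split_genes(
          concordance_with$spiked_dmp_probes$gene)) %||% character(0),
          delta = rep(concordance_with$spiked_dmp_probes$delta,
                      lengths(split_genes(concordance_with$spiked_dmp_probes$gene)))),
        data.frame(gene = unlist(split_genes(
          concordance_with$spiked_dmr_islands$genes)) %||% character(0),
          delta = rep(concordance_with$spiked_dmr_islands$delta,
                      lengths(split_genes(concordance_with$spiked_dmr_islands$genes)))))
      meth_genes <- meth_genes[!duplicated(meth_genes$gene) &
                                 meth_genes$gene %in% gene_pool, , drop = FALSE]
      mag <- abs(de_spikes$log2_fc %||% 1)
      for (i in seq_len(nrow(meth_genes))) {
        concordant <- stats::runif(1) < concordance_fraction
        # repressive pairing: hypermethylated (delta>0) -> down-regulated
        dir <- if (xor(meth_genes$delta[i] > 0, concordant)) 1 else -1
        fc <- dir * mag[((i - 1) %% length(mag)) + 1]
        shift[meth_genes$gene[i]] <- fc
        de_rows[[length(de_rows) + 1L]] <-
          data.frame(gene = meth_genes$gene[i], log2_fc = fc,
                     stringsAsFactors = FALSE)
      }
    }
    if (!is.null(de_spikes$genes)) {
      extra <- setdiff(toupper(de_spikes$genes), vapply(de_rows, `[[`,
                                                        character(1), "gene"))
      extra <- intersect(extra, gene_pool)
      fcs <- rep(de_spikes$log2_fc %||% 1, length.out = length(extra))
      for (i in seq_along(extra)) {
        shift[extra[i]] <- fcs[i]
        de_rows[[length(de_rows) + 1L]] <-
          data.frame(gene = extra[i], log2_fc = fcs[i], stringsAsFactors = FALSE)
      }
    }
    sample_ids <- c(paste0("case_", seq_len(n_case)),
                    paste0("ctrl_", seq_len(n_ctrl)))
    groups <- stats::setNames(rep(c("CASE", "CTRL"), c(n_case, n_ctrl)),
                              sample_ids)
    baseline <- stats::runif(g, 6, 10)
    vals <- outer(baseline, rep(1, n_case + n_ctrl)) +
      outer(shift, as.numeric(groups == "CASE")) +
      matrix(stats::rnorm(g * (n_case + n_ctrl), 0, noise_sd), nrow = g)
    dimnames(vals) <- list(gene_pool, sample_ids)
    de_truth <- do.call(rbind, de_rows) %||%
      data.frame(gene = character(0), log2_fc = numeric(0),
                 stringsAsFactors = FALSE)
    truth <- concordance_with %||%
      structure(list(spiked_dmp_probes = data.frame(),
                     spiked_dmr_islands = data.frame(),
                     spiked_de_genes = de_truth, seed = seed),
                class = "synthetic_truth")
    truth$spiked_de_genes <- de_truth
    list(expr = structure(list(values = vals, groups = groups),
                          class = "expression_matrix"),
         truth = truth)
  })
}

#' Generate a complete synthetic scene
#'
#' Bundles a manifest, beta matrix, ground truth and matched expression
#' matrix. The `"paperlike"` preset emulates a small EPIC whole-blood
#' study: 50 islands of 6 probes plus 100 open-sea probes, 3 cases vs 3
#' controls, 20 spiked single-probe effects (|delta| 0.15–0.45), 5 spiked
#' 3-probe regions at |delta| 0.35, within-group sd 0.03, and a 10 vs 10
#' log2 expression matrix whose spiked genes follow the methylation truth
#' with concordance fraction 0.75. The `"null"` preset is the identical
#' scene with no spikes.
#'
#' @param preset `"paperlike"` or `"null"`.
#' @param seed RNG seed (sub-seeds are derived per stage).
#' @return List of class `synthetic_scene` with `manifest`, `betas`,
#'   `expr`, `truth`, `preset`, `seed`.
#' @export
synthetic_scene <- function(preset = c("paperlike", "null"), seed = 1) {
  preset <- match.arg(preset)
  manifest <- generate_manifest(n_islands = 50, probes_per_island = 6,
                                n_opensea = 100, gene_pool_size = 120,
                                annotated_frac = 0.9, seed = seed)
  spikes <- if (preset == "paperlike") {
    list(dmp = list(n = 20, delta_range = c(0.15, 0.45)),
         dmr = list(n = 5, delta = 0.35, run_length = 3))
  } else {
    list(dmp = list(n = 0), dmr = list(n = 0))
  }
  gb <- generate_betas(manifest, n_case = 3, n_ctrl = 3, within_sd = 0.03,
                       dmp_spikes = spikes$dmp, dmr_spikes = spikes$dmr,
                       seed = seed + 1)
  pool <- sort(unique(unlist(split_genes(manifest$genes))))
  ge <- generate_expression(pool, n_case = 10, n_ctrl = 10,
                            noise_sd = 0.25, concordance_with = gb$truth,
                            concordance_fraction = 0.75, seed = seed + 2)
  structure(list(manifest = manifest, betas = gb$betas, expr = ge$expr,
                 truth = ge$truth, preset = preset, seed = seed),
            class = "synthetic_scene")
}

#' Write a synthetic scene to disk
#'
#' Emits `manifest.tsv`, `betas.tsv`, `samples.tsv`, `expr.tsv`,
#' `expr_samples.tsv` and `truth.json` under `dir`.
#'
#' @param scene A [synthetic_scene()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(manifest = file.path(dir, "manifest.tsv"),
             betas = file.path(dir, "betas.tsv"),
             samples = file.path(dir, "samples.tsv"),
             expr = file.path(dir, "expr.tsv"),
             expr_samples = file.path(dir, "expr_samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_manifest(scene$manifest, paths["manifest"])
  write_beta_matrix(scene$betas, paths["betas"], paths["samples"])
  write_expression_matrix(scene$expr, paths["expr"])
  write_table(data.frame(sample_id = names(scene$expr$groups),
                         group = unname(scene$expr$groups)),
              paths["expr_samples"])
  jsonlite::write_json(list(
    preset = scene$preset, seed = scene$seed,
    spiked_dmp_probes = scene$truth$spiked_dmp_probes,
    spiked_dmr_islands = scene$truth$spiked_dmr_islands,
    spiked_de_genes = scene$truth$spiked_de_genes),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
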