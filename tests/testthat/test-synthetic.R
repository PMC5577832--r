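# The synthetic-data generator: manifest layout, spiked beta matrices with
# an exact ground-truth registry, matched expression, and scene presets.

test_that("generated manifests have the requested layout and are deterministic", {
  man <- generate_manifest(n_islands = 2, probes_per_island = 5, n_opensea = 3,
                           gene_pool_size = 10, seed = 42)
  expect_equal(nrow(man), 13)
  expect_equal(length(unique(man$island_name[nzchar(man$island_name)])), 2)
  expect_equal(sum(man$relation == "OpenSea"), 3)
  expect_false(anyDuplicated(man$probe_id) > 0)
  # positions strictly increasing within each chromosome
  for (ch in unique(man$chrom)) {
    expect_true(all(diff(man$position[man$chrom == ch]) > 0))
  }
  # island/relation invariant
  expect_true(all((man$relation == "OpenSea") == (man$island_name == "")))
  # 5-probe blocks carry shelf/shore flanks positionally
  one <- man[man$island_name == man$island_name[nzchar(man$island_name)][1], ]
  expect_equal(one$relation[order(one$position)],
               c("N_Shelf", "N_Shore", "Island", "S_Shore", "S_Shelf"))

  man2 <- generate_manifest(n_islands = 2, probes_per_island = 5, n_opensea = 3,
                            gene_pool_size = 10, seed = 42)
  expect_identical(man, man2)
})

test_that("spiked beta matrices honour the truth registry exactly", {
  man <- generate_manifest(n_islands = 10, probes_per_island = 6,
                           n_opensea = 20, gene_pool_size = 30,
                           annotated_frac = 1, seed = 1)
  gb <- generate_betas(man, within_sd = 1e-4,
                       dmp_spikes = list(n = 5, delta_range = c(0.2, 0.4)),
                       dmr_spikes = list(n = 2, delta = 0.35, run_length = 3),
                       seed = 2)
  bm <- gb$betas; truth <- gb$truth
  expect_true(all(bm$values >= 0 & bm$values <= 1))
  expect_equal(nrow(truth$spiked_dmp_probes), 5)
  expect_equal(nrow(truth$spiked_dmr_islands), 2)
  # with negligible noise the observed group-mean difference is the truth delta
  case <- bm$values[, bm$groups == "CASE"]; ctrl <- bm$values[, bm$groups == "CTRL"]
  obs_delta <- rowMeans(case) - rowMeans(ctrl)
  expect_equal(unname(obs_delta[truth$spiked_dmp_probes$probe_id]),
               truth$spiked_dmp_probes$delta, tolerance = 1e-3)
  for (i in seq_len(nrow(truth$spiked_dmr_islands))) {
    ids <- strsplit(truth$spiked_dmr_islands$probe_ids[i], ";")[[1]]
    expect_equal(length(ids), 3)
    expect_equal(unname(obs_delta[ids]),
                 rep(truth$spiked_dmr_islands$delta[i], 3), tolerance = 1e-3)
    # spiked run lies inside one island unit
    expect_equal(unique(man$island_name[man$probe_id %in% ids]),
                 truth$spiked_dmr_islands$island_name[i])
  }
  # spiked sets are disjoint: no DMP spike inside a spiked island
  expect_false(any(man$island_name[man$probe_id %in%
                                     truth$spiked_dmp_probes$probe_id] %in%
                     truth$spiked_dmr_islands$island_name))
  # everything not spiked is null
  spiked_ids <- c(truth$spiked_dmp_probes$probe_id,
                  unlist(strsplit(truth$spiked_dmr_islands$probe_ids, ";")))
  expect_true(max(abs(obs_delta[setdiff(man$probe_id, spiked_ids)])) < 0.01)
})

test_that("zero-spike requests give empty truth and seeded reproducibility holds", {
  man <- generate_manifest(5, 4, 5, 10, seed = 3)
  g1 <- generate_betas(man, dmp_spikes = list(n = 0), dmr_spikes = list(n = 0),
                       seed = 4)
  expect_equal(nrow(g1$truth$spiked_dmp_probes), 0)
  expect_equal(nrow(g1$truth$spiked_dmr_islands), 0)
  g2 <- generate_betas(man, dmp_spikes = list(n = 0), dmr_spikes = list(n = 0),
                       seed = 4)
  expect_identical(g1$betas$values, g2$betas$values)
  # infeasible regional spike request errors
  expect_error(generate_betas(man, dmr_spikes = list(n = 50, delta = 0.35,
                                                     run_length = 3), seed = 5),
               "infeasible")
})

test_that("the beta noise model respects bounds without clipping artefacts", {
  man <- generate_manifest(0, 0, 500, 10, seed = 6)
  gb <- generate_betas(man, dmp_spikes = list(n = 0), dmr_spikes = list(n = 0),
                       noise_model = "beta", seed = 7)
  v <- gb$betas$values
  expect_true(all(v > 0 & v < 1))
  expect_equal(sum(v == 0 | v == 1), 0)
})

test_that("expression spikes follow the methylation truth directionally", {
  man <- generate_manifest(10, 6, 0, 30, annotated_frac = 1, seed = 8)
  gb <- generate_betas(man, dmp_spikes = list(n = 6, delta_range = c(0.3, 0.4)),
                       dmr_spikes = list(n = 2, delta = 0.35, run_length = 3),
                       seed = 9)
  pool <- unique(unlist(strsplit(man$genes[nzchar(man$genes)], ";")))
  # zero noise and full concordance: fold changes are exact and repressive
  ge <- generate_expression(pool, noise_sd = 0, concordance_with = gb$truth,
                            concordance_fraction = 1, seed = 10)
  expect_gt(nrow(ge$truth$spiked_de_genes), 0)
  de <- call_de(ge$expr, genes = ge$truth$spiked_de_genes$gene, scale = "log2")
  expect_equal(sort(de$gene), sort(ge$truth$spiked_de_genes$gene))
  expect_equal(de$fold_change[match(ge$truth$spiked_de_genes$gene, de$gene)],
               2^ge$truth$spiked_de_genes$log2_fc, tolerance = 1e-9)
  meth <- data.frame(
    gene = ge$truth$spiked_de_genes$gene,
    direction = ifelse(2^ge$truth$spiked_de_genes$log2_fc > 1, "HYPO", "HYPER"))
  ct <- concordance_table(meth, de)
  expect_true(all(ct$concordant))
  # an explicit unit log2 shift doubles expression exactly at zero noise
  ge2 <- generate_expression(c("GA", "GB"), noise_sd = 0,
                             de_spikes = list(genes = "GA", log2_fc = 1),
                             seed = 11)
  de2 <- call_de(ge2$expr, scale = "log2")
  expect_equal(de2$fold_change[de2$gene == "GA"], 2, tolerance = 1e-12)
  expect_equal(de2$fold_change[de2$gene == "GB"], 1, tolerance = 1e-12)
})

test_that("scene presets bundle matched inputs and a recoverable truth", {
  sc <- synthetic_scene("paperlike", seed = 123)
  expect_equal(nrow(sc$manifest), 50 * 6 + 100)
  expect_equal(ncol(sc$betas$values), 6)
  expect_equal(ncol(sc$expr$values), 20)
  expect_equal(nrow(sc$truth$spiked_dmr_islands), 5)
  expect_equal(nrow(sc$truth$spiked_dmp_probes), 20)
  null_sc <- synthetic_scene("null", seed = 123)
  expect_equal(nrow(null_sc$truth$spiked_dmp_probes), 0)
  expect_identical(null_sc$manifest, sc$manifest)  # same layout, no spikes

  # pipeline recovery agrees with a direct per-island oracle re-test
  res <- call_dmrs(sc$betas, sc$manifest)
  called <- res$dmrs$island_name
  oracle_called <- vapply(seq_len(5), function(i) {
    ids <- strsplit(sc$truth$spiked_dmr_islands$probe_ids[i], ";")[[1]]
    isl <- sc$truth$spiked_dmr_islands$island_name[i]
    el <- eligible_probes(sc$manifest)
    el <- el[el$island_name == isl, ]
    win <- make_windows(el, dmr_params())
    any(vapply(seq_len(nrow(win)), function(w) {
      wids <- strsplit(win$probe_ids[w], ";")[[1]]
      ht <- hotelling_t2(sc$betas$values[wids, , drop = FALSE], sc$betas$groups)
      wsmeth:::.window_significant(ht$p_value, ht$deltas, dmr_params())
    }, logical(1)))
  }, logical(1))
  expect_setequal(intersect(called, sc$truth$spiked_dmr_islands$island_name),
                  sc$truth$spiked_dmr_islands$island_name[oracle_called])
})

test_that("write_scene emits a complete, readable fixture directory", {
  sc <- synthetic_scene("paperlike", seed = 55)
  dir <- tempfile()
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  bm <- read_beta_matrix(paths["betas"], paths["samples"])
  expect_equal(bm$values, sc$betas$values, tolerance = 1e-12)
  man <- read_manifest(paths["manifest"])
  expect_equal(man$probe_id, sc$manifest$probe_id)
  expect_equal(man$genes, sc$manifest$genes)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(sort(truth$spiked_dmp_probes$probe_id),
               sort(sc$truth$spiked_dmp_probes$probe_id))
})
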