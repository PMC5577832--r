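# Region calling: probe eligibility, island-bounded windows, the Hotelling
# T2 statistic and its exact F transform, the dual significance rule, and
# window merging.

test_that("eligible_probes keeps gene-associated CpG-rich probes only", {
  ann <- make_ann(
    probe_id = c("a", "b", "c", "d", "e"),
    position = c(500L, 100L, 200L, 300L, 400L),
    genes = c("FOO", "", "UBLCP1", "BAR", "BAZ"),
    island_name = c("", "chr1:1-9", "chr1:1-9", "chr1:1-9", ""),
    relation = c("OpenSea", "Island", "S_Shore", "N_Shelf", "OpenSea"))
  el <- eligible_probes(ann)
  # open-sea probe with a gene and island probe without a gene both excluded
  expect_setequal(el$probe_id, c("c", "d"))
  # sorted by position
  expect_equal(el$probe_id, c("c", "d"))
})

test_that("windows slide within one island unit and never span boundaries", {
  p <- dmr_params(window_size = 3)
  five <- make_ann(paste0("p", 1:5), seq(100, 500, 100),
                   genes = "G1", island_name = "chr1:100-500",
                   relation = "Island")
  expect_equal(nrow(make_windows(five, p)), 3)   # 5 - 3 + 1

  two <- five[1:2, ]
  expect_equal(nrow(make_windows(two, p)), 0)

  # two adjacent 3-probe islands on one chromosome: 2 windows, none spanning
  both <- rbind(
    make_ann(paste0("a", 1:3), c(100L, 200L, 300L), genes = "G1",
             island_name = "chr1:100-300", relation = "Island"),
    make_ann(paste0("b", 1:3), c(400L, 500L, 600L), genes = "G2",
             island_name = "chr1:400-600", relation = "Island"))
  class(both) <- c("probe_annotation", "data.frame")
  w <- make_windows(eligible_probes(both), p)
  expect_equal(nrow(w), 2)
  expect_equal(sort(w$probe_ids), c("a1;a2;a3", "b1;b2;b3"))
})

test_that("hotelling_t2 handles null, univariate and singular cases", {
  # identical group mean vectors with nonzero within-group variance
  set.seed(40)
  case <- matrix(runif(9, 0.2, 0.8), 3)
  ctrl <- matrix(runif(9, 0.2, 0.8), 3)
  ctrl <- ctrl - rowMeans(ctrl) + rowMeans(case)
  X <- cbind(case, ctrl)
  rownames(X) <- paste0("p", 1:3)
  g <- rep(c("CASE", "CTRL"), each = 3)
  r <- hotelling_t2(X, g)
  expect_equal(r$T2, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)

  # window of one probe reduces exactly to the univariate ANOVA
  set.seed(5)
  x <- matrix(runif(8), 1, 8, dimnames = list("p1", NULL))
  g8 <- rep(c("CASE", "CTRL"), each = 4)
  r1 <- hotelling_t2(x, g8)
  ra <- probe_anova(x[1, 1:4], x[1, 5:8])
  expect_equal(r1$p_value, ra$p_value, tolerance = 1e-12)
  expect_equal(r1$F_stat, ra$F_stat, tolerance = 1e-10)

  # duplicated probe row makes the pooled covariance singular
  Xs <- rbind(X[1:2, ], X[1, , drop = FALSE])
  rownames(Xs) <- paste0("q", 1:3)
  expect_warning(hotelling_t2(Xs, g), "singular")

  expect_error(hotelling_t2(X[, 1:4], g[1:4]), "at least 5")
})

test_that("T2 is invariant to affine rescaling and label swap flips deltas", {
  set.seed(9)
  for (i in 1:10) {
    X <- matrix(runif(18, 0.2, 0.8), 3, 6,
                dimnames = list(paste0("p", 1:3), NULL))
    g <- rep(c("CASE", "CTRL"), each = 3)
    r <- hotelling_t2(X, g)
    r_aff <- hotelling_t2(0.4 * X + 0.1, g)
    expect_equal(r_aff$T2, r$T2, tolerance = 1e-8)
    r_swap <- hotelling_t2(X, rev(g))
    expect_equal(r_swap$T2, r$T2, tolerance = 1e-8)
    expect_equal(r_swap$deltas, -r$deltas, tolerance = 1e-12)
  }
})

test_that("the T2-based p agrees with classical MANOVA (Wilks) to machine precision", {
  set.seed(13)
  for (n_per in c(3, 5)) {
    for (i in 1:25) {
      X <- matrix(runif(3 * 2 * n_per, 0.2, 0.8), 3,
                  dimnames = list(paste0("p", 1:3), NULL))
      g <- factor(rep(c("CASE", "CTRL"), each = n_per))
      r <- hotelling_t2(X, as.character(g))
      fit <- stats::manova(t(X) ~ g)
      wp <- summary(fit, test = "Wilks")$stats[1, "Pr(>F)"]
      expect_equal(r$p_value, unname(wp), tolerance = 1e-10)
    }
  }
})

test_that("window MANOVA p tracks the exact balanced-permutation null on 3v3 toys", {
  set.seed(17)
  diffs <- replicate(25, {
    X <- matrix(rnorm(18, 0.5, 0.05), 3, 6,
                dimnames = list(paste0("p", 1:3), NULL))
    r <- hotelling_t2(X, rep(c("CASE", "CTRL"), each = 3))
    abs(r$p_value - perm_t2_p(X, 3))
  })
  expect_lt(mean(diffs), 0.15)
  expect_true(all(diffs <= 0.35))
})

test_that("the dual significance rule requires adjacency of the exceeding probes", {
  p <- dmr_params()
  sig <- wsmeth:::.window_significant
  expect_true(sig(5e-4, c(0.35, 0.31, 0.05), p))     # two adjacent >= 0.3
  expect_false(sig(5e-4, c(0.35, 0.05, 0.31), p))    # exceeding but not adjacent
  expect_false(sig(0.01, c(0.4, 0.4, 0.4), p))       # p fails
  expect_true(sig(5e-4, c(-0.30, -0.30, 0.0), p))    # 0.3 is inclusive
  expect_false(sig(1e-3, c(0.4, 0.4, 0.4), p))       # p threshold is strict
})

test_that("call_dmrs recovers a strong region and merges overlapping windows", {
  # one island of 6 eligible probes, 4 consecutive strongly shifted
  ann <- make_ann(paste0("p", 1:6), seq(1000, 1500, 100), genes = "GENE1",
                  island_name = "chr1:1000-1500", relation = "Island")
  set.seed(3)
  base <- runif(6, 0.25, 0.45)
  vals <- matrix(rep(base, 6), 6, 6) + matrix(rnorm(36, 0, 0.01), 6, 6)
  vals[2:5, 1:3] <- vals[2:5, 1:3] + 0.4
  vals <- pmin(pmax(vals, 0), 1)
  bm <- make_bm(vals, 3, probe_ids = ann$probe_id)
  res <- call_dmrs(bm, ann, dmr_params())
  expect_equal(nrow(res$windows), 4)
  expect_gt(sum(res$windows$significant), 1)
  expect_equal(nrow(res$dmrs), 1)          # overlapping windows merged
  d <- res$dmrs[1, ]
  expect_equal(d$direction, "HYPER")
  expect_equal(d$island_name, "chr1:1000-1500")
  expect_equal(d$genes, "GENE1")
  expect_equal(d$p_value, min(res$windows$p_value[res$windows$significant]))
  sig_idx <- range(res$windows$start_idx[res$windows$significant])
  expect_equal(d$start, ann$position[sig_idx[1]])
  expect_equal(d$end, ann$position[sig_idx[2] + 2])

  # no region at all when the matrix is null
  null_vals <- matrix(rep(base, 6), 6, 6) + matrix(rnorm(36, 0, 0.01), 6, 6)
  res0 <- call_dmrs(make_bm(pmin(pmax(null_vals, 0), 1), 3,
                            probe_ids = ann$probe_id), ann)
  expect_equal(nrow(res0$dmrs), 0)
})

test_that("hypomethylated regions are labelled HYPO", {
  ann <- make_ann(paste0("p", 1:3), c(100L, 200L, 300L), genes = "G",
                  island_name = "chr2:100-300", relation = "Island")
  set.seed(8)
  vals <- matrix(0.7, 3, 6) + matrix(rnorm(18, 0, 0.01), 3, 6)
  vals[, 1:3] <- vals[, 1:3] - 0.45
  bm <- make_bm(pmin(pmax(vals, 0), 1), 3, probe_ids = ann$probe_id)
  res <- call_dmrs(bm, ann)
  expect_equal(nrow(res$dmrs), 1)
  expect_equal(res$dmrs$direction, "HYPO")
})
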