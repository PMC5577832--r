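# Readers/writers: manifest dialects, beta matrices, GMT libraries, BED
# coordinate conventions, TSV round trips.

write_tmp_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("generic manifest rows parse into annotations with normalised genes and relations", {
  path <- write_tmp_tsv(c(
    "probe_id\tchrom\tposition\tgenes\tisland_name\trelation",
    "cg15294279\tchr3\t174842010\tNAALADL2\t\t",
    "cg06052372\tchr16\t83967808\t\t\t",
    "cg00000001\tchr17\t46620367\tHOXB2; HOXB-AS1\tchr17:46620367-46621373\tS_Shore",
    "cg00000002\tchr17\t46620500\thoxb2;HOXB2\tchr17:46620367-46621373\tIsland"
  ))
  ann <- read_manifest(path, dialect = "generic")
  expect_equal(nrow(ann), 4)
  r1 <- ann[ann$probe_id == "cg15294279", ]
  expect_equal(r1$relation, "OpenSea")
  expect_equal(r1$genes, "NAALADL2")
  expect_equal(r1$position, 174842010L)
  r2 <- ann[ann$probe_id == "cg06052372", ]
  expect_equal(r2$genes, "")
  expect_equal(r2$relation, "OpenSea")
  # multi-gene fields split, trimmed, uppercased, deduplicated, sorted
  expect_equal(ann[ann$probe_id == "cg00000001", ]$genes, "HOXB-AS1;HOXB2")
  expect_equal(ann[ann$probe_id == "cg00000002", ]$genes, "HOXB2")
})

test_that("manifest parsing drops unparseable positions, rejects bad input", {
  path <- write_tmp_tsv(c(
    "probe_id\tchrom\tposition\tgenes\tisland_name\trelation",
    "cg1\tchr1\t100\tA\t\t",
    "cg2\tchr1\tnot_a_number\tB\t\t",
    "cg3\tchr1\t-5\tC\t\t"
  ))
  expect_message(ann <- read_manifest(path), "dropped 2")
  expect_equal(ann$probe_id, "cg1")

  no_col <- write_tmp_tsv(c("probe_id\tchrom\tgenes\tisland_name\trelation",
                            "cg1\tchr1\tA\t\t"))
  expect_error(read_manifest(no_col), "position")

  dup <- write_tmp_tsv(c("probe_id\tchrom\tposition\tgenes\tisland_name\trelation",
                         "cg1\tchr1\t100\t\t\t", "cg1\tchr1\t200\t\t\t"))
  expect_error(read_manifest(dup), "unique")

  bad_rel <- write_tmp_tsv(c("probe_id\tchrom\tposition\tgenes\tisland_name\trelation",
                             "cg1\tchr1\t100\tA\tchr1:90-110\tNorthernShore"))
  expect_error(read_manifest(bad_rel), "relation")
})

test_that("Illumina manifest dialect maps its column names", {
  path <- write_tmp_tsv(c(
    paste("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
          "UCSC_CpG_Islands_Name", "Relation_to_UCSC_CpG_Island", sep = "\t"),
    "cg00597723\tchr5\t158691793\tUBLCP1\tchr5:158690013-158690541\tS_Shore"
  ))
  ann <- read_manifest(path, dialect = "EPIC")
  expect_equal(ann$genes, "UBLCP1")
  expect_equal(ann$relation, "S_Shore")
  expect_equal(ann$position, 158691793L)
})

test_that("beta matrix round-trips through disk exactly and validates bounds", {
  set.seed(4)
  vals <- matrix(runif(12), 4, 3,
                 dimnames = list(paste0("cg", 1:4), c("s1", "s2", "s3")))
  bm <- beta_matrix(vals, c(s1 = "CASE", s2 = "CASE", s3 = "CTRL"))
  mp <- tempfile(); sp <- tempfile()
  write_beta_matrix(bm, mp, sp)
  bm2 <- read_beta_matrix(mp, sp)
  expect_equal(bm2$values, bm$values, tolerance = 1e-12)
  expect_equal(bm2$groups, bm$groups)

  vals_bad <- vals; vals_bad[2, 3] <- 1.2
  expect_error(beta_matrix(vals_bad, bm$groups), "cg2.*s3")
  # within numerical tolerance values are clamped, not rejected
  vals_eps <- vals; vals_eps[1, 1] <- 1 + 1e-9
  expect_equal(beta_matrix(vals_eps, bm$groups)$values[1, 1], 1)
})

test_that("beta matrix loading rejects unknown samples and non-numeric cells", {
  sheet <- write_tmp_tsv(c("sample_id\tgroup", "s1\tCASE", "s2\tControl"))
  ok <- write_tmp_tsv(c("probe_id\ts1\ts2", "cg1\t0.5\t0.6"))
  bm <- read_beta_matrix(ok, sheet)
  expect_equal(unname(bm$groups), c("CASE", "CTRL"))  # CONTROL alias

  stray <- write_tmp_tsv(c("probe_id\ts1\ts9", "cg1\t0.5\t0.6"))
  expect_error(read_beta_matrix(stray, sheet), "s9")

  text_cell <- write_tmp_tsv(c("probe_id\ts1\ts2", "cg1\t0.5\toops"))
  expect_error(read_beta_matrix(text_cell, sheet), "cg1.*s2")

  bad_sheet <- write_tmp_tsv(c("sample_id\tgroup", "s1\tCASE", "s2\tPATIENT"))
  expect_error(read_sample_sheet(bad_sheet), "PATIENT")
})

test_that("GMT parsing keeps well-formed terms, skips malformed lines, round-trips", {
  path <- write_tmp_tsv(c(
    "HSA-00600\tSphingolipid metabolism\tCERS3\tCERS1",
    "BROKEN_LINE\tonly-two-fields",
    "HSA-04068\tFoxO signalling\tfoxo3\tAKT2\takt2"
  ))
  expect_warning(lib <- read_gmt(path), "skipped 1")
  expect_equal(sort(names(lib$sets)), c("HSA-00600", "HSA-04068"))
  expect_setequal(lib$sets[["HSA-00600"]], c("CERS3", "CERS1"))
  expect_setequal(lib$sets[["HSA-04068"]], c("FOXO3", "AKT2"))  # uppercased, deduped

  out <- tempfile(fileext = ".gmt")
  write_gmt(lib, out)
  lib2 <- read_gmt(out)
  expect_equal(lib2$sets, lib$sets)
  expect_equal(lib2$term_names, lib$term_names)

  empty <- write_tmp_tsv(character(0))
  expect_equal(length(read_gmt(empty)$sets), 0)
})

test_that("BED export converts 1-based inclusive spans to 0-based half-open", {
  dmrs <- data.frame(chrom = "chr15", start = 101084428L, end = 101085178L,
                     n_probes = 3L, probe_ids = "a;b;c", genes = "GENEX",
                     island_name = "chr15:101084428-101085178",
                     relations = "Island", p_value = 3.41e-4,
                     direction = "HYPER", stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, path)
  bed <- utils::read.delim(path, header = FALSE)
  expect_equal(bed$V2, 101084427)
  expect_equal(bed$V3, 101085178)
  expect_true(bed$V2 >= 0 && bed$V2 < bed$V3)
  expect_equal(bed$V5, round(-log10(3.41e-4), 6))

  empty <- tempfile(fileext = ".bed")
  write_dmr_bed(dmrs[0, ], empty)
  expect_equal(length(readLines(empty)), 0)
})

test_that("TSV result tables round-trip", {
  df <- data.frame(probe_id = c("cg1", "cg2"), p_value = c(1e-8, 0.5),
                   delta = c(-0.31, 0.02), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_table(df, path)
  back <- read_table_tsv(path)
  expect_equal(back$probe_id, df$probe_id)
  expect_equal(back$p_value, df$p_value, tolerance = 1e-12)
})
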