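# Readers and writers for the standard formats the pipeline touches:
# probe-annotation manifests (EPIC / 450k / generic TSV dialects), beta-value
# matrices with a two-group sample sheet, GMT gene-set libraries, expression
# matrices, and BED/TSV result exports.

.RELATIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")

# Column names expected per manifest dialect.
.manifest_columns <- function(dialect) {
  switch(dialect,
    generic = c(probe_id = "probe_id", chrom = "chrom", position = "position",
                genes = "genes", island_name = "island_name",
                relation = "relation"),
    EPIC = c(probe_id = "IlmnID", chrom = "CHR", position = "MAPINFO",
             genes = "UCSC_RefGene_Name",
             island_name = "UCSC_CpG_Islands_Name",
             relation = "Relation_to_UCSC_CpG_Island"),
    HM450 = c(probe_id = "IlmnID", chrom = "CHR", position = "MAPINFO",
              genes = "UCSC_RefGene_Name",
              island_name = "UCSC_CpG_Islands_Name",
              relation = "Relation_to_UCSC_CpG_Island"),
    stop("unknown manifest dialect: ", dialect)
  )
}

#' Read a probe-annotation manifest
#'
#' Parses a TSV manifest into a probe-annotation table with one row per
#' probe. Three column dialects are supported: `"generic"`
#' (`probe_id, chrom, position, genes, island_name, relation`) and the
#' Illumina `"EPIC"` / `"HM450"` manifest headers (`IlmnID, CHR, MAPINFO,
#' UCSC_RefGene_Name, UCSC_CpG_Islands_Name, Relation_to_UCSC_CpG_Island`).
#'
#' Positions are 1-based base pairs (Illumina `MAPINFO` convention). Gene
#' fields holding several `";"`-separated symbols are split, uppercased and
#' deduplicated. A probe with an empty island name gets relation `OpenSea`;
#' rows whose position cannot be parsed as a positive integer are dropped
#' with a message reporting the count.
#'
#' @param path Path to the manifest TSV.
#' @param dialect One of `"generic"`, `"EPIC"`, `"HM450"`.
#' @return A data frame of class `probe_annotation` with columns
#'   `probe_id`, `chrom`, `position` (integer), `genes` (";"-joined,
#'   `""` when none), `island_name` (`""` when none) and `relation`.
#' @export
read_manifest <- function(path, dialect = c("generic", "EPIC", "HM450")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("manifest file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  cols <- .manifest_columns(dialect)
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("manifest is missing required column(s) for dialect '", dialect,
         "': ", paste(missing_cols, collapse = ", "))
  }
  ann <- data.frame(
    probe_id = trimws(raw[[cols["probe_id"]]]),
    chrom = trimws(raw[[cols["chrom"]]]),
    position = suppressWarnings(as.integer(gsub(",", "", raw[[cols["position"]]]))),
    genes = normalize_genes(raw[[cols["genes"]]]),
    island_name = trimws(raw[[cols["island_name"]]]),
    relation = trimws(raw[[cols["relation"]]]),
    stringsAsFactors = FALSE
  )
  bad <- is.na(ann$position) | ann$position < 1
  if (any(bad)) {
    message("read_manifest: dropped ", sum(bad), " row(s) with unparseable position")
    ann <- ann[!bad, , drop = FALSE]
  }
  # normalise the island/relation pair
  ann$island_name[is.na(ann$island_name) |
                    ann$island_name %in% c("-", "–", "—", ".")] <- ""
  ann$relation[is.na(ann$relation)] <- ""
  ann$relation[ann$island_name == ""] <- "OpenSea"
  bad_rel <- ann$island_name != "" & !(ann$relation %in% .RELATIONS)
  if (any(bad_rel)) {
    stop("manifest has ", sum(bad_rel), " row(s) with an island name but an ",
         "unrecognised relation (first: '", ann$relation[bad_rel][1], "')")
  }
  if (anyDuplicated(ann$probe_id)) {
    stop("manifest probe ids are not unique (e.g. '",
         ann$probe_id[duplicated(ann$probe_id)][1], "')")
  }
  rownames(ann) <- NULL
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Write a probe-annotation table (generic dialect)
#' @param annotations A `probe_annotation` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(annotations, path) {
  write_table(as.data.frame(annotations)[, c("probe_id", "chrom", "position",
                                             "genes", "island_name", "relation")],
              path)
}

#' Read a two-group sample sheet
#'
#' A sample sheet is a TSV with columns `sample_id` and `group`; groups
#' `CASE`/`CTRL` (case-insensitive; `CONTROL` is accepted for `CTRL`).
#'
#' @param path Path to the sample sheet.
#' @return Data frame with columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sh <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sh))) {
    stop("sample sheet must have columns 'sample_id' and 'group'")
  }
  grp <- toupper(trimws(sh$group))
  grp[grp == "CONTROL"] <- "CTRL"
  bad <- !(grp %in% c("CASE", "CTRL"))
  if (any(bad)) {
    stop("sample sheet has unrecognised group label(s): ",
         paste(unique(sh$group[bad]), collapse = ", "))
  }
  if (anyDuplicated(sh$sample_id)) stop("sample sheet sample ids are not unique")
  data.frame(sample_id = as.character(sh$sample_id), group = grp,
             stringsAsFactors = FALSE)
}

#' Construct a beta matrix object
#'
#' A `beta_matrix` couples a probes-by-samples matrix of methylation beta
#' fractions with a case/control group assignment. Values must lie in
#' \[0, 1\] (up to a 1e-6 numerical tolerance, inside which they are
#' clamped); missing values are allowed on construction but probes carrying
#' any missing value are excluded from testing operations.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param groups Character vector of `"CASE"`/`"CTRL"` named by sample id,
#'   covering every column of `values`.
#' @return An object of class `beta_matrix` with elements `values` and
#'   `groups`.
#' @export
beta_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (is.null(names(groups))) stop("'groups' must be named by sample id")
  missing_grp <- setdiff(colnames(values), names(groups))
  if (length(missing_grp) > 0) {
    stop("no group assignment for sample(s): ", paste(missing_grp, collapse = ", "))
  }
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("CASE", "CTRL"))) stop("groups must be CASE or CTRL")
  out_of_range <- which(!is.na(values) & (values < -1e-6 | values > 1 + 1e-6),
                        arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    i <- out_of_range[1, ]
    stop(sprintf("beta value out of [0,1]: probe '%s', sample '%s' (%g)",
                 rownames(values)[i[1]], colnames(values)[i[2]],
                 values[i[1], i[2]]))
  }
  values[!is.na(values) & values < 0] <- 0
  values[!is.na(values) & values > 1] <- 1
  structure(list(values = values, groups = groups), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d CASE, %d CTRL)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "CASE"), sum(x$groups == "CTRL")))
  invisible(x)
}

# Shared loader for numeric sample matrices (betas and expression).
.read_numeric_matrix <- function(path, sheet) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  ids <- raw[[1]]
  sample_ids <- names(raw)[-1]
  extra <- setdiff(sample_ids, sheet$sample_id)
  if (length(extra) > 0) {
    stop("matrix sample(s) absent from sample sheet: ",
         paste(extra, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & col != "NA" & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell at probe '%s', sample '%s': '%s'",
                   ids[bad[1]], sample_ids[j], col[bad[1]]))
    }
    vals[, j] <- num
  }
  vals
}

#' Read a beta-value matrix with its sample sheet
#'
#' The matrix is a TSV whose first column holds probe ids and whose
#' remaining columns are samples; every matrix sample must appear in the
#' sample sheet. Any value outside \[0, 1\] by more than 1e-6 is an error
#' naming the offending probe and sample — values are never silently
#' clipped into range.
#'
#' @param path Path to the beta TSV.
#' @param sample_sheet Path to the sample sheet (see [read_sample_sheet()]).
#' @return A [beta_matrix()] object.
#' @export
read_beta_matrix <- function(path, sample_sheet) {
  sheet <- read_sample_sheet(sample_sheet)
  vals <- .read_numeric_matrix(path, sheet)
  beta_matrix(vals, stats::setNames(sheet$group, sheet$sample_id))
}

#' Write a beta matrix (and optionally its sample sheet) as TSV
#' @param bm A `beta_matrix`.
#' @param path Output path for the matrix.
#' @param sample_sheet_path Optional path to also write the sample sheet.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(bm, path, sample_sheet_path = NULL) {
  stopifnot(inherits(bm, "beta_matrix"))
  df <- data.frame(probe_id = rownames(bm$values), bm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  if (!is.null(sample_sheet_path)) {
    write_table(data.frame(sample_id = names(bm$groups),
                           group = unname(bm$groups)), sample_sheet_path)
  }
  invisible(path)
}

#' Read an expression matrix with its sample sheet
#'
#' Same layout as [read_beta_matrix()] (first column = gene/probe ids) but
#' without the \[0, 1\] bound. Row ids are typically gene symbols and may be
#' duplicated (several array probes per gene).
#'
#' @param path Path to the expression TSV.
#' @param sample_sheet Path to the sample sheet.
#' @return An object of class `expression_matrix` with elements `values`
#'   and `groups`.
#' @export
read_expression_matrix <- function(path, sample_sheet) {
  sheet <- read_sample_sheet(sample_sheet)
  vals <- .read_numeric_matrix(path, sheet)
  groups <- stats::setNames(sheet$group, sheet$sample_id)[colnames(vals)]
  structure(list(values = vals, groups = groups), class = "expression_matrix")
}

#' Write an expression matrix as TSV
#' @param em An `expression_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' GMT lines are `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Gene
#' symbols are uppercased and deduplicated; lines with fewer than three
#' fields are skipped with a warning. An empty file yields an empty library.
#'
#' @param path Path to the `.gmt` file.
#' @return A `gene_set_library`: a list with `sets` (named list of gene
#'   vectors keyed by term id) and `term_names` (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  term_names <- character(0)
  n_skipped <- 0L
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    genes <- unique(toupper(fields[-(1:2)][nzchar(fields[-(1:2)])]))
    if (length(fields) < 3 || length(genes) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    id <- fields[1]
    if (id %in% names(sets)) {
      warning("duplicate GMT term id '", id, "'; keeping the first occurrence")
      next
    }
    sets[[id]] <- genes
    term_names[id] <- fields[2]
  }
  if (n_skipped > 0) {
    warning("read_gmt: skipped ", n_skipped, " malformed line(s) (fewer than 3 fields)")
  }
  structure(list(sets = sets, term_names = term_names),
            class = "gene_set_library")
}

#' Write a gene-set library in GMT format
#' @param library A `gene_set_library`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$sets), function(id) {
    paste(c(id, library$term_names[[id]], library$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export DMRs as a BED file
#'
#' Manifest positions are 1-based; BED is 0-based half-open, so a DMR
#' spanning manifest positions `start..end` is written as
#' `(start-1, end)`. Columns: `chrom`, `start`, `end`,
#' `name` (`genes;island_name`), `score` (−log10 p).
#'
#' @param dmrs DMR result data frame from [call_dmrs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = dmrs$chrom,
    start = dmrs$start - 1L,
    end = dmrs$end,
    name = paste(dmrs$genes, dmrs$island_name, sep = ";"),
    score = round(-log10(dmrs$p_value), 6),
    stringsAsFactors = FALSE
  )
  stopifnot(all(bed$start >= 0), all(bed$start < bed$end))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probe-universe file (one probe id per line)
#' @param path File path.
#' @return Character vector of probe ids.
#' @export
read_probe_universe <- function(path) {
  if (!file.exists(path)) stop("probe universe file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}
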