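#' Read a tab-separated feature matrix
#'
#' Reads a TSV file with one header row of feature identifiers and a first
#' column of sample identifiers into a numeric matrix (samples in rows).
#' Empty cells and `"NA"` denote missing values. This single tabular dialect
#' (tab-separated, UTF-8, `NA` for missing) is used for every matrix the
#' pipeline touches: copy number, expression, methylation betas, detection p
#' values, and IC50 response tables.
#'
#' @param path Path to a TSV file.
#' @param rows_are_samples If `FALSE`, the file is transposed after reading so
#'   that rows are samples in the returned matrix.
#' @param allow_duplicate_cols Permit repeated column headers. Only raw drug
#'   response tables use this: an agent measured in duplicate experiments
#'   appears as two columns with the same identifier (collapsed later by
#'   [prepare_response()]). Duplicate row identifiers are always an error.
#'
#' @return A numeric matrix with sample identifiers as rownames and feature
#'   identifiers as colnames.
#' @seealso [write_feature_matrix()]
#' @export
read_feature_matrix <- function(path, rows_are_samples = TRUE,
                                allow_duplicate_cols = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), name_repair = "minimal",
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 1) stop("empty table in ", path, call. = FALSE)
  row_ids <- raw[[1]]
  col_ids <- colnames(raw)[-1]
  dup_r <- row_ids[duplicated(row_ids)]
  if (length(dup_r) > 0) {
    stop("duplicated row identifier(s): ", paste(unique(dup_r), collapse = ", "),
         call. = FALSE)
  }
  dup_c <- col_ids[duplicated(col_ids)]
  if (length(dup_c) > 0 && !allow_duplicate_cols) {
    stop("duplicated column identifier(s): ", paste(unique(dup_c), collapse = ", "),
         call. = FALSE)
  }
  body <- raw[, -1, drop = FALSE]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(col_ids),
                 dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    cell <- body[[j]]
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                   cell[bad[1]], row_ids[bad[1]], col_ids[j], path),
           call. = FALSE)
    }
    vals[, j] <- parsed
  }
  if (!rows_are_samples) vals <- t(vals)
  vals
}

#' Write a feature matrix as TSV
#'
#' Inverse of [read_feature_matrix()]: writes a numeric matrix with an
#' `sample_id` first column. Finite values round-trip bit-exactly (full
#' precision via [format()] with 17 significant digits); missing values are
#' written as `NA`.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Name used for the first (identifier) column.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path, id_column = "sample_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- dplyr::bind_cols(tibble::tibble(!!id_column := rownames(x)),
                         tibble::as_tibble(x, .name_repair = "minimal"),
                         .name_repair = "minimal")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

chrom_levels <- c(as.character(1:22), "X", "Y")

#' Read a gene catalog
#'
#' The gene catalog carries one row per gene: its symbol, chromosome,
#' cytoband, the rank of that cytoband along the chromosome
#' (`band_order_index`, the adjacency notion used by [assign_segments()];
#' supplied rather than parsed because cytoband lexicographic order is not
#' positional order), an imprinting flag, and an optional curated joint
#' copy-number-alteration group identifier (genes sharing it are forced into
#' one segment, e.g. literature-supported co-deleted clusters).
#'
#' @param path TSV file with columns `gene_symbol`, `chromosome`, `cytoband`,
#'   `band_order_index`, `imprinted`, `curated_joint_cna_group`.
#' @return A tibble, one row per gene, validated (unique symbols, known
#'   chromosomes, band order consistent with cytoband labels per chromosome).
#' @export
read_gene_catalog <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  required <- c("gene_symbol", "chromosome", "cytoband", "band_order_index",
                "imprinted", "curated_joint_cna_group")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop("gene catalog is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  catalog <- tibble::tibble(
    gene_symbol = df$gene_symbol,
    chromosome = df$chromosome,
    cytoband = df$cytoband,
    band_order_index = as.integer(df$band_order_index),
    imprinted = as.logical(df$imprinted),
    curated_joint_cna_group = df$curated_joint_cna_group
  )
  validate_gene_catalog(catalog)
}

#' Validate a gene catalog tibble
#'
#' Checks the catalog invariants: unique gene symbols, chromosomes drawn from
#' 1-22/X/Y, no missing cytobands, and a band order index that is constant
#' within a cytoband and strictly consistent with it per chromosome.
#'
#' @param catalog A tibble shaped like [read_gene_catalog()] output.
#' @return The catalog, invisibly validated (returned unchanged).
#' @export
validate_gene_catalog <- function(catalog) {
  dup <- catalog$gene_symbol[duplicated(catalog$gene_symbol)]
  if (length(dup) > 0) {
    stop("duplicated gene symbol(s) in catalog: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_chr <- setdiff(unique(catalog$chromosome), chrom_levels)
  if (length(bad_chr) > 0) {
    stop("unknown chromosome token(s): ", paste(bad_chr, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(catalog$cytoband)) stop("catalog gene with no cytoband", call. = FALSE)
  if (anyNA(catalog$band_order_index)) {
    stop("catalog gene with no band_order_index", call. = FALSE)
  }
  # one index per cytoband, one cytoband per index, within each chromosome
  per_band <- dplyr::distinct(catalog, .data$chromosome,
                              band = tolower(.data$cytoband),
                              .data$band_order_index)
  clash <- dplyr::count(per_band, .data$chromosome, .data$band) |>
    dplyr::filter(.data$n > 1)
  if (nrow(clash) > 0) {
    stop("cytoband '", clash$band[1], "' on chromosome ", clash$chromosome[1],
         " has inconsistent band_order_index values", call. = FALSE)
  }
  clash2 <- dplyr::count(per_band, .data$chromosome, .data$band_order_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(clash2) > 0) {
    stop("band_order_index ", clash2$band_order_index[1], " on chromosome ",
         clash2$chromosome[1], " maps to multiple cytobands", call. = FALSE)
  }
  catalog
}

#' Write gene catalog as TSV
#' @param catalog Gene catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_catalog <- function(catalog, path) {
  readr::write_tsv(catalog, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a long-format probe annotation
#'
#' One row per probe-gene-region assignment (a 450K-style probe may map to
#' several overlapping genes and region groups, e.g. a probe inside both NNAT
#' and the first intron of BLCAP). `region_group` is restricted to the six
#' UCSC-style gene regions.
#'
#' @param path TSV with columns `probe_id`, `gene_symbol`, `region_group`,
#'   `cytoband`, `snp_masked`.
#' @return A validated tibble.
#' @export
read_probe_annotation <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  required <- c("probe_id", "gene_symbol", "region_group", "cytoband", "snp_masked")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop("probe annotation is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ann <- tibble::tibble(
    probe_id = df$probe_id,
    gene_symbol = df$gene_symbol,
    region_group = df$region_group,
    cytoband = df$cytoband,
    snp_masked = as.logical(df$snp_masked)
  )
  validate_probe_annotation(ann)
}

#' The six gene-region groups of the 450K annotation
#'
#' TSS1500 (200-1500 bases upstream of the transcription start site), TSS200
#' (0-200 bases upstream), the 5' UTR, the first exon, the gene body, and the
#' 3' UTR.
#' @export
GENE_REGION_GROUPS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")

#' Validate a probe annotation tibble
#' @param ann Probe annotation tibble.
#' @return `ann`, validated.
#' @export
validate_probe_annotation <- function(ann) {
  bad <- setdiff(unique(ann$region_group), GENE_REGION_GROUPS)
  if (length(bad) > 0) {
    stop("unknown region_group token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ann
}

#' Write association records as a sorted TSV
#'
#' Records are written sorted by the absolute Spearman correlation,
#' descending, with `feature_id` then `agent_id` as deterministic
#' tie-breakers — the presentation order of supplementary association tables.
#'
#' @param records Association record tibble (see [run_association_screen()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(records, path) {
  if (nrow(records) > 0 && "adjustment_mode" %in% colnames(records)) {
    modes <- unique(records$adjustment_mode[!is.na(records$adjustment_mode)])
    if (length(modes) > 1) {
      stop("records mix adjustment modes: ", paste(modes, collapse = ", "),
           call. = FALSE)
    }
  }
  ord <- records |>
    dplyr::arrange(dplyr::desc(abs(.data$spearman_rho)), .data$feature_id,
                   .data$agent_id)
  readr::write_tsv(ord, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' @param path TSV with columns `specimen_id`, `time_days`, `event`,
#'   `group_flag`, `mutation_flag`.
#' @return A tibble with nonnegative times and logical flags.
#' @export
read_survival_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  required <- c("specimen_id", "time_days", "event", "group_flag", "mutation_flag")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop("survival table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    specimen_id = df$specimen_id,
    time_days = as.numeric(df$time_days),
    event = as.logical(df$event),
    group_flag = as.logical(df$group_flag),
    mutation_flag = as.logical(df$mutation_flag)
  )
  if (any(out$time_days < 0, na.rm = TRUE)) {
    stop("negative survival time", call. = FALSE)
  }
  out
}
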