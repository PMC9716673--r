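#' Assign genes to chromosomal segments (bins)
#'
#' Copy-number values of neighbouring genes are far from independent: genes in
#' one amplified or deleted region rise and fall together. The conservative
#' copy-number FDR procedure therefore tests *segments*, groups of one or more
#' adjacent cytobands, rather than individual genes. Segments are built in
#' three steps:
#'
#' 1. every cytoband with catalog genes starts as its own segment (genes on
#'    the same cytoband always share a segment);
#' 2. two segments occupying adjacent cytobands (consecutive
#'    `band_order_index` on the same chromosome) are merged when their genes
#'    share a `curated_joint_cna_group` (literature-supported joint loss/gain,
#'    applied regardless of the data), or when the copy-number correlation
#'    linkage between them exceeds `merge_r_threshold`;
#' 3. merging repeats to a fixed point, so chains of adjacent correlated
#'    bands collapse into a single multi-band segment.
#'
#' The linkage statistic between two segments is, by default, the median over
#' all cross-segment gene pairs of the pairwise-complete Pearson correlation
#' of continuous copy number (`linkage = "median"`; `"mean"` and `"min"` are
#' available). Cytoband labels are compared case-insensitively; segment
#' identifiers are deterministic, numbered by chromosome then band order.
#'
#' @param catalog Gene catalog tibble ([read_gene_catalog()]).
#' @param cn Cell-line x gene continuous copy-number matrix. Genes absent
#'   from `cn` can merge only through the cytoband or curated rules.
#' @param merge_r_threshold Correlation threshold for adjacency merges,
#'   in (0, 1); a value above 1 disables correlation merging.
#' @param linkage Aggregation of cross-segment gene-pair correlations:
#'   `"median"` (default), `"mean"`, or `"min"`.
#'
#' @return An object of class `segment_assignment`: a list with
#'   `assignment` (tibble: `gene_symbol`, `segment_id`, `chromosome`,
#'   `cytoband`, `provenance`), `segment_provenance` (tibble: `segment_id`,
#'   comma-separated provenance tags), and `n_segments`.
#' @examples
#' catalog <- tibble::tibble(
#'   gene_symbol = c("A", "B", "C"), chromosome = "20",
#'   cytoband = c("q11.21", "q11.21", "q13.32"),
#'   band_order_index = c(1L, 1L, 2L), imprinted = TRUE,
#'   curated_joint_cna_group = c("grp20q", "grp20q", "grp20q"))
#' cn <- matrix(2, 4, 3, dimnames = list(paste0("cl", 1:4), c("A", "B", "C")))
#' assign_segments(catalog, cn)
#' @export
assign_segments <- function(catalog, cn, merge_r_threshold = 0.7,
                            linkage = c("median", "mean", "min")) {
  linkage <- match.arg(linkage)
  catalog <- validate_gene_catalog(catalog)
  if (!is.na(merge_r_threshold) && merge_r_threshold <= 0) {
    stop("merge_r_threshold must be positive", call. = FALSE)
  }
  cat <- catalog |>
    dplyr::mutate(band_key = tolower(.data$cytoband)) |>
    dplyr::arrange(match(.data$chromosome, chrom_levels), .data$band_order_index,
                   .data$gene_symbol)

  # one working unit per (chromosome, cytoband); units hold gene sets
  units <- cat |>
    dplyr::group_by(.data$chromosome, .data$band_key, .data$band_order_index) |>
    dplyr::summarise(genes = list(.data$gene_symbol),
                     groups = list(unique(stats::na.omit(.data$curated_joint_cna_group))),
                     cytoband = .data$cytoband[1], .groups = "drop") |>
    dplyr::arrange(match(.data$chromosome, chrom_levels), .data$band_order_index)

  seg_of <- seq_len(nrow(units))           # current segment index per unit
  provenance <- replicate(nrow(units), "same_cytoband", simplify = FALSE)

  linkage_fun <- switch(linkage, median = stats::median, mean = mean, min = min)
  seg_linkage <- function(genes_a, genes_b) {
    ga <- intersect(genes_a, colnames(cn))
    gb <- intersect(genes_b, colnames(cn))
    if (length(ga) == 0 || length(gb) == 0) return(NA_real_)
    r <- suppressWarnings(stats::cor(cn[, ga, drop = FALSE], cn[, gb, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    r <- r[is.finite(r)]
    if (length(r) == 0) return(NA_real_)
    linkage_fun(r)
  }

  repeat {
    merged_any <- FALSE
    for (i in seq_len(nrow(units) - 1)) {
      j <- i + 1
      if (seg_of[i] == seg_of[j]) next
      same_chr <- units$chromosome[i] == units$chromosome[j]
      adjacent <- same_chr &&
        units$band_order_index[j] == units$band_order_index[i] + 1L
      if (!adjacent) next
      seg_i <- which(seg_of == seg_of[i])
      seg_j <- which(seg_of == seg_of[j])
      genes_i <- unlist(units$genes[seg_i])
      genes_j <- unlist(units$genes[seg_j])
      shared_group <- length(intersect(unlist(units$groups[seg_i]),
                                       unlist(units$groups[seg_j]))) > 0
      tag <- NULL
      if (shared_group) {
        tag <- "curated_merge"
      } else if (!is.na(merge_r_threshold) && merge_r_threshold < 1) {
        link <- seg_linkage(genes_i, genes_j)
        if (!is.na(link) && link > merge_r_threshold) tag <- "correlation_merge"
      }
      if (!is.null(tag)) {
        new_tags <- union(union(unlist(provenance[seg_i]), unlist(provenance[seg_j])), tag)
        keep <- min(seg_of[i], seg_of[j])
        drop <- max(seg_of[i], seg_of[j])
        seg_of[seg_of == drop] <- keep
        for (k in which(seg_of == keep)) provenance[[k]] <- new_tags
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }

  # deterministic segment ids: by first unit (chromosome+band order)
  first_unit <- vapply(unique(seg_of), function(s) min(which(seg_of == s)), integer(1))
  relabel <- stats::setNames(rank(first_unit), unique(seg_of))
  seg_final <- as.integer(relabel[as.character(seg_of)])
  seg_ids <- sprintf("seg%03d", seg_final)

  prov_str <- vapply(provenance, function(p) paste(sort(p), collapse = ","),
                     character(1))
  n_per_unit <- lengths(units$genes)
  assignment <- tibble::tibble(
    gene_symbol = unlist(units$genes),
    segment_id = rep(seg_ids, n_per_unit),
    chromosome = rep(units$chromosome, n_per_unit),
    cytoband = rep(units$cytoband, n_per_unit),
    provenance = rep(prov_str, n_per_unit)
  ) |>
    dplyr::arrange(.data$segment_id, .data$gene_symbol)

  seg_prov <- assignment |>
    dplyr::distinct(.data$segment_id, .data$provenance) |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(provenance = paste(sort(unique(unlist(
      strsplit(.data$provenance, ",", fixed = TRUE)))), collapse = ","),
      .groups = "drop")

  structure(list(assignment = assignment,
                 segment_provenance = seg_prov,
                 n_segments = length(unique(assignment$segment_id))),
            class = "segment_assignment")
}

#' @export
print.segment_assignment <- function(x, ...) {
  cat("<segment_assignment> ", nrow(x$assignment), " genes in ",
      x$n_segments, " segments\n", sep = "")
  print(utils::head(x$assignment, 10))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a segment assignment
#' @param x A `segment_assignment`.
#' @param ... Unused.
#' @return The gene-to-segment tibble.
#' @export
tidy.segment_assignment <- function(x, ...) x$assignment

#' One-row summary of a segment assignment
#' @param x A `segment_assignment`.
#' @param ... Unused.
#' @return Tibble with segment counts by provenance.
#' @export
glance.segment_assignment <- function(x, ...) {
  prov <- x$segment_provenance$provenance
  tibble::tibble(
    n_genes = nrow(x$assignment),
    n_segments = x$n_segments,
    n_curated_merged = sum(grepl("curated_merge", prov, fixed = TRUE)),
    n_correlation_merged = sum(grepl("correlation_merge", prov, fixed = TRUE))
  )
}

#' Write a segment assignment as TSV
#' @param segments A `segment_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(tidy(segments), path, na = "NA", progress = FALSE)
  invisible(path)
}
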