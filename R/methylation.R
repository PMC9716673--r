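#' Filter methylation probes by detection quality and SNP masking
#'
#' Applies the three probe-level quality filters, in order:
#'
#' 1. each beta value whose detection p value is `>= cell_p_cutoff`
#'    (default 1e-3, inclusive) is set to missing for that cell line;
#' 2. each probe whose *median* detection p value across cell lines is
#'    `>= probe_median_cutoff` (default 1e-6, inclusive) is dropped entirely
#'    (the median is computed over all cell lines with a detection p value,
#'    before the cell-level masking, so the probe-drop criterion does not
#'    depend on step 1);
#' 3. each probe flagged `snp_masked` in the annotation (probes overlapping
#'    single nucleotide polymorphisms) is dropped.
#'
#' @param beta Cell-line x probe matrix of methylation beta values in \[0,1\].
#' @param detection_p Matrix of detection p values, same shape and ids as
#'   `beta`.
#' @param annotation Probe annotation tibble ([read_probe_annotation()]);
#'   must cover every probe retained after the detection filters.
#' @param cell_p_cutoff,probe_median_cutoff Inclusive exclusion thresholds.
#' @return The filtered beta matrix (possibly with fewer probe columns and
#'   additional missing cells).
#' @export
filter_probes <- function(beta, detection_p, annotation,
                          cell_p_cutoff = 1e-3, probe_median_cutoff = 1e-6) {
  stopifnot(is.matrix(beta), is.matrix(detection_p))
  if (!identical(dim(beta), dim(detection_p))) {
    stop("beta and detection_p differ in shape", call. = FALSE)
  }
  missing_probe <- setdiff(colnames(beta), colnames(detection_p))
  if (length(missing_probe) > 0) {
    stop("probe(s) absent from detection_p: ",
         paste(utils::head(missing_probe, 5), collapse = ", "), call. = FALSE)
  }
  if (!identical(rownames(beta), rownames(detection_p))) {
    detection_p <- detection_p[rownames(beta), , drop = FALSE]
  }
  detection_p <- detection_p[, colnames(beta), drop = FALSE]

  probe_median <- apply(detection_p, 2, stats::median, na.rm = TRUE)
  keep <- probe_median < probe_median_cutoff
  snp_probes <- unique(annotation$probe_id[annotation$snp_masked])
  keep <- keep & !(colnames(beta) %in% snp_probes)

  out <- beta
  out[!is.na(detection_p) & detection_p >= cell_p_cutoff] <- NA_real_
  out[, keep, drop = FALSE]
}

#' Average filtered probe betas over gene regions
#'
#' For each cell line and each (gene, region-group) pair, computes the
#' arithmetic mean of the non-missing beta values of the probes annotated to
#' that pair. A probe annotated to k gene-regions (overlapping genes are
#' common among imprinted loci) contributes to all k. Output columns are
#' named `"GENE|REGION"`; a cell is missing when no probe contributes.
#'
#' @param filtered_beta Cell-line x probe beta matrix ([filter_probes()]).
#' @param annotation Probe annotation tibble; `region_group` must be drawn
#'   from [GENE_REGION_GROUPS].
#' @return Cell-line x gene-region matrix of averaged betas in \[0,1\].
#' @export
average_gene_regions <- function(filtered_beta, annotation) {
  validate_probe_annotation(annotation)
  ann <- annotation |>
    dplyr::filter(.data$probe_id %in% colnames(filtered_beta)) |>
    dplyr::distinct(.data$probe_id, .data$gene_symbol, .data$region_group)
  if (nrow(ann) == 0) {
    return(matrix(numeric(0), nrow = nrow(filtered_beta), ncol = 0,
                  dimnames = list(rownames(filtered_beta), character(0))))
  }
  region_id <- paste(ann$gene_symbol, ann$region_group, sep = "|")
  regions <- sort(unique(region_id))
  # probe -> region incidence matrix; missing-aware mean via two products
  Z <- matrix(0, nrow = ncol(filtered_beta), ncol = length(regions),
              dimnames = list(colnames(filtered_beta), regions))
  Z[cbind(ann$probe_id, region_id)] <- 1
  B <- filtered_beta
  obs <- !is.na(B)
  B[!obs] <- 0
  sums <- B %*% Z
  counts <- obs %*% Z
  avg <- sums / counts
  avg[counts == 0] <- NA_real_
  avg
}

#' Summarise the beta-value distribution per gene-region group
#'
#' Imprinted differentially methylated regions carry one methylated and one
#' unmethylated allele, so their region-averaged beta values cluster near
#' 0.5 ("hemimethylation") rather than near 0 or 1. This summary pools
#' non-missing gene-region-averaged betas across cell lines within each
#' region group (plus a pooled `"all"` group) and reports a histogram and
#' the fractions of values falling in configurable low / hemimethylated /
#' high windows (all window bounds inclusive).
#'
#' @param region_beta Cell-line x gene-region matrix from
#'   [average_gene_regions()] (columns named `"GENE|REGION"`).
#' @param hemi_window,low_window,high_window Length-2 numeric intervals
#'   inside \[0,1\].
#' @param n_bins Number of equal-width histogram bins on \[0,1\] (>= 2).
#' @return An object of class `hemimeth_summary`: a tibble with one row per
#'   region group (and `"all"`), columns `region_group`, `n_values`,
#'   `low_fraction`, `hemimethylated_fraction`, `high_fraction`, and a
#'   list-column `histogram` of tibbles (`bin_left`, `bin_right`, `count`).
#' @export
hemimethylation_summary <- function(region_beta, hemi_window = c(0.4, 0.6),
                                    n_bins = 50, low_window = c(0, 0.2),
                                    high_window = c(0.8, 1)) {
  if (!is.matrix(region_beta) || length(region_beta) == 0) {
    stop("region_beta is empty", call. = FALSE)
  }
  stopifnot(n_bins >= 2, length(hemi_window) == 2,
            hemi_window[1] >= 0, hemi_window[2] <= 1)
  groups <- sub("^.*\\|", "", colnames(region_beta))
  edges <- seq(0, 1, length.out = n_bins + 1)
  summarise_values <- function(v, label) {
    v <- v[!is.na(v)]
    cnt <- if (length(v) == 0) integer(n_bins) else
      as.integer(graphics::hist(v, breaks = edges, plot = FALSE,
                                include.lowest = TRUE, right = TRUE)$counts)
    tibble::tibble(
      region_group = label,
      n_values = length(v),
      low_fraction = if (length(v)) mean(v >= low_window[1] & v <= low_window[2]) else NA_real_,
      hemimethylated_fraction = if (length(v)) mean(v >= hemi_window[1] & v <= hemi_window[2]) else NA_real_,
      high_fraction = if (length(v)) mean(v >= high_window[1] & v <= high_window[2]) else NA_real_,
      histogram = list(tibble::tibble(bin_left = edges[-length(edges)],
                                      bin_right = edges[-1], count = cnt))
    )
  }
  present <- GENE_REGION_GROUPS[GENE_REGION_GROUPS %in% groups]
  per_group <- purrr::map(present, function(g) {
    summarise_values(as.vector(region_beta[, groups == g, drop = FALSE]), g)
  })
  out <- dplyr::bind_rows(c(per_group,
                            list(summarise_values(as.vector(region_beta), "all"))))
  class(out) <- c("hemimeth_summary", class(out))
  out
}

#' Plot beta-value distributions per gene-region group
#'
#' Faceted histograms of the pooled gene-region-averaged beta values; a peak
#' near 0.5 in the TSS200 / 5'UTR / 1stExon facets is the hemimethylation
#' signature of imprinted promoters.
#'
#' @param object A `hemimeth_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hemimeth_summary <- function(object, ...) {
  df <- tidyr::unnest(tibble::as_tibble(object)[, c("region_group", "histogram")],
                      "histogram")
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = df$bin_right[1] - df$bin_left[1],
                      fill = "steelblue") +
    ggplot2::facet_wrap(~region_group, scales = "free_y") +
    ggplot2::labs(x = "gene-region-averaged methylation beta",
                  y = "gene-region count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write gene-region betas / distribution summaries as TSV
#' @param x Matrix or `hemimeth_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hemimeth_summary <- function(x, path) {
  flat <- tibble::as_tibble(x)[, c("region_group", "n_values", "low_fraction",
                                   "hemimethylated_fraction", "high_fraction")]
  readr::write_tsv(flat, path, na = "NA", progress = FALSE)
  invisible(path)
}
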