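#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment: sort the m non-missing p
#' values ascending, set q_(i) = p_(i) * m / i, enforce monotone
#' non-increase from the largest rank down, cap at 1, and return values in
#' the input order. Missing entries pass through as missing and are excluded
#' from m. Adjusted values are always >= the raw values.
#'
#' @param p Numeric vector of p values in \[0, 1\] (NA allowed).
#' @return Vector of adjusted p values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' bh_adjust(c(0.005, 0.5))              # 0.01, 0.5
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Conservative segment-grouped FDR adjustment
#'
#' Copy-number values of genes in one chromosomal segment are strongly
#' correlated, so treating each gene as an independent test would overcount
#' the family. This procedure instead represents each segment once, by its
#' *least* favourable member: for each (segment, agent\[, stratum\]) group
#' the highest raw p value among the member genes present is taken as the
#' segment's representative, the representatives form one BH family (all
#' segment x agent x stratum combinations pooled), and every member gene of
#' a segment inherits that segment's adjusted p for the given agent. Genes
#' in the same segment therefore share an identical adjusted p
#' (`p_adjusted`, the segment-grouped FDR p) per agent.
#'
#' @param records Association record tibble ([run_association_screen()])
#'   whose `feature_id` values are gene symbols.
#' @param segments A `segment_assignment` from [assign_segments()] (or a
#'   tibble with `gene_symbol`, `segment_id`).
#' @return The records with `segment_id`, `p_adjusted`, and
#'   `adjustment_mode = "segment_max_p"` added.
#' @export
segment_fdr <- function(records, segments) {
  map_tbl <- if (inherits(segments, "segment_assignment")) segments$assignment else segments
  lookup <- stats::setNames(map_tbl$segment_id, map_tbl$gene_symbol)
  unmapped <- setdiff(unique(records$feature_id), names(lookup))
  if (length(unmapped) > 0) {
    stop("gene(s) with no segment assignment: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  if (!"stratum" %in% colnames(records)) records$stratum <- "pancancer"
  rec <- records
  rec$segment_id <- unname(lookup[rec$feature_id])

  reps <- rec |>
    dplyr::group_by(.data$segment_id, .data$agent_id, .data$stratum) |>
    dplyr::summarise(p_rep = max(.data$p0), .groups = "drop")
  reps$p_adj <- bh_adjust(reps$p_rep)

  rec |>
    dplyr::left_join(dplyr::select(reps, "segment_id", "agent_id", "stratum",
                                   "p_adj"),
                     by = c("segment_id", "agent_id", "stratum")) |>
    dplyr::mutate(p_adjusted = .data$p_adj,
                  adjustment_mode = "segment_max_p") |>
    dplyr::select(-"p_adj")
}

#' Per-feature BH adjustment of association records
#'
#' The adjustment used for expression and methylation screens, where genes
#' (or gene regions) are treated as independent of one another: one BH
#' family over all records present (features x agents, with any strata
#' pooled), excluding skipped correlations from the family size.
#'
#' @param records Association record tibble.
#' @return Records with `p_adjusted` and `adjustment_mode =
#'   "per_feature_bh"` added.
#' @export
bh_adjust_records <- function(records) {
  records$p_adjusted <- bh_adjust(records$p0)
  records$adjustment_mode <- "per_feature_bh"
  records
}

#' Filter records to the significant associations
#'
#' Retains records with adjusted p below the FDR level and absolute Spearman
#' rho above the effect-size threshold. `relaxed = TRUE` uses the relaxed
#' threshold (default 0.25) that defines the expanded association list;
#' the default strict threshold (0.3) defines the headline list.
#'
#' @param records Records carrying `p_adjusted`.
#' @param spec A [screen_spec()].
#' @param relaxed Use `spec$relaxed_rho_threshold` instead of
#'   `spec$rho_threshold`.
#' @return The retained records.
#' @export
flag_significant <- function(records, spec = screen_spec(), relaxed = FALSE) {
  if (!"p_adjusted" %in% colnames(records)) {
    stop("records carry no p_adjusted; run an adjustment first", call. = FALSE)
  }
  thr <- if (relaxed) spec$relaxed_rho_threshold else spec$rho_threshold
  dplyr::filter(records, !is.na(.data$p_adjusted),
                .data$p_adjusted < spec$fdr_alpha,
                abs(.data$spearman_rho) > thr)
}
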