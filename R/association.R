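#' Prepare a drug-response matrix from raw IC50 values
#'
#' Transforms all IC50 measures to the log10(IC50) scale (larger = more
#' resistant) and collapses duplicate measurements: when an agent appears as
#' several columns with the same identifier (duplicate experiments from one
#' source), the columns are averaged per cell line on the log10 scale,
#' missing-aware. Agents measured by different sources must carry distinct
#' identifiers (e.g. a source suffix) and are never merged across sources;
#' they remain separate response measures.
#'
#' @param raw_ic50 Cell-line x agent matrix of strictly positive IC50
#'   values, possibly with repeated column names.
#' @return A list of class `drug_response_prep` with `response` (cell-line x
#'   agent log10 IC50 matrix, one column per agent) and `agent_provenance`
#'   (tibble: `agent_id`, `n_measurements`, `collapsed`).
#' @examples
#' ic50 <- matrix(c(10, 100, 1000, 10), 2, 2,
#'                dimnames = list(c("cl1", "cl2"), c("drugA", "drugA")))
#' prepare_response(ic50)$response
#' @export
prepare_response <- function(raw_ic50) {
  stopifnot(is.matrix(raw_ic50))
  bad <- which(!is.na(raw_ic50) & raw_ic50 <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("nonpositive IC50 at row '%s', column '%s'",
                 rownames(raw_ic50)[bad[1, 1]], colnames(raw_ic50)[bad[1, 2]]),
         call. = FALSE)
  }
  lg <- log10(raw_ic50)
  agents <- unique(colnames(lg))
  resp <- matrix(NA_real_, nrow = nrow(lg), ncol = length(agents),
                 dimnames = list(rownames(lg), agents))
  n_meas <- integer(length(agents))
  for (k in seq_along(agents)) {
    idx <- which(colnames(lg) == agents[k])
    n_meas[k] <- length(idx)
    resp[, k] <- rowMeans(lg[, idx, drop = FALSE], na.rm = TRUE)
  }
  resp[is.nan(resp)] <- NA_real_
  structure(list(
    response = resp,
    agent_provenance = tibble::tibble(agent_id = agents,
                                      n_measurements = n_meas,
                                      collapsed = n_meas > 1)
  ), class = "drug_response_prep")
}

#' @export
print.drug_response_prep <- function(x, ...) {
  cat("<drug_response_prep> ", nrow(x$response), " cell lines x ",
      ncol(x$response), " agents (", sum(x$agent_provenance$collapsed),
      " duplicate-collapsed)\n", sep = "")
  invisible(x)
}

#' Screen specification
#'
#' Bundles the tunable parameters of an association screen: the minimum
#' pairwise-complete sample size per correlation, the minimum cell-line
#' count for a cancer category to be analysed in stratified mode, the
#' headline and relaxed absolute-Spearman effect-size thresholds, and the
#' FDR level.
#'
#' @param min_pairs Minimum pairwise-complete n for a correlation (>= 3).
#' @param min_stratum_size Minimum cell-line count per analysed category.
#' @param rho_threshold,relaxed_rho_threshold Absolute Spearman thresholds
#'   in (0, 1\].
#' @param fdr_alpha FDR significance level in (0, 1).
#' @return A list of class `screen_spec`.
#' @export
screen_spec <- function(min_pairs = 10L, min_stratum_size = 10L,
                        rho_threshold = 0.3, relaxed_rho_threshold = 0.25,
                        fdr_alpha = 0.05) {
  stopifnot(min_pairs >= 3, min_stratum_size >= 3,
            rho_threshold > 0, rho_threshold <= 1,
            relaxed_rho_threshold > 0, relaxed_rho_threshold <= 1,
            fdr_alpha > 0, fdr_alpha < 1)
  structure(list(min_pairs = as.integer(min_pairs),
                 min_stratum_size = as.integer(min_stratum_size),
                 rho_threshold = rho_threshold,
                 relaxed_rho_threshold = relaxed_rho_threshold,
                 fdr_alpha = fdr_alpha),
            class = "screen_spec")
}

# two-sided p from a correlation coefficient via the t approximation, n-2 df
cor_p_value <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2 & abs(r) < 1
  tstat <- r[ok] * sqrt((n[ok] - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n[ok] - 2)
  p[!is.na(r) & abs(r) >= 1 & n > 2] <- 0
  p
}

#' Correlate two paired vectors (Spearman and Pearson)
#'
#' Pairwise-complete deletion, then the Spearman coefficient computed as the
#' Pearson correlation of midranks (average ranks for ties) and the Pearson
#' coefficient on the raw values. Both p values come from the two-sided t
#' approximation with n - 2 degrees of freedom. Symmetric in `(x, y)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_pairs Minimum pairwise-complete n; below it the correlation is
#'   skipped (`reason = "insufficient_n"`).
#' @return One-row tibble: `n`, `spearman_rho`, `spearman_p`, `pearson_r`,
#'   `pearson_p`, `reason` (`NA` when computed; `"insufficient_n"` or
#'   `"constant_input"` otherwise).
#' @examples
#' correlate(c(1, 2, 3), c(3, 1, 2), min_pairs = 3)  # rho = -0.5
#' @export
correlate <- function(x, y, min_pairs = 10L) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_pairs) {
    return(tibble::tibble(n = n, spearman_rho = NA_real_, spearman_p = NA_real_,
                          pearson_r = NA_real_, pearson_p = NA_real_,
                          reason = "insufficient_n"))
  }
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(tibble::tibble(n = n, spearman_rho = NA_real_, spearman_p = NA_real_,
                          pearson_r = NA_real_, pearson_p = NA_real_,
                          reason = "constant_input"))
  }
  rho <- stats::cor(rank(xs), rank(ys))
  r <- stats::cor(xs, ys)
  tibble::tibble(n = n,
                 spearman_rho = rho, spearman_p = cor_p_value(rho, n),
                 pearson_r = r, pearson_p = cor_p_value(r, n),
                 reason = NA_character_)
}

# all-pairs correlation screen between the columns of X (features) and
# Y (agents); fast matrix path when both are complete, per-pair otherwise
# (pairwise-complete Spearman requires re-ranking within each complete set).
screen_correlations <- function(X, Y, min_pairs) {
  stopifnot(identical(rownames(X), rownames(Y)))
  nX <- ncol(X); nY <- ncol(Y)
  if (nX == 0 || nY == 0) return(NULL)
  if (!anyNA(X) && !anyNA(Y)) {
    n <- nrow(X)
    if (n < min_pairs) return(NULL)
    RX <- apply(X, 2, rank); RY <- apply(Y, 2, rank)
    sd0x <- apply(X, 2, stats::sd) == 0
    sd0y <- apply(Y, 2, stats::sd) == 0
    rho <- suppressWarnings(stats::cor(RX, RY))
    r <- suppressWarnings(stats::cor(X, Y))
    rho[sd0x, ] <- NA_real_; rho[, sd0y] <- NA_real_
    r[sd0x, ] <- NA_real_; r[, sd0y] <- NA_real_
    out <- tibble::tibble(
      feature_id = rep(colnames(X), times = nY),
      agent_id = rep(colnames(Y), each = nX),
      n = n,
      spearman_rho = as.vector(rho),
      pearson_r = as.vector(r)
    )
    out$p0 <- cor_p_value(out$spearman_rho, out$n)
    out$pearson_p0 <- cor_p_value(out$pearson_r, out$n)
    out$reason <- ifelse(is.na(out$spearman_rho), "constant_input", NA_character_)
    return(out)
  }
  grid <- expand.grid(fi = seq_len(nX), ai = seq_len(nY))
  res <- purrr::map2(grid$fi, grid$ai, function(fi, ai) {
    correlate(X[, fi], Y[, ai], min_pairs = min_pairs)
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::bind_cols(tibble::tibble(feature_id = colnames(X)[grid$fi],
                                         agent_id = colnames(Y)[grid$ai]), out)
  dplyr::rename(out, p0 = "spearman_p", pearson_p0 = "pearson_p")
}

#' Run a correlation screen of molecular features versus drug response
#'
#' Correlates every feature (gene copy number, gene expression, or
#' gene-region methylation) with every agent's log10(IC50), pancancer and —
#' when cell-line metadata are supplied and `strata = "by_category"` —
#' separately within each cancer category having at least
#' `spec$min_stratum_size` cell lines. Correlations are pairwise-complete;
#' pairs with fewer than `spec$min_pairs` complete observations are dropped.
#' Records carry raw p values only; multiple-testing adjustment is a
#' separate stage ([bh_adjust_records()], [segment_fdr()]).
#'
#' @param features Cell-line x feature matrix.
#' @param prep A `drug_response_prep` from [prepare_response()] (or a
#'   log10 IC50 matrix).
#' @param feature_kind `"copy_number"`, `"expression"`, or
#'   `"methylation_region"`.
#' @param metadata Optional tibble with columns `cell_line`,
#'   `cancer_category`.
#' @param strata `"pancancer"` (default) or `"by_category"`.
#' @param spec A [screen_spec()].
#' @return A tibble of association records: `feature_id`, `feature_kind`,
#'   `agent_id`, `stratum`, `n`, `spearman_rho`, `pearson_r`, `p0` (raw
#'   Spearman p), `pearson_p0`. Deterministic order (stratum, feature,
#'   agent).
#' @export
run_association_screen <- function(features, prep,
                                   feature_kind = c("copy_number", "expression",
                                                    "methylation_region"),
                                   metadata = NULL,
                                   strata = c("pancancer", "by_category"),
                                   spec = screen_spec()) {
  feature_kind <- match.arg(feature_kind)
  strata <- match.arg(strata)
  response <- if (inherits(prep, "drug_response_prep")) prep$response else prep
  shared <- intersect(rownames(features), rownames(response))
  if (length(shared) == 0) {
    stop("no cell lines shared between features and response", call. = FALSE)
  }
  shared <- sort(shared)
  X <- features[shared, , drop = FALSE]
  Y <- response[shared, , drop = FALSE]

  run_one <- function(rows, label) {
    rec <- screen_correlations(X[rows, , drop = FALSE], Y[rows, , drop = FALSE],
                               min_pairs = spec$min_pairs)
    if (is.null(rec) || nrow(rec) == 0) return(NULL)
    rec |>
      dplyr::filter(is.na(.data$reason)) |>
      dplyr::mutate(feature_kind = feature_kind, stratum = label) |>
      dplyr::select("feature_id", "feature_kind", "agent_id", "stratum", "n",
                    "spearman_rho", "pearson_r", "p0", "pearson_p0")
  }

  if (strata == "pancancer") {
    out <- run_one(shared, "pancancer")
  } else {
    if (is.null(metadata)) stop("stratified screen needs metadata", call. = FALSE)
    meta <- metadata[metadata$cell_line %in% shared, , drop = FALSE]
    sizes <- table(meta$cancer_category)
    cats <- sort(names(sizes)[sizes >= spec$min_stratum_size])
    out <- purrr::map(cats, function(cc) {
      run_one(meta$cell_line[meta$cancer_category == cc], cc)
    }) |> dplyr::bind_rows()
  }
  if (is.null(out)) out <- tibble::tibble(
    feature_id = character(), feature_kind = character(), agent_id = character(),
    stratum = character(), n = integer(), spearman_rho = numeric(),
    pearson_r = numeric(), p0 = numeric(), pearson_p0 = numeric())
  dplyr::arrange(out, .data$stratum, .data$feature_id, .data$agent_id)
}

#' Volcano-style plot of an association screen
#'
#' Absolute effect size (Spearman rho) against -log10 raw p, with the
#' effect-size threshold drawn as vertical lines.
#'
#' @param records Association record tibble.
#' @param rho_threshold Threshold drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_association_volcano <- function(records, rho_threshold = 0.3) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$spearman_rho,
                                        y = -log10(.data$p0))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-rho_threshold, rho_threshold),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Spearman rho (feature vs log10 IC50)",
                  y = "-log10 raw p") +
    ggplot2::theme_minimal()
}
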