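#' Round continuous copy number to integer estimates
#'
#' Continuous gene-level copy-number values (segmented array log-ratios
#' mapped back to the copy-number scale) are kept for all association
#' screens; rounded integer estimates serve summaries and plots only. Values
#' are rounded to the nearest integer with .5 ties rounded away from zero
#' (so 2.5 becomes 3), negatives are clamped to 0 (a copy number cannot be
#' negative), and missing values are preserved. Rounding is monotone.
#'
#' @param cn Numeric matrix (or vector) of continuous copy number.
#' @return Integer-valued object of the same shape.
#' @examples
#' round_copy_number(c(1.49, 2.5, 2.51, -0.2))
#' @export
round_copy_number <- function(cn) {
  out <- sign(cn) * floor(abs(cn) + 0.5)
  pmax(out, 0)
}

# half-away-from-zero decimal rounding (base round() is round-half-even)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-gene summaries of rounded copy number
#'
#' For each gene: the number of cell lines with data, median and range of the
#' rounded copy number, and the count and percentage of lines with a loss
#' (rounded value `<= loss_threshold`, default 1: loss of at least one copy)
#' or a gain (rounded value `>= gain_threshold`, default 3: more than two
#' copies). Percentages are `100 * count / n`, rounded half-away-from-zero
#' to one decimal place.
#'
#' @param rounded Integer-valued cell-line x gene matrix from
#'   [round_copy_number()].
#' @param loss_threshold,gain_threshold Integer thresholds,
#'   `loss_threshold < gain_threshold`.
#' @return A tibble with one row per gene: `gene_symbol`, `n`,
#'   `median_rounded`, `min_rounded`, `max_rounded`, `n_loss`, `n_gain`,
#'   `pct_loss`, `pct_gain`. A gene with no non-missing values gets `n = 0`
#'   and missing statistics.
#' @export
summarize_copy_number <- function(rounded, loss_threshold = 1L,
                                  gain_threshold = 3L) {
  stopifnot(is.matrix(rounded), loss_threshold < gain_threshold)
  per_gene <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0) {
      return(tibble::tibble(n = 0L, median_rounded = NA_real_,
                            min_rounded = NA_real_, max_rounded = NA_real_,
                            n_loss = NA_integer_, n_gain = NA_integer_,
                            pct_loss = NA_real_, pct_gain = NA_real_))
    }
    n_loss <- sum(v <= loss_threshold)
    n_gain <- sum(v >= gain_threshold)
    tibble::tibble(n = n, median_rounded = stats::median(v),
                   min_rounded = min(v), max_rounded = max(v),
                   n_loss = n_loss, n_gain = n_gain,
                   pct_loss = round_half_away(100 * n_loss / n, 1),
                   pct_gain = round_half_away(100 * n_gain / n, 1))
  }
  purrr::map(colnames(rounded), function(g) {
    dplyr::bind_cols(tibble::tibble(gene_symbol = g), per_gene(rounded[, g]))
  }) |> dplyr::bind_rows()
}

#' Histogram of rounded copy number for one gene
#'
#' @param rounded Integer-valued matrix from [round_copy_number()].
#' @param gene Gene (column) to plot.
#' @return A ggplot object.
#' @export
plot_copy_number_histogram <- function(rounded, gene) {
  if (!gene %in% colnames(rounded)) stop("gene not in matrix: ", gene, call. = FALSE)
  df <- tibble::tibble(copies = rounded[, gene])
  df <- df[!is.na(df$copies), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$copies)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::scale_x_continuous(breaks = seq(0, max(df$copies))) +
    ggplot2::labs(title = gene, x = "rounded copy number", y = "cell lines") +
    ggplot2::theme_minimal()
}
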