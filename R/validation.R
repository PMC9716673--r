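#' Validate expression-response associations in an external cohort
#'
#' Mirrors the validation stage run on an AML patient cohort: for each gene
#' of a small panel and each agent of a small panel, correlates tumor
#' specimen gene expression with ex vivo log10(IC50) over all specimens with
#' both measures, then BH-adjusts the Spearman-derived and Pearson-derived p
#' values in *separate* families, each family being all computed gene x
#' agent pairs of the panel. Two flag pairs are set: `pass_relaxed`
#' (|rho| > 0.25 and Spearman p_fdr < 0.1) and `pass_strict` (|rho| > 0.3
#' and p_fdr < 0.1); strict implies relaxed.
#'
#' @param expr Specimen x gene expression matrix (log2 RPKM scale or
#'   similar; correlations are rank-based for the headline statistic).
#' @param ex_vivo_ic50 Specimen x agent log10 IC50 matrix — transform raw
#'   IC50 with [prepare_response()] first (a `drug_response_prep` is also
#'   accepted).
#' @param gene_panel,agent_panel Non-empty character vectors naming the
#'   columns to analyse.
#' @param min_pairs Minimum pairwise-complete specimen count.
#' @param fdr_alpha FDR level for the pass flags (default 0.1).
#' @param relaxed_rho,strict_rho Absolute-rho thresholds for the two flags.
#' @return Tibble of validation records: `gene_symbol`, `agent_id`, `n`,
#'   `spearman_rho`, `pearson_r`, `p0`, `p_fdr`, `pearson_p0`,
#'   `pearson_p_fdr`, `pass_relaxed`, `pass_strict`.
#' @export
validate_expression_response <- function(expr, ex_vivo_ic50, gene_panel,
                                         agent_panel, min_pairs = 10L,
                                         fdr_alpha = 0.1,
                                         relaxed_rho = 0.25, strict_rho = 0.3) {
  if (inherits(ex_vivo_ic50, "drug_response_prep")) {
    ex_vivo_ic50 <- ex_vivo_ic50$response
  }
  stopifnot(length(gene_panel) > 0, length(agent_panel) > 0)
  missing_g <- setdiff(gene_panel, colnames(expr))
  if (length(missing_g) > 0) {
    stop("panel gene(s) absent from expression: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  missing_a <- setdiff(agent_panel, colnames(ex_vivo_ic50))
  if (length(missing_a) > 0) {
    stop("panel agent(s) absent from response: ",
         paste(missing_a, collapse = ", "), call. = FALSE)
  }
  shared <- sort(intersect(rownames(expr), rownames(ex_vivo_ic50)))
  if (length(shared) == 0) stop("no shared specimens", call. = FALSE)
  rec <- screen_correlations(expr[shared, gene_panel, drop = FALSE],
                             ex_vivo_ic50[shared, agent_panel, drop = FALSE],
                             min_pairs = min_pairs)
  if (is.null(rec)) stop("no computable gene-agent pairs", call. = FALSE)
  rec <- dplyr::filter(rec, is.na(.data$reason))
  rec$p_fdr <- bh_adjust(rec$p0)
  rec$pearson_p_fdr <- bh_adjust(rec$pearson_p0)
  rec |>
    dplyr::mutate(gene_symbol = .data$feature_id,
                  pass_relaxed = abs(.data$spearman_rho) > relaxed_rho &
                    .data$p_fdr < fdr_alpha,
                  pass_strict = abs(.data$spearman_rho) > strict_rho &
                    .data$p_fdr < fdr_alpha) |>
    dplyr::select("gene_symbol", "agent_id", "n", "spearman_rho", "pearson_r",
                  "p0", "p_fdr", "pearson_p0", "pearson_p_fdr",
                  "pass_relaxed", "pass_strict") |>
    dplyr::arrange(dplyr::desc(abs(.data$spearman_rho)), .data$gene_symbol,
                   .data$agent_id)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of the survival experience of two groups
#' (e.g. patients with versus without a cytogenetic 20q loss). At each
#' distinct event time the observed number of events in group 1 is compared
#' with its expectation under the hypergeometric model given the risk sets;
#' the statistic is (sum of O - E)^2 / (sum of variances), chi-squared with
#' 1 df under the null. Tied event times use the standard hypergeometric
#' variance for ties; censored subjects remain in the risk set up to and
#' including their censoring time.
#'
#' @param survival_table Tibble with `time_days` (or `time`), `event`
#'   (logical/0-1), and the grouping column.
#' @param group_col Name of the logical grouping column (default
#'   `"group_flag"`).
#' @return Object of class `logrank_result`: list with `chi_square`,
#'   `p_value`, `n_group1` (flag TRUE), `n_group2`, `observed`, `expected`
#'   (group-1 totals), and `variance`.
#' @export
logrank_test <- function(survival_table, group_col = "group_flag") {
  tcol <- if ("time_days" %in% colnames(survival_table)) "time_days" else "time"
  time <- as.numeric(survival_table[[tcol]])
  event <- as.logical(survival_table$event)
  group <- as.logical(survival_table[[group_col]])
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- group[keep]
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  n1 <- sum(group); n2 <- sum(!group)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)

  event_times <- sort(unique(time[event]))
  if (length(event_times) == 0) {
    res <- list(chi_square = 0, p_value = 1, n_group1 = n1, n_group2 = n2,
                observed = 0, expected = 0, variance = 0)
    class(res) <- "logrank_result"
    return(res)
  }
  o1 <- e1 <- v1 <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group)
    d_t <- sum(event & time == t)
    d1_t <- sum(event & time == t & group)
    o1 <- o1 + d1_t
    e1 <- e1 + d_t * n1_t / n_t
    if (n_t > 1) {
      v1 <- v1 + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  chi <- if (v1 > 0) (o1 - e1)^2 / v1 else 0
  res <- list(chi_square = chi,
              p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
              n_group1 = n1, n_group2 = n2,
              observed = o1, expected = e1, variance = v1)
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Two-group log-rank test: chi-square = %.4f (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  cat(sprintf("  group 1: n = %d, observed events = %g, expected = %.3f\n",
              x$n_group1, x$observed, x$expected))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_result`.
#' @param ... Unused.
#' @export
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(statistic = x$chi_square, p.value = x$p_value, df = 1,
                 observed = x$observed, expected = x$expected,
                 variance = x$variance)
}

#' @rdname logrank_test
#' @export
glance.logrank_result <- function(x, ...) {
  tibble::tibble(statistic = x$chi_square, p.value = x$p_value,
                 n_group1 = x$n_group1, n_group2 = x$n_group2)
}

#' Kaplan-Meier-style survival curves by group
#'
#' Product-limit survival estimates per group, for visual accompaniment of
#' [logrank_test()].
#'
#' @param survival_table As in [logrank_test()].
#' @param group_col Grouping column name.
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(survival_table, group_col = "group_flag") {
  tcol <- if ("time_days" %in% colnames(survival_table)) "time_days" else "time"
  df <- tibble::tibble(time = as.numeric(survival_table[[tcol]]),
                       event = as.logical(survival_table$event),
                       group = as.logical(survival_table[[group_col]]))
  km_one <- function(d) {
    d <- d[order(d$time), ]
    ts <- sort(unique(d$time[d$event]))
    s <- cumprod(vapply(ts, function(t) {
      1 - sum(d$event & d$time == t) / sum(d$time >= t)
    }, numeric(1)))
    tibble::tibble(time = c(0, ts), surv = c(1, s))
  }
  curves <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~km_one(.x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = "group") +
    ggplot2::theme_minimal()
}
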