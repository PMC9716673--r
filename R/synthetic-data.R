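#' Configuration for the synthetic pharmacogenomic cohort generator
#'
#' Bundles and validates every knob of [generate_dataset()]. The defaults
#' emulate the scale and statistical structure of a pancancer cell-line
#' pharmacogenomic screen of imprinted genes: 645 cell lines in 22 cancer
#' categories, 198 genes spread over 35 chromosomal segments, continuous
#' copy number centred near 2 with strong within-segment correlation and
#' occasional segment gain/loss or focal amplification, expression
#' positively coupled to copy number, methylation betas drawn from
#' low/hemimethylated/high mixtures whose hemimethylated (beta near 0.5)
#' component concentrates in the TSS200, 5'UTR, and first-exon regions, and
#' 275 drug-response measures with optional planted monotone copy-number
#' effects.
#'
#' @param n_cell_lines Number of cell lines.
#' @param n_categories Number of cancer categories.
#' @param category_sizes Integer vector summing to `n_cell_lines`
#'   (default: near-equal split).
#' @param n_segments Number of chromosomal segments.
#' @param genes_per_segment Integer vector (recycled) of genes per segment;
#'   the default places 198 genes in 35 segments.
#' @param within_segment_cn_correlation Equicorrelation of the Gaussian
#'   log-ratio component of copy number within a segment, in \[0, 1\].
#' @param cn_baseline Copy-number centre (diploid = 2).
#' @param cn_event_rates Named probabilities `c(gain = , loss = )` of a
#'   segment-level gain/loss per cell line.
#' @param focal_amp_rate Probability of a high-level focal amplification.
#' @param expression_cn_coupling Slope tying log2 expression to the
#'   standardized copy-number latent.
#' @param beta_mixture_weights 6 x 3 matrix (rows named by
#'   [GENE_REGION_GROUPS], columns `low`, `hemi`, `high`) of mixture
#'   weights; each row sums to 1.
#' @param planted_effects Tibble/data.frame with columns `segment`
#'   (1-based segment index), `agent` (1-based agent index), `rho` (target
#'   population Spearman correlation between segment copy number and
#'   log10 IC50).
#' @param n_agents Number of agents.
#' @param duplicate_agent_ids 1-based indices of agents measured twice
#'   (emitted as two raw columns).
#' @param missing_rate Completely-at-random missingness probability
#'   applied to each data matrix, in \[0, 1).
#' @param detection_p_noise_rate Probability that a single beta measurement
#'   has a failed detection p value (>= 1e-3).
#' @param seed Integer RNG seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cell_lines = 645L,
                             n_categories = 22L,
                             category_sizes = NULL,
                             n_segments = 35L,
                             genes_per_segment = NULL,
                             within_segment_cn_correlation = 0.8,
                             cn_baseline = 2,
                             cn_event_rates = c(gain = 0.15, loss = 0.08),
                             focal_amp_rate = 0.01,
                             expression_cn_coupling = 1,
                             beta_mixture_weights = default_beta_weights(),
                             planted_effects = NULL,
                             n_agents = 275L,
                             duplicate_agent_ids = seq_len(min(5L, n_agents)),
                             missing_rate = 0.02,
                             detection_p_noise_rate = 0.01,
                             seed = 1L) {
  fail <- function(inv) stop("invalid synthetic_config: ", inv, call. = FALSE)
  if (n_cell_lines < 1) fail("n_cell_lines must be a positive count")
  if (n_categories < 1) fail("n_categories must be a positive count")
  if (n_segments < 1) fail("n_segments must be a positive count")
  if (n_agents < 1) fail("n_agents must be a positive count")
  if (is.null(category_sizes)) {
    base <- n_cell_lines %/% n_categories
    category_sizes <- rep(base, n_categories)
    rem <- n_cell_lines - sum(category_sizes)
    if (rem > 0) category_sizes[seq_len(rem)] <- category_sizes[seq_len(rem)] + 1L
  }
  if (length(category_sizes) != n_categories || sum(category_sizes) != n_cell_lines) {
    fail("category_sizes must sum to n_cell_lines")
  }
  if (any(category_sizes < 1)) fail("category_sizes must be positive counts")
  if (is.null(genes_per_segment)) {
    genes_per_segment <- rep(5L, n_segments)
    extra <- min(n_segments, max(0L, 198L - 5L * n_segments))
    if (extra > 0) genes_per_segment[seq_len(extra)] <- 6L
  }
  genes_per_segment <- rep_len(as.integer(genes_per_segment), n_segments)
  if (any(genes_per_segment < 1)) fail("genes_per_segment must be positive counts")
  if (is.na(within_segment_cn_correlation) ||
      within_segment_cn_correlation < 0 || within_segment_cn_correlation > 1) {
    fail("within_segment_cn_correlation must lie in [0, 1]")
  }
  probs <- c(cn_event_rates, focal_amp_rate, missing_rate, detection_p_noise_rate)
  if (any(probs < 0 | probs > 1)) fail("all probabilities must lie in [0, 1]")
  if (sum(cn_event_rates) + focal_amp_rate > 1) {
    fail("cn_event_rates plus focal_amp_rate must not exceed 1")
  }
  if (missing_rate >= 1) fail("missing_rate must lie in [0, 1)")
  bw <- beta_mixture_weights
  if (!is.matrix(bw) || nrow(bw) != 6 || ncol(bw) != 3 ||
      !all(rownames(bw) %in% GENE_REGION_GROUPS)) {
    fail("beta_mixture_weights must be a 6 x 3 matrix with gene-region rownames")
  }
  if (any(bw < 0) || any(abs(rowSums(bw) - 1) > 1e-8)) {
    fail("beta_mixture_weights rows must be nonnegative and sum to 1")
  }
  if (is.null(planted_effects)) {
    planted_effects <- tibble::tibble(segment = integer(), agent = integer(),
                                      rho = numeric())
  }
  planted_effects <- tibble::as_tibble(planted_effects)
  if (nrow(planted_effects) > 0) {
    if (any(planted_effects$segment < 1 | planted_effects$segment > n_segments)) {
      fail("every planted segment index must lie in 1..n_segments")
    }
    if (any(planted_effects$agent < 1 | planted_effects$agent > n_agents)) {
      fail("every planted agent index must lie in 1..n_agents")
    }
    if (any(abs(planted_effects$rho) >= 1)) {
      fail("planted rho values must lie in (-1, 1)")
    }
  }
  if (length(duplicate_agent_ids) > 0 &&
      (any(duplicate_agent_ids < 1) || any(duplicate_agent_ids > n_agents))) {
    fail("duplicate_agent_ids must index agents in 1..n_agents")
  }
  structure(list(
    n_cell_lines = as.integer(n_cell_lines),
    n_categories = as.integer(n_categories),
    category_sizes = as.integer(category_sizes),
    n_segments = as.integer(n_segments),
    genes_per_segment = genes_per_segment,
    within_segment_cn_correlation = within_segment_cn_correlation,
    cn_baseline = cn_baseline,
    cn_event_rates = cn_event_rates,
    focal_amp_rate = focal_amp_rate,
    expression_cn_coupling = expression_cn_coupling,
    beta_mixture_weights = bw,
    planted_effects = planted_effects,
    n_agents = as.integer(n_agents),
    duplicate_agent_ids = as.integer(duplicate_agent_ids),
    missing_rate = missing_rate,
    detection_p_noise_rate = detection_p_noise_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default beta-value mixture weights per gene-region group
#'
#' Hemimethylation (component centred at beta 0.5) dominates the promoter-
#' proximal groups (TSS200, 5'UTR, 1stExon) of imprinted genes; gene bodies
#' and 3' UTRs are mostly fully methylated or unmethylated; TSS1500 sits in
#' between.
#' @return 6 x 3 matrix of mixture weights (`low`, `hemi`, `high`).
#' @export
default_beta_weights <- function() {
  w <- rbind(
    TSS1500 = c(0.40, 0.20, 0.40),
    TSS200  = c(0.20, 0.60, 0.20),
    "5'UTR" = c(0.20, 0.60, 0.20),
    "1stExon" = c(0.20, 0.60, 0.20),
    Body    = c(0.35, 0.10, 0.55),
    "3'UTR" = c(0.35, 0.10, 0.55)
  )
  colnames(w) <- c("low", "hemi", "high")
  w
}

# Gaussian-copula driver: y with population Spearman correlation rho_target
# against the (continuous) driver t, via normal scores of t.
# Returns the standardized signal component; caller adds residual noise.
copula_signal <- function(t) {
  stats::qnorm((rank(t, ties.method = "average") - 0.5) / length(t))
}

# sd of the Gaussian gene-level log2-ratio scatter around the segment latent
CN_LOG2_SD <- 0.15

#' Generate a complete synthetic pharmacogenomic cohort
#'
#' Produces every input the analysis pipeline consumes, with known ground
#' truth. Copy number is built from a shared latent segment value plus
#' per-gene noise (equicorrelated Gaussian on a log2-ratio scale, mapped to
#' the nonnegative copy-number scale), with per-cell-line segment-level
#' gain/loss events and rare focal amplifications on top. Planted drug
#' effects act through the latent segment value via a Gaussian copula, so
#' the population Spearman correlation between segment copy number and
#' log10(IC50) equals the configured target. Expression is positively
#' coupled to the copy-number latent; methylation betas follow per-region
#' low/hemi/high mixtures with the mixture component drawn once per gene
#' region (an imprinted differentially methylated region is a region-level
#' state); detection p values are small except for sporadic failed
#' measurements and a ~1% rate of globally failed probes; ~2% of probes are
#' SNP-masked. Identical configurations (including seed) give bit-identical
#' outputs.
#'
#' @param config A [synthetic_config()].
#' @return A list with `gene_catalog` (tibble), `copy_number`, `expression`,
#'   `methylation_beta`, `detection_p`, `drug_response_raw` (matrices;
#'   response with duplicate agent columns), `probe_annotation` (tibble),
#'   `metadata` (tibble: `cell_line`, `cancer_category`), and `truth` (list:
#'   `planted_effects` with resolved ids, `segment_membership`, `seed`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- config$n_cell_lines
  cells <- sprintf("CL%04d", seq_len(n))
  metadata <- tibble::tibble(
    cell_line = cells,
    cancer_category = rep(sprintf("cat%02d", seq_len(config$n_categories)),
                          times = config$category_sizes)
  )

  catalog <- build_synthetic_catalog(config)
  genes <- catalog$gene_symbol
  seg_of_gene <- catalog$segment_index

  # --- copy number: shared segment latent + per-gene noise -----------------
  rho <- config$within_segment_cn_correlation
  rates <- config$cn_event_rates
  cn_log2 <- matrix(NA_real_, n, length(genes), dimnames = list(cells, genes))
  seg_latent <- matrix(NA_real_, n, config$n_segments)
  for (s in seq_len(config$n_segments)) {
    u <- stats::runif(n)
    shift <- numeric(n)
    shift[u < rates["loss"]] <- log2(1 / 2)
    gain_band <- u >= rates["loss"] & u < rates["loss"] + rates["gain"]
    shift[gain_band] <- log2(3 / 2)
    amp_band <- u >= rates["loss"] + rates["gain"] &
      u < rates["loss"] + rates["gain"] + config$focal_amp_rate
    shift[amp_band] <- log2(stats::runif(sum(amp_band), 2, 6))
    z <- stats::rnorm(n)
    latent <- shift + CN_LOG2_SD * sqrt(rho) * z
    seg_latent[, s] <- latent
    members <- which(seg_of_gene == s)
    noise <- matrix(stats::rnorm(n * length(members)), n, length(members))
    cn_log2[, members] <- latent + CN_LOG2_SD * sqrt(1 - rho) * noise
  }
  copy_number <- pmax(config$cn_baseline * 2^cn_log2, 0)

  # --- expression coupled to copy number -----------------------------------
  x_std <- sweep(sweep(cn_log2, 2, colMeans(cn_log2), "-"), 2,
                 apply(cn_log2, 2, stats::sd), "/")
  expr_log2 <- 3 + config$expression_cn_coupling * x_std +
    matrix(stats::rnorm(n * length(genes)), n, length(genes))
  expression <- 2^expr_log2
  dimnames(expression) <- list(cells, genes)

  # --- drug response with planted segment effects --------------------------
  agents <- sprintf("agent%03d", seq_len(config$n_agents))
  y <- matrix(stats::rnorm(n * config$n_agents), n, config$n_agents)
  planted <- config$planted_effects
  if (nrow(planted) > 0) {
    for (a in unique(planted$agent)) {
      rows <- planted[planted$agent == a, ]
      r <- 2 * sin(pi * rows$rho / 6)
      if (sum(r^2) >= 1) {
        stop("planted effects on one agent imply correlation >= 1", call. = FALSE)
      }
      signal <- rowSums(vapply(seq_len(nrow(rows)), function(k) {
        r[k] * copula_signal(seg_latent[, rows$segment[k]])
      }, numeric(n)))
      y[, a] <- signal + sqrt(1 - sum(r^2)) * stats::rnorm(n)
    }
  }
  mu_agent <- stats::rnorm(config$n_agents, 0, 0.7)
  log_ic50 <- sweep(0.5 * y, 2, mu_agent, "+")
  dup <- config$duplicate_agent_ids
  col_idx <- c(seq_len(config$n_agents), dup)
  ord <- order(col_idx)
  col_idx <- col_idx[ord]
  raw <- 10^(log_ic50[, col_idx, drop = FALSE] +
               matrix(stats::rnorm(n * length(col_idx), 0, 0.1), n))
  dimnames(raw) <- list(cells, agents[col_idx])

  # --- methylation probes ---------------------------------------------------
  meth <- build_synthetic_methylation(config, catalog, cells)

  # --- MCAR missingness -----------------------------------------------------
  sprinkle <- function(m) {
    if (config$missing_rate > 0) {
      m[stats::runif(length(m)) < config$missing_rate] <- NA_real_
    }
    m
  }
  copy_number <- sprinkle(copy_number)
  expression <- sprinkle(expression)
  raw <- sprinkle(raw)
  meth$beta <- sprinkle(meth$beta)

  truth <- list(
    planted_effects = if (nrow(planted) > 0) {
      tibble::tibble(segment_label = sprintf("S%02d", planted$segment),
                     agent_id = agents[planted$agent],
                     rho = planted$rho)
    } else {
      tibble::tibble(segment_label = character(), agent_id = character(),
                     rho = numeric())
    },
    segment_membership = tibble::tibble(
      gene_symbol = genes, segment_label = sprintf("S%02d", seg_of_gene)),
    seed = config$seed
  )

  list(gene_catalog = catalog[, c("gene_symbol", "chromosome", "cytoband",
                                  "band_order_index", "imprinted",
                                  "curated_joint_cna_group")],
       copy_number = copy_number,
       expression = expression,
       methylation_beta = meth$beta,
       detection_p = meth$detection_p,
       probe_annotation = meth$annotation,
       drug_response_raw = raw,
       metadata = metadata,
       truth = truth)
}

# catalog topology: segments laid out round-robin over chromosomes 1..22,
# each spanning 1-3 cytobands with dense band_order_index; the first three
# segments carry curated joint-CNA groups (multi-band, literature-style).
build_synthetic_catalog <- function(config) {
  n_seg <- config$n_segments
  bands_per_segment <- rep_len(c(2L, 3L, 2L, 1L, 1L, 2L, 1L, 1L, 3L, 1L), n_seg)
  chrom_of_seg <- chrom_levels[((seq_len(n_seg) - 1L) %% 22L) + 1L]
  next_band <- stats::setNames(rep(1L, 22), chrom_levels[1:22])

  rows <- vector("list", n_seg)
  gene_counter <- 0L
  for (s in seq_len(n_seg)) {
    chr <- chrom_of_seg[s]
    nb <- bands_per_segment[s]
    idx <- next_band[chr] + seq_len(nb) - 1L
    next_band[chr] <- next_band[chr] + nb
    n_genes <- config$genes_per_segment[s]
    band_of_gene <- rep_len(seq_len(nb), n_genes)
    syms <- sprintf("IMP%03d", gene_counter + seq_len(n_genes))
    gene_counter <- gene_counter + n_genes
    rows[[s]] <- tibble::tibble(
      gene_symbol = syms,
      chromosome = chr,
      cytoband = sprintf("q%02d.1", idx[band_of_gene]),
      band_order_index = idx[band_of_gene],
      imprinted = TRUE,
      curated_joint_cna_group = if (s <= 3L && nb > 1L) sprintf("curated%02d", s)
                                else NA_character_,
      segment_index = s
    )
  }
  dplyr::bind_rows(rows)
}

build_synthetic_methylation <- function(config, catalog, cells) {
  w <- config$beta_mixture_weights[GENE_REGION_GROUPS, , drop = FALSE]
  comp_shapes <- list(low = c(1.5, 15), hemi = c(30, 30), high = c(15, 1.5))
  genes <- catalog$gene_symbol
  n <- length(cells)

  ann_rows <- list()
  beta_cols <- list()
  detp_cols <- list()
  probe_counter <- 0L
  for (gi in seq_along(genes)) {
    present <- c("Body", GENE_REGION_GROUPS[stats::runif(6) < 0.6])
    present <- GENE_REGION_GROUPS[GENE_REGION_GROUPS %in% present]
    for (rg in present) {
      comp <- sample(colnames(w), 1, prob = w[rg, ])
      shp <- comp_shapes[[comp]]
      n_probes <- sample(2:4, 1)
      for (p in seq_len(n_probes)) {
        probe_counter <- probe_counter + 1L
        pid <- sprintf("cg%07d", probe_counter)
        betas <- stats::rbeta(n, shp[1], shp[2])
        failed_probe <- stats::runif(1) < 0.01
        detp <- if (failed_probe) 10^stats::runif(n, -6, -3)
                else 10^stats::runif(n, -9, -7)
        bad <- stats::runif(n) < config$detection_p_noise_rate
        detp[bad] <- 10^stats::runif(sum(bad), -3, -0.3)
        ann_rows[[length(ann_rows) + 1L]] <- tibble::tibble(
          probe_id = pid, gene_symbol = genes[gi], region_group = rg,
          cytoband = catalog$cytoband[gi],
          snp_masked = stats::runif(1) < 0.02)
        beta_cols[[pid]] <- betas
        detp_cols[[pid]] <- detp
      }
    }
  }
  beta <- do.call(cbind, beta_cols)
  detection_p <- do.call(cbind, detp_cols)
  rownames(beta) <- rownames(detection_p) <- cells
  list(beta = beta, detection_p = detection_p,
       annotation = dplyr::bind_rows(ann_rows))
}

#' Write a generated cohort to a directory of TSV files
#'
#' Emits the canonical file set (`gene_catalog.tsv`, `copy_number.tsv`,
#' `expression.tsv`, `methylation_beta.tsv`, `detection_p.tsv`,
#' `probe_annotation.tsv`, `drug_response.tsv`, `metadata.tsv`) plus a
#' `truth.json` file with the planted effects and seed.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gene_catalog(dataset$gene_catalog, file.path(dir, "gene_catalog.tsv"))
  write_feature_matrix(dataset$copy_number, file.path(dir, "copy_number.tsv"))
  write_feature_matrix(dataset$expression, file.path(dir, "expression.tsv"))
  write_feature_matrix(dataset$methylation_beta,
                       file.path(dir, "methylation_beta.tsv"))
  write_feature_matrix(dataset$detection_p, file.path(dir, "detection_p.tsv"))
  readr::write_tsv(dataset$probe_annotation,
                   file.path(dir, "probe_annotation.tsv"), na = "NA",
                   progress = FALSE)
  write_feature_matrix(dataset$drug_response_raw,
                       file.path(dir, "drug_response.tsv"))
  readr::write_tsv(dataset$metadata, file.path(dir, "metadata.tsv"), na = "NA",
                   progress = FALSE)
  truth <- dataset$truth
  json <- c("{",
            paste0('  "seed": ', truth$seed, ","),
            '  "planted_effects": [',
            paste(sprintf('    {"segment": "%s", "agent": "%s", "rho": %s}',
                          truth$planted_effects$segment_label,
                          truth$planted_effects$agent_id,
                          format(truth$planted_effects$rho)),
                  collapse = ",\n"),
            "  ]", "}")
  writeLines(json, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Configuration for the synthetic validation cohort
#'
#' Emulates an AML-patient validation cohort: specimen-level gene
#' expression, ex vivo IC50 response for a small agent panel, and overall
#' survival with a cytogenetic-loss grouping flag. Defaults follow the
#' scale of such cohorts (409 specimens, 9 genes, 13 agents).
#'
#' @param n_specimens Positive specimen count.
#' @param n_genes,n_agents Panel sizes.
#' @param planted_effects Tibble with `gene` (1-based index), `agent`
#'   (1-based index), `rho` (target Spearman between expression and
#'   log10 IC50).
#' @param hazard_ratio Hazard ratio of the flagged group (1 = no survival
#'   difference).
#' @param group_rate Probability a specimen carries the cytogenetic-loss
#'   flag.
#' @param mutation_rate Probability of the mutation flag.
#' @param median_survival_days Baseline median overall survival.
#' @param seed Integer RNG seed.
#' @return A validated list of class `validation_config`.
#' @export
validation_config <- function(n_specimens = 409L, n_genes = 9L, n_agents = 13L,
                              planted_effects = NULL, hazard_ratio = 1.23,
                              group_rate = 0.12, mutation_rate = 0.1,
                              median_survival_days = 365, seed = 1L) {
  fail <- function(inv) stop("invalid validation_config: ", inv, call. = FALSE)
  if (n_specimens < 1) fail("n_specimens must be a positive count")
  if (n_genes < 1 || n_agents < 1) fail("panel sizes must be positive counts")
  if (hazard_ratio <= 0) fail("hazard_ratio must be positive")
  if (group_rate < 0 || group_rate > 1 || mutation_rate < 0 || mutation_rate > 1) {
    fail("all probabilities must lie in [0, 1]")
  }
  if (is.null(planted_effects)) {
    planted_effects <- tibble::tibble(gene = integer(), agent = integer(),
                                      rho = numeric())
  }
  planted_effects <- tibble::as_tibble(planted_effects)
  if (nrow(planted_effects) > 0) {
    if (any(planted_effects$gene < 1 | planted_effects$gene > n_genes)) {
      fail("every planted gene index must lie in 1..n_genes")
    }
    if (any(planted_effects$agent < 1 | planted_effects$agent > n_agents)) {
      fail("every planted agent index must lie in 1..n_agents")
    }
    if (any(abs(planted_effects$rho) >= 1)) {
      fail("planted rho values must lie in (-1, 1)")
    }
  }
  structure(list(n_specimens = as.integer(n_specimens),
                 n_genes = as.integer(n_genes), n_agents = as.integer(n_agents),
                 planted_effects = planted_effects, hazard_ratio = hazard_ratio,
                 group_rate = group_rate, mutation_rate = mutation_rate,
                 median_survival_days = median_survival_days,
                 seed = as.integer(seed)),
            class = "validation_config")
}

#' Generate a synthetic validation cohort
#'
#' Specimen x gene log2 expression, specimen x agent raw ex vivo IC50 with
#' planted expression-response correlations (Gaussian copula on the
#' expression values, so the population Spearman correlation equals the
#' target), and a survival table with exponential survival times, uniform
#' censoring, and a configurable hazard ratio for the flagged
#' (cytogenetic-loss) group. Deterministic under the configured seed.
#'
#' @param config A [validation_config()].
#' @return List with `expression` (matrix), `ex_vivo_ic50` (matrix, raw
#'   IC50 scale), `survival` (tibble: `specimen_id`, `time_days`, `event`,
#'   `group_flag`, `mutation_flag`), and `truth`.
#' @export
generate_validation_cohort <- function(config = validation_config()) {
  stopifnot(inherits(config, "validation_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- config$n_specimens
  specimens <- sprintf("SP%04d", seq_len(n))
  genes <- sprintf("VGENE%02d", seq_len(config$n_genes))
  agents <- sprintf("vagent%02d", seq_len(config$n_agents))

  expr <- matrix(stats::rnorm(n * config$n_genes, mean = 3, sd = 1.5), n,
                 dimnames = list(specimens, genes))
  y <- matrix(stats::rnorm(n * config$n_agents), n, config$n_agents)
  planted <- config$planted_effects
  if (nrow(planted) > 0) {
    for (a in unique(planted$agent)) {
      rows <- planted[planted$agent == a, ]
      r <- 2 * sin(pi * rows$rho / 6)
      if (sum(r^2) >= 1) {
        stop("planted effects on one agent imply correlation >= 1", call. = FALSE)
      }
      signal <- rowSums(vapply(seq_len(nrow(rows)), function(k) {
        r[k] * copula_signal(expr[, rows$gene[k]])
      }, numeric(n)))
      y[, a] <- signal + sqrt(1 - sum(r^2)) * stats::rnorm(n)
    }
  }
  mu_agent <- stats::rnorm(config$n_agents, 0, 0.7)
  ic50 <- 10^sweep(0.5 * y, 2, mu_agent, "+")
  dimnames(ic50) <- list(specimens, agents)

  group_flag <- stats::runif(n) < config$group_rate
  base_rate <- log(2) / config$median_survival_days
  haz <- base_rate * ifelse(group_flag, config$hazard_ratio, 1)
  true_time <- stats::rexp(n, rate = haz)
  censor_time <- stats::runif(n, 0, 3 * config$median_survival_days)
  survival <- tibble::tibble(
    specimen_id = specimens,
    time_days = pmin(true_time, censor_time),
    event = true_time <= censor_time,
    group_flag = group_flag,
    mutation_flag = stats::runif(n) < config$mutation_rate
  )
  truth <- list(
    planted_effects = if (nrow(planted) > 0) {
      tibble::tibble(gene_symbol = genes[planted$gene],
                     agent_id = agents[planted$agent], rho = planted$rho)
    } else {
      tibble::tibble(gene_symbol = character(), agent_id = character(),
                     rho = numeric())
    },
    hazard_ratio = config$hazard_ratio,
    seed = config$seed
  )
  list(expression = expr, ex_vivo_ic50 = ic50, survival = survival,
       truth = truth)
}
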