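test_that("invalid configurations are rejected naming the violated invariant", {
  expect_error(synthetic_config(n_cell_lines = 0), "n_cell_lines")
  expect_error(synthetic_config(n_cell_lines = 10, n_categories = 2,
                                category_sizes = c(4L, 4L)),
               "category_sizes")
  expect_error(synthetic_config(within_segment_cn_correlation = 1.2),
               "within_segment_cn_correlation")
  expect_error(synthetic_config(missing_rate = 1), "missing_rate")
  expect_error(synthetic_config(n_segments = 3, n_agents = 4,
                                planted_effects = data.frame(segment = 5,
                                                             agent = 1,
                                                             rho = 0.3)),
               "segment index")
  expect_error(synthetic_config(n_segments = 3, n_agents = 4,
                                planted_effects = data.frame(segment = 1,
                                                             agent = 9,
                                                             rho = 0.3)),
               "agent index")
  bad_w <- default_beta_weights(); bad_w[1, ] <- c(0.5, 0.5, 0.5)
  expect_error(synthetic_config(beta_mixture_weights = bad_w), "sum to 1")
  expect_error(validation_config(n_specimens = 0), "n_specimens")
})

test_that("generation is deterministic under the seed", {
  cfg <- synthetic_config(n_cell_lines = 50, n_segments = 4,
                          genes_per_segment = 3, n_agents = 6,
                          planted_effects = data.frame(segment = 1, agent = 1,
                                                       rho = 0.3),
                          seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  c <- generate_dataset(synthetic_config(n_cell_lines = 50, n_segments = 4,
                                         genes_per_segment = 3, n_agents = 6,
                                         seed = 100))
  expect_false(identical(a$copy_number, c$copy_number))

  va <- generate_validation_cohort(validation_config(n_specimens = 40, seed = 7))
  vb <- generate_validation_cohort(validation_config(n_specimens = 40, seed = 7))
  expect_identical(va, vb)
})

test_that("generated values satisfy their range contracts", {
  cfg <- synthetic_config(n_cell_lines = 120, n_segments = 6,
                          genes_per_segment = 3, n_agents = 10,
                          missing_rate = 0.05, seed = 2)
  ds <- generate_dataset(cfg)
  expect_true(all(ds$methylation_beta >= 0 & ds$methylation_beta <= 1,
                  na.rm = TRUE))
  expect_true(all(ds$drug_response_raw > 0, na.rm = TRUE))
  expect_true(all(ds$copy_number >= 0, na.rm = TRUE))
  expect_true(all(ds$probe_annotation$region_group %in% GENE_REGION_GROUPS))
  # duplicate agents appear as two raw columns
  dups <- table(colnames(ds$drug_response_raw))
  expect_equal(sum(dups == 2), length(cfg$duplicate_agent_ids))
  # every gene sits in exactly one segment
  memb <- ds$truth$segment_membership
  expect_equal(anyDuplicated(memb$gene_symbol), 0)
  expect_equal(nrow(memb), sum(cfg$genes_per_segment))
  # with missing_rate = 0 there are no NAs anywhere
  ds0 <- generate_dataset(synthetic_config(n_cell_lines = 30, n_segments = 3,
                                           genes_per_segment = 2, n_agents = 4,
                                           missing_rate = 0,
                                           detection_p_noise_rate = 0, seed = 3))
  expect_false(anyNA(ds0$copy_number))
  expect_false(anyNA(ds0$drug_response_raw))
})

test_that("within-segment copy-number correlation approaches the configured value", {
  cfg <- synthetic_config(n_cell_lines = 2000, n_segments = 3,
                          genes_per_segment = 4,
                          within_segment_cn_correlation = 0.8,
                          cn_event_rates = c(gain = 0, loss = 0),
                          focal_amp_rate = 0, missing_rate = 0, seed = 8)
  ds <- generate_dataset(cfg)
  memb <- ds$truth$segment_membership
  for (s in unique(memb$segment_label)) {
    genes <- memb$gene_symbol[memb$segment_label == s]
    cc <- cor(ds$copy_number[, genes])
    off <- cc[upper.tri(cc)]
    expect_equal(mean(off), 0.8, tolerance = 0.05)
  }
  # across segments: essentially uncorrelated
  g1 <- memb$gene_symbol[memb$segment_label == memb$segment_label[1]][1]
  g2 <- memb$gene_symbol[memb$segment_label != memb$segment_label[1]][1]
  expect_lt(abs(cor(ds$copy_number[, g1], ds$copy_number[, g2])), 0.1)
})

test_that("a planted effect lands near its target Spearman correlation", {
  rhos <- vapply(1:20, function(s) {
    ds <- generate_dataset(synthetic_config(
      n_cell_lines = 500, n_segments = 4, genes_per_segment = 3, n_agents = 5,
      duplicate_agent_ids = integer(),
      planted_effects = data.frame(segment = 2, agent = 3, rho = 0.4),
      missing_rate = 0, seed = 400 + s))
    genes <- ds$truth$segment_membership$gene_symbol[
      ds$truth$segment_membership$segment_label == "S02"]
    seg_cn <- rowMeans(ds$copy_number[, genes])
    y <- log10(ds$drug_response_raw[, "agent003"])
    cor(rank(seg_cn), rank(y))
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.4), 0.05)
  expect_true(all(abs(rhos - 0.4) < 0.1))
})

test_that("null cohorts are calibrated: ~5% of raw p below 0.05", {
  ds <- generate_dataset(synthetic_config(
    n_cell_lines = 500, n_categories = 4, n_segments = 20,
    genes_per_segment = 1, n_agents = 100, duplicate_agent_ids = integer(),
    missing_rate = 0, seed = 17))
  prep <- prepare_response(ds$drug_response_raw)
  rec <- run_association_screen(ds$copy_number, prep, "copy_number")
  expect_equal(nrow(rec), 2000)
  frac <- mean(rec$p0 < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), 3 * se + 1 / 2000)
})

test_that("written datasets round-trip through their TSV formats", {
  ds <- generate_dataset(synthetic_config(n_cell_lines = 20, n_categories = 2,
                                          n_segments = 3, genes_per_segment = 2,
                                          n_agents = 4, seed = 30))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "gene_catalog.tsv", "copy_number.tsv", "expression.tsv",
    "methylation_beta.tsv", "detection_p.tsv", "probe_annotation.tsv",
    "drug_response.tsv", "metadata.tsv", "truth.json")))))
  cn <- read_feature_matrix(file.path(dir, "copy_number.tsv"))
  expect_identical(cn, ds$copy_number)
  raw <- read_feature_matrix(file.path(dir, "drug_response.tsv"),
                             allow_duplicate_cols = TRUE)
  expect_identical(raw, ds$drug_response_raw)
  cat <- read_gene_catalog(file.path(dir, "gene_catalog.tsv"))
  expect_equal(cat$gene_symbol, ds$gene_catalog$gene_symbol)
  ann <- read_probe_annotation(file.path(dir, "probe_annotation.tsv"))
  expect_equal(nrow(ann), nrow(ds$probe_annotation))
})
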