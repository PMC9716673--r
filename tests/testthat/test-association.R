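test_that("prepare_response log-transforms, averages duplicates, keeps sources apart", {
  raw <- matrix(c(10, 100,
                  1000, 10,
                  1, NA,
                  5, 50), 2, 4,
                dimnames = list(c("cl1", "cl2"),
                                c("drugA", "drugA", "drugB_GDSC", "drugB_CCLE")))
  prep <- prepare_response(raw)
  expect_equal(prep$response["cl1", "drugA"], 2)     # mean(log10(10), log10(1000))
  expect_equal(prep$response["cl2", "drugA"], 1.5)
  expect_equal(prep$response["cl1", "drugB_GDSC"], 0)  # missing-aware
  expect_setequal(colnames(prep$response), c("drugA", "drugB_GDSC", "drugB_CCLE"))
  expect_identical(prep$agent_provenance$collapsed,
                   c(TRUE, FALSE, FALSE))

  raw[1, 3] <- -2
  expect_error(prepare_response(raw), "cl1.*drugB_GDSC")
})

test_that("correlate matches hand and brute-force oracles", {
  r <- correlate(c(1, 2, 3), c(3, 1, 2), min_pairs = 3)
  expect_equal(r$spearman_rho, -0.5)   # 1 - 6*6/(3*8)

  mono <- correlate(1:12, (1:12)^3, min_pairs = 3)
  expect_equal(mono$spearman_rho, 1)
  expect_lte(mono$pearson_r, 1)

  withr::local_seed(31)
  for (i in 1:20) {
    x <- sample(1:6, 30, replace = TRUE)     # heavy ties
    y <- x + rnorm(30, 0, 2)
    x[sample(30, 3)] <- NA
    got <- correlate(x, y, min_pairs = 5)
    expect_equal(got$spearman_rho, spearman_brute(x, y), tolerance = 1e-12)
    sym <- correlate(y, x, min_pairs = 5)
    expect_equal(sym$spearman_rho, got$spearman_rho)
    expect_equal(sym$spearman_p, got$spearman_p)
    # p from the t approximation with n-2 df
    ok <- sum(!is.na(x) & !is.na(y))
    tt <- got$spearman_rho * sqrt((ok - 2) / (1 - got$spearman_rho^2))
    expect_equal(got$spearman_p, 2 * pt(-abs(tt), ok - 2), tolerance = 1e-12)
  }

  expect_identical(correlate(rep(1, 20), rnorm(20))$reason, "constant_input")
  expect_identical(correlate(c(1:5, rep(NA, 10)), 1:15)$reason, "insufficient_n")
})

test_that("the fast complete-case screen equals the per-pair path", {
  withr::local_seed(19)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(sprintf("c%02d", 1:20),
                                                  sprintf("f%02d", 1:10)))
  Y <- matrix(rnorm(100), 20, 5, dimnames = list(sprintf("c%02d", 1:20),
                                                 sprintf("a%02d", 1:5)))
  fast <- imprintscreen:::screen_correlations(X, Y, min_pairs = 5)
  X2 <- X; X2[1, 1] <- NA  # force the per-pair path
  slow <- imprintscreen:::screen_correlations(X2, Y, min_pairs = 5)
  slow_clean <- slow[slow$feature_id != "f01", ]
  fast_clean <- fast[fast$feature_id != "f01", ]
  expect_equal(fast_clean$spearman_rho, slow_clean$spearman_rho, tolerance = 1e-12)
  expect_equal(fast_clean$p0, slow_clean$p0, tolerance = 1e-12)
  expect_equal(fast_clean$pearson_r, slow_clean$pearson_r, tolerance = 1e-12)
})

test_that("screen records recompute exactly and are row-order invariant", {
  ds <- generate_dataset(synthetic_config(
    n_cell_lines = 80, n_categories = 4, n_segments = 5, genes_per_segment = 2,
    n_agents = 6, missing_rate = 0.05, seed = 13))
  prep <- prepare_response(ds$drug_response_raw)
  rec <- run_association_screen(ds$copy_number, prep, "copy_number")
  expect_gt(nrow(rec), 0)
  for (i in sample(nrow(rec), 5)) {
    again <- correlate(ds$copy_number[, rec$feature_id[i]],
                       prep$response[rownames(ds$copy_number), rec$agent_id[i]],
                       min_pairs = 10)
    expect_equal(rec$spearman_rho[i], again$spearman_rho)
    expect_equal(rec$p0[i], again$spearman_p)
    expect_equal(rec$n[i], again$n)
  }
  perm <- sample(nrow(ds$copy_number))
  rec2 <- run_association_screen(ds$copy_number[perm, ], prep, "copy_number")
  expect_equal(rec, rec2)
  expect_true(all(rec$n <= nrow(ds$copy_number)))
})

test_that("stratified screens honour the minimum category size", {
  ds <- generate_dataset(synthetic_config(
    n_cell_lines = 49, n_categories = 3, category_sizes = c(25L, 15L, 9L),
    n_segments = 3, genes_per_segment = 2, n_agents = 4,
    missing_rate = 0, seed = 14))
  prep <- prepare_response(ds$drug_response_raw)
  rec <- run_association_screen(ds$copy_number, prep, "copy_number",
                                metadata = ds$metadata, strata = "by_category")
  expect_setequal(unique(rec$stratum), c("cat01", "cat02"))  # 9-line cat03 absent
  expect_error(run_association_screen(
    ds$copy_number[0, , drop = FALSE], prep, "copy_number"), "shared")
})

test_that("a planted segment effect tops the |rho| ranking for its agent", {
  cfg <- synthetic_config(n_cell_lines = 600, n_categories = 4, n_segments = 8,
                          genes_per_segment = 3, n_agents = 10,
                          planted_effects = data.frame(segment = 4, agent = 6,
                                                       rho = 0.4),
                          missing_rate = 0, seed = 15)
  ds <- generate_dataset(cfg)
  prep <- prepare_response(ds$drug_response_raw)
  rec <- run_association_screen(ds$copy_number, prep, "copy_number")
  planted_agent <- ds$truth$planted_effects$agent_id
  planted_genes <- ds$truth$segment_membership$gene_symbol[
    ds$truth$segment_membership$segment_label ==
      ds$truth$planted_effects$segment_label]
  per_agent <- rec[rec$agent_id == planted_agent, ]
  top <- per_agent$feature_id[order(-abs(per_agent$spearman_rho))][
    seq_along(planted_genes)]
  expect_setequal(top, planted_genes)
  expect_lt(abs(mean(per_agent$spearman_rho[per_agent$feature_id %in% planted_genes]) -
                  0.4), 0.1)
})

test_that("null cohorts give roughly uniform raw p values", {
  cfg <- synthetic_config(n_cell_lines = 500, n_categories = 4, n_segments = 10,
                          genes_per_segment = 2, n_agents = 100,
                          duplicate_agent_ids = integer(),
                          missing_rate = 0, seed = 16)
  ds <- generate_dataset(cfg)
  prep <- prepare_response(ds$drug_response_raw)
  rec <- run_association_screen(ds$copy_number, prep, "copy_number")
  expect_equal(nrow(rec), 2000)
  frac <- mean(rec$p0 < 0.05)
  # pairs sharing a segment or an agent are correlated, so allow a loose band
  expect_lt(abs(frac - 0.05), 0.02)
  ks <- suppressWarnings(stats::ks.test(rec$p0, "punif"))
  expect_gt(ks$p.value, 0.001)
})
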