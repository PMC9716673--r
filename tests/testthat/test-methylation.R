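make_beta_fixture <- function() {
  cells <- c("c1", "c2", "c3")
  probes <- c("p1", "p2", "p3", "p4")
  beta <- matrix(0.5, 3, 4, dimnames = list(cells, probes))
  detp <- matrix(1e-9, 3, 4, dimnames = list(cells, probes))
  ann <- tibble::tibble(probe_id = probes, gene_symbol = "G1",
                        region_group = c("TSS200", "TSS200", "Body", "Body"),
                        cytoband = "q11.21", snp_masked = FALSE)
  list(beta = beta, detp = detp, ann = ann)
}

test_that("detection-p thresholds are inclusive at the cell and probe level", {
  fx <- make_beta_fixture()
  fx$detp["c2", "p1"] <- 1e-3          # exactly at the cell cutoff -> masked
  fx$detp["c1", "p2"] <- 0.999e-3      # just below -> kept
  out <- filter_probes(fx$beta, fx$detp, fx$ann)
  expect_true(is.na(out["c2", "p1"]))
  expect_false(is.na(out["c1", "p2"]))

  fx2 <- make_beta_fixture()
  fx2$detp[, "p2"] <- 1e-6             # median exactly at probe cutoff -> dropped
  out2 <- filter_probes(fx2$beta, fx2$detp, fx2$ann)
  expect_false("p2" %in% colnames(out2))
  expect_true(all(c("p1", "p3", "p4") %in% colnames(out2)))
})

test_that("SNP-masked probes are dropped even with perfect detection", {
  fx <- make_beta_fixture()
  fx$detp[] <- 0
  fx$ann$snp_masked[fx$ann$probe_id == "p3"] <- TRUE
  out <- filter_probes(fx$beta, fx$detp, fx$ann)
  expect_false("p3" %in% colnames(out))
  # and with all-zero detection p and no masks, filtering is the identity
  fx$ann$snp_masked[] <- FALSE
  expect_identical(filter_probes(fx$beta, fx$detp, fx$ann), fx$beta)
})

test_that("filter_probes is idempotent and rejects shape mismatches", {
  ds <- generate_dataset(synthetic_config(n_cell_lines = 40, n_segments = 4,
                                          genes_per_segment = 2, n_agents = 5,
                                          detection_p_noise_rate = 0.1,
                                          missing_rate = 0, seed = 3))
  once <- filter_probes(ds$methylation_beta, ds$detection_p, ds$probe_annotation)
  twice <- filter_probes(once, ds$detection_p[, colnames(once), drop = FALSE],
                         ds$probe_annotation)
  expect_identical(once, twice)
  expect_error(filter_probes(ds$methylation_beta, ds$detection_p[, -1],
                             ds$probe_annotation), "absent|shape")
})

test_that("gene-region averages are missing-aware means over annotated probes", {
  fx <- make_beta_fixture()
  fx$beta["c1", c("p1", "p2")] <- c(0.2, 0.4)
  fx$beta["c2", "p1"] <- NA
  fx$beta["c2", "p2"] <- 0.8
  avg <- average_gene_regions(fx$beta, fx$ann)
  expect_equal(avg["c1", "G1|TSS200"], 0.3)
  expect_equal(avg["c2", "G1|TSS200"], 0.8)  # mean over the remaining probe
  expect_setequal(colnames(avg), c("G1|TSS200", "G1|Body"))

  # a gene with probes only in Body yields exactly one region column
  solo <- fx$ann[fx$ann$region_group == "Body", ]
  expect_equal(colnames(average_gene_regions(fx$beta, solo)), "G1|Body")

  bad <- fx$ann
  bad$region_group[1] <- "Promoter"
  expect_error(average_gene_regions(fx$beta, bad), "Promoter")
})

test_that("matrix-product averaging equals a naive double loop on random data", {
  withr::local_seed(77)
  cells <- sprintf("c%02d", 1:15)
  probes <- sprintf("p%02d", 1:40)
  beta <- matrix(runif(600), 15, 40, dimnames = list(cells, probes))
  beta[sample(600, 60)] <- NA
  ann <- tibble::tibble(
    probe_id = sample(probes, 55, replace = TRUE),
    gene_symbol = sample(c("G1", "G2", "G3"), 55, replace = TRUE),
    region_group = sample(GENE_REGION_GROUPS, 55, replace = TRUE),
    cytoband = "q1.1", snp_masked = FALSE) |>
    dplyr::distinct(probe_id, gene_symbol, region_group, .keep_all = TRUE)
  avg <- average_gene_regions(beta, ann)
  for (cl in cells) {
    for (col in colnames(avg)) {
      parts <- strsplit(col, "|", fixed = TRUE)[[1]]
      pr <- ann$probe_id[ann$gene_symbol == parts[1] & ann$region_group == parts[2]]
      vals <- beta[cl, pr]
      expected <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      expect_equal(avg[cl, col], expected, tolerance = 1e-12)
    }
  }
  expect_true(all(avg >= 0 & avg <= 1, na.rm = TRUE))
  expect_lte(ncol(avg), 6 * 3)
})

test_that("hemimethylation fractions respect their windows", {
  m <- matrix(0.5, 4, 2, dimnames = list(paste0("c", 1:4),
                                         c("G1|TSS200", "G1|Body")))
  hs <- hemimethylation_summary(m)
  expect_true(all(hs$hemimethylated_fraction == 1))

  m2 <- matrix(rep(c(0, 1), 4), 4, 2,
               dimnames = list(paste0("c", 1:4), c("G1|TSS200", "G1|Body")))
  hs2 <- hemimethylation_summary(m2)
  expect_true(all(hs2$hemimethylated_fraction == 0))
  expect_equal(hs2$low_fraction + hs2$high_fraction, rep(1, nrow(hs2)))

  # histogram counts total the non-missing values; disjoint windows sum <= 1
  withr::local_seed(8)
  m3 <- matrix(runif(200), 20, 10,
               dimnames = list(sprintf("c%02d", 1:20),
                               paste0("G", 1:10, "|Body")))
  m3[sample(200, 11)] <- NA
  hs3 <- hemimethylation_summary(m3)
  all_row <- hs3[hs3$region_group == "all", ]
  expect_equal(sum(all_row$histogram[[1]]$count), 189)
  expect_lte(all_row$low_fraction + all_row$hemimethylated_fraction +
               all_row$high_fraction, 1)
  expect_error(hemimethylation_summary(matrix(numeric(0), 0, 0)), "empty")
})

test_that("synthetic imprinted fixtures put the hemimethylation peak in promoter regions", {
  ds <- generate_dataset(synthetic_config(n_cell_lines = 80, n_segments = 6,
                                          genes_per_segment = 5, n_agents = 5,
                                          missing_rate = 0, seed = 21))
  fb <- filter_probes(ds$methylation_beta, ds$detection_p, ds$probe_annotation)
  gr <- average_gene_regions(fb, ds$probe_annotation)
  hs <- hemimethylation_summary(gr)
  hemi <- stats::setNames(hs$hemimethylated_fraction, hs$region_group)
  expect_gt(hemi[["TSS200"]], hemi[["Body"]])
})
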