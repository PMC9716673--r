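# shared fixtures and independent brute-force oracles

tiny_catalog <- function() {
  tibble::tibble(
    gene_symbol = c("GA", "GB", "GC", "GD", "GE"),
    chromosome = c("20", "20", "20", "20", "7"),
    cytoband = c("q11.21", "q11.21", "q11.23", "q13.32", "q32.2"),
    band_order_index = c(1L, 1L, 2L, 3L, 1L),
    imprinted = TRUE,
    curated_joint_cna_group = NA_character_
  )
}

# equicorrelated CN matrix: one latent per segment listed in `seg_of`
correlated_cn <- function(n, seg_of, rho = 0.9, seed = 42) {
  withr::with_seed(seed, {
    genes <- names(seg_of)
    out <- matrix(NA_real_, n, length(genes),
                  dimnames = list(sprintf("cl%03d", seq_len(n)), genes))
    for (s in unique(seg_of)) {
      z <- rnorm(n)
      for (g in genes[seg_of == s]) {
        out[, g] <- 2 + 0.3 * (sqrt(rho) * z + sqrt(1 - rho) * rnorm(n))
      }
    }
    out
  })
}

# step-up BH written independently of the package (vectorised differently)
bh_brute <- function(p) {
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  pv <- p[idx]
  m <- length(pv)
  if (m == 0) return(out)
  ord <- order(pv)
  q <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, pv[ord[i]] * m / i)
    q[ord[i]] <- min(running_min, 1)
  }
  out[idx] <- q
  out
}

# group by (segment, agent, stratum), take max p, BH, broadcast back
segment_fdr_brute <- function(records, gene_to_segment) {
  seg <- gene_to_segment[records$feature_id]
  strat <- if ("stratum" %in% colnames(records)) records$stratum else "pancancer"
  key <- paste(seg, records$agent_id, strat, sep = "\r")
  reps <- tapply(records$p0, key, max)
  adj <- bh_brute(as.vector(reps))
  names(adj) <- names(reps)
  unname(adj[key])
}

# Spearman rho by the textbook route: Pearson product-moment on midranks
spearman_brute <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- rank(x[ok]); ry <- rank(y[ok])
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
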