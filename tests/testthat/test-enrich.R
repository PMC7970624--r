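mk_counts <- function(mat, conditions, replicates) {
  # mat: genes x samples
  genes <- rownames(mat)
  out <- list()
  for (j in seq_len(ncol(mat))) {
    out[[j]] <- tibble::tibble(
      sample = paste0(conditions[j], "_", replicates[j]),
      condition = conditions[j], replicate = replicates[j],
      gene_id = genes, count = unname(mat[, j])
    )
  }
  dplyr::bind_rows(out)
}

test_that("frequencies are counts over totals and sum to one", {
  m <- matrix(c(2L, 8L), ncol = 1, dimnames = list(c("A", "B"), NULL))
  counts <- mk_counts(m, "control", 1)
  fr <- compute_frequency(counts, pseudocount = 0)
  expect_equal(fr$freq, c(0.2, 0.8))
  # single gene -> frequency 1 regardless of count
  one <- mk_counts(matrix(17L, dimnames = list("A", NULL)), "control", 1)
  expect_equal(compute_frequency(one, pseudocount = 0)$freq, 1)
  # random table: per-sample frequencies sum to 1 within 1e-12
  set.seed(3)
  m20 <- matrix(rpois(20 * 4, 50), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
  c20 <- mk_counts(m20, rep(c("control", "max"), each = 2), rep(1:2, 2))
  fr20 <- compute_frequency(c20)
  sums <- tapply(fr20$freq, fr20$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # all-zero sample without pseudocount is an error naming the sample
  z <- mk_counts(matrix(0L, 2, dimnames = list(c("A", "B"), NULL)),
                 "control", 1)
  expect_error(compute_frequency(z, pseudocount = 0),
               class = "crisprsort_zero_sample")
})

test_that("frequencies are invariant to uniform count scaling", {
  set.seed(4)
  m <- matrix(rpois(30, 200) + 50L, nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  f1 <- compute_frequency(mk_counts(m, "control", 1))$freq
  f2 <- compute_frequency(mk_counts(m * 10L, "control", 1))$freq
  # pseudocount is << counts, so scaling leaves frequencies ~unchanged
  expect_equal(f1, f2, tolerance = 1e-3)
})

test_that("enrichment score is the frequency ratio", {
  expect_equal(enrichment_score(0.04, 0.01)$enrichment_score, 4)
  expect_equal(enrichment_score(0.3, 0.3)$enrichment_score, 1)
  expect_equal(enrichment_score(0.3, 0.3)$log2_score, 0)
  expect_error(enrichment_score(0, 0.1), "pseudocount")
})

test_that("the replicate test is a two-tailed Student's t-test", {
  # identical replicate vectors in both groups -> p = 1
  expect_equal(test_enrichment(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2)), 1)
  expect_error(test_enrichment(0.1, c(0.2, 0.3)), "replicates")
  # agreement with the pooled-variance formula against the t distribution,
  # an independent implementation
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(3, 0.2, 0.02); y <- rnorm(4, 0.18, 0.05)
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p_ref <- 2 * pt(-abs(tstat), n1 + n2 - 2)
    expect_equal(test_enrichment(x, y), p_ref, tolerance = 1e-10)
  }
})

test_that("type-I error under the null is near nominal", {
  genes <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000))
  cfg <- sim_config(n_reads = 1e5, conditions = c("control", "max"),
                    n_replicates = 3, seed = 202)
  counts <- simulate_screen_counts(genes, cfg)
  res <- screen_enrichment(counts, "max")
  frac <- mean(res$p_value < 0.05)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  # and the null ranking's top set is centred on log2 score 0
  top <- rank_candidates(res, 50)
  expect_lt(abs(median(res$log2_score)), 0.05)
  expect_true(all(top$log2_score >= 0))
})

test_that("fold-4 spikes are recovered at the top of the Max ranking", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:200))
  spiked <- c(g001 = 4, g050 = 4, g100 = 4, g150 = 4, g200 = 4)
  cfg <- sim_config(n_reads = 1e5, spikes = list(max = spiked),
                    conditions = c("control", "max"), n_replicates = 3,
                    seed = 301)
  counts <- simulate_screen_counts(genes, cfg)
  res <- screen_enrichment(counts, "max")
  top10 <- rank_candidates(res, 10)
  expect_true(all(names(spiked) %in% top10$gene_id))
  # the recovered mean score is close to the simulated fold change
  sc <- res$enrichment_score[match(names(spiked), res$gene_id)]
  expect_lt(abs(mean(sc) - 4) / 4, 0.2)
})

test_that("Min-pool ranking is ascending and deterministic on ties", {
  m <- matrix(
    c(100L, 100L, 100L, 100L,   # gA flat
      400L, 400L, 100L, 100L,   # gB depleted in min
      100L, 100L, 400L, 400L),  # gC enriched in min
    nrow = 3, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC"), NULL)
  )
  counts <- mk_counts(m, rep(c("control", "min"), each = 2), rep(1:2, 2))
  res <- screen_enrichment(counts, "min")
  expect_equal(res$gene_id[1], "gB")   # most depleted first
  expect_equal(res$gene_id[3], "gC")
  # ties break by gene id
  tie <- mk_counts(matrix(100L, 2, 4, dimnames = list(c("zz", "aa"), NULL)),
                   rep(c("control", "min"), each = 2), rep(1:2, 2))
  res_tie <- screen_enrichment(tie, "min")
  expect_equal(res_tie$gene_id, c("aa", "zz"))
})

test_that("per-direction shortlists reproduce a 9/6/3/6 candidate pattern", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:100))
  mk <- function(contrast, n_up, seed) {
    # min-direction candidates head an ascending ranking: spike downwards
    fold <- if (contrast == "min") 1 / 6 else 6
    sp <- setNames(rep(fold, n_up), sprintf("g%03d", seq_len(n_up)))
    cfg <- sim_config(n_reads = 2e4,
                      spikes = setNames(list(sp), contrast),
                      conditions = c("control", contrast),
                      n_replicates = 3, seed = seed)
    screen_enrichment(simulate_screen_counts(genes, cfg), contrast)
  }
  results <- list(mk("min", 9, 11), mk("max", 6, 12),
                  mk("min", 3, 13), mk("max", 6, 14))
  shortlist <- rank_candidates(results, top_n = c(9, 6, 3, 6))
  expect_equal(nrow(shortlist), 24)
  expect_equal(as.vector(table(shortlist$direction)[c("min", "max")]),
               c(12, 12))
})

test_that("tidy and glance summarise an enrichment result", {
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20))
  cfg <- sim_config(n_reads = 5000, conditions = c("control", "max"),
                    n_replicates = 3, seed = 5)
  res <- screen_enrichment(simulate_screen_counts(genes, cfg), "max")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(any(c("freq_control", "freq_sorted") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_genes, 20)
  expect_equal(gl$n_replicates_control, 3)
  expect_equal(gl$contrast, "max")
  expect_s3_class(autoplot(res), "ggplot")
})
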