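params_flank <- selection_params("flank_gene", 1e6)
params_mid <- selection_params("midpoint", 1e5)

test_that("cis windows follow the gene-flank and midpoint conventions with clamping", {
  gene <- list(chrom = "1", start = 1e6, end = 1.05e6)
  w <- cis_window(gene, params_flank)
  expect_equal(c(w$start, w$end), c(1, 2050000))
  w <- cis_window(gene, params_mid)
  expect_equal(c(w$start, w$end), c(925000, 1125000))
  # degenerate point gene: both modes symmetric about the point
  pt <- list(chrom = "1", start = 5e6, end = 5e6)
  wf <- cis_window(pt, params_flank)
  wm <- cis_window(pt, params_mid)
  expect_equal(wf$end - 5e6, 5e6 - wf$start)
  expect_equal(wm$end - 5e6, 5e6 - wm$start)
})

test_that("significance filtering keeps p < threshold, preserving order", {
  set.seed(21)
  rec <- rand_records(2, with_missing = FALSE)
  rec$pvalue <- c(1e-6, 1e-4)
  s <- assoc_set("t", rec, validate = FALSE)
  kept <- filter_significant(s, 1e-5)
  expect_equal(kept$records$snp_id, rec$snp_id[1])

  s2 <- rand_assoc_set(6)
  expect_equal(nrow(filter_significant(s2, 1)$records), 6L)
  s2$records$pvalue <- pmax(s2$records$pvalue, 0.5)
  expect_equal(nrow(filter_significant(s2, 1e-5)$records), 0L)
})

make_clump_set <- function(p, pos = seq_along(p) * 1000,
                           ids = paste0("SNP", seq_along(p))) {
  rec <- rand_records(length(p), with_missing = FALSE)
  rec$snp_id <- ids; rec$pos <- pos; rec$pvalue <- p
  assoc_set("t", rec, validate = FALSE)
}

test_that("greedy clumping matches hand execution and handles degenerate LD", {
  # r2(1,2)=0.5 removes SNP2 when SNP1 is taken; SNP3 survives at r2 < 0.1
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- sqrt(0.5)
  r[1, 3] <- r[3, 1] <- sqrt(0.05)
  r[2, 3] <- r[3, 2] <- sqrt(0.04)
  ld <- ld_matrix(r, paste0("SNP", 1:3))
  out <- clump(make_clump_set(c(1e-8, 1e-7, 1e-6)), ld, 0.1)
  expect_equal(out$records$snp_id, c("SNP1", "SNP3"))

  # all independent: identity
  ld0 <- ld_matrix(diag(4), paste0("SNP", 1:4))
  s <- make_clump_set(c(1e-4, 1e-6, 1e-5, 1e-3))
  expect_equal(clump(s, ld0, 0.1)$records$snp_id, s$records$snp_id)

  # perfect proxies: only the smaller-p one kept
  ld1 <- ld_matrix(matrix(c(1, 1, 1, 1), 2), c("SNP1", "SNP2"))
  out <- clump(make_clump_set(c(1e-4, 1e-9)), ld1, 0.1)
  expect_equal(out$records$snp_id, "SNP2")
})

test_that("clump output satisfies pairwise r2 < threshold, keeps the top hit, and is idempotent", {
  set.seed(22)
  for (rep in 1:25) {
    q <- sample(5:15, 1)
    ld <- rand_corr(q, paste0("SNP", 1:q))
    s <- make_clump_set(runif(q, 1e-10, 1e-2), ids = rownames(ld))
    thr <- runif(1, 0.05, 0.5)
    out <- clump(s, ld, thr)
    ids <- out$records$snp_id
    expect_true(s$records$snp_id[which.min(s$records$pvalue)] %in% ids)
    if (length(ids) > 1) {
      r2 <- unclass(ld)[ids, ids]^2
      expect_lt(max(r2[upper.tri(r2)]), thr)
    }
    again <- clump(out, ld, thr)
    expect_equal(again$records, out$records)
  }
})

test_that("variants absent from the LD reference are dropped with a warning, or kept if assumed independent", {
  ld <- ld_matrix(diag(2), c("SNP1", "SNP2"))
  s <- make_clump_set(c(1e-6, 1e-7, 1e-8))
  expect_warning(out <- clump(s, ld, 0.1), "absent from LD")
  expect_setequal(out$records$snp_id, c("SNP1", "SNP2"))
  out2 <- clump(s, ld, 0.1, missing_ld = "independent")
  expect_setequal(out2$records$snp_id, c("SNP1", "SNP2", "SNP3"))
})

test_that("instrument selection composes window, p-filter and clumping per gene x cell type", {
  set.seed(23)
  # strong single eQTL
  loc <- simulate_locus(scenario("H1", causal_variance_exp = 0.05,
                                 n_exp = 10000, Q = 50), seed = 5)
  genes <- gene_annotation("GENE", "1", 1e6, 1e6 + 49 * 1000)
  inst <- select_instruments(list(loc$exposure), genes, loc$ld, params_flank)
  expect_length(inst, 1L)
  expect_gte(nrow(inst[[1]]$variants), 1L)
  expect_true(all(inst[[1]]$variants$pvalue < 1e-5))

  # two independent signals in separate LD blocks; moderate power so that
  # LD-shadow neighbours of each causal variant stay above the p threshold
  loc2 <- simulate_locus(scenario("H1", causal_variance_exp = 0.01,
                                  n_exp = 6400, Q = 50, blocks = 2,
                                  n_signals = 2), seed = 6)
  inst2 <- select_instruments(list(loc2$exposure), genes, loc2$ld,
                              params_flank)
  expect_equal(nrow(inst2[[1]]$variants), 2L)

  # all-null locus yields no instrument set but a report row
  loc3 <- simulate_locus(scenario("H0", Q = 50), seed = 7)
  inst3 <- select_instruments(list(loc3$exposure), genes, loc3$ld,
                              params_flank)
  expect_length(inst3, 0L)
  expect_equal(attr(inst3, "report")$n_clumped, 0L)

  # gene missing from annotation is a recorded skip
  other <- loc$exposure
  other$trait_id <- exposure_trait_id("NOPE", "cell")
  inst4 <- select_instruments(list(other), genes, loc$ld, params_flank)
  expect_length(inst4, 0L)
  expect_match(attr(inst4, "report")$note, "absent")
})

test_that("lowering the p threshold never adds instruments", {
  set.seed(24)
  loc <- simulate_locus(scenario("H1", causal_variance_exp = 0.03,
                                 n_exp = 5000, Q = 40), seed = 11)
  genes <- gene_annotation("GENE", "1", 1e6, 1e6 + 39 * 1000)
  prev <- NULL
  for (thr in c(1e-2, 1e-4, 1e-6, 1e-8)) {
    p <- selection_params("flank_gene", 1e6, p_threshold = thr)
    inst <- select_instruments(list(loc$exposure), genes, loc$ld, p)
    ids <- if (length(inst)) inst[[1]]$variants$snp_id else character()
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})
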