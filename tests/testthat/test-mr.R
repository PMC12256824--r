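test_that("Wald ratio arithmetic and both SE methods are correct", {
  w <- wald_ratio(make_pairs(1, 0.5, 0.05, 0.1))
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(w$pvalue, 2 * pnorm(-5), tolerance = 1e-12)

  w2 <- wald_ratio(make_pairs(-0.5, 0.2, 0.05, 0.1))
  expect_equal(w2$beta, -0.4)
  expect_equal(w2$se, 0.2)

  w3 <- wald_ratio(make_pairs(2, 0.6, 0.1, 0.2), "second_order")
  expect_equal(w3$se, sqrt(0.2^2 / 4 + 0.6^2 * 0.1^2 / 16), tolerance = 1e-12)

  expect_error(wald_ratio(make_pairs(0, 0.5, 0.05, 0.1)), "zero")
})

test_that("second-order Wald SE agrees with the Monte-Carlo SD of the ratio", {
  set.seed(41)
  bx <- 1; sx <- 0.05; by <- 0.3; sy <- 0.1
  draws <- rnorm(1e6, by, sy) / rnorm(1e6, bx, sx)
  mc_sd <- sd(draws)
  w <- wald_ratio(make_pairs(bx, by, sx, sy), "second_order")
  expect_equal(w$se, mc_sd, tolerance = 0.05)
})

test_that("IVW on one instrument equals the first-order Wald ratio exactly", {
  set.seed(42)
  for (rep in 1:100) {
    bx <- rnorm(1, 0, 0.5); if (bx == 0) bx <- 0.1
    p <- make_pairs(bx, rnorm(1), runif(1, 0.01, 0.2), runif(1, 0.01, 0.2))
    w <- wald_ratio(p)
    v <- ivw(p, "fe")
    expect_identical(v$beta, w$beta)
    expect_identical(v$se, w$se)
    expect_identical(v$pvalue, w$pvalue)
    # mre with a single instrument also reduces to fe
    m <- ivw(p, "mre")
    expect_identical(m$se, w$se)
    expect_equal(m$method, "ivw_fe")
  }
})

test_that("IVW pools two identical Wald ratios at the pooled precision", {
  # both ratios 0.5; weights w_j = bx_j^2/sy_j^2
  p <- make_pairs(c(1, 2), c(0.5, 1.0), c(0.05, 0.05), c(0.1, 0.1))
  v <- ivw(p, "fe")
  expect_equal(v$beta, 0.5, tolerance = 1e-12)
  expect_equal(v$se, 1 / sqrt(1 / 0.1^2 + 4 / 0.1^2), tolerance = 1e-12)
  # mre residuals are exactly zero here, so the floor keeps the fe SE
  expect_equal(ivw(p, "mre")$se, v$se, tolerance = 1e-12)
})

test_that("MR estimates are equivariant under exposure negation and scaling", {
  set.seed(43)
  p <- make_pairs(rnorm(4, 0.5, 0.1), rnorm(4, 0.1, 0.05),
                  runif(4, 0.02, 0.1), runif(4, 0.02, 0.1))
  v <- ivw(p)
  neg <- p; neg$beta_exp <- -neg$beta_exp
  expect_equal(ivw(neg)$beta, -v$beta, tolerance = 1e-12)
  expect_equal(ivw(neg)$se, v$se, tolerance = 1e-12)
  sc <- p; sc$beta_exp <- 3 * sc$beta_exp
  expect_equal(ivw(sc)$beta, v$beta / 3, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand formula and an independent step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(44)
  for (rep in 1:50) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # q is monotone in the rank of p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("batch MR applies the single/multi instrument rule and the FDR family", {
  set.seed(45)
  genes <- gene_annotation(c("G1", "G2"), "1", c(1e6, 1e6),
                           c(1e6 + 49e3, 1e6 + 49e3))
  loc1 <- simulate_locus(scenario("H4", alpha = 0.3,
                                  causal_variance_exp = 0.05,
                                  n_exp = 10000, n_out = 50000, Q = 50),
                         seed = 1, gene_id = "G1")
  loc2 <- simulate_locus(scenario("H1", causal_variance_exp = 0.05,
                                  n_exp = 20000, Q = 50, blocks = 2,
                                  n_signals = 2), seed = 2, gene_id = "G2")
  inst <- select_instruments(list(loc1$exposure, loc2$exposure), genes,
                             list(G1 = loc1$ld, G2 = loc2$ld),
                             selection_params())
  res <- run_mr_batch(inst, list(loc1$outcome, loc2$outcome))
  expect_s3_class(res, "mr_result")
  expect_equal(nrow(res), length(inst) * 2L)
  expect_true(all(res$method[res$n_snps == 1] == "wald_ratio"))
  expect_true(all(res$method[res$n_snps > 1] %in% c("ivw_fe", "ivw_mre")))
  expect_true(all(res$qvalue >= res$pvalue - 1e-15))
  # per-outcome family: q within an outcome equals BH on that outcome alone
  for (oid in unique(res$outcome_id)) {
    sel <- res$outcome_id == oid
    expect_equal(res$qvalue[sel], bh_oracle(res$pvalue[sel]),
                 tolerance = 1e-12)
  }
})

test_that("a strongly mediated gene lands in the significant set", {
  set.seed(46)
  loc <- simulate_locus(scenario("H4", alpha = 0.4,
                                 causal_variance_exp = 0.05,
                                 n_exp = 10000, n_out = 50000, Q = 50),
                        seed = 3, gene_id = "G1")
  genes <- gene_annotation("G1", "1", 1e6, 1e6 + 49e3)
  inst <- select_instruments(list(loc$exposure), genes, loc$ld,
                             selection_params())
  res <- run_mr_batch(inst, loc$outcome)
  expect_true(res$significant[res$gene_id == "G1"])
})

test_that("weighted estimate correlations behave at the degenerate ends", {
  set.seed(47)
  tb <- run_mr_batch(list(), list())  # empty edge: no rows
  expect_equal(nrow(tb), 0L)

  mk_tab <- function(beta, se, genes) {
    structure(data.frame(exposure_id = paste0(genes, "::x"), gene_id = genes,
                         cell_type = "x", outcome_id = "CAD",
                         method = "wald_ratio", n_snps = 1L, beta = beta,
                         se = se, pvalue = 0.5, qvalue = 0.5,
                         significant = FALSE),
              class = c("mr_result", "data.frame"))
  }
  g <- sprintf("G%02d", 1:20)
  a <- mk_tab(rnorm(20), runif(20, 0.05, 0.2), g)
  r <- estimate_correlation_matrix(list(a = a, b = a))
  expect_equal(unname(r["a", "b"]), 1, tolerance = 1e-12)

  b <- mk_tab(a$beta + rnorm(20, 0, 0.3), runif(20, 0.05, 0.2), g)
  r_eq <- estimate_correlation_matrix(list(a = a, b = b),
                                      weight_scheme = "equal")
  expect_equal(unname(r_eq["a", "b"]), cor(a$beta, b$beta),
               tolerance = 1e-12)
  # precision weights agree with the cov.wt cross-check
  w <- 1 / (a$se^2 + b$se^2)
  cw <- cov.wt(cbind(a$beta, b$beta), wt = w / sum(w), cor = TRUE,
               method = "ML")$cor[1, 2]
  r_w <- estimate_correlation_matrix(list(a = a, b = b))
  expect_equal(unname(r_w["a", "b"]), cw, tolerance = 1e-10)

  # too little overlap -> NA with a warning
  c_tab <- mk_tab(rnorm(2), c(0.1, 0.1), c("G01", "ZZZ"))
  expect_warning(r2 <- estimate_correlation_matrix(list(a = a, c = c_tab)),
                 "shared")
  expect_true(is.na(r2["a", "c"]))
})

test_that("correlated and independent cell-type effects are recovered in the estimate correlation", {
  set.seed(48)
  n_genes <- 40
  g <- sprintf("G%02d", seq_len(n_genes))
  true_beta <- rnorm(n_genes, 0, 0.3)
  noisy <- function(b) b + rnorm(n_genes, 0, 0.05)
  mk_tab <- function(beta) {
    structure(data.frame(exposure_id = paste0(g, "::x"), gene_id = g,
                         cell_type = "x", outcome_id = "CAD",
                         method = "wald_ratio", n_snps = 1L, beta = beta,
                         se = 0.05, pvalue = 0.5, qvalue = 0.5,
                         significant = FALSE),
              class = c("mr_result", "data.frame"))
  }
  shared <- estimate_correlation_matrix(
    list(a = mk_tab(noisy(true_beta)), b = mk_tab(noisy(true_beta))))
  indep <- estimate_correlation_matrix(
    list(a = mk_tab(rnorm(n_genes, 0, 0.3)),
         b = mk_tab(rnorm(n_genes, 0, 0.3))))
  expect_gt(shared["a", "b"], 0.9)
  expect_lt(abs(indep["a", "b"]), 0.45)
})
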