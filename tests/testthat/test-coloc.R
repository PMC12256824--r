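zset <- function(beta, se, trait_id = "t") {
  n <- length(beta)
  rec <- data.frame(snp_id = paste0("s", seq_len(n)), chrom = "1",
                    pos = 1000 * seq_len(n), effect_allele = "A",
                    other_allele = "G", eaf = 0.3, beta = beta, se = se,
                    pvalue = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
                    n = 1000, stringsAsFactors = FALSE)
  assoc_set(trait_id, rec, validate = FALSE)
}

test_that("log ABF matches the closed form, its limits, and numerical quadrature", {
  # collapses to 0 as the prior variance vanishes
  expect_equal(log_abf(0.3, 0.1, effect_prior(prior_sd = 1e-8)), 0,
               tolerance = 1e-6)
  # hand arithmetic: z = 0, V = 0.01, W = 0.15^2 -> 0.5 log(1 - 0.6923)
  r <- 0.0225 / (0.0225 + 0.01)
  expect_equal(log_abf(0, 0.1, effect_prior(prior_sd = 0.15)),
               0.5 * log(1 - r), tolerance = 1e-12)
  expect_equal(0.5 * log(1 - r), -0.589, tolerance = 1e-3)
  # increasing in |z| at fixed V
  l <- log_abf(c(0, 0.1, 0.2, 0.4), 0.1)
  expect_true(all(diff(l) > 0))
  # quadrature oracle over random (z, V, W)
  set.seed(51)
  for (rep in 1:25) {
    beta <- rnorm(1, 0, 0.3); se <- runif(1, 0.02, 0.3)
    sdW <- runif(1, 0.05, 0.5)
    expect_equal(log_abf(beta, se, effect_prior(prior_sd = sdW)),
                 abf_quadrature(beta, se, sdW), tolerance = 1e-6)
  }
  expect_error(log_abf(0.1, 0), "se > 0")
})

test_that("posteriors match brute-force enumeration over all causal configurations", {
  set.seed(52)
  priors <- coloc_priors()
  for (rep in 1:200) {
    Q <- sample(1:20, 1)
    b1 <- rnorm(Q, 0, 0.15); s1 <- runif(Q, 0.02, 0.2)
    b2 <- rnorm(Q, 0, 0.15); s2 <- runif(Q, 0.02, 0.2)
    res <- coloc_abf(zset(b1, s1, "e"), zset(b2, s2, "o"), priors)
    oracle <- coloc_enum_oracle(b1, s1, b2, s2, priors)
    expect_equal(unname(res$pph), oracle, tolerance = 1e-10)
    expect_equal(sum(res$pph), 1, tolerance = 1e-10)
  }
})

test_that("posteriors are normalized and trait swap exchanges PPH1 and PPH2 exactly", {
  set.seed(53)
  for (rep in 1:50) {
    Q <- sample(c(1, 2, 5, 50, 200), 1)
    scale1 <- sample(c(0.1, 1, 10), 1)  # include strong-signal extremes
    b1 <- rnorm(Q, 0, 0.1 * scale1); s1 <- runif(Q, 0.01, 0.2)
    b2 <- rnorm(Q, 0, 0.1); s2 <- runif(Q, 0.01, 0.2)
    a <- coloc_abf(zset(b1, s1, "x"), zset(b2, s2, "y"))
    b <- coloc_abf(zset(b2, s2, "y"), zset(b1, s1, "x"))
    expect_equal(sum(a$pph), 1, tolerance = 1e-10)
    expect_equal(a$pph[["PPH1"]], b$pph[["PPH2"]], tolerance = 1e-12)
    expect_equal(a$pph[["PPH2"]], b$pph[["PPH1"]], tolerance = 1e-12)
    expect_equal(a$pph[["PPH0"]], b$pph[["PPH0"]], tolerance = 1e-12)
    expect_equal(a$pph[["PPH3"]], b$pph[["PPH3"]], tolerance = 1e-12)
    expect_equal(a$pph[["PPH4"]], b$pph[["PPH4"]], tolerance = 1e-12)
  }
})

test_that("strong shared signals drive PPH4 to 1 and distinct low-LD signals drive PPH3 to 1", {
  Q <- 50
  b1 <- rep(0, Q); b2 <- rep(0, Q)
  b1[10] <- 2; b2[10] <- 2
  shared <- coloc_abf(zset(b1, rep(0.05, Q)), zset(b2, rep(0.05, Q)))
  expect_gt(shared$pph[["PPH4"]], 0.99)
  b2b <- rep(0, Q); b2b[40] <- 2
  distinct <- coloc_abf(zset(b1, rep(0.05, Q)), zset(b2b, rep(0.05, Q)))
  expect_gt(distinct$pph[["PPH3"]], 0.99)
})

test_that("all-null locus of 100 variants yields PPH0 above 0.99", {
  set.seed(54)
  loc <- simulate_locus(scenario("H0", Q = 100), seed = 11)
  res <- coloc_abf(loc$exposure, loc$outcome)
  expect_gt(res$pph[["PPH0"]], 0.99)
})

test_that("raising p12 never decreases PPH4 on fixed data", {
  set.seed(55)
  Q <- 30
  b1 <- rnorm(Q, 0, 0.2); s1 <- runif(Q, 0.02, 0.1)
  b2 <- rnorm(Q, 0, 0.2); s2 <- runif(Q, 0.02, 0.1)
  p12s <- c(1e-7, 1e-6, 1e-5, 1e-4)
  pph4 <- vapply(p12s, function(p12)
    coloc_abf(zset(b1, s1), zset(b2, s2),
              coloc_priors(p12 = p12))$pph[["PPH4"]], 1)
  expect_true(all(diff(pph4) >= -1e-12))
})

test_that("conditional statistics match the closed form", {
  ids <- c("s1", "s2")
  ld <- ld_matrix(matrix(c(1, 0.8, 0.8, 1), 2), ids)
  set <- zset(c(5, 4) * 0.1, c(0.1, 0.1))  # z = (5, 4)
  cond <- conditional_stats(set, ld, "s1")
  z <- cond$records$beta / cond$records$se
  expect_equal(z[1], 0)                      # conditioned on itself
  expect_equal(z[2], (4 - 0.8 * 5) / sqrt(1 - 0.64), tolerance = 1e-4)

  # conditioning on an uncorrelated variant leaves others unchanged
  ld0 <- ld_matrix(diag(3), paste0("s", 1:3))
  set3 <- zset(c(3, 2, 1) * 0.1, rep(0.1, 3))
  cond3 <- conditional_stats(set3, ld0, "s1", ridge = 0)
  expect_equal(cond3$records$beta[2:3], set3$records$beta[2:3],
               tolerance = 1e-10)
  expect_error(conditional_stats(set3, ld0, "nope"), "index")
})

test_that("stepwise decomposition finds the simulated number of signals", {
  # one causal variant -> one signal
  loc1 <- simulate_locus(scenario("H1", causal_variance_exp = 0.05,
                                  n_exp = 20000, Q = 60), seed = 21)
  sig1 <- decompose_signals(loc1$exposure, loc1$ld)
  expect_length(sig1, 1L)
  expect_length(attr(sig1, "index_snps"), 1L)

  # two causal variants in unlinked blocks -> two signals
  loc2 <- simulate_locus(scenario("H1", causal_variance_exp = 0.05,
                                  n_exp = 20000, Q = 60, blocks = 2,
                                  n_signals = 2), seed = 22)
  sig2 <- decompose_signals(loc2$exposure, loc2$ld)
  expect_length(sig2, 2L)

  # null locus -> no signal
  loc0 <- simulate_locus(scenario("H0", Q = 60), seed = 23)
  expect_length(decompose_signals(loc0$exposure, loc0$ld), 0L)
})

test_that("multi-signal colocalization reduces to single coloc and isolates the shared signal", {
  # single signal on both traits: identical to coloc_abf
  loc <- simulate_locus(scenario("H4", alpha = 0.3,
                                 causal_variance_exp = 0.05,
                                 n_exp = 10000, n_out = 20000, Q = 60),
                        seed = 24)
  single <- coloc_abf(loc$exposure, loc$outcome)
  multi <- coloc_multi(loc$exposure, loc$outcome, loc$ld)
  expect_equal(multi$pph, single$pph, tolerance = 1e-10)
  expect_null(multi$signal_pairs)

  # trait A has two signals, trait B shares only one of them
  set.seed(25)
  Q <- 80
  ld <- simulate_ld(Q, 0.9, blocks = 2)
  R <- unclass(ld)
  chol_R <- chol(R)
  b_a <- numeric(Q); b_a[c(10, 60)] <- sqrt(0.05)
  b_b <- numeric(Q); b_b[60] <- sqrt(0.05)
  mkz <- function(n, b) sqrt(n) * as.vector(R %*% b) +
    as.vector(crossprod(chol_R, rnorm(Q)))
  se <- rep(1 / sqrt(2 * 20000 * 0.3 * 0.7), Q)
  za <- mkz(20000, b_a); zb <- mkz(20000, b_b)
  a <- zset(za * se, se, "a"); b <- zset(zb * se, se, "b")
  a$records$snp_id <- rownames(ld); b$records$snp_id <- rownames(ld)
  res <- coloc_multi(a, b, ld)
  expect_gte(length(res$signal_pairs), 2L)
  pph4s <- vapply(res$signal_pairs, function(p) p$pph[["PPH4"]], 1)
  expect_gt(res$max_pph4, 0.8)        # the shared signal colocalizes
  expect_lt(min(pph4s), 0.2)          # the unshared pair does not
})
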