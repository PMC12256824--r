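# Fixture builders and independent oracles shared across the suite.

VCOLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pvalue", "n")

# Random valid variant table (optionally with missing eaf/n entries).
rand_records <- function(n, chrom = "1", pos_start = 1000,
                         with_missing = TRUE) {
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), "")
  beta <- stats::rnorm(n, 0, 0.2)
  se <- stats::runif(n, 0.01, 0.3)
  eaf <- stats::runif(n, 0.01, 0.99)
  if (with_missing && n > 2) eaf[sample.int(n, 1L)] <- NA
  data.frame(
    snp_id = sprintf("rs%05d", sample.int(99999, n)),
    chrom = chrom, pos = pos_start + seq_len(n) * 500,
    effect_allele = ea, other_allele = unname(oa),
    eaf = eaf, beta = beta, se = se,
    pvalue = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
    n = sample(c(500, 1000, NA), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

rand_assoc_set <- function(n, trait_id = "trait", ...) {
  assoc_set(trait_id, rand_records(n, ...))
}

# Random positive-definite correlation matrix of dimension q.
rand_corr <- function(q, snp_ids = paste0("s", seq_len(q))) {
  a <- matrix(stats::rnorm(q * q), q)
  s <- crossprod(a) + diag(q) * 0.5
  r <- stats::cov2cor(s)
  ld_matrix(r, snp_ids)
}

# Independent BH step-up oracle: sort, find largest i with
# p_(i) <= i/m * q  -- implemented as the adjusted-p form
# q_(i) = min_{j >= i} p_(j) * m / j, by explicit loop.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  run <- Inf
  for (i in seq(m, 1)) {
    run <- min(run, ps[i] * m / i)
    q[i] <- min(run, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force five-hypothesis colocalization oracle: enumerate all
# Q^2 + 2Q + 1 causal configurations in plain arithmetic.
coloc_enum_oracle <- function(b1, s1, b2, s2, priors,
                              prior1 = effect_prior(),
                              prior2 = effect_prior()) {
  bf1 <- exp(log_abf(b1, s1, prior1))
  bf2 <- exp(log_abf(b2, s2, prior2))
  Q <- length(b1)
  w0 <- 1
  w1 <- priors$p1 * sum(bf1)
  w2 <- priors$p2 * sum(bf2)
  w3 <- 0
  for (i in seq_len(Q)) for (j in seq_len(Q)) if (i != j)
    w3 <- w3 + priors$p1 * priors$p2 * bf1[i] * bf2[j]
  w4 <- priors$p12 * sum(bf1 * bf2)
  w <- c(w0, w1, w2, w3, w4)
  w / sum(w)
}

# Quadrature oracle for the approximate Bayes factor: the normal-normal
# marginal likelihood ratio integrated numerically over the effect prior.
abf_quadrature <- function(beta, se, prior_sd) {
  num <- stats::integrate(function(b)
    stats::dnorm(beta, b, se) * stats::dnorm(b, 0, prior_sd),
    lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  den <- stats::dnorm(beta, 0, se)
  log(num / den)
}

# Tiny aligned harmonized-pairs table for estimator tests.
make_pairs <- function(bx, by, sx, sy) {
  data.frame(snp_id = paste0("s", seq_along(bx)),
             beta_exp = bx, se_exp = sx, beta_out = by, se_out = sy,
             kept = TRUE)
}
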