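# Bayesian colocalization from marginal summary statistics: per-SNP
# approximate Bayes factors (ABFs), enumeration of the five causal
# configurations (H0: neither trait associated; H1/H2: only one trait;
# H3: both, different causal variants; H4: both, the same causal variant),
# all mixture sums in log space, plus a multi-signal mode that decomposes
# each trait into approximately independent signals by stepwise conditional
# analysis and reports the maximum PPH4 over signal pairs.

#' Per-SNP effect-size prior
#'
#' Normal prior on the true effect with standard deviation `prior_sd`
#' (prior variance W = prior_sd^2). Defaults follow the established
#' colocalization convention: 0.15 for quantitative traits measured in
#' trait-SD units, 0.2 (log-odds) for case-control traits.
#'
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param prior_sd overrides the default standard deviation.
#' @return list of class `effect_prior`.
#' @export
effect_prior <- function(trait_type = c("quantitative", "case_control"),
                         prior_sd = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(prior_sd))
    prior_sd <- if (trait_type == "quantitative") 0.15 else 0.2
  stopifnot(prior_sd > 0)
  structure(list(trait_type = trait_type, prior_sd = prior_sd),
            class = "effect_prior")
}

#' Colocalization priors
#'
#' Per-SNP prior probabilities that a variant is causal for trait 1 only
#' (`p1`), trait 2 only (`p2`), or both (`p12`). Defaults are the standard
#' p1 = p2 = 1e-4, p12 = 1e-5. A warning is raised if `p12 > min(p1, p2)`
#' or if `Q * (p1 + p2 + p12)` approaches 1 for the locus SNP count Q
#' (checked at use).
#'
#' @param p1,p2,p12 per-SNP priors in (0, 1).
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1)
  if (p12 > min(p1, p2))
    stop("p12 must not exceed min(p1, p2)")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Log approximate Bayes factor for one marginal association
#'
#' Wakefield-style ABF for a marginal estimate `beta` with standard error
#' `se` under a normal effect prior with variance `W = prior_sd^2`: with
#' `z = beta/se`, `V = se^2`, `r = W/(W+V)`,
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)`.
#' Increasing in |z| for fixed V; tends to 0 as W tends to 0.
#'
#' @param beta,se marginal effect and standard error (`se > 0`),
#'   vectorized.
#' @param prior an [effect_prior()].
#' @return log ABF (natural log), same length as `beta`.
#' @export
log_abf <- function(beta, se, prior = effect_prior()) {
  if (any(se <= 0)) stop("log_abf requires se > 0")
  W <- prior$prior_sd^2
  V <- se^2
  r <- W / (W + V)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

coloc_result <- function(pph, n_snps, priors, prior_sd, snp_pp_h4 = NULL,
                         signal_pairs = NULL) {
  names(pph) <- paste0("PPH", 0:4)
  max_pph4 <- if (length(signal_pairs))
    max(vapply(signal_pairs, function(s) s$pph[["PPH4"]], 0))
  else pph[["PPH4"]]
  structure(list(pph = pph, n_snps = n_snps, priors = priors,
                 prior_sd = prior_sd, snp_pp_h4 = snp_pp_h4,
                 signal_pairs = signal_pairs, max_pph4 = max_pph4),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, digits = 3, ...) {
  cat(sprintf("<coloc_result> Q = %d shared variants\n", x$n_snps))
  print(round(x$pph, digits))
  if (length(x$signal_pairs))
    cat(sprintf("multi-signal: %d signal pair(s), max PPH4 = %s\n",
                length(x$signal_pairs), format(x$max_pph4, digits = digits)))
  invisible(x)
}

#' @export
summary.coloc_result <- function(object, pph4_threshold = 0.8, ...) {
  c(object$pph, max_pph4 = object$max_pph4, n_snps = object$n_snps,
    colocalized = as.numeric(object$max_pph4 >= pph4_threshold))
}

# Shared-variant intersection with optional allele alignment.
coloc_intersect <- function(set1, set2, align = TRUE,
                            policy = palindrome_policy()) {
  if (align && all(c("effect_allele", "other_allele") %in%
                   names(set1$records))) {
    al <- align_sets(set1, set2, policy)
    list(b1 = al$exposure$records$beta, s1 = al$exposure$records$se,
         b2 = al$outcome$records$beta, s2 = al$outcome$records$se,
         snp_id = al$exposure$records$snp_id)
  } else {
    shared <- intersect(set1$records$snp_id, set2$records$snp_id)
    r1 <- set1$records[match(shared, set1$records$snp_id), ]
    r2 <- set2$records[match(shared, set2$records$snp_id), ]
    list(b1 = r1$beta, s1 = r1$se, b2 = r2$beta, s2 = r2$se,
         snp_id = shared)
  }
}

#' Five-hypothesis colocalization from two sets of summary statistics
#'
#' Computes posterior probabilities of the five causal configurations at a
#' locus from per-SNP log ABFs `l1`, `l2` of the two traits. In log space,
#' with `S1 = logsumexp(l1)`, `S2 = logsumexp(l2)`,
#' `S12 = logsumexp(l1 + l2)`, the unnormalized log posteriors are
#' `L0 = 0`, `L1 = log p1 + S1`, `L2 = log p2 + S2`,
#' `L3 = log(p1 p2) + log(exp(S1 + S2) - exp(S12))` (stable log-diff-exp;
#' the subtraction removes same-SNP configurations from the two-causal sum),
#' `L4 = log p12 + S12`; posteriors are their softmax. Significant
#' colocalization is conventionally `PPH4 >= 0.8`.
#'
#' @param set1,set2 [assoc_set()] objects sharing at least one variant;
#'   `set1` is conventionally the expression exposure, `set2` the outcome.
#'   When allele columns are present and `align = TRUE`, the two sets are
#'   harmonized first (the posteriors depend on z only through z^2, but
#'   alignment is enforced for auditability of the shared-variant table).
#' @param priors a [coloc_priors()].
#' @param prior1,prior2 [effect_prior()] for each trait.
#' @param align harmonize allele orientation before intersecting.
#' @return a `coloc_result`: posteriors `PPH0..PPH4` (summing to 1 within
#'   1e-10), the shared-SNP count `Q`, the priors used, and the per-SNP
#'   posterior of being the shared causal variant under H4 (`snp_pp_h4`,
#'   for credible-set reporting).
#' @export
coloc_abf <- function(set1, set2, priors = coloc_priors(),
                      prior1 = effect_prior(set1$trait_type),
                      prior2 = effect_prior(set2$trait_type),
                      align = TRUE) {
  pieces <- coloc_intersect(set1, set2, align)
  Q <- length(pieces$snp_id)
  if (Q == 0)
    stop("colocalization failed: no shared variants between '",
         set1$trait_id, "' and '", set2$trait_id, "'")
  if (Q * (priors$p1 + priors$p2 + priors$p12) >= 1)
    warning("per-SNP priors sum to >= 1 over the locus (Q = ", Q,
            "); posteriors unreliable")
  l1 <- log_abf(pieces$b1, pieces$s1, prior1)
  l2 <- log_abf(pieces$b2, pieces$s2, prior2)
  S1 <- logsumexp(l1)
  S2 <- logsumexp(l2)
  S12 <- logsumexp(l1 + l2)
  L0 <- 0
  L1 <- log(priors$p1) + S1
  L2 <- log(priors$p2) + S2
  d <- logdiffexp(S1 + S2, S12)
  if (is.nan(d) || Q == 1L) {
    # single shared SNP (no distinct-variant configuration) or the
    # difference underflowed: H3 carries no mass
    if (is.nan(d) && Q > 1L)
      warning("H3 mass numerically non-positive; clamped to zero")
    L3 <- -Inf
  } else {
    L3 <- log(priors$p1) + log(priors$p2) + d
  }
  L4 <- log(priors$p12) + S12
  L <- c(L0, L1, L2, L3, L4)
  m <- max(L)
  pph <- exp(L - m) / sum(exp(L - m))
  snp_pp <- exp((l1 + l2) - S12)
  names(snp_pp) <- pieces$snp_id
  coloc_result(pph, Q, priors,
               c(trait1 = prior1$prior_sd, trait2 = prior2$prior_sd),
               snp_pp_h4 = snp_pp)
}

#' Conditional summary statistics given index variants
#'
#' Standard summary-statistics conditional adjustment: for each variant j,
#' the z-score conditional on the index set S is
#' `z_{j|S} = (z_j - R_{jS} R_{SS}^{-1} z_S) / sqrt(1 - R_{jS} R_{SS}^{-1} R_{Sj})`.
#' Standard errors are kept (the marginal se is retained as the scale), so
#' betas are rescaled to `beta = z * se`; p-values are recomputed. Index
#' variants themselves get z = 0. A small ridge is added to `R_SS` for
#' numerical stability.
#'
#' @param set an [assoc_set()].
#' @param ld an [ld_matrix()] covering the set's variants.
#' @param index_snps character vector of index variant ids (subset of the
#'   set).
#' @param ridge diagonal ridge added to `R_SS` (default 1e-6).
#' @return the conditionally adjusted `assoc_set`.
#' @export
conditional_stats <- function(set, ld, index_snps, ridge = 1e-6) {
  rec <- set$records
  if (!all(index_snps %in% rec$snp_id))
    stop("index variant(s) not in the association set")
  if (!all(rec$snp_id %in% rownames(ld)))
    stop("association set contains variants absent from the LD reference")
  if (length(index_snps) == 0L) return(set)
  R <- unclass(ld)[rec$snp_id, rec$snp_id, drop = FALSE]
  S <- match(index_snps, rec$snp_id)
  z <- rec$beta / rec$se
  Rss <- R[S, S, drop = FALSE] + diag(ridge, length(S))
  inv <- tryCatch(solve(Rss), error = function(e)
    stop("conditioning failed: singular LD submatrix for the index set"))
  RjS <- R[, S, drop = FALSE]
  adj <- RjS %*% inv
  z_cond <- z - as.vector(adj %*% z[S])
  denom <- 1 - rowSums(adj * RjS)
  denom[denom < 1e-10] <- NA_real_  # fully explained by the index set
  z_new <- z_cond / sqrt(denom)
  z_new[S] <- 0
  z_new[is.na(z_new)] <- 0
  rec$beta <- z_new * rec$se
  rec$pvalue <- pmax(2 * stats::pnorm(-abs(z_new)), .Machine$double.xmin)
  set$records <- rec
  set
}

#' Decompose a locus into approximately independent signals
#'
#' Forward stepwise selection on conditional p-values: repeatedly add the
#' variant with the smallest p conditional on the current index set while
#' that p is below `p_enter`, up to `max_signals`. One conditional
#' association set is emitted per selected index, conditioned on all the
#' *other* indices, so each carries one isolated signal. This is a
#' deliberate, documented approximation to fine-mapping-based signal
#' decomposition (sum-of-single-effects credible sets); it does not claim
#' numerical equivalence with it.
#'
#' @param set an [assoc_set()].
#' @param ld an [ld_matrix()].
#' @param p_enter conditional p-value threshold to admit a signal
#'   (default 1e-6, conservative).
#' @param max_signals cap on the number of signals (default 10).
#' @param ridge passed to [conditional_stats()].
#' @return list of conditional `assoc_set`s (empty when the locus has no
#'   signal at `p_enter`); attribute `index_snps` holds the selected ids.
#' @export
decompose_signals <- function(set, ld, p_enter = 1e-6, max_signals = 10L,
                              ridge = 1e-6) {
  idx <- character()
  repeat {
    cur <- if (length(idx)) conditional_stats(set, ld, idx, ridge) else set
    cand <- cur$records[!cur$records$snp_id %in% idx, , drop = FALSE]
    if (nrow(cand) == 0L) break
    best <- order(cand$pvalue, cand$pos, cand$snp_id)[1L]
    if (cand$pvalue[best] >= p_enter) break
    idx <- c(idx, cand$snp_id[best])
    if (length(idx) >= max_signals) break
  }
  out <- if (length(idx) <= 1L) {
    if (length(idx) == 0L) list() else list(set)
  } else {
    lapply(seq_along(idx), function(i)
      conditional_stats(set, ld, idx[-i], ridge))
  }
  attr(out, "index_snps") <- idx
  out
}

#' Multi-signal colocalization with max-PPH4 reporting
#'
#' Decomposes both traits into approximately independent signals
#' ([decompose_signals()]), runs [coloc_abf()] on every cross pair of
#' per-signal conditional sets (falling back to the marginal set for a
#' trait with at most one signal), and reports the maximum PPH4 across
#' signal pairs, mirroring the "maximum PPH4 across credible sets" rule for
#' loci with more than one causal variant.
#'
#' @param set1,set2 [assoc_set()] objects (aligned or alignable).
#' @param ld an [ld_matrix()] covering both (used for the conditional
#'   decomposition).
#' @param priors a [coloc_priors()].
#' @param prior1,prior2 [effect_prior()] per trait.
#' @param p_enter,max_signals,ridge see [decompose_signals()].
#' @param align see [coloc_abf()].
#' @return a `coloc_result` whose `pph` is the top-level (best-pair)
#'   posterior, with all signal-pair results in `signal_pairs` and
#'   `max_pph4` their PPH4 maximum.
#' @export
coloc_multi <- function(set1, set2, ld, priors = coloc_priors(),
                        prior1 = effect_prior(set1$trait_type),
                        prior2 = effect_prior(set2$trait_type),
                        p_enter = 1e-6, max_signals = 10L, ridge = 1e-6,
                        align = TRUE) {
  if (align && all(c("effect_allele", "other_allele") %in%
                   names(set1$records))) {
    al <- align_sets(set1, set2)
    set1 <- al$exposure; set2 <- al$outcome
  }
  sig1 <- decompose_signals(set1, ld, p_enter, max_signals, ridge)
  sig2 <- decompose_signals(set2, ld, p_enter, max_signals, ridge)
  if (length(sig1) <= 1L && length(sig2) <= 1L)
    return(coloc_abf(set1, set2, priors, prior1, prior2, align = FALSE))
  if (length(sig1) == 0L) sig1 <- list(set1)
  if (length(sig2) == 0L) sig2 <- list(set2)
  pairs <- list()
  for (i in seq_along(sig1)) for (j in seq_along(sig2)) {
    res <- coloc_abf(sig1[[i]], sig2[[j]], priors, prior1, prior2,
                     align = FALSE)
    res$signal_index <- c(trait1 = i, trait2 = j)
    pairs[[length(pairs) + 1L]] <- res
  }
  best <- which.max(vapply(pairs, function(p) p$pph[["PPH4"]], 0))
  top <- pairs[[best]]
  coloc_result(top$pph, top$n_snps, priors,
               c(trait1 = prior1$prior_sd, trait2 = prior2$prior_sd),
               snp_pp_h4 = top$snp_pp_h4, signal_pairs = pairs)
}
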