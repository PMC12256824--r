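# Two-sample MR estimators on harmonized summary statistics: Wald ratio
# for single-instrument exposures, inverse-variance weighting (fixed-effect
# or multiplicative random-effects) for multi-instrument exposures, BH FDR
# across a test family, and the cross-cell-type weighted correlation of
# estimates. P-values use the standard normal throughout, the usual
# summary-statistics convention.

mr_estimate <- function(exposure_id, outcome_id, method, beta, se, n_snps) {
  pvalue <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  out <- data.frame(exposure_id = exposure_id, outcome_id = outcome_id,
                    method = method, beta = beta, se = se,
                    pvalue = pvalue, qvalue = NA_real_,
                    n_snps = as.integer(n_snps),
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_estimate", class(out))
  out
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect of the exposure on the outcome per unit exposure is
#' `beta_out / beta_exp`. The default first-order standard error
#' `se_out / |beta_exp|` ignores exposure-side sampling noise (the
#' convention of standard two-sample MR software); the second-order delta
#' approximation
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`
#' additionally propagates it.
#'
#' @param pair a single row of [harmonize()] output (or any list with
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`).
#' @param se_method `"first_order"` (default) or `"second_order"`.
#' @param exposure_id,outcome_id labels carried into the result.
#' @return one-row data.frame of class `mr_estimate` with `beta`, `se`,
#'   `pvalue` (two-sided normal), `n_snps = 1`.
#' @export
wald_ratio <- function(pair, se_method = c("first_order", "second_order"),
                       exposure_id = "exposure", outcome_id = "outcome") {
  se_method <- match.arg(se_method)
  bx <- pair$beta_exp[1]; by <- pair$beta_out[1]
  sx <- pair$se_exp[1]; sy <- pair$se_out[1]
  if (!is.finite(bx) || bx == 0)
    stop("Wald ratio undefined: exposure beta is zero")
  beta <- by / bx
  se <- if (se_method == "first_order") sy / abs(bx)
        else sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  mr_estimate(exposure_id, outcome_id, "wald_ratio", beta, se, 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Combines per-variant Wald ratios with weights
#' `w_j = beta_exp_j^2 / se_out_j^2`:
#' `beta = sum(beta_exp_j * beta_out_j / se_out_j^2) / sum(w_j)`.
#' The fixed-effect standard error is `1 / sqrt(sum(w_j))`; the
#' multiplicative random-effects variant (`"mre"`, the default of common MR
#' software and this package) multiplies it by `max(1, phi)`, where `phi`
#' is the square-root of the weighted residual variance about the fitted
#' slope with `k - 1` degrees of freedom. A single instrument forces the
#' fixed-effect form, making `ivw` coincide exactly with
#' [wald_ratio()] (first-order) at k = 1.
#'
#' @param pairs [harmonize()] output rows (k >= 1 retained instruments).
#' @param variant `"mre"` or `"fe"`.
#' @param exposure_id,outcome_id labels carried into the result.
#' @return one-row data.frame of class `mr_estimate`.
#' @export
ivw <- function(pairs, variant = c("mre", "fe"),
                exposure_id = "exposure", outcome_id = "outcome") {
  variant <- match.arg(variant)
  if (NROW(pairs) == 0) stop("ivw requires at least one harmonized pair")
  bx <- pairs$beta_exp; by <- pairs$beta_out; sy <- pairs$se_out
  stopifnot(all(sy > 0))
  k <- length(bx)
  if (k == 1L) {
    # single instrument: algebraically (and exactly) the Wald ratio
    beta <- by / bx
    se <- sy / abs(bx)
  } else {
    w <- bx^2 / sy^2
    beta <- sum(bx * by / sy^2) / sum(w)
    se <- 1 / sqrt(sum(w))
  }
  method <- "ivw_fe"
  if (variant == "mre" && k > 1L) {
    # weighted residual SD about the fitted slope (slope-only WLS)
    rss <- sum((by - beta * bx)^2 / sy^2)
    phi <- sqrt(rss / (k - 1))
    se <- se * max(1, phi)
    method <- "ivw_mre"
  }
  mr_estimate(exposure_id, outcome_id, method, beta, se, k)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1
#' and mapped back to the input order.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return q-values in input order, `q >= p` elementwise.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Batch two-sample MR across instrument sets and outcomes
#'
#' For every instrument set x outcome pair with at least one harmonized
#' instrument, estimates the causal effect with the Wald ratio (one
#' instrument) or IVW (more than one) — the standard rule for cis-MR — and
#' adjusts p-values by BH FDR within the configured family. This also
#' serves PheWAS-style runs: one exposure against many outcome phenotypes
#' with FDR across phenotypes.
#'
#' @param instruments list of [instrument_set()].
#' @param outcomes list of outcome [assoc_set()] (or a single one).
#' @param policy a [palindrome_policy()].
#' @param ivw_variant `"mre"` or `"fe"`.
#' @param se_method Wald-ratio SE method.
#' @param fdr_family `"per_outcome"` (BH within each outcome's tests,
#'   the default) or `"global"` (one family across all tests).
#' @param alpha FDR significance level used for the `significant` flag.
#' @return data.frame of class `mr_result`: one row per exposure x outcome,
#'   columns `exposure_id`, `gene_id`, `cell_type`, `outcome_id`, `method`,
#'   `n_snps`, `beta`, `se`, `pvalue`, `qvalue`, `significant`. Skipped
#'   pairs (no shared variants) are recorded in attribute `skips`.
#' @export
run_mr_batch <- function(instruments, outcomes, policy = palindrome_policy(),
                         ivw_variant = "mre", se_method = "first_order",
                         fdr_family = c("per_outcome", "global"),
                         alpha = 0.05) {
  fdr_family <- match.arg(fdr_family)
  if (inherits(outcomes, "assoc_set")) outcomes <- list(outcomes)
  rows <- list()
  skips <- list()
  for (inst in instruments) {
    exp_id <- exposure_trait_id(inst$gene_id, inst$cell_type)
    for (out in outcomes) {
      h <- tryCatch(harmonize(inst, out, policy), error = function(e) NULL)
      if (is.null(h)) {
        skips[[length(skips) + 1L]] <- data.frame(
          exposure_id = exp_id, outcome_id = out$trait_id,
          reason = "no shared variants")
        next
      }
      h <- h[h$kept & h$beta_exp != 0, , drop = FALSE]
      if (nrow(h) == 0) {
        skips[[length(skips) + 1L]] <- data.frame(
          exposure_id = exp_id, outcome_id = out$trait_id,
          reason = "no harmonized instruments")
        next
      }
      est <- if (nrow(h) == 1L)
        wald_ratio(h, se_method, exposure_id = exp_id,
                   outcome_id = out$trait_id)
      else ivw(h, ivw_variant, exposure_id = exp_id,
               outcome_id = out$trait_id)
      rows[[length(rows) + 1L]] <- est
    }
  }
  if (length(rows) == 0) {
    res <- data.frame(exposure_id = character(), outcome_id = character(),
                      method = character(), beta = numeric(),
                      se = numeric(), pvalue = numeric(),
                      qvalue = numeric(), n_snps = integer(),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, rows)
  }
  if (nrow(res)) {
    if (fdr_family == "global") {
      res$qvalue <- bh_fdr(res$pvalue)
    } else {
      for (oid in unique(res$outcome_id)) {
        sel <- res$outcome_id == oid
        res$qvalue[sel] <- bh_fdr(res$pvalue[sel])
      }
    }
  }
  ids <- split_trait_id(res$exposure_id)
  res$gene_id <- ids$gene_id
  res$cell_type <- ids$cell_type
  res$significant <- res$qvalue < alpha
  res <- res[, c("exposure_id", "gene_id", "cell_type", "outcome_id",
                 "method", "n_snps", "beta", "se", "pvalue", "qvalue",
                 "significant")]
  rownames(res) <- NULL
  class(res) <- c("mr_result", "data.frame")
  attr(res, "skips") <- if (length(skips)) do.call(rbind, skips) else NULL
  attr(res, "fdr_family") <- fdr_family
  res
}

#' Pairwise weighted correlation of MR estimates across cell types
#'
#' For each pair of MR result tables (e.g. one per cell type, plus a bulk
#' table), aligns estimates on shared gene x outcome keys and computes the
#' weighted Pearson correlation of the causal-effect estimates. The default
#' weight for a shared estimate pair is the precision of the difference of
#' the two estimates, `w = 1 / (se_x^2 + se_y^2)`; `"equal"` gives the
#' plain Pearson correlation.
#'
#' @param tables named list of `mr_result` tables (one per cell type /
#'   bulk source).
#' @param weight_scheme `"precision"` or `"equal"`.
#' @param min_shared minimum shared keys for a defined entry (default 2;
#'   pairs below it get `NA` with a warning).
#' @return symmetric correlation matrix with unit diagonal, attribute
#'   `n_shared` holding the per-pair overlap counts.
#' @export
estimate_correlation_matrix <- function(tables,
                                        weight_scheme = c("precision", "equal"),
                                        min_shared = 2L) {
  weight_scheme <- match.arg(weight_scheme)
  nm <- names(tables)
  stopifnot(!is.null(nm), !any(nm == ""))
  k <- length(tables)
  r <- diag(1, k); dimnames(r) <- list(nm, nm)
  n_shared <- matrix(0L, k, k, dimnames = list(nm, nm))
  keyed <- lapply(tables, function(tb) {
    key <- paste(tb$gene_id, tb$outcome_id, sep = "\r")
    data.frame(key = key, beta = tb$beta, se = tb$se,
               stringsAsFactors = FALSE)
  })
  for (i in seq_len(k)) n_shared[i, i] <- nrow(keyed[[i]])
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    a <- keyed[[i]]; b <- keyed[[j]]
    shared <- intersect(a$key, b$key)
    n_shared[i, j] <- n_shared[j, i] <- length(shared)
    if (length(shared) < min_shared) {
      warning("fewer than ", min_shared, " shared estimates between '",
              nm[i], "' and '", nm[j], "'; correlation set to NA")
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    x <- a[match(shared, a$key), ]
    y <- b[match(shared, b$key), ]
    w <- if (weight_scheme == "precision") 1 / (x$se^2 + y$se^2)
         else rep(1, length(shared))
    r[i, j] <- r[j, i] <- weighted_pearson(x$beta, y$beta, w)
  }
  attr(r, "n_shared") <- n_shared
  attr(r, "weight_scheme") <- weight_scheme
  r
}
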