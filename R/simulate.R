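# Synthetic-locus simulator: LD-structured marginal summary statistics for
# an expression exposure and a GWAS outcome under each colocalization
# hypothesis and under MR mediation, generated directly in z-space from the
# standard multivariate-normal model of marginal statistics under LD
# (z ~ MVN(sqrt(n) R b, R)) — no individual-level genotypes. Traits are on
# the standardized scale (trait SD = 1), so the quantitative coloc prior
# applies without rescaling.

#' Block-diagonal AR(1) LD matrix
#'
#' Within a block, `r_ij = ld_rho^|i-j|`; zero between blocks. Positive
#' semi-definite by construction for `|ld_rho| < 1`.
#'
#' @param Q number of variants.
#' @param ld_rho AR(1) decay parameter, `|ld_rho| < 1`.
#' @param blocks number of equal-size blocks (default 1).
#' @param snp_prefix id prefix; ids are `<prefix><1..Q>`.
#' @return an [ld_matrix()].
#' @export
simulate_ld <- function(Q, ld_rho = 0.9, blocks = 1L, snp_prefix = "snp") {
  stopifnot(Q >= 1, abs(ld_rho) < 1, blocks >= 1)
  block_id <- sort(rep_len(seq_len(blocks), Q))
  idx <- seq_len(Q)
  r <- ld_rho^abs(outer(idx, idx, "-"))
  same <- outer(block_id, block_id, "==")
  r[!same] <- 0
  ld_matrix(r, paste0(snp_prefix, idx))
}

#' Simulation scenario
#'
#' The generative conditions for one locus: the causal configuration
#' (`hypothesis`), the mediated causal effect `alpha` (outcome change per
#' SD of expression, used under H4), per-signal causal variance fractions,
#' sample sizes, locus size and LD decay.
#'
#' @param hypothesis `"H0"` (neither trait associated), `"H1"` (exposure
#'   only), `"H2"` (outcome only), `"H3"` (both, distinct causal variants),
#'   `"H4"` (both, shared causal variant).
#' @param alpha mediated effect under H4 (outcome per unit exposure).
#' @param causal_variance_exp,causal_variance_out fraction of trait
#'   variance explained by each causal variant; under H4 the outcome's
#'   causal effect is `alpha` times the exposure's, so
#'   `causal_variance_out` is ignored there.
#' @param n_exp,n_out sample sizes.
#' @param Q variants per locus.
#' @param ld_rho AR(1) LD decay.
#' @param blocks LD blocks.
#' @param n_signals causal variants per trait (placed in distinct blocks
#'   when possible).
#' @param cross_trait_r2_min,cross_trait_r2_max admissible LD range between
#'   the exposure's and the outcome's causal variants under H3 (cap low for
#'   genuinely independent signals; raise the floor to emulate
#'   LD-confounded loci).
#' @return list of class `scenario`.
#' @export
scenario <- function(hypothesis = c("H4", "H0", "H1", "H2", "H3"),
                     alpha = 0.2,
                     causal_variance_exp = 0.01,
                     causal_variance_out = 0.01,
                     n_exp = 10000, n_out = 10000,
                     Q = 500, ld_rho = 0.9, blocks = 1L,
                     n_signals = 1L,
                     cross_trait_r2_min = 0, cross_trait_r2_max = 0.01) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(causal_variance_exp > 0, causal_variance_exp < 1,
            causal_variance_out > 0, causal_variance_out < 1,
            is.finite(alpha), Q >= 1, abs(ld_rho) < 1, n_signals >= 1,
            cross_trait_r2_min >= 0, cross_trait_r2_max <= 1,
            cross_trait_r2_min <= cross_trait_r2_max)
  if (hypothesis == "H3" && Q < 2)
    stop("H3 requires at least two variants (distinct causal variants)")
  structure(list(hypothesis = hypothesis, alpha = alpha,
                 causal_variance_exp = causal_variance_exp,
                 causal_variance_out = causal_variance_out,
                 n_exp = n_exp, n_out = n_out, Q = Q, ld_rho = ld_rho,
                 blocks = blocks, n_signals = n_signals,
                 cross_trait_r2_min = cross_trait_r2_min,
                 cross_trait_r2_max = cross_trait_r2_max),
            class = "scenario")
}

# Pick n_signals causal indices, one per block when possible, otherwise
# spread within the locus.
pick_causal_indices <- function(Q, blocks, n_signals) {
  block_id <- sort(rep_len(seq_len(blocks), Q))
  if (n_signals <= blocks) {
    use <- sample(seq_len(blocks), n_signals)
    vapply(use, function(b) {
      cand <- which(block_id == b)
      cand[sample.int(length(cand), 1L)]
    }, 1L)
  } else {
    sort(sample.int(Q, n_signals))
  }
}

# Draw marginal z-vector(s): z = sqrt(n) R b + L' eps, R = L'L (chol).
draw_z <- function(n, R, chol_R, b, ndraws = 1L) {
  mu <- if (all(b == 0)) numeric(nrow(R)) else sqrt(n) * as.vector(R %*% b)
  eps <- matrix(stats::rnorm(nrow(R) * ndraws), nrow(R), ndraws)
  mu + crossprod(chol_R, eps)
}

make_records <- function(snp_ids, chrom, pos, alleles, eaf, z, n,
                         case_fraction = NA_real_) {
  eff_n <- if (is.finite(case_fraction)) n * case_fraction * (1 - case_fraction)
           else n
  se <- 1 / sqrt(2 * eff_n * eaf * (1 - eaf))
  data.frame(snp_id = snp_ids, chrom = chrom, pos = pos,
             effect_allele = alleles$ea, other_allele = alleles$oa,
             eaf = eaf, beta = as.vector(z) * se, se = se,
             pvalue = pmax(2 * stats::pnorm(-abs(as.vector(z))),
                           .Machine$double.xmin),
             n = n, stringsAsFactors = FALSE)
}

draw_alleles <- function(Q) {
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, Q, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), "")
  list(ea = ea, oa = unname(oa))
}

#' Simulate one locus under a scenario
#'
#' Draws variant frequencies (EAF ~ Uniform(0.05, 0.5), shared by both
#' traits — the same variants have one population frequency), chooses
#' causal indices per the hypothesis (shared index under H4; distinct
#' indices with pairwise r^2 in the configured range under H3), sets
#' standardized causal effects `b` so each explains its configured causal
#' variance, draws the observed z from MVN(sqrt(n) R b, R), and converts to
#' beta/se via `se_j = 1/sqrt(2 n eaf_j (1 - eaf_j))`. Under H4 the
#' outcome's causal effect at the shared variant is `alpha` times the
#' exposure's.
#'
#' @param sc a [scenario()].
#' @param ld optional pre-built [ld_matrix()] (its dimension must be
#'   `sc$Q`); rebuilt from the scenario when `NULL`.
#' @param chrom,pos_start locus placement (positions are consecutive
#'   1-kb-spaced).
#' @param seed optional seed applied locally.
#' @param gene_id,cell_type,outcome_id trait labels.
#' @param outcome_case_fraction when finite, the outcome is emitted as a
#'   case-control trait with the effective-n standard-error approximation
#'   `se = 1/sqrt(2 n phi (1-phi) eaf (1-eaf))`.
#' @return list of class `simulated_locus`: `truth` (scenario, causal
#'   indices/ids, causal effects), `ld`, `exposure` and `outcome`
#'   [assoc_set()]s.
#' @export
simulate_locus <- function(sc, ld = NULL, chrom = "1", pos_start = 1e6,
                           seed = NULL, gene_id = "GENE",
                           cell_type = "cell", outcome_id = "outcome",
                           outcome_case_fraction = NA_real_) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ld)) ld <- simulate_ld(sc$Q, sc$ld_rho, sc$blocks)
  stopifnot(nrow(ld) == sc$Q)
  R <- unclass(ld)
  chol_R <- attr(ld, "chol") %||% chol(R)

  Q <- sc$Q
  pos <- pos_start + (seq_len(Q) - 1L) * 1000
  eaf <- stats::runif(Q, 0.05, 0.5)
  alleles <- draw_alleles(Q)

  b_exp <- numeric(Q); b_out <- numeric(Q)
  idx_exp <- integer(); idx_out <- integer()
  hyp <- sc$hypothesis
  if (hyp %in% c("H1", "H3", "H4")) {
    idx_exp <- pick_causal_indices(Q, sc$blocks, sc$n_signals)
    b_exp[idx_exp] <- sqrt(sc$causal_variance_exp) *
      sample(c(-1, 1), length(idx_exp), replace = TRUE)
  }
  if (hyp == "H4") {
    idx_out <- idx_exp
    b_out[idx_out] <- sc$alpha * b_exp[idx_out]
  } else if (hyp == "H2") {
    idx_out <- pick_causal_indices(Q, sc$blocks, sc$n_signals)
    b_out[idx_out] <- sqrt(sc$causal_variance_out) *
      sample(c(-1, 1), length(idx_out), replace = TRUE)
  } else if (hyp == "H3") {
    r2 <- R^2
    idx_out <- vapply(idx_exp, function(i) {
      cand <- setdiff(which(r2[i, ] >= sc$cross_trait_r2_min &
                            r2[i, ] <= sc$cross_trait_r2_max), i)
      cand <- setdiff(cand, c(idx_exp, idx_out))
      if (length(cand) == 0L)
        stop("infeasible H3 scenario: no variant with cross-trait r2 in [",
             sc$cross_trait_r2_min, ", ", sc$cross_trait_r2_max,
             "] available")
      cand[sample.int(length(cand), 1L)]
    }, 1L)
    b_out[idx_out] <- sqrt(sc$causal_variance_out) *
      sample(c(-1, 1), length(idx_out), replace = TRUE)
  }

  z_exp <- draw_z(sc$n_exp, R, chol_R, b_exp)
  z_out <- draw_z(sc$n_out, R, chol_R, b_out)

  exp_rec <- make_records(rownames(ld), chrom, pos, alleles, eaf, z_exp,
                          sc$n_exp)
  out_rec <- make_records(rownames(ld), chrom, pos, alleles, eaf, z_out,
                          sc$n_out, case_fraction = outcome_case_fraction)
  region <- list(chrom = chrom, start = min(pos), end = max(pos))
  exposure <- assoc_set(exposure_trait_id(gene_id, cell_type), exp_rec,
                        region, validate = FALSE)
  outcome <- assoc_set(
    outcome_id, out_rec, region,
    trait_type = if (is.finite(outcome_case_fraction)) "case_control"
                 else "quantitative",
    case_fraction = outcome_case_fraction, validate = FALSE)
  structure(
    list(truth = list(scenario = sc,
                      causal_exp = rownames(ld)[idx_exp],
                      causal_out = rownames(ld)[idx_out],
                      b_exp = b_exp[idx_exp], b_out = b_out[idx_out]),
         ld = ld, exposure = exposure, outcome = outcome),
    class = "simulated_locus")
}

#' Simulate a multi-gene, multi-cell-type discovery/replication study
#'
#' Generates a full synthetic study for the three-stage screen. Each gene
#' is assigned a truth label: `"h4"` (expression mediates the outcome,
#' `alpha != 0`, in a designated causal cell-type set), `"h3"`
#' (LD-confounded: the gene has cis-eQTLs, and the outcome has a *distinct*
#' causal variant in LD with the eQTL), or `"null"` (cis-eQTLs in every
#' cell type, no outcome association — so null genes still enter MR and
#' exercise FDR control). Exposures are generated per cell type at
#' `n_exp` (effects only in designated cell types for h4/h3 genes; every
#' cell type carries the eQTL for null genes); the replication exposures
#' are regenerated with independent noise at `n_rep` under coarsened labels
#' from `map`; one outcome set spans all gene loci. Loci are placed far
#' apart on one chromosome with disjoint cis windows.
#'
#' Every locus derives a child seed deterministically from
#' `(seed, gene, cell type, trait)`, so any subset regenerates identically
#' in isolation.
#'
#' @param n_genes total genes.
#' @param cell_types discovery cell-type labels.
#' @param n_h4,n_h3 number of mediated and LD-confounded genes (the rest
#'   are null).
#' @param map a [cell_type_map()] from discovery to replication labels.
#' @param sc baseline [scenario()] (its `hypothesis` field is overridden
#'   per gene; `cross_trait_r2_*` applies to h3 genes).
#' @param n_rep replication exposure sample size (default `n_exp / 8`,
#'   emulating a smaller replication cohort).
#' @param outcome_id outcome label.
#' @param seed global seed.
#' @return list of class `simulated_study`: `genes` (annotation),
#'   `discovery`, `replication` (lists of exposure assoc_sets), `outcome`,
#'   `ld` (named list per gene), `map`, and `truth` (data.frame with one
#'   row per gene: label, causal cell types, causal variants, alpha).
#' @export
simulate_study <- function(n_genes = 60, cell_types = c("Mono_C", "B", "CD4_NC"),
                           n_h4 = 15, n_h3 = 15,
                           map = default_cell_type_map(),
                           sc = scenario("H4", alpha = 0.2,
                                         causal_variance_exp = 0.05,
                                         causal_variance_out = 0.05,
                                         n_exp = 10000, n_out = 50000,
                                         Q = 200, ld_rho = 0.9,
                                         cross_trait_r2_min = 0.4,
                                         cross_trait_r2_max = 0.6),
                           n_rep = NULL, outcome_id = "outcome",
                           seed = 1L) {
  stopifnot(n_h4 + n_h3 <= n_genes)
  if (!all(cell_types %in% names(map)))
    stop("cell type(s) missing from map: ",
         paste(setdiff(cell_types, names(map)), collapse = ", "))
  n_rep <- n_rep %||% max(100, round(sc$n_exp / 8))
  set.seed(child_seed(seed, "study-design"))
  gene_ids <- sprintf("GENE%03d", seq_len(n_genes))
  labels <- sample(c(rep("h4", n_h4), rep("h3", n_h3),
                     rep("null", n_genes - n_h4 - n_h3)))
  causal_ct <- sample(cell_types, n_genes, replace = TRUE)
  rep_cts <- unique(unname(unclass(map)[cell_types]))

  spacing <- 4e6
  locus_kb <- sc$Q * 1000
  gene_start <- spacing * seq_len(n_genes) + 1e6
  genes <- gene_annotation(gene_ids, "1", gene_start,
                           gene_start + locus_kb - 1)

  discovery <- list(); replication <- list()
  ld_list <- list()
  out_records <- list()
  truth_rows <- list()

  for (g in seq_len(n_genes)) {
    gid <- gene_ids[g]
    lab <- labels[g]
    ld <- simulate_ld(sc$Q, sc$ld_rho, sc$blocks,
                      snp_prefix = paste0(gid, "_snp"))
    attr(ld, "chol") <- chol(unclass(ld))
    ld_list[[gid]] <- ld

    # one latent causal architecture per gene locus, shared across traits
    set.seed(child_seed(seed, gid, "architecture"))
    Q <- sc$Q
    pos <- gene_start[g] + (seq_len(Q) - 1L) * 1000
    eaf <- stats::runif(Q, 0.05, 0.5)
    alleles <- draw_alleles(Q)
    R <- unclass(ld)
    idx_exp <- pick_causal_indices(Q, sc$blocks, sc$n_signals)
    b_eqtl <- numeric(Q)
    b_eqtl[idx_exp] <- sqrt(sc$causal_variance_exp) *
      sample(c(-1, 1), length(idx_exp), replace = TRUE)
    b_out <- numeric(Q)
    idx_out <- integer()
    if (lab == "h4") {
      idx_out <- idx_exp
      b_out[idx_out] <- sc$alpha * b_eqtl[idx_out]
    } else if (lab == "h3") {
      r2 <- R^2
      idx_out <- vapply(idx_exp, function(i) {
        cand <- setdiff(which(r2[i, ] >= sc$cross_trait_r2_min &
                              r2[i, ] <= sc$cross_trait_r2_max),
                        c(i, idx_exp))
        if (length(cand) == 0L)
          stop("infeasible h3 architecture for ", gid)
        cand[sample.int(length(cand), 1L)]
      }, 1L)
      b_out[idx_out] <- sqrt(sc$causal_variance_out) *
        sample(c(-1, 1), length(idx_out), replace = TRUE)
    }

    emit_exposure <- function(ct, n, source, b) {
      set.seed(child_seed(seed, gid, ct, source))
      z <- draw_z(n, R, attr(ld, "chol"), b)
      rec <- make_records(rownames(ld), "1", pos, alleles, eaf, z, n)
      assoc_set(exposure_trait_id(gid, ct), rec,
                list(chrom = "1", start = min(pos), end = max(pos)),
                validate = FALSE)
    }
    # discovery exposures: eQTL present in designated cell type(s) for
    # h4/h3 genes, in all cell types for null genes
    for (ct in cell_types) {
      has_eqtl <- lab == "null" || ct == causal_ct[g]
      b_ct <- if (has_eqtl) b_eqtl else numeric(Q)
      discovery[[exposure_trait_id(gid, ct)]] <-
        emit_exposure(ct, sc$n_exp, "discovery", b_ct)
    }
    for (ct in rep_cts) {
      has_eqtl <- lab == "null" || ct == unname(unclass(map)[causal_ct[g]])
      b_ct <- if (has_eqtl) b_eqtl else numeric(Q)
      replication[[exposure_trait_id(gid, ct)]] <-
        emit_exposure(ct, n_rep, "replication", b_ct)
    }

    set.seed(child_seed(seed, gid, "outcome"))
    z_out <- draw_z(sc$n_out, R, attr(ld, "chol"), b_out)
    out_records[[gid]] <- make_records(rownames(ld), "1", pos, alleles,
                                       eaf, z_out, sc$n_out)
    truth_rows[[gid]] <- data.frame(
      gene_id = gid, label = lab,
      causal_cell_type = if (lab == "null") NA_character_ else causal_ct[g],
      replication_cell_type = if (lab == "null") NA_character_
                              else unname(unclass(map)[causal_ct[g]]),
      causal_exp = paste(rownames(ld)[idx_exp], collapse = ","),
      causal_out = paste(rownames(ld)[idx_out], collapse = ","),
      alpha = if (lab == "h4") sc$alpha else 0,
      stringsAsFactors = FALSE)
  }
  out_rec <- do.call(rbind, out_records)
  outcome <- assoc_set(outcome_id, out_rec,
                       list(chrom = "1", start = min(out_rec$pos),
                            end = max(out_rec$pos)),
                       validate = FALSE)
  structure(
    list(genes = genes, discovery = discovery, replication = replication,
         outcome = outcome, ld = ld_list, map = map,
         truth = do.call(rbind, c(truth_rows, make.row.names = FALSE)),
         scenario = sc, n_rep = n_rep, seed = seed),
    class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d genes (%s), %d discovery / %d replication exposure sets\n",
    nrow(x$truth),
    paste(names(table(x$truth$label)), table(x$truth$label),
          sep = "=", collapse = ", "),
    length(x$discovery), length(x$replication)))
  invisible(x)
}
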