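# Three-stage prioritization screen: discovery MR with FDR, replication MR
# on discovery survivors under coarsened cell-type labels, then
# colocalization of the discovery exposure against the outcome for
# replication survivors. Emits the prioritized table plus a stage-count
# funnel and per-stage tables for audit.

#' Pipeline configuration
#'
#' @param discovery_params,replication_params [selection_params()] for the
#'   two instrument sources. Defaults: 1-Mb gene-flank window for
#'   discovery; 100-kb midpoint window for replication (the conventions of
#'   per-gene sc-eQTL releases); both at p < 1e-5, clumped at r^2 < 0.1.
#' @param policy a [palindrome_policy()].
#' @param ivw_variant,se_method,fdr_family see [run_mr_batch()].
#' @param fdr_level FDR significance level for both MR stages
#'   (default 0.05).
#' @param priors a [coloc_priors()].
#' @param pph4_threshold PPH4 threshold for significant colocalization
#'   (default 0.8).
#' @param p_enter,max_signals multi-signal decomposition settings (see
#'   [decompose_signals()]).
#' @param seed seed recorded with the run for determinism of any
#'   stochastic components.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(discovery_params = selection_params("flank_gene", 1e6),
                            replication_params = selection_params("midpoint", 1e5),
                            policy = palindrome_policy(),
                            ivw_variant = "mre", se_method = "first_order",
                            fdr_family = "per_outcome", fdr_level = 0.05,
                            priors = coloc_priors(), pph4_threshold = 0.8,
                            p_enter = 1e-6, max_signals = 10L,
                            seed = 1L) {
  stopifnot(fdr_level > 0, fdr_level < 1,
            pph4_threshold > 0, pph4_threshold < 1)
  structure(list(discovery_params = discovery_params,
                 replication_params = replication_params,
                 policy = policy, ivw_variant = ivw_variant,
                 se_method = se_method, fdr_family = fdr_family,
                 fdr_level = fdr_level, priors = priors,
                 pph4_threshold = pph4_threshold, p_enter = p_enter,
                 max_signals = max_signals, seed = seed),
            class = "pipeline_config")
}

#' Map discovery cell-type labels onto replication labels
#'
#' Applies a many-to-one [cell_type_map()] to an MR hit table and
#' deduplicates: replication tests are keyed on
#' (gene, replication label, outcome), so several fine-grained discovery
#' hits that coarsen to the same label yield a single replication test.
#'
#' @param hits data.frame with `gene_id`, `cell_type`, `outcome_id`.
#' @param map a [cell_type_map()].
#' @return data.frame with columns `gene_id`, `replication_cell_type`,
#'   `outcome_id`, deduplicated; attribute `source_rows` maps each row back
#'   to the contributing discovery rows.
#' @export
map_cell_types <- function(hits, map) {
  unmapped <- setdiff(unique(hits$cell_type), names(map))
  if (length(unmapped))
    stop("cell type(s) absent from map: ", paste(unmapped, collapse = ", "))
  rep_ct <- unname(unclass(map)[hits$cell_type])
  key <- paste(hits$gene_id, rep_ct, hits$outcome_id, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(gene_id = hits$gene_id[first],
                    replication_cell_type = rep_ct[first],
                    outcome_id = hits$outcome_id[first],
                    stringsAsFactors = FALSE)
  attr(out, "source_rows") <- split(seq_len(nrow(hits)), match(key, key[first]))
  out
}

#' Run the three-stage discovery / replication / colocalization screen
#'
#' Stage 1 — discovery MR: select instruments from the discovery exposures
#' (fine-grained cell types), run MR against every outcome, BH-FDR within
#' the configured family; survivors have `q < fdr_level`.
#' Stage 2 — replication MR: coarsen survivor cell types through `map`,
#' select instruments from the replication exposures, and test only the
#' surviving (gene, replication cell type, outcome) keys, with FDR computed
#' within that survivor family.
#' Stage 3 — colocalization: for stage-2 survivors, colocalize the
#' discovery exposure's full-region statistics against the outcome.
#' Multi-signal colocalization (conditional decomposition, max PPH4 over
#' signal pairs) is engaged when the discovery MR used more than one
#' instrument; single-instrument loci use single-signal [coloc_abf()].
#'
#' A hit passes overall iff it passes all three stages; the funnel counts
#' are monotone by construction.
#'
#' @param discovery,replication lists of exposure [assoc_set()]s.
#' @param outcomes outcome [assoc_set()] or list of them.
#' @param genes a [gene_annotation()].
#' @param ld named list of [ld_matrix()] per gene id (or a single matrix).
#' @param map a [cell_type_map()].
#' @param config a [pipeline_config()].
#' @param discovery_ld,replication_ld optional overrides of `ld` for
#'   instrument clumping per source (default: `ld` for both).
#' @return list of class `pipeline_result`: `prioritized` (one row per
#'   discovery hit with replication estimate, coloc posteriors and
#'   per-stage pass flags), `discovery`, `replication`, `coloc` tables, and
#'   `funnel` (named stage counts).
#' @export
run_pipeline <- function(discovery, replication, outcomes, genes, ld, map,
                         config = pipeline_config(),
                         discovery_ld = NULL, replication_ld = NULL) {
  set.seed(config$seed)
  if (inherits(outcomes, "assoc_set")) outcomes <- list(outcomes)
  names(outcomes) <- vapply(outcomes, `[[`, "", "trait_id")
  discovery_ld <- discovery_ld %||% ld
  replication_ld <- replication_ld %||% ld

  # Stage 1: discovery MR
  inst_disc <- select_instruments(discovery, genes, discovery_ld,
                                  config$discovery_params, "discovery")
  mr_disc <- run_mr_batch(inst_disc, outcomes, config$policy,
                          config$ivw_variant, config$se_method,
                          config$fdr_family, config$fdr_level)
  surv1 <- mr_disc[mr_disc$significant, , drop = FALSE]

  # Stage 2: replication MR on coarsened survivor keys
  rep_tests <- if (nrow(surv1)) map_cell_types(surv1, map) else
    data.frame(gene_id = character(), replication_cell_type = character(),
               outcome_id = character())
  inst_rep_all <- select_instruments(replication, genes, replication_ld,
                                     config$replication_params, "replication")
  keep <- vapply(inst_rep_all, function(ins) {
    any(rep_tests$gene_id == ins$gene_id &
        rep_tests$replication_cell_type == ins$cell_type)
  }, TRUE)
  inst_rep <- inst_rep_all[keep]
  mr_rep <- run_mr_batch(inst_rep, outcomes, config$policy,
                         config$ivw_variant, config$se_method,
                         config$fdr_family, config$fdr_level)
  # restrict to the tested keys (an instrument set may exist for outcomes
  # not represented among survivors)
  if (nrow(mr_rep)) {
    tested_key <- paste(rep_tests$gene_id, rep_tests$replication_cell_type,
                        rep_tests$outcome_id, sep = "\r")
    mr_key <- paste(mr_rep$gene_id, mr_rep$cell_type, mr_rep$outcome_id,
                    sep = "\r")
    mr_rep <- mr_rep[mr_key %in% tested_key, , drop = FALSE]
    # recompute FDR within the survivor family actually tested
    if (nrow(mr_rep)) {
      if (config$fdr_family == "global") {
        mr_rep$qvalue <- bh_fdr(mr_rep$pvalue)
      } else {
        for (oid in unique(mr_rep$outcome_id)) {
          sel <- mr_rep$outcome_id == oid
          mr_rep$qvalue[sel] <- bh_fdr(mr_rep$pvalue[sel])
        }
      }
      mr_rep$significant <- mr_rep$qvalue < config$fdr_level
    }
  }

  # Stage 3: colocalization for replication survivors, keyed back to the
  # contributing discovery hits
  rep_ct_of <- function(ct) unname(unclass(map)[ct])
  coloc_rows <- list()
  coloc_cache <- new.env(parent = emptyenv())
  get_coloc <- function(gene_id, cell_type, outcome_id, n_snps) {
    key <- paste(gene_id, cell_type, outcome_id, sep = "\r")
    if (!is.null(coloc_cache[[key]])) return(coloc_cache[[key]])
    exp_set <- discovery[[exposure_trait_id(gene_id, cell_type)]]
    gld <- if (inherits(ld, "ld_matrix")) ld else ld[[gene_id]]
    res <- tryCatch({
      if (n_snps > 1L && !is.null(gld))
        coloc_multi(exp_set, outcomes[[outcome_id]], gld, config$priors,
                    p_enter = config$p_enter,
                    max_signals = config$max_signals)
      else
        coloc_abf(exp_set, outcomes[[outcome_id]], config$priors)
    }, error = function(e) NULL)
    coloc_cache[[key]] <- res
    res
  }

  prioritized <- surv1
  names(prioritized) <- paste0("disc_", names(surv1))
  prioritized$gene_id <- surv1$gene_id
  prioritized$cell_type <- surv1$cell_type
  prioritized$outcome_id <- surv1$outcome_id
  prioritized$replication_cell_type <- rep_ct_of(surv1$cell_type)
  prioritized$pass_discovery <- rep(TRUE, nrow(prioritized))
  m <- match(paste(prioritized$gene_id, prioritized$replication_cell_type,
                   prioritized$outcome_id, sep = "\r"),
             paste(mr_rep$gene_id, mr_rep$cell_type, mr_rep$outcome_id,
                   sep = "\r"))
  prioritized$rep_beta <- mr_rep$beta[m]
  prioritized$rep_se <- mr_rep$se[m]
  prioritized$rep_pvalue <- mr_rep$pvalue[m]
  prioritized$rep_qvalue <- mr_rep$qvalue[m]
  prioritized$rep_n_snps <- mr_rep$n_snps[m]
  prioritized$pass_replication <- !is.na(m) & mr_rep$significant[m]

  nr <- nrow(prioritized)
  for (cl in c("pph0", "pph1", "pph2", "pph3", "pph4", "max_pph4"))
    prioritized[[cl]] <- rep(NA_real_, nr)
  prioritized$coloc_n_signals <- rep(NA_integer_, nr)
  for (i in seq_len(nrow(prioritized))) {
    if (!prioritized$pass_replication[i]) next
    res <- get_coloc(prioritized$gene_id[i], prioritized$cell_type[i],
                     prioritized$outcome_id[i],
                     prioritized$disc_n_snps[i])
    if (is.null(res)) next
    prioritized[i, c("pph0", "pph1", "pph2", "pph3", "pph4")] <-
      as.list(unname(res$pph))
    prioritized$max_pph4[i] <- res$max_pph4
    prioritized$coloc_n_signals[i] <- max(1L, length(res$signal_pairs))
    coloc_rows[[length(coloc_rows) + 1L]] <- data.frame(
      gene_id = prioritized$gene_id[i],
      cell_type = prioritized$cell_type[i],
      outcome_id = prioritized$outcome_id[i],
      n_snps = res$n_snps, t(res$pph), max_pph4 = res$max_pph4,
      colocalized = res$max_pph4 >= config$pph4_threshold)
  }
  prioritized$pass_coloc <- !is.na(prioritized$max_pph4) &
    prioritized$max_pph4 >= config$pph4_threshold
  prioritized$pass <- prioritized$pass_discovery &
    prioritized$pass_replication & prioritized$pass_coloc
  rownames(prioritized) <- NULL

  funnel <- c(tested = nrow(mr_disc),
              discovery = sum(prioritized$pass_discovery),
              replication = sum(prioritized$pass_replication),
              colocalized = sum(prioritized$pass))
  structure(
    list(prioritized = prioritized, discovery = mr_disc,
         replication = mr_rep,
         coloc = if (length(coloc_rows)) do.call(rbind, coloc_rows) else NULL,
         funnel = funnel, config = config),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  tested:      %d gene x cell-type x outcome combinations\n",
              x$funnel[["tested"]]))
  cat(sprintf("  discovery:   %d at FDR q < %g\n",
              x$funnel[["discovery"]], x$config$fdr_level))
  cat(sprintf("  replication: %d at FDR q < %g\n",
              x$funnel[["replication"]], x$config$fdr_level))
  cat(sprintf("  colocalized: %d at max PPH4 >= %g\n",
              x$funnel[["colocalized"]], x$config$pph4_threshold))
  invisible(x)
}

#' Write per-stage pipeline outputs to a directory
#'
#' Writes `discovery_mr.tsv`, `replication_mr.tsv`, `coloc.tsv`,
#' `prioritized.tsv` and `funnel.txt`.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  wt(result$discovery, "discovery_mr.tsv")
  wt(result$replication, "replication_mr.tsv")
  wt(result$coloc, "coloc.tsv")
  wt(result$prioritized, "prioritized.tsv")
  writeLines(paste(names(result$funnel), result$funnel, sep = "\t"),
             file.path(dir, "funnel.txt"))
  invisible(dir)
}
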