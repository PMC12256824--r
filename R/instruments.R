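# Instrument selection: cis-window definition, significance filtering, and
# greedy LD clumping, composed per gene x cell type.

#' Instrument-selection parameters
#'
#' @param window_mode `"flank_gene"` (window extends `window_bp` beyond
#'   either end of the gene body, the convention of per-gene cis-eQTL
#'   releases) or `"midpoint"` (window of half-width `window_bp` around the
#'   gene midpoint).
#' @param window_bp window size in base pairs (default 1 Mb, the
#'   conventional cis flank).
#' @param p_threshold marginal p-value ceiling for candidate instruments
#'   (default 1e-5).
#' @param r2_threshold LD-clumping r-squared ceiling (default 0.1): every
#'   retained pair of instruments has r^2 strictly below this.
#' @return list of class `selection_params`.
#' @export
selection_params <- function(window_mode = c("flank_gene", "midpoint"),
                             window_bp = 1e6, p_threshold = 1e-5,
                             r2_threshold = 0.1) {
  window_mode <- match.arg(window_mode)
  stopifnot(window_bp > 0, p_threshold > 0, p_threshold < 1,
            r2_threshold > 0, r2_threshold <= 1)
  structure(list(window_mode = window_mode, window_bp = window_bp,
                 p_threshold = p_threshold, r2_threshold = r2_threshold),
            class = "selection_params")
}

#' Cis window around a gene
#'
#' `flank_gene` yields `[start - window_bp, end + window_bp]`; `midpoint`
#' yields `[mid - window_bp, mid + window_bp]` with
#' `mid = floor((start + end)/2)`. The lower bound is clamped at 1.
#'
#' @param gene one row of a [gene_annotation()] (or any list with
#'   `chrom`, `start`, `end`).
#' @param params a [selection_params()].
#' @return list with `chrom`, `start`, `end` (1-based inclusive).
#' @export
cis_window <- function(gene, params) {
  if (params$window_mode == "flank_gene") {
    lo <- gene$start - params$window_bp
    hi <- gene$end + params$window_bp
  } else {
    mid <- floor((gene$start + gene$end) / 2)
    lo <- mid - params$window_bp
    hi <- mid + params$window_bp
  }
  list(chrom = gene$chrom, start = max(1, lo), end = hi)
}

#' Keep variants below a significance threshold
#'
#' Subsets an association set to `pvalue < p_threshold`, preserving order.
#' @param set an [assoc_set()].
#' @param p_threshold strict upper bound on p.
#' @return the filtered `assoc_set` (possibly empty).
#' @export
filter_significant <- function(set, p_threshold) {
  keep <- set$records$pvalue < p_threshold
  set$records <- set$records[keep, , drop = FALSE]
  rownames(set$records) <- NULL
  set
}

#' Restrict an association set to a genomic region
#' @param set an [assoc_set()].
#' @param region list with `chrom`, `start`, `end`.
#' @return the restricted `assoc_set`, with its region set to `region`.
#' @export
restrict_region <- function(set, region) {
  keep <- set$records$chrom == region$chrom &
    set$records$pos >= region$start & set$records$pos <= region$end
  set$records <- set$records[keep, , drop = FALSE]
  rownames(set$records) <- NULL
  set$region <- region
  set
}

#' Greedy LD clumping
#'
#' Repeatedly takes the not-yet-removed variant with the smallest p-value
#' and removes all others with r^2 at or above `r2_threshold` to it. The
#' output always contains the globally smallest-p variant, and every
#' retained pair has r^2 strictly below the threshold. Ties on p are broken
#' by smaller position, then lexicographic snp_id, for determinism.
#'
#' Variants absent from the LD reference are dropped with a warning by
#' default (`missing_ld = "drop"`); `missing_ld = "independent"` retains
#' them as if uncorrelated with everything, for sources whose per-gene top
#' variants may lack LD coverage.
#'
#' @param set an [assoc_set()].
#' @param ld an [ld_matrix()] covering the variants.
#' @param r2_threshold r-squared ceiling.
#' @param missing_ld `"drop"` or `"independent"`.
#' @return the clumped `assoc_set`.
#' @export
clump <- function(set, ld, r2_threshold = 0.1,
                  missing_ld = c("drop", "independent")) {
  missing_ld <- match.arg(missing_ld)
  rec <- set$records
  if (nrow(rec) <= 1L) return(set)
  in_ld <- rec$snp_id %in% rownames(ld)
  if (any(!in_ld)) {
    if (missing_ld == "drop") {
      warning(sum(!in_ld), " variant(s) absent from LD reference dropped ",
              "before clumping")
    }
  }
  covered <- rec[in_ld, , drop = FALSE]
  orphan <- if (missing_ld == "independent") rec[!in_ld, , drop = FALSE]
            else rec[0, , drop = FALSE]

  kept <- character()
  if (nrow(covered)) {
    r2 <- unclass(ld)[covered$snp_id, covered$snp_id, drop = FALSE]^2
    ord <- order(covered$pvalue, covered$pos, covered$snp_id)
    active <- rep(TRUE, nrow(covered))
    for (i in ord) {
      if (!active[i]) next
      kept <- c(kept, covered$snp_id[i])
      active[r2[i, ] >= r2_threshold] <- FALSE
    }
  }
  keep_ids <- c(kept, orphan$snp_id)
  set$records <- rec[rec$snp_id %in% keep_ids, , drop = FALSE]
  rownames(set$records) <- NULL
  set
}

#' An instrument set for one gene x cell type
#'
#' @param gene_id,cell_type identifiers.
#' @param variants variant table (rows of an exposure `assoc_set` that
#'   survived window restriction, significance filtering and clumping).
#' @param params the [selection_params()] used.
#' @param source_label provenance tag, e.g. `"discovery"`/`"replication"`.
#' @return list of class `instrument_set`.
#' @export
instrument_set <- function(gene_id, cell_type, variants, params,
                           source_label = "discovery") {
  structure(list(gene_id = gene_id, cell_type = cell_type,
                 variants = variants, params = params,
                 source_label = source_label),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s / %s (%s): %d variant(s)\n",
              x$gene_id, x$cell_type, x$source_label, nrow(x$variants)))
  invisible(x)
}

#' Select cis-eQTL instruments per gene x cell type
#'
#' For each exposure association set (keyed `"<gene>::<cell_type>"`):
#' restrict to the gene's cis window, keep variants with
#' `p < p_threshold`, then LD-clump at `r2_threshold`. Combinations with no
#' surviving variant are reported, not emitted. When `ld` is `NULL`,
#' clumping is skipped with a logged notice (for pre-pruned sources such as
#' per-gene top-variant releases).
#'
#' @param exposures list of exposure [assoc_set()] objects.
#' @param genes a [gene_annotation()].
#' @param ld an [ld_matrix()], a named list of them keyed by gene id, or
#'   `NULL` to skip clumping.
#' @param params a [selection_params()].
#' @param source_label provenance tag stored on each instrument set.
#' @param missing_ld passed to [clump()].
#' @return list of [instrument_set()]; attribute `report` is a data.frame
#'   with one row per exposure (variants surviving each step, skip reason).
#' @export
select_instruments <- function(exposures, genes, ld, params,
                               source_label = "discovery",
                               missing_ld = "drop") {
  out <- list()
  rep_rows <- list()
  for (set in exposures) {
    ids <- split_trait_id(set$trait_id)
    g <- genes[genes$gene_id == ids$gene_id, , drop = FALSE]
    note <- ""
    if (nrow(g) == 0) {
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        trait_id = set$trait_id, n_window = 0L, n_significant = 0L,
        n_clumped = 0L, note = "gene absent from annotation")
      next
    }
    win <- cis_window(g[1L, ], params)
    s <- restrict_region(set, win)
    n_win <- nrow(s$records)
    s <- filter_significant(s, params$p_threshold)
    n_sig <- nrow(s$records)
    gld <- if (is.null(ld)) NULL
           else if (inherits(ld, "ld_matrix")) ld
           else ld[[ids$gene_id]]
    if (is.null(gld)) {
      note <- "no LD reference; clumping skipped"
    } else if (n_sig > 1L) {
      s <- clump(s, gld, params$r2_threshold, missing_ld = missing_ld)
    }
    n_cl <- nrow(s$records)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      trait_id = set$trait_id, n_window = n_win, n_significant = n_sig,
      n_clumped = n_cl, note = note)
    if (n_cl > 0)
      out[[set$trait_id]] <- instrument_set(ids$gene_id, ids$cell_type,
                                            s$records, params, source_label)
  }
  attr(out, "report") <- do.call(rbind, rep_rows)
  out
}
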