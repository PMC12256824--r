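# Core containers: per-locus association sets, LD matrices, gene
# annotations and cell-type maps. Coordinates are 1-based inclusive
# throughout, following GWAS summary-statistics convention. Alleles are
# assumed reported on the forward strand; strand ambiguity is handled only
# at harmonization.

VARIANT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pvalue", "n")

#' Validate a table of marginal variant associations
#'
#' Applies the per-variant invariants: positive standard error, allele
#' strings drawn from A/C/G/T (multi-character alleles, i.e. indels, are
#' invalid), effect-allele frequency in \[0, 1\] when present, p-value in
#' (0, 1\], positive sample size. Rows failing any invariant are dropped and
#' counted. A p-value inconsistent with the two-sided normal p implied by
#' |beta/se| (relative discrepancy of -log10 p above `p_tolerance`) triggers
#' a warning and is recomputed from beta/se, since downstream arithmetic
#' uses z = beta/se rather than the file's p.
#'
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @param p_tolerance allowed relative discrepancy on the -log10 p scale.
#' @return the validated records, with attributes `n_dropped` and
#'   `drop_reasons` (a named count by reason).
#' @export
validate_variant_records <- function(records, p_tolerance = 0.5) {
  for (cl in setdiff(VARIANT_COLS, names(records))) records[[cl]] <- NA
  records <- records[, union(VARIANT_COLS, names(records)), drop = FALSE]
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (cl in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    records[[cl]] <- as.numeric(records[[cl]])

  bad_allele <- !(records$effect_allele %in% c("A", "C", "G", "T")) |
    !(records$other_allele %in% c("A", "C", "G", "T")) |
    records$effect_allele == records$other_allele
  bad_se <- !is.finite(records$se) | records$se <= 0
  bad_p <- !is.finite(records$pvalue) | records$pvalue <= 0 | records$pvalue > 1
  bad_eaf <- !is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1)
  bad_n <- !is.na(records$n) & records$n <= 0
  bad_beta <- !is.finite(records$beta)
  bad_core <- is.na(records$snp_id) | is.na(records$chrom) |
    !is.finite(records$pos)

  reasons <- c(allele = sum(bad_allele), se = sum(bad_se & !bad_allele),
               pvalue = sum(bad_p & !bad_allele & !bad_se),
               eaf = sum(bad_eaf), n = sum(bad_n), beta = sum(bad_beta),
               id = sum(bad_core))
  drop <- bad_allele | bad_se | bad_p | bad_eaf | bad_n | bad_beta | bad_core
  out <- records[!drop, , drop = FALSE]

  # p vs |z| consistency: warn and recompute from beta/se
  if (nrow(out)) {
    z <- abs(out$beta / out$se)
    p_z <- 2 * stats::pnorm(-z)
    rel <- abs(-log10(out$pvalue) + log10(pmax(p_z, .Machine$double.xmin))) /
      pmax(-log10(pmax(p_z, .Machine$double.xmin)), 1)
    inc <- is.finite(rel) & rel > p_tolerance
    if (any(inc)) {
      warning(sprintf(
        "%d record(s) with p inconsistent with |beta/se|; p recomputed from z",
        sum(inc)))
      out$pvalue[inc] <- pmax(p_z[inc], .Machine$double.xmin)
    }
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  attr(out, "drop_reasons") <- reasons
  out
}

#' Construct a per-locus association set
#'
#' An `assoc_set` holds the marginal summary statistics of one trait
#' (a gene x cell-type expression exposure, or a GWAS outcome) at one locus:
#' a validated variant table plus a 1-based inclusive region.
#'
#' @param trait_id trait label; exposure sets conventionally use
#'   `"<gene_id>::<cell_type>"` (see [exposure_trait_id()]).
#' @param records variant table (see [validate_variant_records()]).
#' @param region list with `chrom`, `start`, `end`; inferred from the
#'   records when `NULL`.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param case_fraction case fraction in (0,1), required for case-control
#'   traits.
#' @param validate set `FALSE` to skip row validation (internal use on
#'   already-validated records).
#' @return an object of class `assoc_set`.
#' @export
assoc_set <- function(trait_id, records, region = NULL,
                      trait_type = c("quantitative", "case_control"),
                      case_fraction = NA_real_, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "case_control" &&
      (!is.finite(case_fraction) || case_fraction <= 0 || case_fraction >= 1))
    stop("case_control traits require case_fraction in (0, 1)")
  if (validate) records <- validate_variant_records(records)
  if (anyDuplicated(records$snp_id))
    stop("duplicate snp_id in association set '", trait_id, "'")
  if (is.null(region)) {
    region <- if (nrow(records) == 0) list(chrom = NA, start = 1, end = 1)
    else list(chrom = records$chrom[1L],
              start = min(records$pos), end = max(records$pos))
  }
  if (nrow(records)) {
    off <- records$chrom != region$chrom | records$pos < region$start |
      records$pos > region$end
    if (any(off))
      stop(sum(off), " record(s) outside the region of set '", trait_id, "'")
  }
  structure(
    list(trait_id = trait_id, records = records, region = region,
         trait_type = trait_type, case_fraction = case_fraction),
    class = "assoc_set")
}

#' @export
print.assoc_set <- function(x, ...) {
  cat(sprintf("<assoc_set> %s: %d variants, %s:%s-%s (%s)\n",
              x$trait_id, nrow(x$records), x$region$chrom,
              format(x$region$start, big.mark = ","),
              format(x$region$end, big.mark = ","), x$trait_type))
  invisible(x)
}

#' @export
format.assoc_set <- function(x, ...) {
  sprintf("assoc_set %s (%d variants)", x$trait_id, nrow(x$records))
}

#' Compose / split exposure trait identifiers
#'
#' Exposure association sets are keyed by gene and cell type; the composite
#' trait id is `"<gene_id>::<cell_type>"`.
#' @param gene_id,cell_type character scalars or vectors.
#' @return `exposure_trait_id` returns the composite id;
#'   `split_trait_id` a data.frame with `gene_id` and `cell_type`.
#' @export
exposure_trait_id <- function(gene_id, cell_type) {
  paste(gene_id, cell_type, sep = "::")
}

#' @rdname exposure_trait_id
#' @param trait_id composite id(s) produced by `exposure_trait_id`.
#' @export
split_trait_id <- function(trait_id) {
  parts <- strsplit(trait_id, "::", fixed = TRUE)
  data.frame(gene_id = vapply(parts, `[`, "", 1L),
             cell_type = vapply(parts, function(p) p[2L] %||% NA_character_, ""),
             stringsAsFactors = FALSE)
}

#' Construct an LD matrix
#'
#' A square matrix of pairwise allelic correlations r (not r-squared),
#' ordered as `snp_ids`. The matrix must be symmetric within `tol`
#' (it is then symmetrized as (r + t(r))/2), have unit diagonal within
#' 1e-6, and entries in \[-1, 1\].
#'
#' @param r square numeric matrix.
#' @param snp_ids character vector matching the matrix dimension.
#' @param tol symmetry tolerance.
#' @return matrix of class `ld_matrix` with snp ids as dimnames.
#' @export
ld_matrix <- function(r, snp_ids, tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (length(snp_ids) != nrow(r))
    stop("LD matrix dimension (", nrow(r), ") does not match snplist length (",
         length(snp_ids), ")")
  if (max(abs(r - t(r))) > tol) stop("LD matrix not symmetric within ", tol)
  r <- (r + t(r)) / 2
  if (nrow(r) && max(abs(diag(r) - 1)) > 1e-6)
    stop("LD matrix diagonal deviates from 1 by more than 1e-6")
  diag(r) <- 1
  if (any(r < -1 - 1e-8 | r > 1 + 1e-8)) stop("LD entries outside [-1, 1]")
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- list(snp_ids, snp_ids)
  class(r) <- c("ld_matrix", class(r))
  r
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d variants\n", nrow(x)))
  invisible(x)
}

#' Gene annotation table
#'
#' @param gene_id,chrom character vectors.
#' @param start,end 1-based inclusive gene body coordinates, start <= end.
#' @param strand `"+"`, `"-"` or `"unknown"`.
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end,
                            strand = "unknown") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start > end)) stop("gene annotation with start > end")
  if (!all(strand %in% c("+", "-", "unknown")))
    stop("strand must be '+', '-' or 'unknown'")
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    start = start, end = end,
                    strand = rep_len(strand, length(gene_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", class(out))
  out
}

#' Cell-type map (discovery label -> replication label)
#'
#' A many-to-one relabeling used to coarsen fine-grained discovery cell
#' types onto the replication dataset's cell types. The map must be total
#' on the labels it is applied to.
#'
#' @param discovery,replication equal-length character vectors.
#' @return named character vector of class `cell_type_map`
#'   (names = discovery labels, values = replication labels).
#' @export
cell_type_map <- function(discovery, replication) {
  if (length(discovery) != length(replication))
    stop("discovery and replication label vectors differ in length")
  if (anyDuplicated(discovery)) stop("duplicate discovery labels in map")
  out <- stats::setNames(as.character(replication), as.character(discovery))
  class(out) <- "cell_type_map"
  out
}

#' Default 14-to-6 immune cell-type map
#'
#' The bundled coarsening from 14 fine-grained PBMC cell types (B-cell
#' lineage split three ways, CD4 and CD8 T cells split three ways each, two
#' NK states, classical/non-classical monocytes, dendritic cells) onto the
#' six major immune cell types used by typical replication sc-eQTL sources.
#'
#' @return a [cell_type_map()].
#' @export
default_cell_type_map <- function() {
  cell_type_map(
    discovery = c("B", "BM", "Plasma",
                  "CD4_NC", "CD4_ET", "CD4_SOX4",
                  "CD8_NC", "CD8_ET", "CD8_S100B",
                  "NK", "NK_R", "Mono_C", "Mono_NC", "DC"),
    replication = c("B", "B", "B",
                    "CD4_T", "CD4_T", "CD4_T",
                    "CD8_T", "CD8_T", "CD8_T",
                    "NK", "NK", "Monocytes", "Monocytes", "DC"))
}
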