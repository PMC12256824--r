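# Readers and writers for the plain-text exchange formats: TSV summary
# statistics (configurable header dialect), plain-text LD matrix with a
# companion .snplist, gene annotation TSV, and cell-type map TSV. Missing
# values are serialized as the literal token "NA".

#' Column-name dialects for summary-statistics TSVs
#'
#' A dialect maps the canonical field names to the column headers used by a
#' file. Two dialects are bundled: `"generic"` (a `trait_id` column keys the
#' trait) and `"exposure"` (separate `gene_id` + `cell_type` columns key
#' gene x cell-type exposures).
#'
#' @param name `"generic"` or `"exposure"`, or a named character vector
#'   mapping canonical names (`snp`, `chrom`, `pos`, `ea`, `oa`, `beta`,
#'   `se`, `p` and optionally `eaf`, `n`, `trait`, `gene`, `cell_type`)
#'   to file column headers.
#' @return named character vector (canonical -> file column).
#' @export
sumstats_dialect <- function(name = "generic") {
  if (is.character(name) && length(name) == 1L && is.null(names(name))) {
    base <- c(snp = "snp_id", chrom = "chrom", pos = "pos",
              ea = "effect_allele", oa = "other_allele", eaf = "eaf",
              beta = "beta", se = "se", p = "pvalue", n = "n")
    return(switch(name,
      generic = c(base, trait = "trait_id"),
      exposure = c(base, gene = "gene_id", cell_type = "cell_type"),
      stop("unknown dialect '", name, "'")))
  }
  name
}

required_dialect_keys <- c("snp", "chrom", "pos", "ea", "oa", "beta", "se", "p")

#' Read summary statistics grouped into association sets
#'
#' Reads a TSV of marginal associations, validates every row (invalid rows
#' are dropped and counted; see [validate_variant_records()]) and groups the
#' result by trait. The `"exposure"` dialect groups by
#' `gene_id` x `cell_type`; the `"generic"` dialect by `trait_id` (a file
#' without a trait column yields a single set named after the file).
#'
#' @param path TSV file path.
#' @param dialect dialect name or mapping, see [sumstats_dialect()].
#' @param trait_type,case_fraction forwarded to [assoc_set()].
#' @return list of [assoc_set()] objects, with attribute `report`:
#'   a list with `n_read`, `n_dropped`, `drop_reasons`.
#' @export
read_sumstats <- function(path, dialect = "generic",
                          trait_type = "quantitative",
                          case_fraction = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- sumstats_dialect(dialect)
  miss <- setdiff(required_dialect_keys, names(dialect))
  if (length(miss))
    stop("dialect lacks required column mapping(s): ",
         paste(miss, collapse = ", "))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""))
  if (nrow(raw) == 0)
    stop("empty summary-statistics file: ", path)
  for (key in names(dialect)) {
    col <- dialect[[key]]
    if (key %in% required_dialect_keys && !col %in% names(raw))
      stop("missing required column '", col, "' in ", path)
  }
  getcol <- function(key) {
    col <- dialect[[key]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NA
  }
  records <- data.frame(
    snp_id = getcol("snp"), chrom = getcol("chrom"),
    pos = suppressWarnings(as.numeric(getcol("pos"))),
    effect_allele = getcol("ea"), other_allele = getcol("oa"),
    eaf = suppressWarnings(as.numeric(getcol("eaf"))),
    beta = suppressWarnings(as.numeric(getcol("beta"))),
    se = suppressWarnings(as.numeric(getcol("se"))),
    pvalue = suppressWarnings(as.numeric(getcol("p"))),
    n = suppressWarnings(as.numeric(getcol("n"))),
    stringsAsFactors = FALSE)

  trait <- if (!is.null(dialect["gene"]) && !is.na(dialect["gene"]) &&
               dialect[["gene"]] %in% names(raw)) {
    ct <- getcol("cell_type")
    exposure_trait_id(getcol("gene"), ct)
  } else if (!is.na(dialect["trait"] %||% NA) &&
             dialect[["trait"]] %in% names(raw)) {
    getcol("trait")
  } else {
    rep(tools::file_path_sans_ext(basename(path)), nrow(records))
  }

  total_dropped <- 0L
  reasons <- NULL
  sets <- list()
  for (tid in unique(trait)) {
    sub <- records[trait == tid, , drop = FALSE]
    v <- validate_variant_records(sub)
    total_dropped <- total_dropped + attr(v, "n_dropped")
    r <- attr(v, "drop_reasons")
    reasons <- if (is.null(reasons)) r else reasons + r
    if (nrow(v) == 0) next
    sets[[tid]] <- assoc_set(tid, v, trait_type = trait_type,
                             case_fraction = case_fraction,
                             validate = FALSE)
  }
  attr(sets, "report") <- list(n_read = nrow(records),
                               n_dropped = total_dropped,
                               drop_reasons = reasons)
  sets
}

#' Write association sets to a summary-statistics TSV
#'
#' Inverse of [read_sumstats()]: `read_sumstats(write_sumstats(x))`
#' reproduces every field. Missing `eaf`/`n` are written as the explicit
#' `NA` token. An empty set list produces a header-only file.
#'
#' @param sets an `assoc_set` or list of them.
#' @param path output path.
#' @param dialect see [sumstats_dialect()]; the `"exposure"` dialect writes
#'   `gene_id`/`cell_type` columns split from composite trait ids.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sets, path, dialect = "generic") {
  if (inherits(sets, "assoc_set")) sets <- list(sets)
  dialect <- sumstats_dialect(dialect)
  exposure_style <- "gene" %in% names(dialect)
  rows <- lapply(sets, function(s) {
    df <- s$records[, VARIANT_COLS, drop = FALSE]
    if (exposure_style) {
      ids <- split_trait_id(s$trait_id)
      df$gene_id <- ids$gene_id
      df$cell_type <- ids$cell_type
    } else {
      df$trait_id <- s$trait_id
    }
    df
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    df <- data.frame(snp_id = character(), chrom = character(),
                     pos = numeric(), effect_allele = character(),
                     other_allele = character(), eaf = numeric(),
                     beta = numeric(), se = numeric(), pvalue = numeric(),
                     n = numeric(), stringsAsFactors = FALSE)
    if (exposure_style) { df$gene_id <- character(); df$cell_type <- character() }
    else df$trait_id <- character()
    df
  }
  # rename canonical -> dialect headers
  canon <- c(snp = "snp_id", chrom = "chrom", pos = "pos",
             ea = "effect_allele", oa = "other_allele", eaf = "eaf",
             beta = "beta", se = "se", p = "pvalue", n = "n",
             trait = "trait_id", gene = "gene_id", cell_type = "cell_type")
  for (key in names(dialect)) {
    from <- canon[[key]]
    if (!is.null(from) && from %in% names(out))
      names(out)[names(out) == from] <- dialect[[key]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an LD matrix from a plain-text matrix + snplist pair
#'
#' The matrix file is a whitespace-delimited square numeric matrix of
#' allelic correlations r; the companion snplist holds one variant id per
#' line in matrix order (the convention of common LD-reference exports).
#'
#' @param matrix_path,snplist_path file paths.
#' @return an [ld_matrix()].
#' @export
read_ld <- function(matrix_path, snplist_path) {
  snps <- scan(snplist_path, what = character(), quiet = TRUE)
  r <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  if (nrow(r) != ncol(r))
    stop("LD matrix is not square: ", nrow(r), " x ", ncol(r))
  ld_matrix(unname(r), snps)
}

#' @rdname read_ld
#' @param ld an [ld_matrix()] to write.
#' @export
write_ld <- function(ld, matrix_path, snplist_path) {
  utils::write.table(format(unclass(ld), digits = 10), matrix_path,
                     sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(rownames(ld), snplist_path)
  invisible(matrix_path)
}

#' Read a gene annotation TSV
#'
#' Expects columns `gene_id`, `chrom`, `start`, `end` and optionally
#' `strand` (1-based inclusive coordinates).
#' @param path file path.
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene annotation lacks column(s): ", paste(miss, collapse = ", "))
  gene_annotation(df$gene_id, df$chrom, df$start, df$end,
                  strand = df$strand %||% "unknown")
}

#' @rdname read_gene_annotation
#' @param genes a [gene_annotation()] to write.
#' @export
write_gene_annotation <- function(genes, path) {
  utils::write.table(as.data.frame(unclass(genes)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a two-column cell-type map TSV
#'
#' Columns `discovery` and `replication`.
#' @param path file path.
#' @return a [cell_type_map()].
#' @export
read_cell_type_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("discovery", "replication") %in% names(df)))
    stop("cell-type map needs columns 'discovery' and 'replication'")
  cell_type_map(df$discovery, df$replication)
}

#' @rdname read_cell_type_map
#' @param map a [cell_type_map()] to write.
#' @export
write_cell_type_map <- function(map, path) {
  utils::write.table(
    data.frame(discovery = names(map), replication = unname(unclass(map))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
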