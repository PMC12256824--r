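# Allele harmonization: align exposure and outcome marginal effects to the
# same effect allele, resolving allele-order swaps, strand flips, and
# palindromic (A/T, G/C) ambiguity. Only biallelic SNVs are handled; indels
# and irreconcilable allele pairs are dropped as mismatches.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) !is.na(ea) & !is.na(oa) &
  COMPLEMENT[ea] == oa

#' Palindrome-handling policy
#'
#' Palindromic SNPs (A/T or G/C) cannot be strand-resolved from allele
#' labels alone. `drop_all` removes them; `infer_by_frequency` (the default)
#' aligns them by requiring the effect-allele frequencies to be concordant
#' on the same side of 0.5, and drops any palindrome whose minor-allele
#' frequency on either side exceeds `maf_ambiguity_threshold` (too close to
#' 0.5 to call) or whose frequency is missing on either side.
#'
#' @param mode `"infer_by_frequency"` or `"drop_all"`.
#' @param maf_ambiguity_threshold MAF ceiling in (0, 0.5) above which a
#'   palindrome is considered ambiguous; default 0.42, the common
#'   convention of two-sample MR harmonization routines.
#' @return list of class `palindrome_policy`.
#' @export
palindrome_policy <- function(mode = c("infer_by_frequency", "drop_all"),
                              maf_ambiguity_threshold = 0.42) {
  mode <- match.arg(mode)
  stopifnot(maf_ambiguity_threshold > 0, maf_ambiguity_threshold < 0.5)
  structure(list(mode = mode,
                 maf_ambiguity_threshold = maf_ambiguity_threshold),
            class = "palindrome_policy")
}

#' Harmonize exposure instruments against outcome summary statistics
#'
#' For every variant shared between the exposure and the outcome, aligns
#' the outcome effect to the exposure's effect allele:
#'
#' * identical alleles — kept as is (`action = "identical"`);
#' * swapped alleles — outcome beta negated, eaf reflected
#'   (`"swapped"`);
#' * strand-flipped alleles — relabeled via complement, then as above
#'   (`"strand_flipped"` / `"strand_flipped_swapped"`);
#' * palindromic SNPs — resolved per the [palindrome_policy()]
#'   (`"dropped_palindrome"` when unresolvable);
#' * anything else, including indels — `"dropped_mismatch"`.
#'
#' @param exposure an [instrument_set()] or [assoc_set()] (the exposure's
#'   variant table supplies the reference allele orientation).
#' @param outcome an [assoc_set()].
#' @param policy a [palindrome_policy()].
#' @return data.frame of class `harmonized_pairs`, one row per shared
#'   variant (dropped rows included for audit, flagged by their `action`):
#'   columns `snp_id`, `pos`, `effect_allele`, `other_allele`,
#'   `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `n_exp`, `n_out`, `action`, `kept`.
#' @export
harmonize <- function(exposure, outcome, policy = palindrome_policy()) {
  exp_df <- if (inherits(exposure, "instrument_set")) exposure$variants
            else exposure$records
  out_df <- outcome$records
  shared <- intersect(exp_df$snp_id, out_df$snp_id)
  if (length(shared) == 0)
    stop("harmonization failed: no shared variants between '",
         if (inherits(exposure, "instrument_set"))
           exposure_trait_id(exposure$gene_id, exposure$cell_type)
         else exposure$trait_id,
         "' and '", outcome$trait_id, "'")
  e <- exp_df[match(shared, exp_df$snp_id), , drop = FALSE]
  o <- out_df[match(shared, out_df$snp_id), , drop = FALSE]

  n <- length(shared)
  action <- character(n)
  beta_out <- o$beta
  eaf_out <- o$eaf

  ea_e <- e$effect_allele; oa_e <- e$other_allele
  ea_o <- o$effect_allele; oa_o <- o$other_allele
  snv <- ea_e %in% names(COMPLEMENT) & oa_e %in% names(COMPLEMENT) &
    ea_o %in% names(COMPLEMENT) & oa_o %in% names(COMPLEMENT)
  pal <- snv & is_palindromic(ea_e, oa_e)

  for (i in seq_len(n)) {
    if (!snv[i]) { action[i] <- "dropped_mismatch"; next }
    identical_ <- ea_o[i] == ea_e[i] && oa_o[i] == oa_e[i]
    swapped <- ea_o[i] == oa_e[i] && oa_o[i] == ea_e[i]
    flipped <- COMPLEMENT[[ea_o[i]]] == ea_e[i] &&
      COMPLEMENT[[oa_o[i]]] == oa_e[i]
    flip_swap <- COMPLEMENT[[ea_o[i]]] == oa_e[i] &&
      COMPLEMENT[[oa_o[i]]] == ea_e[i]

    if (pal[i]) {
      # identical is indistinguishable from flipped+swapped; use frequency
      if (!(identical_ || swapped)) { action[i] <- "dropped_mismatch"; next }
      if (policy$mode == "drop_all") { action[i] <- "dropped_palindrome"; next }
      if (is.na(e$eaf[i]) || is.na(o$eaf[i])) {
        action[i] <- "dropped_palindrome"; next
      }
      maf_e <- min(e$eaf[i], 1 - e$eaf[i])
      maf_o <- min(o$eaf[i], 1 - o$eaf[i])
      if (maf_e > policy$maf_ambiguity_threshold ||
          maf_o > policy$maf_ambiguity_threshold) {
        action[i] <- "dropped_palindrome"; next
      }
      label_swap <- swapped
      if (label_swap) { beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i] }
      freq_flip <- (e$eaf[i] < 0.5) != (eaf_out[i] < 0.5)
      if (freq_flip) { beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i] }
      action[i] <-
        if (!label_swap && !freq_flip) "identical"
        else if (label_swap && !freq_flip) "swapped"
        else if (!label_swap) "strand_flipped_swapped"
        else "strand_flipped"
      next
    }

    if (identical_) {
      action[i] <- "identical"
    } else if (swapped) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "swapped"
    } else if (flipped) {
      action[i] <- "strand_flipped"
    } else if (flip_swap) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "strand_flipped_swapped"
    } else {
      action[i] <- "dropped_mismatch"
    }
  }

  res <- data.frame(
    snp_id = shared, pos = e$pos,
    effect_allele = ea_e, other_allele = oa_e,
    beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf,
    beta_out = beta_out, se_out = o$se, eaf_out = eaf_out,
    n_exp = e$n, n_out = o$n,
    action = action,
    kept = !startsWith(action, "dropped"),
    stringsAsFactors = FALSE)
  class(res) <- c("harmonized_pairs", class(res))
  res
}

#' Align an outcome association set onto an exposure's allele orientation
#'
#' Convenience wrapper used before colocalization: harmonizes all shared
#' variants of two association sets and returns both as aligned
#' `assoc_set`s restricted to the retained intersection.
#'
#' @inheritParams harmonize
#' @return list with aligned `exposure` and `outcome` assoc_sets.
#' @export
align_sets <- function(exposure, outcome, policy = palindrome_policy()) {
  h <- harmonize(exposure, outcome, policy)
  h <- h[h$kept, , drop = FALSE]
  exp_rec <- exposure$records[match(h$snp_id, exposure$records$snp_id), ,
                              drop = FALSE]
  out_rec <- exp_rec
  out_rec$beta <- h$beta_out
  out_rec$se <- h$se_out
  out_rec$eaf <- h$eaf_out
  out_rec$n <- h$n_out
  out_rec$pvalue <- pmax(2 * stats::pnorm(-abs(h$beta_out / h$se_out)),
                         .Machine$double.xmin)
  e <- exposure; e$records <- exp_rec; rownames(e$records) <- NULL
  o <- outcome
  o$records <- out_rec; rownames(o$records) <- NULL
  o$region <- exposure$region
  list(exposure = e, outcome = o)
}
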