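# Candidate-gene filter cascade: delta(SNP-index) threshold, codon-level
# variant effect annotation, and the cross-variety allele-pattern filter
# that isolates variants private to the photoperiod-sensitive group.

#' Filter sites by delta(SNP-index)
#'
#' Keeps sites with `delta` strictly greater than `threshold` (default 0.7).
#' Missing deltas never pass.
#'
#' @param sites Indexed site data frame with a `delta` column.
#' @param threshold Strict lower bound on delta.
#' @return The surviving subset of `sites`.
#' @export
filter_delta_sites <- function(sites, threshold = 0.7) {
  if (!"delta" %in% names(sites)) {
    stop("'sites' must carry a 'delta' column", call. = FALSE)
  }
  sites[!is.na(sites$delta) & sites$delta > threshold, , drop = FALSE]
}

#' Codon-level consequence of a single-nucleotide variant on a CDS
#'
#' Translates the reference and mutated codon under the standard genetic
#' code and classifies the change. `ref` and `alt` are given in genomic
#' orientation; for minus-strand genes they are reverse-complemented before
#' lookup. The reference allele must match the CDS at `cds_pos` (after
#' strand adjustment), otherwise an error names the offending position.
#'
#' @param cds Spliced coding sequence (character string, 5'->3' on the
#'   coding strand), length divisible by three.
#' @param cds_pos 1-based position of the variant within the CDS.
#' @param ref,alt Genomic reference and alternate alleles (single bases).
#' @param strand `"+"` or `"-"` (strand of the gene on the genome).
#' @param gene_id Optional gene identifier carried into the result.
#' @return One-row data frame: `gene_id`, `cds_pos`, `codon_index`,
#'   `codon_pos`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `consequence` (`synonymous`, `nonsynonymous`, `stop_gained`,
#'   `stop_lost`).
#' @examples
#' annotate_effect("ATGGATTAA", 5, "A", "G")  # GAT -> GGT: D -> G
#' annotate_effect("ATGGATTAA", 6, "T", "C")  # GAT -> GAC: synonymous
#' @export
annotate_effect <- function(cds, cds_pos, ref, alt, strand = "+",
                            gene_id = NA_character_) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3", call. = FALSE)
  if (cds_pos < 1 || cds_pos > n) {
    stop(sprintf("CDS position %d is beyond the CDS (length %d)", cds_pos, n),
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("'strand' must be '+' or '-'", call. = FALSE)
  cds <- toupper(cds)
  ref_c <- if (strand == "-") revcomp_base(toupper(ref)) else toupper(ref)
  alt_c <- if (strand == "-") revcomp_base(toupper(alt)) else toupper(alt)
  have <- substr(cds, cds_pos, cds_pos)
  if (have != ref_c) {
    stop(sprintf("reference allele mismatch at CDS position %d: CDS has %s, variant expects %s (coding strand)",
                 cds_pos, have, ref_c), call. = FALSE)
  }
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  codon_pos <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substr(cds, 3L * codon_index - 2L, 3L * codon_index)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_c
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[[ref_codon]])
  alt_aa <- unname(code[[alt_codon]])
  consequence <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else "nonsynonymous"
  data.frame(gene_id = gene_id, cds_pos = as.integer(cds_pos),
             codon_index = codon_index, codon_pos = codon_pos,
             ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence,
             stringsAsFactors = FALSE)
}

#' Cross-variety allele-pattern rule
#'
#' Describes the genotype pattern expected of a variant causal for a trait
#' private to one variety group: every accession in `ref_groups` matches
#' the reference genome while every accession in `alt_group` shares the
#' same non-reference allele. With `missing_policy = "fail"` (default) a
#' site must be fully observed and homozygous in every relevant accession;
#' `"ignore"` lets missing calls pass as compatible (heterozygous calls
#' always fail — the accessions are inbred, so residual heterozygosity is
#' treated as a non-match).
#'
#' @param ref_groups Group labels whose accessions must match the reference.
#' @param alt_group Group label whose accessions must share the alternate
#'   allele.
#' @param missing_policy `"fail"` or `"ignore"`.
#' @return A `pattern_rule` list.
#' @export
pattern_rule <- function(ref_groups = c("north", "south"), alt_group = "xis",
                         missing_policy = c("fail", "ignore")) {
  if (alt_group %in% ref_groups) {
    stop("'alt_group' must be disjoint from 'ref_groups'", call. = FALSE)
  }
  structure(list(ref_groups = ref_groups, alt_group = alt_group,
                 missing_policy = match.arg(missing_policy)),
            class = "pattern_rule")
}

#' Which panel sites match the allele-pattern rule?
#'
#' @param calls Sites x varieties character matrix with codes `ref`, `alt`,
#'   `het`, `missing`.
#' @param groups Named character vector mapping variety to group label.
#' @param rule A [pattern_rule()].
#' @return Named logical vector, one element per site.
#' @export
pattern_matches <- function(calls, groups, rule = pattern_rule()) {
  calls <- as.matrix(calls)
  unknown <- setdiff(c(rule$ref_groups, rule$alt_group), unique(groups))
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ref_vars <- names(groups)[groups %in% rule$ref_groups]
  alt_vars <- names(groups)[groups == rule$alt_group]
  missing_vars <- setdiff(c(ref_vars, alt_vars), colnames(calls))
  if (length(missing_vars)) {
    stop("panel lacks variety column(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  refm <- calls[, ref_vars, drop = FALSE]
  altm <- calls[, alt_vars, drop = FALSE]
  if (rule$missing_policy == "fail") {
    ok <- rowSums(refm == "ref") == length(ref_vars) &
      rowSums(altm == "alt") == length(alt_vars)
  } else {
    ref_ok <- rowSums(refm == "ref" | refm == "missing") == length(ref_vars)
    alt_ok <- rowSums(altm == "alt" | altm == "missing") == length(alt_vars) &
      rowSums(altm == "alt") >= 1
    ok <- ref_ok & alt_ok
  }
  stats::setNames(as.logical(ok), rownames(calls))
}

#' Filter panel sites by the allele-pattern rule
#'
#' @inheritParams pattern_matches
#' @return The subset of `calls` rows matching the rule.
#' @export
pattern_filter <- function(calls, groups, rule = pattern_rule()) {
  calls <- as.matrix(calls)
  calls[pattern_matches(calls, groups, rule), , drop = FALSE]
}

#' Candidate-gene filter cascade
#'
#' Applies the full funnel used to nominate a causal gene inside a mapped
#' QTL: (1) keep sites with delta(SNP-index) above `threshold`; (2) keep
#' sites whose coding effect is non-synonymous (including stop changes);
#' (3) keep sites in genes overlapping the consensus `region`; (4) keep
#' sites matching the cross-variety allele `rule`; (5, optional) keep genes
#' whose functional annotation matches `annotation_keyword` — this last
#' stage reproduces a curator's function-based choice among the pattern
#' genes and runs only when annotations are supplied. Per-stage site and
#' gene counts are recorded as an audit trail.
#'
#' @param sites Site data frame with columns `chrom`, `pos`, `gene`,
#'   `cds_pos`, `ref`, `alt`, `delta`.
#' @param genes Gene features (`gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `strand`).
#' @param cds_set Named list (or character vector) of CDS strings, one per
#'   gene id.
#' @param panel Sites x varieties call matrix; rownames must be
#'   `"chrom:pos"` keys. Sites without a panel row fail the pattern stage.
#' @param groups Variety-to-group map for `panel`.
#' @param region One-row interval data frame (Mb).
#' @param threshold delta threshold (strict, default 0.7).
#' @param rule A [pattern_rule()].
#' @param annotations Optional data frame `gene_id`, `product`.
#' @param annotation_keyword Optional regular expression matched
#'   (case-insensitively) against `product` for the final stage.
#' @return A `candidate_cascade` list: `stages` (stage, n_sites, n_genes),
#'   `candidates` (surviving sites with effect annotation, ranked by
#'   descending delta), and `sites` (all annotated sites that passed the
#'   delta stage, with a `stage_reached` column).
#' @export
candidate_cascade <- function(sites, genes, cds_set, panel, groups, region,
                              threshold = 0.7, rule = pattern_rule(),
                              annotations = NULL, annotation_keyword = NULL) {
  stage_row <- function(stage, s) {
    data.frame(stage = stage, n_sites = nrow(s),
               n_genes = length(unique(s$gene)), stringsAsFactors = FALSE)
  }
  stages <- stage_row("input", sites)

  s1 <- filter_delta_sites(sites, threshold)
  stages <- rbind(stages, stage_row("delta", s1))

  strand_of <- stats::setNames(genes$strand, genes$gene_id)
  eff <- if (nrow(s1)) {
    do.call(rbind, lapply(seq_len(nrow(s1)), function(i) {
      annotate_effect(cds_set[[s1$gene[i]]], s1$cds_pos[i], s1$ref[i],
                      s1$alt[i], strand = strand_of[[s1$gene[i]]],
                      gene_id = s1$gene[i])
    }))
  } else NULL
  s1$consequence <- if (is.null(eff)) character(0) else eff$consequence
  s1$ref_aa <- if (is.null(eff)) character(0) else eff$ref_aa
  s1$alt_aa <- if (is.null(eff)) character(0) else eff$alt_aa
  s2 <- s1[s1$consequence %in% c("nonsynonymous", "stop_gained", "stop_lost"),
           , drop = FALSE]
  stages <- rbind(stages, stage_row("nonsynonymous", s2))

  region_genes <- if (nrow(s2) == 0L) genes[0, , drop = FALSE] else
    genes_in_region(genes[genes$gene_id %in% unique(s2$gene), , drop = FALSE],
                    region)
  s3 <- s2[s2$gene %in% region_genes$gene_id, , drop = FALSE]
  stages <- rbind(stages, stage_row("region", s3))

  keys <- paste(s3$chrom, s3$pos, sep = ":")
  in_panel <- keys %in% rownames(panel)
  ok <- rep(FALSE, nrow(s3))
  if (any(in_panel)) {
    ok[in_panel] <- pattern_matches(panel[keys[in_panel], , drop = FALSE],
                                    groups, rule)
  }
  s4 <- s3[ok, , drop = FALSE]
  stages <- rbind(stages, stage_row("pattern", s4))

  s5 <- s4
  if (!is.null(annotations) && !is.null(annotation_keyword)) {
    prod_of <- stats::setNames(annotations$product, annotations$gene_id)
    hit <- prod_of[s4$gene]
    s5 <- s4[!is.na(hit) & grepl(annotation_keyword, hit, ignore.case = TRUE), ,
             drop = FALSE]
    stages <- rbind(stages, stage_row("annotation", s5))
  }

  s1$stage_reached <- rep("delta", nrow(s1))
  s1$stage_reached[rownames(s1) %in% rownames(s2)] <- "nonsynonymous"
  s1$stage_reached[rownames(s1) %in% rownames(s3)] <- "region"
  s1$stage_reached[rownames(s1) %in% rownames(s4)] <- "pattern"
  s1$stage_reached[rownames(s1) %in% rownames(s5)] <-
    if (!is.null(annotations) && !is.null(annotation_keyword)) "annotation" else "pattern"

  candidates <- s5[order(-s5$delta), , drop = FALSE]
  structure(list(stages = stages, candidates = candidates, sites = s1),
            class = "candidate_cascade")
}

#' @export
print.candidate_cascade <- function(x, ...) {
  cat("Candidate-gene filter cascade\n")
  print(x$stages, row.names = FALSE)
  if (nrow(x$candidates)) {
    cat("\nCandidates (ranked by delta):\n")
    print(x$candidates[, c("gene", "chrom", "pos", "delta", "consequence",
                           "ref_aa", "alt_aa")], row.names = FALSE)
  } else {
    cat("\nNo candidate survived all stages.\n")
  }
  invisible(x)
}
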