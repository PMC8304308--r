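# Planted-truth fixture for the candidate-gene cascade: a fully synthetic
# chromosome whose site, gene, CDS, panel and annotation tables are built so
# that each cascade stage has an exactly known survivor set.

# Overwrite codon `ci` of a codon vector with `codon` and return the variant
# row describing a substitution at `codon_off` (1..3) of that codon.
.plant_codon_variant <- function(codons, ci, codon, codon_off, alt_base) {
  codons[ci] <- codon
  cds_pos <- 3L * (ci - 1L) + codon_off
  list(codons = codons,
       variant = data.frame(cds_pos = cds_pos,
                            ref = substr(codon, codon_off, codon_off),
                            alt = alt_base, stringsAsFactors = FALSE))
}

#' Simulate a planted-truth fixture for the candidate cascade
#'
#' Builds a synthetic chromosome with a known candidate-gene funnel: exactly
#' `n_delta_genes` genes carry non-synonymous variants with delta(SNP-index)
#' above `threshold` (spread over `n_delta_sites` sites), of which exactly
#' `n_region_genes` lie inside `region`, of which exactly `n_pattern_genes`
#' carry the group-private allele pattern in the variety panel, of which
#' exactly one carries the target functional annotation. Decoy genes that
#' fail the delta stage (low delta) or the effect stage (synonymous
#' variants) are planted as well, so every stage of the cascade does real
#' work. All non-synonymous plants are GAT->GGT (Asp->Gly) second-codon-
#' position changes and all synonymous plants are GAT->GAC third-position
#' changes; a few region genes are placed on the minus strand, where the
#' genomic alleles are the reverse complement of the CDS alleles.
#'
#' @param n_delta_genes Genes surviving the delta + non-synonymous stages.
#' @param n_delta_sites Total sites carried by those genes (>=
#'   `n_delta_genes`; extra sites are distributed one per gene).
#' @param n_region_genes Of those, genes inside `region`.
#' @param n_pattern_genes Of those, genes whose sites match the panel
#'   pattern.
#' @param region Consensus interval the region stage filters on.
#' @param threshold delta threshold the fixture is built against.
#' @param n_decoy_low_delta Decoy genes whose sites have delta below the
#'   threshold.
#' @param n_decoy_synonymous Decoy genes whose sites exceed the threshold
#'   but are synonymous.
#' @param chrom_length_bp Chromosome length.
#' @param cds_codons CDS length (codons) of every synthetic gene.
#' @param seed Optional integer seed.
#' @return A list with `sites`, `genes`, `cds_set`, `panel`, `groups`,
#'   `annotations`, `region`, and `truth` (the planted stage counts and the
#'   final gene id).
#' @export
simulate_candidate_truth <- function(n_delta_genes = 150L,
                                     n_delta_sites = 298L,
                                     n_region_genes = 15L,
                                     n_pattern_genes = 4L,
                                     region = genomic_interval("chr1", 21.65, 23.03, "consensus"),
                                     threshold = 0.7,
                                     n_decoy_low_delta = 30L,
                                     n_decoy_synonymous = 20L,
                                     chrom_length_bp = 3e7,
                                     cds_codons = 60L,
                                     seed = NULL) {
  stopifnot(n_region_genes <= n_delta_genes,
            n_pattern_genes <= n_region_genes,
            n_delta_sites >= n_delta_genes,
            n_delta_sites <= 2L * n_delta_genes)
  with_seed_if(seed, {
    chrom <- region$chrom[1]
    r_start <- round(region$start_mb * 1e6)
    r_end <- round(region$end_mb * 1e6)
    gene_len <- 2000L
    margin <- 50000L

    n_out <- n_delta_genes - n_region_genes
    n_total <- n_delta_genes + n_decoy_low_delta + n_decoy_synonymous
    # non-overlapping gene placement: sample starts from a gene-length grid
    starts_in <- sort(sample(seq.int(r_start, r_end - gene_len, by = gene_len),
                             n_region_genes))
    out_space <- c(seq.int(1L, r_start - margin - gene_len, by = gene_len),
                   seq.int(r_end + margin, chrom_length_bp - gene_len,
                           by = gene_len))
    starts_out <- sort(sample(out_space, n_out + n_decoy_low_delta +
                                n_decoy_synonymous))
    gene_id <- sprintf("gene_%03d", seq_len(n_total))
    role <- c(rep("signal_in", n_region_genes), rep("signal_out", n_out),
              rep("decoy_low", n_decoy_low_delta),
              rep("decoy_syn", n_decoy_synonymous))
    start_bp <- c(starts_in, starts_out)
    strand <- rep("+", n_total)
    strand[seq_len(n_region_genes)[c(FALSE, TRUE)]] <- "-"  # alternate in region
    genes <- data.frame(gene_id = gene_id, chrom = chrom,
                        start_bp = start_bp, end_bp = start_bp + gene_len - 1L,
                        strand = strand, stringsAsFactors = FALSE)

    # two sites for the first (n_delta_sites - n_delta_genes) signal genes
    signal_ids <- gene_id[role %in% c("signal_in", "signal_out")]
    extra <- n_delta_sites - n_delta_genes
    sites_per_gene <- stats::setNames(rep(1L, n_total), gene_id)
    sites_per_gene[signal_ids[seq_len(extra)]] <- 2L

    cds_set <- list()
    site_rows <- list()
    for (g in seq_len(n_total)) {
      id <- gene_id[g]
      codons <- .random_cds_codons(cds_codons)
      k <- sites_per_gene[[id]]
      cis <- sample(2:(cds_codons - 1L), k)
      for (j in seq_len(k)) {
        if (role[g] == "decoy_syn") {
          planted <- .plant_codon_variant(codons, cis[j], "GAT", 3L, "C")
        } else {
          planted <- .plant_codon_variant(codons, cis[j], "GAT", 2L, "G")
        }
        codons <- planted$codons
        v <- planted$variant
        minus <- strand[g] == "-"
        delta <- switch(role[g],
                        decoy_low = stats::runif(1, 0.05, threshold - 0.05),
                        stats::runif(1, threshold + 0.05, 0.98))
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          chrom = chrom,
          pos = start_bp[g] + v$cds_pos - 1L,  # toy 1:1 gene-to-genome map
          gene = id,
          cds_pos = v$cds_pos,
          ref = if (minus) revcomp_base(v$ref) else v$ref,
          alt = if (minus) revcomp_base(v$alt) else v$alt,
          delta = delta,
          stringsAsFactors = FALSE)
      }
      cds_set[[id]] <- paste0(codons, collapse = "")
    }
    sites <- do.call(rbind, site_rows)
    sites <- sites[order(sites$pos), , drop = FALSE]
    rownames(sites) <- NULL

    # panel: pattern rows for the chosen pattern genes, violations elsewhere
    groups <- .panel_groups()
    varieties <- names(groups)
    xis <- varieties[groups == "xis"]
    pattern_genes <- sample(gene_id[role == "signal_in"], n_pattern_genes)
    calls <- matrix("ref", nrow = nrow(sites), ncol = length(varieties),
                    dimnames = list(paste(sites$chrom, sites$pos, sep = ":"),
                                    varieties))
    is_pattern <- sites$gene %in% pattern_genes
    calls[is_pattern, xis] <- "alt"
    for (i in which(!is_pattern)) {
      calls[i, xis] <- "alt"
      calls[i, sample(xis, 1L)] <- sample(c("ref", "missing", "het"), 1L)
    }

    final_gene <- sample(pattern_genes, 1L)
    region_ids <- gene_id[role == "signal_in"]
    products <- rep("hypothetical protein", n_total)
    products[gene_id %in% region_ids] <- sample(
      c("protein kinase", "pentatricopeptide repeat protein",
        "cytochrome P450", "WD40 repeat protein"),
      length(region_ids), replace = TRUE)
    products[gene_id == final_gene] <- "nuclear factor Y subunit A (NF-YA)"
    annotations <- data.frame(gene_id = gene_id, product = products,
                              stringsAsFactors = FALSE)

    list(sites = sites, genes = genes, cds_set = cds_set, panel = calls,
         groups = groups, annotations = annotations, region = region,
         truth = list(n_delta_nonsyn_genes = n_delta_genes,
                      n_region_genes = n_region_genes,
                      n_pattern_genes = n_pattern_genes,
                      n_final_genes = 1L,
                      final_gene = final_gene))
  })
}
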