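# Independent oracles and small fixture builders used across the suite.
# Each oracle recomputes a quantity by a route independent of the package
# code path it checks.

# Naive window mean: filter-and-average, no cumulative sums.
oracle_window_mean <- function(sites, chrom, start, window_bp) {
  d <- sites$delta[sites$chrom == chrom &
                     sites$pos >= start & sites$pos < start + window_bp]
  d <- d[!is.na(d)]
  if (length(d) == 0) return(NA_real_)
  sum(d) / length(d)
}

# Whole-CDS translation diff via Biostrings: mutate, translate both, diff.
oracle_effect <- function(cds, cds_pos, alt_coding) {
  mut <- cds
  substr(mut, cds_pos, cds_pos) <- alt_coding
  aa_ref <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(cds), no.init.codon = TRUE)), "")[[1]]
  aa_alt <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(mut), no.init.codon = TRUE)), "")[[1]]
  diff_at <- which(aa_ref != aa_alt)
  list(n_changed = length(diff_at),
       codon_index = if (length(diff_at)) diff_at else NA_integer_,
       ref_aa = if (length(diff_at)) aa_ref[diff_at] else NA_character_,
       alt_aa = if (length(diff_at)) aa_alt[diff_at] else NA_character_)
}

# Set-logic pattern check written independently: explicit per-variety loop.
oracle_pattern_row <- function(row, groups, ref_groups = c("north", "south"),
                               alt_group = "xis", policy = "fail") {
  for (v in names(groups)) {
    call <- row[[v]]
    if (groups[[v]] %in% ref_groups) {
      if (policy == "fail" && call != "ref") return(FALSE)
      if (policy == "ignore" && !(call %in% c("ref", "missing"))) return(FALSE)
    } else if (groups[[v]] == alt_group) {
      if (policy == "fail" && call != "alt") return(FALSE)
      if (policy == "ignore" && !(call %in% c("alt", "missing"))) return(FALSE)
    }
  }
  if (policy == "ignore") {
    alt_calls <- unlist(row[names(groups)[groups == alt_group]])
    if (!any(alt_calls == "alt")) return(FALSE)
  }
  TRUE
}

# Brute-force bulk selection: lexicographic (phenotype, index) sort done
# with repeated explicit minimum search, no order().
oracle_tail_bulks <- function(phenotypes, bulk_size) {
  n <- length(phenotypes)
  key <- phenotypes * n + (seq_len(n) - 1) / n  # strict lexicographic key
  remaining <- seq_len(n)
  e_pool <- integer(0)
  for (i in seq_len(bulk_size)) {
    pick <- remaining[which.min(key[remaining])]
    e_pool <- c(e_pool, pick)
    remaining <- setdiff(remaining, pick)
  }
  l_pool <- integer(0)
  remaining <- seq_len(n)
  for (i in seq_len(bulk_size)) {
    cand <- remaining[key[remaining] == max(key[remaining])]
    pick <- cand[length(cand)]
    l_pool <- c(l_pool, pick)
    remaining <- setdiff(remaining, pick)
  }
  list(e_pool = sort(e_pool), l_pool = sort(l_pool))
}

# Minimal polarised site table from explicit per-pool depths.
make_sites <- function(pos, e_ref, e_alt, l_ref, l_alt, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             p1_gt = "ref_hom", p2_gt = "alt_hom",
             e_ref = e_ref, e_alt = e_alt, l_ref = l_ref, l_alt = l_alt,
             stringsAsFactors = FALSE)
}

# All codes at one site for the nine-variety panel, as a one-row matrix.
panel_row <- function(codes, groups) {
  matrix(codes, nrow = 1, dimnames = list("s1", names(groups)))
}
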