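# Synthetic F2-cross generator: the data model the QTL-seq statistics assume.
#
# An F2 from an insensitive x sensitive cross segregates 1:2:1 at every
# locus; tail selection on the phenotype enriches the two bulks for opposite
# alleles around the causal locus, and pooled short-read sequencing turns
# bulk allele frequencies into binomially sampled allele depths.

#' Configuration of a synthetic F2 QTL-seq experiment
#'
#' Bundles every parameter of the simulated cross, bulk selection and pooled
#' sequencing. Defaults describe the reference design this package is
#' validated against: an F2 of 234 plants from a photoperiod-insensitive
#' (P1, early) x photoperiod-sensitive (P2, late) cucumber cross, tail bulks
#' of 17 plants, a single causal flowering-time locus, and ~30x pooled
#' coverage.
#'
#' @param n_individuals Number of F2 plants.
#' @param bulk_size Plants per bulk; must not exceed `n_individuals / 2`.
#' @param n_sites Number of segregating marker sites on the chromosome.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param causal_pos_bp Position of the causal locus in bp, or `NULL` for a
#'   null chromosome without any QTL.
#' @param effect_days Phenotype shift (days to first flowering) between the
#'   two homozygote classes at the causal locus; positive values mean the P2
#'   allele delays flowering.
#' @param dominance Dominance of the P1 (early) allele in `[0, 1]`: 0 gives
#'   an additive locus (heterozygote shifted by `effect_days / 2`), 1 makes
#'   the early allele fully dominant (heterozygote flowers like P1).
#' @param baseline_days Days to first flowering of the P1 homozygote class.
#' @param noise_sd Standard deviation of Gaussian phenotype noise, in days.
#' @param mean_depth Expected sequencing depth per site per pool.
#' @param bp_per_cm Physical-to-genetic map scale (bp per centimorgan);
#'   recombination uses the Haldane map function without interference.
#' @param depth_mode `"poisson"` draws per-site depths from a Poisson with
#'   mean `mean_depth`; `"fixed"` uses exactly `mean_depth` reads (useful
#'   for exact enumeration checks).
#' @param chrom Chromosome name used in emitted variant tables.
#' @param seed Integer seed; identical configurations reproduce bit-identical
#'   populations and depth tables. `NULL` uses the current RNG stream.
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(n_individuals = 234L,
                         bulk_size = 17L,
                         n_sites = 1000L,
                         chrom_length_bp = 1e7,
                         causal_pos_bp = round(chrom_length_bp / 2),
                         effect_days = 20,
                         dominance = 1,
                         baseline_days = 80,
                         noise_sd = 2,
                         mean_depth = 30,
                         bp_per_cm = 250000,
                         depth_mode = c("poisson", "fixed"),
                         chrom = "chr1",
                         seed = NULL) {
  depth_mode <- match.arg(depth_mode)
  assert_scalar_number(n_individuals, "n_individuals", min = 2)
  assert_scalar_number(bulk_size, "bulk_size", min = 1)
  if (bulk_size > n_individuals / 2) {
    stop("'bulk_size' must be at most n_individuals / 2 so the two bulks can be disjoint",
         call. = FALSE)
  }
  assert_scalar_number(n_sites, "n_sites", min = 1)
  assert_scalar_number(chrom_length_bp, "chrom_length_bp", min = 1)
  if (n_sites > chrom_length_bp) {
    stop("'n_sites' cannot exceed 'chrom_length_bp' (one site per bp at most)",
         call. = FALSE)
  }
  if (!is.null(causal_pos_bp)) {
    if (!is.numeric(causal_pos_bp) || length(causal_pos_bp) != 1L ||
        causal_pos_bp < 1 || causal_pos_bp > chrom_length_bp) {
      stop(sprintf("'causal_pos_bp' (%s) lies outside the chromosome [1, %s]",
                   format(causal_pos_bp), format(chrom_length_bp)), call. = FALSE)
    }
  }
  assert_scalar_number(dominance, "dominance", min = 0, max = 1)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(mean_depth, "mean_depth")
  if (mean_depth <= 0) stop("'mean_depth' must be > 0", call. = FALSE)
  assert_scalar_number(bp_per_cm, "bp_per_cm", min = 1)
  structure(list(
    n_individuals = as.integer(n_individuals),
    bulk_size = as.integer(bulk_size),
    n_sites = as.integer(n_sites),
    chrom_length_bp = as.numeric(chrom_length_bp),
    causal_pos_bp = if (is.null(causal_pos_bp)) NULL else as.numeric(causal_pos_bp),
    effect_days = as.numeric(effect_days),
    dominance = as.numeric(dominance),
    baseline_days = as.numeric(baseline_days),
    noise_sd = as.numeric(noise_sd),
    mean_depth = as.numeric(mean_depth),
    bp_per_cm = as.numeric(bp_per_cm),
    depth_mode = depth_mode,
    chrom = chrom,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cross_config")
}

#' Assemble an F2 population object from its components
#'
#' Mostly useful for constructing small populations by hand (e.g. in
#' enumeration tests); `simulate_f2()` is the usual entry point.
#'
#' @param genotypes Integer matrix, sites x individuals, coding the dose of
#'   the P2 allele: 0 (P1 homozygote), 1 (heterozygote), 2 (P2 homozygote).
#' @param phenotypes Numeric vector of days to first flowering, one per
#'   individual.
#' @param site_positions 1-based bp positions, one per genotype row.
#' @param chrom Chromosome name.
#' @param config Optional `cross_config` the population was generated from.
#' @param causal_dose Optional P2-allele dose at the causal locus.
#' @return An object of class `f2_population`.
#' @export
f2_population <- function(genotypes, phenotypes, site_positions,
                          chrom = "chr1", config = NULL, causal_dose = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (ncol(genotypes) != length(phenotypes)) {
    stop("one phenotype per individual (column) is required", call. = FALSE)
  }
  if (nrow(genotypes) != length(site_positions)) {
    stop("one position per site (row) is required", call. = FALSE)
  }
  if (any(!is.finite(phenotypes))) stop("phenotypes must be finite", call. = FALSE)
  if (any(!(genotypes %in% 0:2))) {
    stop("genotype codes must be 0, 1 or 2 (P2-allele dose)", call. = FALSE)
  }
  structure(list(
    genotypes = genotypes,
    phenotypes = as.numeric(phenotypes),
    site_positions = as.numeric(site_positions),
    chrom = chrom,
    config = config,
    causal_dose = causal_dose
  ), class = "f2_population")
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf("F2 population: %d individuals, %d sites on %s\n",
              ncol(x$genotypes), nrow(x$genotypes), x$chrom))
  cat(sprintf("  days to first flowering: %.1f-%.1f (mean %.1f)\n",
              min(x$phenotypes), max(x$phenotypes), mean(x$phenotypes)))
  invisible(x)
}

# One recombinant gamete evaluated at `pts`: 0 = P1 allele, 1 = P2 allele.
# Crossovers are Poisson in map length (Haldane model, no interference) and
# the starting haplotype is chosen at random.
.gamete_at <- function(pts, chrom_length_bp, map_morgans) {
  k <- stats::rpois(1L, map_morgans)
  o0 <- sample.int(2L, 1L) - 1L
  if (k == 0L) return(rep.int(o0, length(pts)))
  breaks <- sort(stats::runif(k, 0, chrom_length_bp))
  (o0 + findInterval(pts, breaks)) %% 2L
}

#' Simulate an F2 population with an optional causal flowering-time locus
#'
#' Each individual receives two independent recombinant gametes, each a
#' mosaic of the two parental haplotypes with a Poisson number of crossovers
#' in map length (Haldane mapping, no interference). Days to first flowering
#' is `baseline_days` plus a causal-locus shift (with dominance) plus
#' Gaussian noise.
#'
#' @param config A [cross_config()].
#' @return An [f2_population()] with `causal_dose` filled in when the
#'   configuration has a causal locus.
#' @examples
#' pop <- simulate_f2(cross_config(n_individuals = 50, n_sites = 20, seed = 1))
#' table(pop$genotypes[1, ])
#' @export
simulate_f2 <- function(config) {
  if (!inherits(config, "cross_config")) {
    stop("'config' must be created by cross_config()", call. = FALSE)
  }
  with_seed_if(config$seed, {
    n <- config$n_individuals
    L <- config$chrom_length_bp
    pos <- sort(sample.int(L, config$n_sites))
    map_m <- L / config$bp_per_cm / 100
    pts <- c(pos, config$causal_pos_bp)
    doses <- matrix(0L, nrow = length(pts), ncol = n)
    for (j in seq_len(n)) {
      doses[, j] <- .gamete_at(pts, L, map_m) + .gamete_at(pts, L, map_m)
    }
    has_causal <- !is.null(config$causal_pos_bp)
    causal_dose <- if (has_causal) doses[length(pts), ] else NULL
    genotypes <- doses[seq_along(pos), , drop = FALSE]
    shift <- if (has_causal) {
      # heterozygote shift interpolates between additive (dominance 0) and
      # full dominance of the early P1 allele (dominance 1)
      per_dose <- c(0, 0.5 * (1 - config$dominance), 1)
      config$effect_days * per_dose[causal_dose + 1L]
    } else 0
    phenotypes <- config$baseline_days + shift +
      stats::rnorm(n, 0, config$noise_sd)
    f2_population(genotypes, phenotypes, pos, chrom = config$chrom,
                  config = config, causal_dose = causal_dose)
  })
}

#' Select the early- and late-flowering bulks
#'
#' `mode = "tails"` takes the `bulk_size` earliest-flowering individuals as
#' the E-pool and the `bulk_size` latest as the L-pool. `mode = "thresholds"`
#' selects by day cut-offs instead: E-pool from individuals flowering inside
#' `thresholds$e` (a `[lo, hi]` pair of days), L-pool from those flowering
#' after `thresholds$l_min` days. Ties are broken by ascending individual
#' index, so selection is deterministic; the two pools are always disjoint.
#'
#' @param pop An [f2_population()].
#' @param bulk_size Individuals per pool.
#' @param mode `"tails"` or `"thresholds"`.
#' @param thresholds For `mode = "thresholds"`: `list(e = c(lo, hi), l_min = x)`
#'   in days. The default mirrors a tail-selected field design (early pool
#'   36-40 d, late pool beyond 52 d).
#' @return `list(e_pool =, l_pool =)` of individual indices (ascending).
#' @export
make_bulks <- function(pop, bulk_size = pop$config$bulk_size %||% 17L,
                       mode = c("tails", "thresholds"),
                       thresholds = list(e = c(36, 40), l_min = 52)) {
  mode <- match.arg(mode)
  ph <- pop$phenotypes
  n <- length(ph)
  ord <- order(ph, seq_len(n))
  if (mode == "tails") {
    if (bulk_size > n / 2) {
      stop("'bulk_size' must be at most half the population so pools are disjoint",
           call. = FALSE)
    }
    e_pool <- ord[seq_len(bulk_size)]
    l_pool <- ord[seq.int(n - bulk_size + 1L, n)]
  } else {
    if (thresholds$l_min < thresholds$e[2]) {
      stop("threshold ranges overlap: 'l_min' must be at least the upper E-pool cutoff",
           call. = FALSE)
    }
    e_eligible <- which(ph >= thresholds$e[1] & ph <= thresholds$e[2])
    l_eligible <- which(ph > thresholds$l_min)
    if (length(e_eligible) < bulk_size) {
      stop(sprintf("E-pool: only %d individuals flower within [%s, %s] d but bulk_size is %d",
                   length(e_eligible), thresholds$e[1], thresholds$e[2], bulk_size),
           call. = FALSE)
    }
    if (length(l_eligible) < bulk_size) {
      stop(sprintf("L-pool: only %d individuals flower after %s d but bulk_size is %d",
                   length(l_eligible), thresholds$l_min, bulk_size), call. = FALSE)
    }
    e_pool <- e_eligible[order(ph[e_eligible], e_eligible)][seq_len(bulk_size)]
    lo <- l_eligible[order(ph[l_eligible], l_eligible)]
    l_pool <- lo[seq.int(length(lo) - bulk_size + 1L, length(lo))]
  }
  list(e_pool = sort(e_pool), l_pool = sort(l_pool))
}

#' Sample pooled allele depths over the bulks
#'
#' Emulates pooled short-read sequencing of the two bulks and the two
#' parents. Per site and pool the total depth is Poisson(`mean_depth`)
#' (or exactly `mean_depth` in `"fixed"` mode) and the alternate-allele
#' depth is Binomial(depth, pool alternate-allele frequency), where the pool
#' frequency is the mean P2-allele dose of the bulk members divided by two.
#' Parents are emitted as fixed opposite homozygotes (P1 carries only the
#' reference allele, P2 only the alternate allele).
#'
#' @param pop An [f2_population()].
#' @param pools Pool index sets from [make_bulks()].
#' @param mean_depth Expected reads per site per pool.
#' @param depth_mode `"poisson"` or `"fixed"`.
#' @param seed Optional integer seed.
#' @return A variant-site data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `p1_gt`, `p2_gt`, `p1_ref`, `p1_alt`, `p2_ref`, `p2_alt`,
#'   `e_ref`, `e_alt`, `l_ref`, `l_alt`.
#' @export
sample_depths <- function(pop, pools,
                          mean_depth = pop$config$mean_depth %||% 30,
                          depth_mode = pop$config$depth_mode %||% "poisson",
                          seed = NULL) {
  if (length(pools$e_pool) == 0L) stop("E-pool is empty", call. = FALSE)
  if (length(pools$l_pool) == 0L) stop("L-pool is empty", call. = FALSE)
  depth_mode <- match.arg(depth_mode, c("poisson", "fixed"))
  n_sites <- nrow(pop$genotypes)
  with_seed_if(seed, {
    freq_e <- rowMeans(pop$genotypes[, pools$e_pool, drop = FALSE]) / 2
    freq_l <- rowMeans(pop$genotypes[, pools$l_pool, drop = FALSE]) / 2
    draw_depth <- function() {
      if (depth_mode == "poisson") stats::rpois(n_sites, mean_depth)
      else rep.int(as.integer(round(mean_depth)), n_sites)
    }
    d_e <- draw_depth(); d_l <- draw_depth()
    d_p1 <- draw_depth(); d_p2 <- draw_depth()
    e_alt <- stats::rbinom(n_sites, d_e, freq_e)
    l_alt <- stats::rbinom(n_sites, d_l, freq_l)
    data.frame(
      chrom = pop$chrom,
      pos = pop$site_positions,
      ref = "A", alt = "G",
      p1_gt = "ref_hom", p2_gt = "alt_hom",
      p1_ref = d_p1, p1_alt = 0L,
      p2_ref = 0L, p2_alt = d_p2,
      e_ref = d_e - e_alt, e_alt = e_alt,
      l_ref = d_l - l_alt, l_alt = l_alt,
      stringsAsFactors = FALSE
    )
  })
}

# Nine-variety panel layout: three photoperiod-insensitive North China
# accessions (including the reference accession), three intermediate South
# China accessions, three photoperiod-sensitive XIS accessions.
.panel_groups <- function() {
  c(north_1 = "north", north_2 = "north", north_ref = "north",
    south_1 = "south", south_2 = "south", south_3 = "south",
    xis_1 = "xis", xis_2 = "xis", xis_3 = "xis")
}

#' Simulate a multi-variety genotype panel with planted pattern sites
#'
#' Generates a sites x varieties call matrix (codes `ref`, `alt`, `het`,
#' `missing`) over nine accessions in three photoperiod-sensitivity groups
#' (north, south, xis). Exactly `n_pattern_sites` sites carry the
#' XIS-specific pattern (all three XIS accessions share the same
#' non-reference allele while every north and south accession matches the
#' reference); the remaining sites violate it in randomised ways: all
#' accessions reference, discordant XIS calls, the alternate allele shared
#' with a south accession, a missing XIS call, or a heterozygous XIS call.
#'
#' @param n_sites Total sites.
#' @param n_pattern_sites Sites carrying the planted pattern.
#' @param seed Optional integer seed.
#' @return `list(calls =, groups =, pattern_sites =)`: the call matrix
#'   (rownames are site ids), the variety-to-group map, and the ids of the
#'   planted pattern sites.
#' @export
simulate_variety_panel <- function(n_sites, n_pattern_sites, seed = NULL) {
  if (n_pattern_sites > n_sites) {
    stop("'n_pattern_sites' cannot exceed 'n_sites'", call. = FALSE)
  }
  groups <- .panel_groups()
  varieties <- names(groups)
  xis <- varieties[groups == "xis"]
  south <- varieties[groups == "south"]
  with_seed_if(seed, {
    calls <- matrix("ref", nrow = n_sites, ncol = length(varieties),
                    dimnames = list(sprintf("site_%03d", seq_len(n_sites)),
                                    varieties))
    pattern_idx <- sort(sample.int(n_sites, n_pattern_sites))
    calls[pattern_idx, xis] <- "alt"
    violations <- c("all_ref", "xis_discordant", "south_shared",
                    "xis_missing", "xis_het")
    other_idx <- setdiff(seq_len(n_sites), pattern_idx)
    for (i in other_idx) {
      switch(sample(violations, 1L),
        all_ref = NULL,
        xis_discordant = {
          calls[i, xis] <- "alt"
          calls[i, sample(xis, 1L)] <- "ref"
        },
        south_shared = {
          calls[i, xis] <- "alt"
          calls[i, sample(south, 1L)] <- "alt"
        },
        xis_missing = {
          calls[i, xis] <- "alt"
          calls[i, sample(xis, 1L)] <- "missing"
        },
        xis_het = {
          calls[i, xis] <- "alt"
          calls[i, sample(xis, 1L)] <- "het"
        })
    }
    list(calls = calls, groups = groups,
         pattern_sites = rownames(calls)[pattern_idx])
  })
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1L, paste0, collapse = "")
}

# Random open reading frame: ATG start, no internal stop codon.
.random_cds_codons <- function(length_codons) {
  sense <- setdiff(.all_codons(), .STOP_CODONS)
  c("ATG", sample(sense, length_codons - 1L, replace = TRUE))
}

#' Simulate a coding sequence carrying planted variants
#'
#' Builds a random valid CDS (starts with ATG, length divisible by three, no
#' internal stop codon) whose reference bases at the planted positions equal
#' the stated reference alleles, so the planted variants can be fed straight
#' into [annotate_effect()].
#'
#' @param length_codons CDS length in codons (>= 2).
#' @param planted Data frame with columns `cds_pos` (1-based position in the
#'   CDS), `ref` and `alt` (single bases), or `NULL` for none.
#' @param constraints Optional data frame (`cds_pos`, `base`) pinning
#'   additional reference bases, e.g. to force a whole codon.
#' @param seed Optional integer seed.
#' @return `list(cds =, variants =)`: the CDS as a character string and the
#'   planted variant table.
#' @export
simulate_cds_with_variants <- function(length_codons, planted = NULL,
                                       constraints = NULL, seed = NULL) {
  assert_scalar_number(length_codons, "length_codons", min = 2)
  length_codons <- as.integer(length_codons)
  if (is.null(planted)) {
    planted <- data.frame(cds_pos = integer(), ref = character(),
                          alt = character(), stringsAsFactors = FALSE)
  }
  if (nrow(planted) > 0) {
    bases <- c("A", "C", "G", "T")
    stopifnot(all(c("cds_pos", "ref", "alt") %in% names(planted)))
    if (any(planted$cds_pos < 1 | planted$cds_pos > 3L * length_codons)) {
      stop("planted 'cds_pos' outside the CDS", call. = FALSE)
    }
    if (!all(planted$ref %in% bases) || !all(planted$alt %in% bases)) {
      stop("planted alleles must be single bases A/C/G/T", call. = FALSE)
    }
    if (any(planted$ref == planted$alt)) {
      stop("planted ref and alt alleles must differ", call. = FALSE)
    }
    if (anyDuplicated(planted$cds_pos)) {
      dup <- planted$cds_pos[duplicated(planted$cds_pos)][1]
      stop(sprintf("planted reference base conflicts with an already-constrained position (CDS position %d)",
                   dup), call. = FALSE)
    }
  }
  pinned <- data.frame(cds_pos = planted$cds_pos, base = planted$ref,
                       stringsAsFactors = FALSE)
  if (!is.null(constraints)) {
    stopifnot(all(c("cds_pos", "base") %in% names(constraints)))
    pinned <- rbind(pinned, constraints[, c("cds_pos", "base")])
    clash <- pinned$cds_pos[duplicated(pinned$cds_pos)]
    for (p in clash) {
      if (length(unique(pinned$base[pinned$cds_pos == p])) > 1L) {
        stop(sprintf("planted reference base conflicts with an already-constrained position (CDS position %d)",
                     p), call. = FALSE)
      }
    }
    pinned <- pinned[!duplicated(pinned$cds_pos), , drop = FALSE]
    if (any(pinned$cds_pos < 1 | pinned$cds_pos > 3L * length_codons)) {
      stop("constrained 'cds_pos' outside the CDS", call. = FALSE)
    }
  }
  with_seed_if(seed, {
    codons <- .random_cds_codons(length_codons)
    sense <- setdiff(.all_codons(), .STOP_CODONS)
    for (ci in unique((pinned$cds_pos - 1L) %/% 3L + 1L)) {
      in_codon <- pinned[(pinned$cds_pos - 1L) %/% 3L + 1L == ci, ]
      within <- (in_codon$cds_pos - 1L) %% 3L + 1L
      pool <- if (ci == 1L) "ATG" else sense
      ok <- pool
      for (k in seq_along(within)) {
        ok <- ok[substr(ok, within[k], within[k]) == in_codon$base[k]]
      }
      if (length(ok) == 0L) {
        stop(sprintf("planted reference base conflicts with an already-constrained position (codon %d)",
                     ci), call. = FALSE)
      }
      codons[ci] <- if (length(ok) == 1L) ok else sample(ok, 1L)
    }
    list(cds = paste0(codons, collapse = ""), variants = planted)
  })
}
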