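# Synthetic F2 generator: Mendelian structure, linkage, bulk selection,
# depth sampling, variety panel and CDS fixtures.

test_that("identical configurations reproduce bit-identical populations and depth tables", {
  cc <- cross_config(n_individuals = 60, n_sites = 40, seed = 42)
  pop1 <- simulate_f2(cc)
  pop2 <- simulate_f2(cc)
  expect_identical(pop1$genotypes, pop2$genotypes)
  expect_identical(pop1$phenotypes, pop2$phenotypes)
  b <- make_bulks(pop1, 10)
  expect_identical(sample_depths(pop1, b, seed = 7), sample_depths(pop2, b, seed = 7))
})

test_that("genotype frequencies are Mendelian 1:2:1", {
  cc <- cross_config(n_individuals = 10000, n_sites = 5, effect_days = 0,
                     seed = 101)
  pop <- simulate_f2(cc)
  n <- ncol(pop$genotypes)
  for (s in seq_len(nrow(pop$genotypes))) {
    freq <- tabulate(pop$genotypes[s, ] + 1L, 3L) / n
    se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
    expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se),
                info = paste("site", s))
  }
  # chi-square of 1:2:1 rejects at alpha = 0.01 in at most 2% of seeds
  rejects <- vapply(1:200, function(i) {
    p <- simulate_f2(cross_config(n_individuals = 1000, n_sites = 1,
                                  effect_days = 0, seed = 5000 + i))
    obs <- tabulate(p$genotypes[1, ] + 1L, 3L)
    suppressWarnings(
      stats::chisq.test(obs, p = c(0.25, 0.5, 0.25))$p.value) < 0.01
  }, logical(1))
  expect_lte(mean(rejects), 0.02)
})

test_that("a null locus is uncorrelated with the phenotype", {
  cors <- vapply(1:20, function(i) {
    pop <- simulate_f2(cross_config(n_individuals = 500, n_sites = 3,
                                    effect_days = 0, seed = 900 + i))
    stats::cor(pop$causal_dose, pop$phenotypes)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.02)
  expect_lt(max(abs(cors)), 0.2)
})

test_that("genotype correlation decays monotonically with map distance", {
  cc <- cross_config(n_individuals = 10000, n_sites = 400,
                     chrom_length_bp = 2e7, effect_days = 0, seed = 77)
  pop <- simulate_f2(cc)
  anchor <- pop$genotypes[1, ]
  d <- pop$site_positions - pop$site_positions[1]
  cors <- apply(pop$genotypes, 1, stats::cor, y = anchor)
  bins <- cut(d, breaks = seq(0, 2e7, by = 4e6), include.lowest = TRUE)
  mean_cor <- tapply(cors, bins, mean)
  expect_true(all(diff(mean_cor) < 0))
  # expectation is the Haldane decay (1 - 2c) = exp(-2 d_Morgans)
  expected <- exp(-2 * tapply(d, bins, mean) / cc$bp_per_cm / 100)
  expect_lt(max(abs(mean_cor - expected)), 0.05)
})

test_that("bulk allele frequencies match brute-force enumeration over all genotype assignments", {
  # n = 6, one site, noise 0: every one of 3^6 genotype assignments gives
  # a deterministic selection; simulator and oracle must agree exactly
  grid <- expand.grid(rep(list(0:2), 6))
  for (r in seq_len(nrow(grid))) {
    doses <- as.integer(grid[r, ])
    pheno <- 80 + 10 * c(0, 0.5, 1)[doses + 1L]  # additive, noise-free
    pop <- f2_population(matrix(doses, nrow = 1), pheno, 1000)
    b <- make_bulks(pop, 2, mode = "tails")
    o <- oracle_tail_bulks(pheno, 2)
    expect_identical(b, o)
    # bulk allele frequencies implied by the selected pools agree exactly
    expect_equal(mean(doses[b$e_pool]) / 2, mean(doses[o$e_pool]) / 2)
    expect_equal(mean(doses[b$l_pool]) / 2, mean(doses[o$l_pool]) / 2)
  }
})

test_that("tail and threshold bulk selection follow the stated rules", {
  pop <- f2_population(matrix(0L, 1, 10), phenotypes = 1:10,
                       site_positions = 1)
  b <- make_bulks(pop, 2, mode = "tails")
  expect_equal(b$e_pool, c(1L, 2L))
  expect_equal(b$l_pool, c(9L, 10L))

  pop2 <- f2_population(matrix(0L, 1, 5), c(35, 37, 39, 53, 60), 1)
  b2 <- make_bulks(pop2, 2, mode = "thresholds",
                   thresholds = list(e = c(36, 40), l_min = 52))
  expect_equal(b2$e_pool, c(2L, 3L))
  expect_equal(b2$l_pool, c(4L, 5L))
  expect_error(make_bulks(pop2, 3, mode = "thresholds",
                          thresholds = list(e = c(36, 40), l_min = 52)),
               "E-pool")
  expect_error(make_bulks(pop2, 3, mode = "thresholds",
                          thresholds = list(e = c(30, 40), l_min = 52)),
               "L-pool")

  # ties fall back to index order; pools stay disjoint
  pop3 <- f2_population(matrix(0L, 1, 8), rep(50, 8), 1)
  b3 <- make_bulks(pop3, 3, mode = "tails")
  expect_equal(b3$e_pool, 1:3)
  expect_equal(b3$l_pool, 6:8)
  expect_length(intersect(b3$e_pool, b3$l_pool), 0)
})

test_that("depth sampling reflects pool allele frequencies", {
  # pools fixed for one parental allele give all-or-nothing depths
  pop <- f2_population(matrix(c(rep(2L, 5), rep(0L, 5)), nrow = 1),
                       phenotypes = rep(1, 10), site_positions = 5)
  sr <- sample_depths(pop, list(e_pool = 1:5, l_pool = 6:10),
                      mean_depth = 20, depth_mode = "fixed", seed = 3)
  expect_equal(sr$e_alt, 20L)  # E-pool fixed for P2 allele here
  expect_equal(sr$e_ref, 0L)
  expect_equal(sr$l_alt, 0L)
  expect_equal(sr$l_ref, 20L)
  expect_error(sample_depths(pop, list(e_pool = integer(), l_pool = 1:2)),
               "E-pool")

  # heterozygous pool: mean alt fraction within 3 SE of 0.5
  n_sites <- 10000
  poph <- f2_population(matrix(1L, n_sites, 4), rep(1, 4), seq_len(n_sites))
  srh <- sample_depths(poph, list(e_pool = 1:2, l_pool = 3:4),
                       mean_depth = 30, depth_mode = "fixed", seed = 4)
  frac <- srh$e_alt / (srh$e_ref + srh$e_alt)
  se <- sqrt(0.25 / 30 / n_sites)
  expect_lt(abs(mean(frac) - 0.5), 3 * se)
})

test_that("variety panel plants exactly the requested pattern sites", {
  panel <- simulate_variety_panel(n_sites = 10, n_pattern_sites = 4, seed = 21)
  hit <- pattern_matches(panel$calls, panel$groups)
  expect_identical(sort(names(hit)[hit]), sort(panel$pattern_sites))
  expect_equal(sum(hit), 4)

  none <- simulate_variety_panel(10, 0, seed = 22)
  expect_equal(sum(pattern_matches(none$calls, none$groups)), 0)
  expect_error(simulate_variety_panel(5, 6), "exceed")

  # knocking one XIS call to missing removes the site under the fail policy
  p <- simulate_variety_panel(6, 3, seed = 23)
  target <- p$pattern_sites[1]
  xis_var <- names(p$groups)[p$groups == "xis"][1]
  p$calls[target, xis_var] <- "missing"
  expect_false(pattern_matches(p$calls, p$groups)[[target]])
})

test_that("simulated CDS fixtures are valid and carry the planted variants", {
  fx <- simulate_cds_with_variants(
    30, planted = data.frame(cds_pos = c(14, 27), ref = c("A", "T"),
                             alt = c("G", "C")), seed = 31)
  expect_equal(nchar(fx$cds) %% 3, 0)
  expect_equal(substr(fx$cds, 1, 3), "ATG")
  codons <- substring(fx$cds, seq(1, nchar(fx$cds) - 2, 3),
                      seq(3, nchar(fx$cds), 3))
  expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  expect_equal(substr(fx$cds, 14, 14), "A")
  expect_equal(substr(fx$cds, 27, 27), "T")

  expect_error(simulate_cds_with_variants(
    10, planted = data.frame(cds_pos = c(5, 5), ref = c("A", "C"),
                             alt = c("G", "G"))), "conflicts")
  expect_error(simulate_cds_with_variants(
    10, planted = data.frame(cds_pos = 1, ref = "C", alt = "G")), "conflicts")

  none <- simulate_cds_with_variants(10, seed = 32)
  expect_equal(nrow(none$variants), 0)
})
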