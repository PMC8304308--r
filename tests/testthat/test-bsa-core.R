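# SNP-index statistics, window scan, null band and QTL calling.

test_that("polarisation keeps opposite homozygotes and swaps inverted sites", {
  sites <- data.frame(
    chrom = "chr1", pos = c(10, 20, 30, 40, 50),
    ref = "A", alt = "G",
    p1_gt = c("ref_hom", "alt_hom", "het", "ref_hom", "missing"),
    p2_gt = c("alt_hom", "ref_hom", "alt_hom", "ref_hom", "alt_hom"),
    p1_ref = c(10L, 0L, 5L, 10L, 0L), p1_alt = c(0L, 10L, 5L, 0L, 0L),
    p2_ref = c(0L, 12L, 0L, 11L, 0L), p2_alt = c(12L, 0L, 12L, 0L, 9L),
    e_ref = c(3L, 4L, 5L, 6L, 7L), e_alt = c(13L, 14L, 15L, 16L, 17L),
    l_ref = c(23L, 24L, 25L, 26L, 27L), l_alt = c(33L, 34L, 35L, 36L, 37L),
    stringsAsFactors = FALSE)
  pol <- polarize_sites(sites)
  expect_equal(pol$sites$pos, c(10, 20))
  # straight site unchanged
  expect_equal(pol$sites$e_ref[1], 3L)
  expect_equal(pol$sites$e_alt[1], 13L)
  # inverted site: alleles and every ref/alt depth pair swapped
  expect_equal(pol$sites$ref[2], "G")
  expect_equal(pol$sites$alt[2], "A")
  expect_equal(pol$sites$e_ref[2], 14L)
  expect_equal(pol$sites$e_alt[2], 4L)
  expect_equal(pol$sites$l_ref[2], 34L)
  expect_equal(pol$sites$l_alt[2], 24L)
  expect_equal(pol$sites$p1_gt[2], "ref_hom")
  expect_equal(pol$sites$p2_gt[2], "alt_hom")
  expect_equal(pol$rejected$reason, c("het_parent", "concordant_parents",
                                      "missing_parent"))
})

test_that("SNP-index follows the boundary principles and depth cutoff", {
  expect_equal(snp_index(20, 0), 0)   # pool identical to the early parent
  expect_equal(snp_index(0, 20), 1)   # pool completely different
  expect_equal(snp_index(15, 5), 0.25)
  expect_true(is.na(snp_index(3, 3, min_depth = 7)))
  expect_equal(snp_index(3, 3, min_depth = 6), 0.5)
  expect_true(is.na(snp_index(0, 0, min_depth = 0)))
  expect_error(snp_index(-1, 5), "non-negative")
  # always in [0, 1] on random depths
  set.seed(1)
  r <- rpois(500, 10); a <- rpois(500, 10)
  ix <- snp_index(r, a, min_depth = 1)
  expect_true(all(ix >= 0 & ix <= 1, na.rm = TRUE))
})

test_that("delta is the L-pool minus E-pool index and is antisymmetric", {
  expect_equal(delta_snp_index(0, 1), 1)
  expect_equal(delta_snp_index(1, 0), -1)
  expect_equal(delta_snp_index(0.37, 0.37), 0)
  expect_true(is.na(delta_snp_index(NA, 0.5)))
  set.seed(2)
  e <- runif(100); l <- runif(100)
  expect_equal(delta_snp_index(e, l), -delta_snp_index(l, e))
  expect_true(all(abs(delta_snp_index(e, l)) <= 1))
})

test_that("swapping the pools negates every delta and flips interval signs", {
  cc <- cross_config(n_individuals = 100, bulk_size = 10, n_sites = 300,
                     chrom_length_bp = 5e6, causal_pos_bp = 2.5e6,
                     effect_days = 20, noise_sd = 2, seed = 11)
  pop <- simulate_f2(cc)
  b <- make_bulks(pop, 10)
  sr <- sample_depths(pop, b, seed = 12)
  swapped <- sr
  swapped[c("e_ref", "e_alt", "l_ref", "l_alt")] <-
    sr[c("l_ref", "l_alt", "e_ref", "e_alt")]
  ix <- index_sites(polarize_sites(sr)$sites)
  ix_sw <- index_sites(polarize_sites(swapped)$sites)
  expect_equal(ix_sw$delta, -ix$delta)

  pr <- window_scan(ix, window_bp = 1e6, step_bp = 1e5)
  pr <- add_null_band(pr, ix, bulk_size = 10, reps = 300, seed = 5)
  # negating the profile (the effect of a pool swap) flips interval signs
  # but leaves their extent unchanged
  pr_neg <- pr
  pr_neg$mean_delta <- -pr$mean_delta
  pr_neg$band_lo <- -pr$band_hi
  pr_neg$band_hi <- -pr$band_lo
  q <- call_qtls(pr, min_run = 3)
  q_neg <- call_qtls(pr_neg, min_run = 3)
  expect_gt(nrow(q), 0)
  expect_equal(q_neg$sign, -q$sign)
  expect_equal(q_neg$start_bp, q$start_bp)
  expect_equal(q_neg$end_bp, q$end_bp)
})

test_that("window means equal a naive per-window recomputation", {
  # constant field
  const <- make_sites(seq(1000, 90000, by = 1000), 10, 10, 10, 10)
  const$delta <- 0.5
  const$e_index <- 0.25; const$l_index <- 0.75
  pr <- window_scan(const, window_bp = 10000, step_bp = 2000, min_sites = 1)
  expect_true(all(pr$mean_delta[!is.na(pr$mean_delta)] == 0.5))

  # random field, one window
  set.seed(3)
  s1 <- make_sites(sort(sample.int(1e6, 50)), 10, 10, 10, 10)
  s1$delta <- runif(50, -1, 1)
  one <- window_scan(s1, window_bp = 1e6, step_bp = 1e6, min_sites = 1)[1, ]
  expect_equal(one$mean_delta, oracle_window_mean(s1, "chr1", 1, 1e6))

  # random field, sliding windows, some sites missing
  set.seed(4)
  s2 <- make_sites(sort(sample.int(5e5, 200)), 10, 10, 10, 10)
  s2$delta <- runif(200, -1, 1)
  s2$delta[sample.int(200, 30)] <- NA
  pr2 <- window_scan(s2, window_bp = 5e4, step_bp = 7000, min_sites = 3)
  for (i in seq_len(nrow(pr2))) {
    o <- oracle_window_mean(s2, "chr1", pr2$window_start[i], 5e4)
    n_o <- sum(!is.na(s2$delta) & s2$pos >= pr2$window_start[i] &
                 s2$pos < pr2$window_start[i] + 5e4)
    if (n_o < 3) expect_true(is.na(pr2$mean_delta[i]))
    else expect_equal(pr2$mean_delta[i], o)
  }
})

test_that("windows without sites are missing, not zero, and unsorted input errors", {
  s <- make_sites(c(1000, 2000, 901000, 902000, 903000), 10, 10, 10, 10)
  s$delta <- 0.8
  pr <- window_scan(s, window_bp = 1e5, step_bp = 1e5, min_sites = 3)
  mid <- pr[pr$window_start == 400001, ]
  expect_equal(mid$n_sites, 0L)
  expect_true(is.na(mid$mean_delta))
  bad <- s[c(2, 1, 3, 4, 5), ]
  bad$delta <- 0.1
  expect_error(window_scan(bad, 1e5, 1e5), "sorted")
  expect_error(window_scan(s, window_bp = 100, step_bp = 200), "step_bp")
})

test_that("per-site null band matches exact enumeration in the minimal case", {
  # bulk_size 1, depth 1: each pool's index is Bernoulli(E[f]) with
  # E[f] = 1/2, so delta is -1, 0, +1 with probability 1/4, 1/2, 1/4 and
  # the exact two-sided 95% band is [-1, 1]
  sb <- site_null_band(e_depth = 1, l_depth = 1, bulk_size = 1,
                       reps = 2000, level = 95, seed = 5)
  expect_equal(sb$lo, -1)
  expect_equal(sb$hi, 1)
  # zero-depth sites are uninformative
  sb0 <- site_null_band(0, 10, bulk_size = 17, reps = 200, seed = 6)
  expect_equal(c(sb0$lo, sb0$hi), c(-1, 1))
  expect_error(site_null_band(1, 1, 1, reps = 10), "at least 100")
})

test_that("the null band brackets zero and narrows with depth and bulk size", {
  widths <- vapply(list(c(10, 5), c(40, 5), c(40, 20), c(160, 20)),
                   function(p) {
    sb <- site_null_band(rep(p[1], 50), rep(p[1], 50), bulk_size = p[2],
                         reps = 1000, seed = 8)
    expect_true(all(sb$lo <= 0 & sb$hi >= 0))
    mean(sb$hi - sb$lo)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # binomial + bulk variance formula:
  # Var(index) = Var(f) + E[f(1-f)]/d with Var(f) = 1/(8b), E[f] = 1/2
  v <- function(d, b) 2 * (1 / (8 * b) + (0.25 - 1 / (8 * b)) / d)
  expected <- vapply(list(c(10, 5), c(40, 5), c(40, 20), c(160, 20)),
                     function(p) 2 * stats::qnorm(0.975) * sqrt(v(p[1], p[2])),
                     numeric(1))
  expect_lt(max(abs(widths - expected) / expected), 0.15)
})

test_that("QTL calling reports maximal exceedance runs and merges across missing gaps", {
  prof <- data.frame(chrom = "chr1",
                     window_start = seq(1, by = 1000, length.out = 2000),
                     window_end = seq(1, by = 1000, length.out = 2000) + 1e5,
                     n_sites = 5L, mean_delta = 0.9,
                     band_lo = -0.3, band_hi = 0.3,
                     stringsAsFactors = FALSE)
  inside <- prof
  inside$mean_delta <- 0.1
  expect_equal(nrow(call_qtls(inside, min_run = 10)), 0)

  q <- call_qtls(prof, min_run = 10)
  expect_equal(nrow(q), 1)
  expect_equal(q$start_bp, 1)
  expect_equal(q$end_bp, prof$window_end[2000] - 1)
  expect_equal(q$sign, 1L)
  expect_equal(q$n_windows, 2000L)

  # a short missing gap merges; an in-band gap does not
  gap <- prof
  gap$mean_delta[1000:1004] <- NA
  expect_equal(nrow(call_qtls(gap, min_run = 10)), 1)
  split <- prof
  split$mean_delta[1000:1004] <- 0
  expect_equal(nrow(call_qtls(split, min_run = 10)), 2)

  # runs shorter than min_run are suppressed
  short <- inside
  short$mean_delta[5:9] <- 0.9
  expect_equal(nrow(call_qtls(short, min_run = 10)), 0)
  expect_equal(nrow(call_qtls(short, min_run = 5)), 1)

  # negative deltas give negative signs
  neg <- prof
  neg$mean_delta <- -0.9
  expect_equal(call_qtls(neg, min_run = 10)$sign, -1L)
  expect_error(call_qtls(data.frame(chrom = "x", window_start = 1,
                                    window_end = 2, n_sites = 0L,
                                    mean_delta = NA, band_lo = NA,
                                    band_hi = NA)), "band")
})

test_that("stronger causal effects never weaken the peak signal", {
  peak <- function(effect) {
    mean(vapply(1:5, function(i) {
      cc <- cross_config(n_individuals = 100, bulk_size = 10, n_sites = 200,
                         chrom_length_bp = 5e6, causal_pos_bp = 2.5e6,
                         effect_days = effect, noise_sd = 5, seed = 40 + i)
      pop <- simulate_f2(cc)
      sr <- sample_depths(pop, make_bulks(pop, 10), seed = 60 + i)
      ix <- index_sites(polarize_sites(sr)$sites)
      pr <- window_scan(ix, window_bp = 1e6, step_bp = 2e5)
      max(abs(pr$mean_delta), na.rm = TRUE)
    }, numeric(1)))
  }
  peaks <- vapply(c(0, 5, 20), peak, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
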