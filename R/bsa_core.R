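# QTL-seq core: SNP-index, delta(SNP-index), sliding-window averaging,
# simulation null band and QTL interval calling.
#
# Orientation convention used throughout: after polarisation the "alt"
# allele is the P2 (late, sensitive-parent) allele, so a pool identical to
# the P1 (early) parent has SNP-index 0 and a pool fixed for the P2 allele
# has SNP-index 1. delta(SNP-index) = SNP-index(L-pool) - SNP-index(E-pool),
# so a locus where late-flowering plants are enriched for the P2 allele
# shows positive delta.

.site_required_cols <- c("chrom", "pos", "ref", "alt", "p1_gt", "p2_gt",
                         "e_ref", "e_alt", "l_ref", "l_alt")

.check_site_table <- function(sites) {
  missing <- setdiff(.site_required_cols, names(sites))
  if (length(missing)) {
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  depth_cols <- intersect(
    c("e_ref", "e_alt", "l_ref", "l_alt", "p1_ref", "p1_alt", "p2_ref", "p2_alt"),
    names(sites))
  for (col in depth_cols) {
    if (any(sites[[col]] < 0, na.rm = TRUE)) {
      stop("allele depths must be non-negative (column ", col, ")", call. = FALSE)
    }
  }
  invisible(sites)
}

#' Polarise variant sites against the parental genotypes
#'
#' Keeps only sites where the two parents are opposite homozygotes — the
#' informative configuration for an F2 bulk comparison — and relabels
#' alleles so that `alt` is always the P2 (sensitive-parent) allele. Sites
#' where P1 is homozygous for the alternate allele are kept with ref/alt and
#' all ref/alt depth columns swapped. Other sites are rejected with a reason
#' code rather than an error: `het_parent`, `missing_parent` or
#' `concordant_parents`.
#'
#' @param sites Variant-site data frame (see [sample_depths()] for columns).
#' @return `list(sites =, rejected =)`: polarised sites, and rejected rows
#'   with an extra `reason` column.
#' @export
polarize_sites <- function(sites) {
  .check_site_table(sites)
  p1 <- sites$p1_gt
  p2 <- sites$p2_gt
  reason <- rep(NA_character_, nrow(sites))
  reason[p1 == "missing" | p2 == "missing"] <- "missing_parent"
  reason[is.na(reason) & (p1 == "het" | p2 == "het")] <- "het_parent"
  opposite <- is.na(reason) &
    ((p1 == "ref_hom" & p2 == "alt_hom") | (p1 == "alt_hom" & p2 == "ref_hom"))
  reason[is.na(reason) & !opposite] <- "concordant_parents"

  kept <- sites[opposite, , drop = FALSE]
  swap <- kept$p1_gt == "alt_hom"
  if (any(swap)) {
    swap_cols <- function(df, a, b) {
      tmp <- df[[a]][swap]
      df[[a]][swap] <- df[[b]][swap]
      df[[b]][swap] <- tmp
      df
    }
    kept <- swap_cols(kept, "ref", "alt")
    kept <- swap_cols(kept, "e_ref", "e_alt")
    kept <- swap_cols(kept, "l_ref", "l_alt")
    if (all(c("p1_ref", "p1_alt", "p2_ref", "p2_alt") %in% names(kept))) {
      kept <- swap_cols(kept, "p1_ref", "p1_alt")
      kept <- swap_cols(kept, "p2_ref", "p2_alt")
    }
    kept$p1_gt[swap] <- "ref_hom"
    kept$p2_gt[swap] <- "alt_hom"
  }
  rejected <- sites[!opposite, , drop = FALSE]
  rejected$reason <- reason[!opposite]
  list(sites = kept, rejected = rejected)
}

#' Per-pool SNP-index
#'
#' The fraction of a pool's reads carrying the allele that differs from the
#' P1 (early) parent: `alt / (ref + alt)`. A pool whose reads all match P1
#' scores 0; a pool completely different from P1 scores 1. Sites with total
#' depth below `min_depth` return `NA` (insufficient evidence).
#'
#' @param ref_depth,alt_depth Non-negative read counts (vectorised).
#' @param min_depth Minimum total depth for a defined index.
#' @return Numeric vector in `[0, 1]`, `NA` where depth is insufficient.
#' @examples
#' snp_index(20, 0)  # identical to the early parent -> 0
#' snp_index(0, 20)  # completely different -> 1
#' @export
snp_index <- function(ref_depth, alt_depth, min_depth = 7) {
  if (any(ref_depth < 0, na.rm = TRUE) || any(alt_depth < 0, na.rm = TRUE)) {
    stop("allele depths must be non-negative", call. = FALSE)
  }
  total <- ref_depth + alt_depth
  out <- ifelse(total >= pmax(min_depth, 1), alt_depth / total, NA_real_)
  as.numeric(out)
}

#' delta(SNP-index) of the two bulks
#'
#' `l_index - e_index`; `NA` whenever either pool index is missing.
#'
#' @param e_index,l_index SNP-index of the early and late pool (vectorised).
#' @return Numeric vector in `[-1, 1]`.
#' @export
delta_snp_index <- function(e_index, l_index) {
  l_index - e_index
}

#' Add per-pool SNP-index and delta columns to a polarised site table
#'
#' @param sites Polarised variant-site data frame.
#' @param min_depth Minimum per-pool depth for a defined index (default 7,
#'   common practice for pooled QTL-seq data).
#' @return The input with `e_index`, `l_index` and `delta` columns appended.
#' @export
index_sites <- function(sites, min_depth = 7) {
  .check_site_table(sites)
  sites$e_index <- snp_index(sites$e_ref, sites$e_alt, min_depth)
  sites$l_index <- snp_index(sites$l_ref, sites$l_alt, min_depth)
  sites$delta <- delta_snp_index(sites$e_index, sites$l_index)
  sites
}

.window_starts <- function(max_pos, window_bp, step_bp, chrom_length = NULL) {
  end <- chrom_length %||% max_pos
  seq.int(1L, max(1, end), by = step_bp)
}

#' Sliding-window average of delta(SNP-index)
#'
#' Averages per-site delta over windows `[start, start + window_bp)` that
#' advance by `step_bp` along each chromosome (defaults: 1 Mb windows, 1 kb
#' step). Windows holding fewer than `min_sites` sites with a defined delta
#' are reported with `mean_delta = NA` — missing, not zero — to avoid
#' single-SNP spikes.
#'
#' @param sites Indexed site table from [index_sites()], sorted by
#'   `(chrom, pos)`.
#' @param window_bp Window size in bp.
#' @param step_bp Step between window starts in bp; must not exceed
#'   `window_bp`.
#' @param min_sites Minimum informative sites per window.
#' @param chrom_lengths Optional named vector of chromosome lengths; windows
#'   are generated up to the chromosome end rather than the last site.
#' @return A window profile data frame: `chrom`, `window_start`,
#'   `window_end` (half-open), `n_sites`, `mean_delta`, plus empty
#'   `band_lo`/`band_hi` columns filled by [add_null_band()].
#' @export
window_scan <- function(sites, window_bp = 1e6, step_bp = 1e3, min_sites = 3,
                        chrom_lengths = NULL) {
  if (step_bp > window_bp) stop("'step_bp' must not exceed 'window_bp'", call. = FALSE)
  if (!"delta" %in% names(sites)) {
    stop("run index_sites() first ('delta' column required)", call. = FALSE)
  }
  pieces <- lapply(split(sites, sites$chrom), function(cs) {
    if (is.unsorted(cs$pos)) {
      stop("sites must be sorted by position within chromosome ", cs$chrom[1],
           call. = FALSE)
    }
    ok <- !is.na(cs$delta)
    pos_m <- cs$pos[ok]
    cum <- c(0, cumsum(cs$delta[ok]))
    starts <- .window_starts(max(cs$pos), window_bp, step_bp,
                             chrom_lengths[[cs$chrom[1]]])
    lo <- findInterval(starts - 1, pos_m)
    hi <- findInterval(starts + window_bp - 1, pos_m)
    n <- hi - lo
    mean_delta <- ifelse(n >= min_sites, (cum[hi + 1] - cum[lo + 1]) / n, NA_real_)
    data.frame(chrom = cs$chrom[1],
               window_start = starts,
               window_end = starts + window_bp,
               n_sites = n,
               mean_delta = mean_delta,
               band_lo = NA_real_,
               band_hi = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# Pool allele frequencies under the no-QTL null: the mean P2-allele dose of
# `bulk_size` independent F2 genotypes (0, 1, 2 with probability 1/4, 1/2,
# 1/4) divided by two. Returns `n` draws.
.null_pool_freq <- function(n, bulk_size) {
  hom2 <- stats::rbinom(n, bulk_size, 0.25)
  het <- stats::rbinom(n, bulk_size - hom2, 2 / 3)
  (hom2 + 0.5 * het) / bulk_size
}

#' Per-site null band for delta(SNP-index)
#'
#' Simulates the no-QTL null at each observed depth pair: each pool's allele
#' frequency is the mean of `bulk_size` independent F2 genotype doses, and
#' the alternate depth is Binomial(depth, frequency). The two-sided
#' `level`% quantiles of the simulated delta give the per-site band. Sites
#' with zero depth in a pool get the uninformative band `(-1, 1)`.
#'
#' @param e_depth,l_depth Total observed depth per pool (vectorised).
#' @param bulk_size Individuals per bulk.
#' @param reps Null replicates per site (>= 100).
#' @param level Two-sided confidence level in percent.
#' @param seed Optional integer seed.
#' @return Data frame with columns `lo`, `hi`.
#' @export
site_null_band <- function(e_depth, l_depth, bulk_size, reps = 1000,
                           level = 95, seed = NULL) {
  if (reps < 100) stop("'reps' must be at least 100", call. = FALSE)
  if (level <= 0 || level >= 100) stop("'level' must be in (0, 100)", call. = FALSE)
  n <- length(e_depth)
  stopifnot(length(l_depth) == n)
  probs <- c((1 - level / 100) / 2, 1 - (1 - level / 100) / 2)
  with_seed_if(seed, {
    lo <- hi <- numeric(n)
    chunk <- max(1L, floor(2e6 / reps))
    for (from in seq(1L, n, by = chunk)) {
      idx <- from:min(n, from + chunk - 1L)
      m <- length(idx) * reps
      fe <- .null_pool_freq(m, bulk_size)
      fl <- .null_pool_freq(m, bulk_size)
      de <- rep(e_depth[idx], times = reps)
      dl <- rep(l_depth[idx], times = reps)
      ie <- stats::rbinom(m, de, fe) / de  # depth 0 -> NaN
      il <- stats::rbinom(m, dl, fl) / dl
      dmat <- matrix(il - ie, nrow = length(idx))
      qs <- apply(dmat, 1L, stats::quantile, probs = probs,
                  na.rm = TRUE, names = FALSE)
      lo[idx] <- qs[1L, ]
      hi[idx] <- qs[2L, ]
      zero <- e_depth[idx] == 0 | l_depth[idx] == 0
      lo[idx][zero] <- -1
      hi[idx][zero] <- 1
    }
    data.frame(lo = lo, hi = hi)
  })
}

#' Attach a null confidence band to a window profile
#'
#' The band is the two-sided `level`% quantile of the window statistic
#' simulated under the no-QTL null, and three constructions are available:
#'
#' * `method = "linkage"` (default) is a parametric bootstrap of the whole
#'   observed process: per replicate, each pool's allele frequency is the
#'   mean over its `2 * bulk_size` gametes, simulated jointly along the
#'   chromosome as a Markov chain on the pooled P2-gamete count whose
#'   transition between adjacent sites is the Haldane recombination
#'   fraction for their distance (scale `bp_per_cm`); alternate depths are
#'   then Binomial(observed depth, frequency) per member site. This
#'   reproduces both the bulk-sampling and the read-sampling variance of
#'   the window mean, so the per-window false-positive rate sits at the
#'   nominal `100 - level` percent.
#' * `method = "window"` shares one frequency draw per pool across the
#'   window (perfect within-window linkage). Slightly conservative, and
#'   needs no genetic-map scale.
#' * `method = "site"` is the common per-site construction — per-site bands
#'   averaged over window members. Markedly conservative at the window
#'   level because read-sampling noise averages out across member sites
#'   while the band does not shrink.
#'
#' @param profile Window profile from [window_scan()].
#' @param sites The indexed site table the profile was computed from.
#' @param bulk_size Individuals per bulk.
#' @param reps Null replicates (>= 100; default 1000).
#' @param level Two-sided confidence level in percent (default 95).
#' @param method `"linkage"`, `"window"` or `"site"` (see Details).
#' @param bp_per_cm Physical-to-genetic map scale for `method = "linkage"`.
#' @param seed Optional integer seed.
#' @return The profile with `band_lo` and `band_hi` filled in (windows with
#'   no informative sites keep `NA` bands).
#' @export
add_null_band <- function(profile, sites, bulk_size, reps = 1000, level = 95,
                          method = c("linkage", "window", "site"),
                          bp_per_cm = 250000, seed = NULL) {
  method <- match.arg(method)
  if (reps < 100) stop("'reps' must be at least 100", call. = FALSE)
  if (level <= 0 || level >= 100) stop("'level' must be in (0, 100)", call. = FALSE)
  probs <- c((1 - level / 100) / 2, 1 - (1 - level / 100) / 2)
  seeds <- derive_seeds(seed, length(unique(profile$chrom)))
  chroms <- unique(profile$chrom)
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    pidx <- which(profile$chrom == ch)
    cs <- sites[sites$chrom == ch & !is.na(sites$delta), , drop = FALSE]
    if (nrow(cs) == 0L) next
    starts <- profile$window_start[pidx]
    window_bp <- profile$window_end[pidx][1] - starts[1]
    lo_i <- findInterval(starts - 1, cs$pos)
    hi_i <- findInterval(starts + window_bp - 1, cs$pos)
    n_in <- hi_i - lo_i
    d_e <- cs$e_ref + cs$e_alt
    d_l <- cs$l_ref + cs$l_alt
    band <- with_seed_if(seeds[k], {
      if (method == "site") {
        sb <- site_null_band(d_e, d_l, bulk_size, reps, level)
        cum_lo <- c(0, cumsum(sb$lo))
        cum_hi <- c(0, cumsum(sb$hi))
        cbind((cum_lo[hi_i + 1] - cum_lo[lo_i + 1]) / n_in,
              (cum_hi[hi_i + 1] - cum_hi[lo_i + 1]) / n_in)
      } else {
        n_s <- nrow(cs)
        m <- n_s * reps
        if (method == "window") {
          fe <- rep(.null_pool_freq(reps, bulk_size), each = n_s)
          fl <- rep(.null_pool_freq(reps, bulk_size), each = n_s)
        } else {
          # Markov chain on the pooled P2-gamete count along the chromosome:
          # each of the 2 * bulk_size gametes switches parental origin
          # between adjacent sites with the Haldane recombination fraction.
          g <- 2L * bulk_size
          cfrac <- (1 - exp(-2 * diff(cs$pos) / bp_per_cm / 100)) / 2
          chain <- function() {
            f <- matrix(0, nrow = n_s, ncol = reps)
            k <- stats::rbinom(reps, g, 0.5)
            f[1L, ] <- k / g
            for (j in seq_len(n_s - 1L)) {
              k <- k - stats::rbinom(reps, k, cfrac[j]) +
                stats::rbinom(reps, g - k, cfrac[j])
              f[j + 1L, ] <- k / g
            }
            as.vector(f)
          }
          fe <- chain()
          fl <- chain()
        }
        ie <- stats::rbinom(m, rep(d_e, times = reps), fe) / rep(d_e, times = reps)
        il <- stats::rbinom(m, rep(d_l, times = reps), fl) / rep(d_l, times = reps)
        dmat <- matrix(il - ie, nrow = n_s)
        dmat[is.na(dmat)] <- 0  # zero-depth members contribute no signal
        cum <- rbind(0, apply(dmat, 2L, cumsum))
        wmat <- (cum[hi_i + 1, , drop = FALSE] - cum[lo_i + 1, , drop = FALSE]) /
          n_in
        qs <- apply(wmat, 1L, stats::quantile, probs = probs,
                    na.rm = TRUE, names = FALSE)
        t(qs)
      }
    })
    has <- n_in > 0
    profile$band_lo[pidx[has]] <- band[has, 1L]
    profile$band_hi[pidx[has]] <- band[has, 2L]
  }
  profile
}

#' Call QTL intervals from a banded window profile
#'
#' Reports maximal runs of at least `min_run` consecutive windows whose mean
#' delta lies outside the null band. Runs of the same sign separated only by
#' missing windows (gaps shorter than `min_run`) are merged. Reported
#' coordinates are 1-based inclusive: from the first window start to the
#' last window end minus one.
#'
#' @param profile Banded window profile from [add_null_band()].
#' @param min_run Minimum consecutive exceeding windows (default 10; with a
#'   1 kb step this demands 10 kb of support and suppresses isolated
#'   exceedances).
#' @return Data frame of intervals: `chrom`, `start_bp`, `end_bp`, `sign`
#'   (`+1` means the late pool is enriched for the P2 allele), `n_windows`,
#'   `peak_delta`.
#' @export
call_qtls <- function(profile, min_run = 10) {
  if (all(is.na(profile$band_lo))) {
    stop("profile has no null band; run add_null_band() first", call. = FALSE)
  }
  out <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    p <- p[order(p$window_start), , drop = FALSE]
    state <- rep(NA_integer_, nrow(p))  # NA missing, 0 inside, +/-1 outside
    defined <- !is.na(p$mean_delta) & !is.na(p$band_lo)
    state[defined] <- 0L
    state[defined & p$mean_delta > p$band_hi] <- 1L
    state[defined & p$mean_delta < p$band_lo] <- -1L

    # collapse to runs, then merge same-sign runs split by short missing gaps
    r <- rle(ifelse(is.na(state), -9L, state))
    ends <- cumsum(r$lengths)
    starts_i <- ends - r$lengths + 1L
    runs <- data.frame(value = r$values, start = starts_i, end = ends,
                       len = r$lengths)
    sig <- runs[runs$value %in% c(-1L, 1L), , drop = FALSE]
    if (nrow(sig) == 0L) next
    merged <- sig[1, , drop = FALSE]
    if (nrow(sig) > 1L) {
      for (i in 2:nrow(sig)) {
        prev <- merged[nrow(merged), ]
        gap_idx <- if (sig$start[i] - prev$end <= 1L) integer(0)
                   else seq.int(prev$end + 1L, sig$start[i] - 1L)
        gap_all_missing <- length(gap_idx) == 0L || all(is.na(state[gap_idx]))
        if (sig$value[i] == prev$value && gap_all_missing &&
            length(gap_idx) < min_run) {
          merged$end[nrow(merged)] <- sig$end[i]
          merged$len[nrow(merged)] <- prev$len + sig$len[i]
        } else {
          merged <- rbind(merged, sig[i, ])
        }
      }
    }
    merged <- merged[merged$len >= min_run, , drop = FALSE]
    if (nrow(merged) == 0L) next
    for (i in seq_len(nrow(merged))) {
      idx <- seq.int(merged$start[i], merged$end[i])
      idx_sig <- idx[!is.na(state[idx]) & state[idx] != 0L]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start_bp = p$window_start[merged$start[i]],
        end_bp = p$window_end[merged$end[i]] - 1,
        sign = merged$value[i],
        n_windows = merged$len[i],
        peak_delta = p$mean_delta[idx_sig][which.max(abs(p$mean_delta[idx_sig]))],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), sign = integer(),
                      n_windows = integer(), peak_delta = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert called QTLs to Mb intervals
#'
#' @param qtls Data frame from [call_qtls()].
#' @param labels Optional interval labels (default `qtl_1`, `qtl_2`, ...).
#' @return An interval data frame compatible with [intersect_intervals()].
#' @export
qtls_to_intervals <- function(qtls, labels = NULL) {
  if (nrow(qtls) == 0L) {
    return(data.frame(chrom = character(), start_mb = numeric(),
                      end_mb = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(chrom = qtls$chrom,
             start_mb = qtls$start_bp / 1e6,
             end_mb = qtls$end_bp / 1e6,
             label = labels %||% sprintf("qtl_%d", seq_len(nrow(qtls))),
             stringsAsFactors = FALSE)
}
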