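#' SNP-index: donor-allele read fraction
#'
#' The SNP-index of a pool or sample at a site is the fraction of reads
#' carrying the donor (alternate) allele. Sites with zero total depth are
#' undefined (`NA`), never 0.
#'
#' @param ref_depth,donor_depth non-negative integer read depths
#'   (vectorised).
#' @return numeric vector in `[0, 1]`; `NA` where `ref_depth + donor_depth`
#'   is 0. Multiply by 100 for the percent form used in reports.
#' @examples
#' snp_index(3, 17) # 0.85
#' @export
snp_index <- function(ref_depth, donor_depth) {
  if (any(ref_depth < 0 | donor_depth < 0, na.rm = TRUE)) {
    data_abort("read depths must be non-negative")
  }
  total <- ref_depth + donor_depth
  ifelse(total == 0, NA_real_, donor_depth / total)
}

#' Absolute delta-SNP-index between pools
#'
#' The scan statistic of the bulked-segregant analysis: the absolute
#' difference between the susceptible-pool and resistant-pool SNP-indexes.
#' Symmetric and bounded in `[0, 1]` (or `[0, 100]` in percent form).
#'
#' @param si_s,si_r SNP-index of the susceptible and resistant pool
#'   (vectorised; both on the same scale).
#' @return `|si_s - si_r|`; `NA` propagates.
#' @examples
#' delta_snp_index(0.85, 0.10) # 0.75
#' @export
delta_snp_index <- function(si_s, si_r) {
  abs(si_s - si_r)
}

#' Per-site SNP-index table for a pair of pools
#'
#' Aggregates allele depths over the member samples of each pool (a
#' single-sample pool passes through unchanged), computes both pool
#' SNP-indexes and their absolute difference.
#'
#' @param sites long site x sample tibble (see [read_variants()]).
#' @param pools data frame with columns `sample`, `pool` where `pool` is
#'   `"resistant"` or `"susceptible"`.
#' @return a tibble per site: depths and SNP-index per pool, `delta_snp`,
#'   and `min_depth` (the smaller of the two pool total depths, used for
#'   null-threshold stratification). Sites where either pool has zero depth
#'   carry `NA` indexes.
#' @export
snp_index_table <- function(sites, pools) {
  stopifnot(is.data.frame(sites), is.data.frame(pools))
  if (!all(c("sample", "pool") %in% names(pools))) {
    data_abort("`pools` needs columns sample, pool")
  }
  bad <- setdiff(unique(pools$pool), c("resistant", "susceptible"))
  if (length(bad)) data_abort("unknown pool label(s): %s", paste(bad, collapse = ", "))
  x <- sites %>%
    dplyr::inner_join(pools, by = "sample") %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$pool) %>%
    dplyr::summarise(
      ref_depth = sum(.data$ref_depth),
      donor_depth = sum(.data$donor_depth),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(names_from = "pool",
                       values_from = c("ref_depth", "donor_depth"),
                       values_fill = 0L)
  for (col in c("ref_depth_resistant", "donor_depth_resistant",
                "ref_depth_susceptible", "donor_depth_susceptible")) {
    if (!col %in% names(x)) x[[col]] <- 0L
  }
  x %>%
    dplyr::mutate(
      depth_resistant = .data$ref_depth_resistant + .data$donor_depth_resistant,
      depth_susceptible = .data$ref_depth_susceptible + .data$donor_depth_susceptible,
      si_resistant = snp_index(.data$ref_depth_resistant, .data$donor_depth_resistant),
      si_susceptible = snp_index(.data$ref_depth_susceptible, .data$donor_depth_susceptible),
      delta_snp = delta_snp_index(.data$si_susceptible, .data$si_resistant),
      min_depth = pmin(.data$depth_resistant, .data$depth_susceptible)
    ) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Average delta-SNP-index over sliding genomic windows
#'
#' Windows of `window_size` bp advance by `step` bp from position 1 along
#' each chromosome; SNP membership is by half-open interval
#' `[start, start + window_size)`. The window statistic is the unweighted
#' mean of the member sites' `delta_snp`. Windows with fewer than
#' `min_snps` sites are reported but flagged `masked` and excluded from QTL
#' calling. Chromosomes shorter than the window yield a single truncated
#' window.
#'
#' @param snp_table per-site tibble from [snp_index_table()]; rows with `NA`
#'   `delta_snp` are ignored.
#' @param chrom_lengths named numeric vector (or two-column data frame
#'   `chrom`, `length`) of chromosome lengths in bp.
#' @param window_size,step window span and increment in bp (defaults 2 Mb
#'   and 10 kb).
#' @param min_snps minimum informative sites per window (default 3).
#' @return a tibble of class `hopper_windows`: `chrom`, `start`, `end`,
#'   `n_snps`, `mean_delta`, `mean_depth`, `masked`.
#' @export
sliding_windows <- function(snp_table, chrom_lengths, window_size = 2e6,
                            step = 1e4, min_snps = 3) {
  if (window_size <= 0) config_abort("window_size", "must be positive")
  if (step <= 0) config_abort("step", "must be positive")
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- stats::setNames(chrom_lengths$length, chrom_lengths$chrom)
  }
  snp_table <- dplyr::filter(snp_table, !is.na(.data$delta_snp))
  out <- purrr::map_dfr(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- if (len >= window_size) seq(1, len - window_size + 1, by = step) else 1
    ends <- pmin(starts + window_size - 1, len)
    d <- snp_table[snp_table$chrom == ch, ]
    d <- d[order(d$pos), ]
    pos <- d$pos
    cum_delta <- cumsum(c(0, d$delta_snp))
    cum_depth <- cumsum(c(0, d$min_depth))
    i1 <- findInterval(starts - 0.5, pos) + 1L   # first site with pos >= start
    i2 <- findInterval(ends + 0.5, pos)          # last site with pos <= end
    n <- pmax(i2 - i1 + 1L, 0L)
    mean_delta <- ifelse(n > 0, (cum_delta[i2 + 1L] - cum_delta[i1]) / n, NA_real_)
    mean_depth <- ifelse(n > 0, (cum_depth[i2 + 1L] - cum_depth[i1]) / n, NA_real_)
    tibble::tibble(chrom = ch, start = starts, end = ends, n_snps = n,
                   mean_delta = mean_delta, mean_depth = mean_depth,
                   masked = n < min_snps)
  })
  class(out) <- c("hopper_windows", class(out))
  out
}

#' Monte-Carlo null thresholds for the delta-SNP-index
#'
#' Simulates the scan statistic under the null hypothesis of no QTL: for
#' each depth stratum, pool allele frequencies are obtained by resampling
#' individual genotypes from the population's expected genotype frequencies
#' (inbred lines by default: homozygous donor with probability
#' `donor_freq`), reads are then drawn binomially at the stratum depth, and
#' the upper quantiles of `|delta SNP-index|` are recorded. Thresholds are
#' forced non-increasing in depth by isotonic regression, since the binomial
#' sampling variance shrinks with coverage.
#'
#' @param n_resistant,n_susceptible number of lines in each pool.
#' @param depths numeric vector of depth strata (default 5x bins up to
#'   100x).
#' @param donor_freq expected donor-allele frequency under the null
#'   (default 0.5; set to the empirical genome-wide frequency for a
#'   selection-skewed population).
#' @param inbred if `TRUE`, lines are homozygous (dosage 0 or 2); if
#'   `FALSE`, Hardy-Weinberg diploid dosages.
#' @param n_sims null replicates per stratum (default 10000; fewer than 100
#'   triggers a warning).
#' @param quantiles upper-tail probabilities, strictly inside (0, 1).
#' @param snps_per_window number of sites over which the scan statistic is
#'   averaged. With the default 1 the thresholds describe the per-SNP
#'   |delta SNP-index|. For window-level thresholds pass the typical number
#'   of sites per window: each null replicate then draws one pool
#'   composition (sites in a 2-Mb window of an inbred-line population are
#'   tightly linked, so the composition is shared) but independent
#'   sequencing noise per site, and records the mean per-site
#'   |delta SNP-index| -- the statistic [sliding_windows()] computes.
#' @param seed optional RNG seed.
#' @return a tibble with one row per depth stratum: `depth`, `q95`, `q99`
#'   (columns named after `quantiles`).
#' @export
null_thresholds <- function(n_resistant, n_susceptible,
                            depths = seq(5, 100, by = 5), donor_freq = 0.5,
                            inbred = TRUE, n_sims = 10000,
                            quantiles = c(0.95, 0.99),
                            snps_per_window = 1, seed = NULL) {
  if (n_resistant < 1 || n_susceptible < 1) {
    config_abort("pool_sizes", "both pools need at least one line")
  }
  if (any(quantiles <= 0 | quantiles >= 1)) {
    config_abort("quantiles", "must lie strictly inside (0, 1)")
  }
  if (n_sims < 100) warn("n_sims < 100 gives unstable quantile estimates")
  if (snps_per_window < 1) config_abort("snps_per_window", "must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  qnames <- paste0("q", round(quantiles * 100))
  res <- purrr::map_dfr(depths, function(d) {
    delta <- simulate_null_delta(n_sims, d, n_resistant, n_susceptible,
                                 donor_freq, inbred, snps_per_window)
    q <- stats::quantile(delta, probs = quantiles, names = FALSE, type = 8)
    tibble::tibble(depth = d, !!!stats::setNames(as.list(q), qnames))
  })
  # isotonic smoothing: thresholds must not increase with depth
  for (nm in qnames) {
    res[[nm]] <- -stats::isoreg(res$depth, -res[[nm]])$yf
  }
  res
}

# draw n null scan-statistic values at fixed per-pool depth d: per-SNP
# |delta SNP-index| (m = 1), or the mean over m linked sites sharing one
# pool composition (the window statistic)
simulate_null_delta <- function(n, d, n_r, n_s, p, inbred = TRUE, m = 1) {
  freq_r <- if (inbred) stats::rbinom(n, n_r, p) / n_r else
    stats::rbinom(n, 2 * n_r, p) / (2 * n_r)
  freq_s <- if (inbred) stats::rbinom(n, n_s, p) / n_s else
    stats::rbinom(n, 2 * n_s, p) / (2 * n_s)
  if (m == 1) {
    si_r <- stats::rbinom(n, d, freq_r) / d
    si_s <- stats::rbinom(n, d, freq_s) / d
    return(abs(si_s - si_r))
  }
  si_r <- matrix(stats::rbinom(n * m, d, rep(freq_r, m)), nrow = n)
  si_s <- matrix(stats::rbinom(n * m, d, rep(freq_s, m)), nrow = n)
  rowMeans(abs(si_s - si_r)) / d
}

#' Attach null thresholds to sliding windows
#'
#' Each window inherits the thresholds of the depth stratum nearest to its
#' mean site depth.
#'
#' @param windows output of [sliding_windows()].
#' @param thresholds output of [null_thresholds()].
#' @return `windows` with the threshold columns (`q95`, `q99`, ...) added.
#' @export
attach_thresholds <- function(windows, thresholds) {
  stopifnot(is.data.frame(windows), is.data.frame(thresholds))
  qcols <- setdiff(names(thresholds), "depth")
  idx <- vapply(windows$mean_depth, function(d) {
    if (is.na(d)) NA_integer_ else which.min(abs(thresholds$depth - d))
  }, integer(1))
  for (nm in qcols) windows[[nm]] <- thresholds[[nm]][idx]
  windows
}

#' Call candidate QTL regions from significant windows
#'
#' A window is significant when unmasked and its mean delta-SNP-index
#' exceeds the null threshold at the requested level. Overlapping or
#' adjacent significant windows are merged into maximal regions; each region
#' reports its peak window (maximum mean delta).
#'
#' @param windows output of [attach_thresholds()].
#' @param level confidence level, `0.95` (uses `q95`) or `0.99` (`q99`);
#'   any level whose `q<level*100>` column is present works.
#' @return a tibble per called region: `chrom`, `start`, `end`,
#'   `peak_start`, `peak_end`, `peak_delta`, `n_windows`, `level`. Empty
#'   (zero rows) when nothing is significant.
#' @export
call_qtl <- function(windows, level = 0.95) {
  qcol <- paste0("q", round(level * 100))
  if (!qcol %in% names(windows)) {
    data_abort("windows lack a `%s` threshold column; run attach_thresholds()", qcol)
  }
  sig <- windows %>%
    dplyr::filter(!.data$masked, !is.na(.data$mean_delta),
                  !is.na(.data[[qcol]]), .data$mean_delta > .data[[qcol]])
  empty <- tibble::tibble(
    chrom = character(), start = double(), end = double(),
    peak_start = double(), peak_end = double(), peak_delta = double(),
    n_windows = integer(), level = double()
  )
  if (nrow(sig) == 0) return(empty)
  sig <- dplyr::arrange(sig, .data$chrom, .data$start)
  purrr::map_dfr(unique(sig$chrom), function(ch) {
    s <- sig[sig$chrom == ch, ]
    new_run <- c(TRUE, s$start[-1] > cummax(s$end[-nrow(s)]) + 1)
    run_id <- cumsum(new_run)
    s %>%
      dplyr::mutate(.run = run_id) %>%
      dplyr::group_by(.data$.run) %>%
      dplyr::summarise(
        chrom = ch,
        peak_start = .data$start[which.max(.data$mean_delta)],
        peak_end = .data$end[which.max(.data$mean_delta)],
        peak_delta = max(.data$mean_delta),
        n_windows = dplyr::n(),
        level = level,
        start = min(.data$start),
        end = max(.data$end),
        .groups = "drop"
      ) %>%
      dplyr::select("chrom", "start", "end", "peak_start", "peak_end",
                    "peak_delta", "n_windows", "level")
  })
}
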