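#' Haploview-style locus filters
#'
#' Summarises each biallelic marker of a genotype matrix and flags the ones
#' usable for LD analysis: minor-allele frequency above `maf_min` and
#' genotyping call rate above `call_rate_min`. The Hardy-Weinberg filter is
#' disabled (cut-off 0), appropriate for inbred-line panels.
#'
#' @param genotypes data frame with a `line` column and one numeric column
#'   per marker coding donor-allele dosage 0/1/2 (`NA` missing).
#' @param maf_min,call_rate_min thresholds (defaults 0.05 and 0.50; the
#'   comparison is strict, `>`).
#' @return a tibble per marker: `marker`, `maf`, `call_rate`,
#'   `passes_filters`.
#' @export
filter_loci <- function(genotypes, maf_min = 0.05, call_rate_min = 0.50) {
  stopifnot(is.data.frame(genotypes), "line" %in% names(genotypes))
  marker_cols <- setdiff(names(genotypes), "line")
  g <- as.matrix(genotypes[marker_cols])
  if (!is.numeric(g)) data_abort("genotypes must be numeric dosages 0/1/2")
  called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(called, 1))
  maf <- pmin(p, 1 - p)
  call_rate <- called / nrow(g)
  tibble::tibble(
    marker = marker_cols, maf = unname(maf), call_rate = unname(call_rate),
    passes_filters = unname(maf > maf_min & call_rate > call_rate_min)
  )
}

# haplotype frequencies for two dosage vectors, EM over double heterozygotes
hap_freqs <- function(g1, g2, max_iter = 100, tol = 1e-10) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  dh <- g1 == 1 & g2 == 1
  # unambiguous haplotype counts (hom-hom: 2 copies; single het: 1 of each)
  n <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  add <- function(n, x, y, w) {
    key <- paste0(if (x == 1) "A" else "a", if (y == 1) "B" else "b")
    n[key] <- n[key] + w
    n
  }
  for (i in which(!dh)) {
    a <- g1[i]; b <- g2[i]
    if (a != 1 && b != 1) {
      n <- add(n, a / 2, b / 2, 2)
    } else if (a == 1) {            # het at locus 1 only
      n <- add(n, 1, b / 2, 1); n <- add(n, 0, b / 2, 1)
    } else {                        # het at locus 2 only
      n <- add(n, a / 2, 1, 1); n <- add(n, a / 2, 0, 1)
    }
  }
  n_dh <- sum(dh)
  f <- (n + 0.25) / sum(n + 0.25)   # start near the unambiguous estimate
  if (n_dh > 0) {
    for (it in seq_len(max_iter)) {
      cis <- f["AB"] * f["ab"]; tr <- f["Ab"] * f["aB"]
      w <- if (cis + tr > 0) cis / (cis + tr) else 0.5
      new_n <- n + n_dh * c(AB = w, Ab = 1 - w, aB = 1 - w, ab = w)
      new_f <- new_n / sum(new_n)
      if (max(abs(new_f - f)) < tol) { f <- new_f; break }
      f <- new_f
    }
  } else {
    f <- n / sum(n)
  }
  list(freqs = f, counts = n, n_double_het = n_dh,
       n_haplotypes = sum(n) + 2 * n_dh)
}

#' Pairwise linkage disequilibrium between two loci
#'
#' Computes haplotype frequencies (direct counting for homozygous inbred
#' lines, EM phase resolution for double heterozygotes), then `D = p(AB) -
#' p(A)p(B)`, the normalised `D' = |D| / Dmax`, and the squared allele
#' frequency correlation `r^2 = D^2 / (p(A)p(a)p(B)p(b))`. A D' confidence
#' interval (5th-95th percentile) is obtained from the likelihood profile on
#' a D' grid, the quantity the Gabriel block definition consumes.
#'
#' @param g1,g2 numeric dosage vectors (0/1/2, `NA` missing) at the two
#'   loci, same lines in the same order.
#' @return a one-row tibble: haplotype frequencies `hap_AB`..`hap_ab`, `d`,
#'   `d_prime`, `r2`, `ci_low`, `ci_high`, `n_haplotypes`, `p_value`
#'   (chi-squared test of allelic association).
#' @export
ld_pair <- function(g1, g2) {
  if (length(g1) != length(g2)) data_abort("genotype vectors differ in length")
  hf <- hap_freqs(g1, g2)
  f <- hf$freqs
  pA <- f["AB"] + f["Ab"]; pB <- f["AB"] + f["aB"]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    data_abort("monomorphic locus: LD undefined; apply filter_loci() first")
  }
  pA <- unname(pA); pB <- unname(pB)
  D <- unname(f[["AB"]] - pA * pB)
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax > 0) abs(D) / dmax else 0
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  ci <- dprime_ci(hf$counts, hf$n_double_het, pA, pB, sign(D))
  n_hap <- hf$n_haplotypes
  chi2 <- r2 * n_hap
  tibble::tibble(
    hap_AB = unname(f["AB"]), hap_Ab = unname(f["Ab"]),
    hap_aB = unname(f["aB"]), hap_ab = unname(f["ab"]),
    d = unname(D), d_prime = unname(d_prime), r2 = unname(r2),
    ci_low = ci[1], ci_high = ci[2], n_haplotypes = n_hap,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  )
}

# likelihood-profile CI on D' (allele freqs held at their estimates)
dprime_ci <- function(counts, n_dh, pA, pB, d_sign, grid_step = 0.005) {
  pA <- unname(pA); pB <- unname(pB); d_sign <- unname(d_sign)
  counts <- counts[c("AB", "Ab", "aB", "ab")]
  if (d_sign == 0) d_sign <- 1
  dmax <- if (d_sign >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = grid_step)
  eps <- 1e-10
  ll <- vapply(grid, function(dp) {
    D <- d_sign * dp * dmax
    p <- c(AB = pA * pB + D, Ab = pA * (1 - pB) - D,
           aB = (1 - pA) * pB - D, ab = (1 - pA) * (1 - pB) + D)
    p <- pmax(p, eps)
    sum(counts * log(p)) +
      if (n_dh > 0) n_dh * log(p["AB"] * p["ab"] + p["Ab"] * p["aB"]) else 0
  }, numeric(1))
  lik <- exp(ll - max(ll))
  total <- sum(lik)
  cum <- cumsum(lik)
  low <- grid[min(which(cum >= 0.05 * total))]
  cum_rev <- rev(cumsum(rev(lik)))
  high <- grid[max(which(cum_rev >= 0.05 * total))]
  c(low, high)
}

#' All-pairs LD table for a genotype matrix
#'
#' @param genotypes data frame with `line` plus numeric dosage columns.
#' @param marker_map optional data frame `marker`, `chrom`, `pos`; when
#'   given, only within-chromosome pairs are computed and markers are
#'   ordered by position.
#' @param apply_filters run [filter_loci()] first (default TRUE).
#' @param maf_min,call_rate_min passed to [filter_loci()].
#' @return a tibble with one row per marker pair (`marker1`, `marker2` in
#'   map order) and the [ld_pair()] statistics.
#' @export
ld_matrix <- function(genotypes, marker_map = NULL, apply_filters = TRUE,
                      maf_min = 0.05, call_rate_min = 0.50) {
  stopifnot(is.data.frame(genotypes))
  marker_cols <- setdiff(names(genotypes), "line")
  if (apply_filters) {
    ls <- filter_loci(genotypes, maf_min, call_rate_min)
    marker_cols <- ls$marker[ls$passes_filters]
  }
  if (length(marker_cols) < 2) {
    return(tibble::tibble(marker1 = character(), marker2 = character()))
  }
  if (!is.null(marker_map)) {
    mm <- marker_map[match(marker_cols, marker_map$marker), ]
    ord <- order(mm$chrom, mm$pos)
    marker_cols <- marker_cols[ord]
    chrom_of <- stats::setNames(mm$chrom[ord], marker_cols)
  } else {
    chrom_of <- stats::setNames(rep("un", length(marker_cols)), marker_cols)
  }
  pairs <- purrr::map_dfr(seq_along(marker_cols)[-length(marker_cols)], function(i) {
    purrr::map_dfr(seq(i + 1, length(marker_cols)), function(j) {
      if (chrom_of[i] != chrom_of[j]) return(NULL)
      dplyr::bind_cols(
        tibble::tibble(marker1 = marker_cols[i], marker2 = marker_cols[j]),
        ld_pair(genotypes[[marker_cols[i]]], genotypes[[marker_cols[j]]])
      )
    })
  })
  pairs
}

#' Gabriel confidence-interval LD blocks
#'
#' A marker pair is in "strong LD" when its D' confidence interval has
#' lower bound >= 0.70 and upper bound >= 0.98, and shows "strong
#' recombination" when the upper bound < 0.90 (the published defaults).
#' A candidate span of consecutive markers is a block when at least 95% of
#' its informative pairs (strong LD or strong recombination) are strong LD.
#' Maximal non-overlapping blocks are returned greedily, longest span
#' first.
#'
#' @param pairs output of [ld_matrix()] (needs `ci_low`, `ci_high`).
#' @param marker_map data frame `marker`, `chrom`, `pos` covering every
#'   marker in `pairs`.
#' @param ci_strong_low,ci_strong_high,ci_recomb_high,strong_fraction
#'   Gabriel thresholds (defaults 0.70, 0.98, 0.90, 0.95).
#' @return a tibble per block: `chrom`, `start`, `end` (bp of outermost
#'   markers), `n_markers`, `members` (comma-collapsed marker ids). Empty
#'   when fewer than two passing markers or no span qualifies.
#' @export
gabriel_blocks <- function(pairs, marker_map, ci_strong_low = 0.70,
                           ci_strong_high = 0.98, ci_recomb_high = 0.90,
                           strong_fraction = 0.95) {
  empty <- tibble::tibble(chrom = character(), start = double(),
                          end = double(), n_markers = integer(),
                          members = character())
  if (nrow(pairs) == 0) return(empty)
  purrr::map_dfr(unique(marker_map$chrom[marker_map$marker %in%
                                           c(pairs$marker1, pairs$marker2)]),
                 function(ch) {
    mm <- marker_map[marker_map$chrom == ch &
                       marker_map$marker %in% c(pairs$marker1, pairs$marker2), ]
    mm <- mm[order(mm$pos), ]
    m <- nrow(mm)
    if (m < 2) return(NULL)
    idx <- stats::setNames(seq_len(m), mm$marker)
    strong <- matrix(NA, m, m)
    inform_m <- matrix(NA, m, m)
    pp <- pairs[pairs$marker1 %in% mm$marker & pairs$marker2 %in% mm$marker, ]
    i <- idx[pp$marker1]; j <- idx[pp$marker2]
    s <- pp$ci_low >= ci_strong_low & pp$ci_high >= ci_strong_high
    r <- pp$ci_high < ci_recomb_high
    strong[cbind(i, j)] <- s; strong[cbind(j, i)] <- s
    inform_m[cbind(i, j)] <- s | r; inform_m[cbind(j, i)] <- s | r
    # candidate spans, longest (bp) first
    spans <- tidyr::expand_grid(a = seq_len(m - 1), b = seq(2, m)) %>%
      dplyr::filter(.data$b > .data$a) %>%
      dplyr::mutate(bp = mm$pos[.data$b] - mm$pos[.data$a]) %>%
      dplyr::arrange(dplyr::desc(.data$bp), .data$a)
    used <- rep(FALSE, m)
    out <- list()
    for (k in seq_len(nrow(spans))) {
      a <- spans$a[k]; b <- spans$b[k]
      if (any(used[a:b])) next
      sub_s <- strong[a:b, a:b]; sub_i <- inform_m[a:b, a:b]
      ut <- upper.tri(sub_s)
      n_inf <- sum(sub_i[ut], na.rm = TRUE)
      n_str <- sum(sub_s[ut] & sub_i[ut], na.rm = TRUE)
      if (n_inf == 0) next
      if (n_str / n_inf >= strong_fraction) {
        used[a:b] <- TRUE
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = ch, start = mm$pos[a], end = mm$pos[b],
          n_markers = b - a + 1L,
          members = paste(mm$marker[a:b], collapse = ","))
      }
    }
    dplyr::bind_rows(out) %>% dplyr::arrange(.data$start)
  })
}
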