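#' Configuration for the synthetic BIL / mutant study generator
#'
#' Bundles every parameter of the simulated study: a recipient x donor cross
#' advanced by backcrossing and selfing (a BC3F5 backcross-inbred-line
#' population by default), seedling damage phenotyping on the SES 1-9 scale,
#' pooled reduced-representation sequencing of extreme lines, and a
#' fast-neutron mutant population.
#'
#' Defaults emulate the study conditions this package targets: 105 BILs from
#' three backcrosses plus four selfing generations, two resistance QTLs on
#' one chromosome (effects 10 and 8 score-days, donor allele reducing
#' damage), pools of 19 resistant and 16 susceptible lines, ~20x pooled
#' coverage, and a fast-neutron mutation spectrum of 56% single-base
#' substitutions, 23% deletions, 21% insertions.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (recycled across
#'   chromosomes).
#' @param marker_spacing_bp mean distance between adjacent markers in bp;
#'   markers are laid out on a regular grid at this spacing.
#' @param recomb_rate expected crossovers per chromosome per meiosis
#'   (Poisson count, uniform placement, no interference).
#' @param qtls data frame with columns `chrom`, `pos`, `effect` (reduction
#'   in damage AUC, in score-days, for a homozygous donor genotype).
#' @param n_backcrosses backcross generations after the F1 (default 3).
#' @param n_selfings selfing generations after the last backcross (default
#'   4, i.e. to F5).
#' @param n_lines number of inbred lines (default 105).
#' @param pool_sizes named vector `c(resistant = ..., susceptible = ...)`.
#' @param mean_depth mean sequencing depth per site per pool (Poisson).
#' @param mutation_rate_per_line expected fast-neutron mutations per mutant
#'   line (Poisson).
#' @param mutation_type_mix proportions of SBS / deletion / insertion
#'   mutations; must sum to 1.
#' @param noise_sd residual SD of a daily damage score.
#' @param baseline_auc damage AUC of a line with no donor QTL allele over a
#'   5-day screen (susceptible recipient level).
#' @param qtl_freq probability that a line carries the planted donor
#'   fragment at a given QTL (default 0.5). Planting happens on top of the
#'   neutral backcross background: a carrier line is made homozygous donor
#'   over a fragment containing the QTL, which reproduces the bimodal AUC
#'   distribution and near-fixed resistant-pool SNP-indexes seen in real
#'   extreme-pool designs.
#' @param frag_min,frag_max planted donor fragment length range in bp
#'   (default 0.25-5.1 Mb, the span observed for donor fragments in
#'   resistant backcross lines).
#' @param retained_intervals optional data frame `chrom`, `start`, `end` of
#'   donor regions retained by foreground marker selection during
#'   backcrossing (default `NULL`, off).
#' @param seed RNG seed used by the `simulate_*` functions.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 3,
                       chrom_length_bp = 25e6,
                       marker_spacing_bp = 25e3,
                       recomb_rate = 1.5,
                       qtls = tibble::tibble(chrom = 1L,
                                             pos = c(6.5e6, 16.3e6),
                                             effect = c(10, 8)),
                       n_backcrosses = 3,
                       n_selfings = 4,
                       n_lines = 105,
                       pool_sizes = c(resistant = 19, susceptible = 16),
                       mean_depth = 20,
                       mutation_rate_per_line = 20,
                       mutation_type_mix = c(sbs = 0.56, deletion = 0.23,
                                             insertion = 0.21),
                       noise_sd = 1.5,
                       baseline_auc = 32,
                       qtl_freq = 0.5,
                       frag_min = 2.5e5,
                       frag_max = 5.1e6,
                       retained_intervals = NULL,
                       seed = 1) {
  chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min) {
      config_abort(nm, sprintf("must be a single number >= %s", min))
    }
  }
  chk_count(n_chromosomes, "n_chromosomes")
  chk_count(chrom_length_bp, "chrom_length_bp")
  chk_count(marker_spacing_bp, "marker_spacing_bp")
  chk_count(n_lines, "n_lines")
  chk_count(mean_depth, "mean_depth")
  if (!is.numeric(recomb_rate) || recomb_rate < 0) {
    config_abort("recomb_rate", "must be >= 0")
  }
  if (n_backcrosses < 0) config_abort("n_backcrosses", "must be >= 0")
  if (n_selfings < 0) config_abort("n_selfings", "must be >= 0")
  if (mutation_rate_per_line < 0) {
    config_abort("mutation_rate_per_line", "must be >= 0")
  }
  if (abs(sum(mutation_type_mix) - 1) > 1e-9 || any(mutation_type_mix < 0)) {
    config_abort("mutation_type_mix", "proportions must be non-negative and sum to 1")
  }
  if (length(mutation_type_mix) != 3) {
    config_abort("mutation_type_mix", "needs exactly (SBS, deletion, insertion)")
  }
  if (!all(c("resistant", "susceptible") %in% names(pool_sizes)) ||
      any(pool_sizes < 1)) {
    config_abort("pool_sizes", "needs named positive sizes for resistant and susceptible")
  }
  if (sum(pool_sizes) > n_lines) {
    config_abort("pool_sizes", "pools cannot exceed n_lines")
  }
  if (noise_sd < 0) config_abort("noise_sd", "must be >= 0")
  qtls <- tibble::as_tibble(qtls)
  if (nrow(qtls)) {
    if (!all(c("chrom", "pos", "effect") %in% names(qtls))) {
      config_abort("qtls", "needs columns chrom, pos, effect")
    }
    if (any(qtls$chrom < 1 | qtls$chrom > n_chromosomes) ||
        any(qtls$pos < 1 | qtls$pos > chrom_length_bp)) {
      config_abort("qtls", "QTL positions must lie inside their chromosome")
    }
  }
  if (qtl_freq < 0 || qtl_freq > 1) {
    config_abort("qtl_freq", "must be a probability in [0, 1]")
  }
  if (frag_min <= 0 || frag_max < frag_min) {
    config_abort("frag_min/frag_max", "need 0 < frag_min <= frag_max")
  }
  if (!is.null(retained_intervals) &&
      !all(c("chrom", "start", "end") %in% names(retained_intervals))) {
    config_abort("retained_intervals", "needs columns chrom, start, end")
  }
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         chrom_length_bp = chrom_length_bp,
         marker_spacing_bp = marker_spacing_bp,
         recomb_rate = recomb_rate, qtls = qtls,
         n_backcrosses = as.integer(n_backcrosses),
         n_selfings = as.integer(n_selfings),
         n_lines = as.integer(n_lines),
         pool_sizes = pool_sizes, mean_depth = mean_depth,
         mutation_rate_per_line = mutation_rate_per_line,
         mutation_type_mix = mutation_type_mix,
         noise_sd = noise_sd, baseline_auc = baseline_auc,
         qtl_freq = qtl_freq, frag_min = frag_min, frag_max = frag_max,
         retained_intervals = retained_intervals, seed = seed),
    class = "sim_config"
  )
}

# one gamete from a plant with haplotype pair (h1, h2): matrices over markers
# of one chromosome are handled per-chromosome outside
sim_gamete <- function(h1, h2, marker_pos, chrom_len, recomb_rate) {
  k <- stats::rpois(1, recomb_rate)
  use_first <- stats::runif(1) < 0.5
  if (k == 0) return(if (use_first) h1 else h2)
  xo <- sort(stats::runif(k, 0, chrom_len))
  seg <- findInterval(marker_pos, xo) # 0..k segment index per marker
  from_first <- (seg %% 2 == 0) == use_first
  ifelse(from_first, h1, h2)
}

#' Simulate a backcross-inbred-line population
#'
#' Starting from an F1 between a recipient (allele 0) and a donor (allele
#' 1), each line is advanced independently by `n_backcrosses` backcrosses to
#' the recurrent (recipient) parent followed by `n_selfings` generations of
#' single-seed-descent selfing. Meioses place a Poisson number of crossovers
#' uniformly along each chromosome (no interference). Optional foreground
#' selection re-draws backcross gametes until the donor allele is retained
#' at every marker inside `retained_intervals`.
#'
#' QTLs are then planted on this background: each line independently
#' carries, with probability `qtl_freq`, a homozygous donor fragment of
#' length uniform on `[frag_min, frag_max]` containing the QTL position.
#' With `qtls` empty the population is strictly neutral.
#'
#' The expected donor genome fraction after `b` backcrosses is
#' `(1/2)^(b+1)`; heterozygosity halves with each selfing generation.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_truth`: `genotypes` (n_lines x n_markers
#'   integer matrix, 0 = recipient homozygote, 1 = heterozygote, 2 = donor
#'   homozygote), `markers` (tibble `marker`, `chrom`, `pos`, with simulated
#'   `ref_allele`/`donor_allele` bases), `qtl_index` (marker column of each
#'   QTL, nearest marker), and the `config`.
#' @export
simulate_bil_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  spacing <- config$marker_spacing_bp
  len <- config$chrom_length_bp
  pos1 <- seq(spacing / 2, len, by = spacing)
  markers <- purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
    tibble::tibble(chrom = ch, pos = round(pos1))
  })
  markers$marker <- sprintf("M%02d_%07d", markers$chrom, markers$pos)
  n_mark <- nrow(markers)
  bases <- c("A", "C", "G", "T")
  markers$ref_allele <- sample(bases, n_mark, replace = TRUE)
  markers$donor_allele <- vapply(markers$ref_allele,
                                 function(b) sample(setdiff(bases, b), 1),
                                 character(1))
  markers <- markers[c("marker", "chrom", "pos", "ref_allele", "donor_allele")]

  by_chrom <- split(seq_len(n_mark), markers$chrom)
  retained_idx <- integer(0)
  if (!is.null(config$retained_intervals)) {
    ri <- config$retained_intervals
    for (i in seq_len(nrow(ri))) {
      retained_idx <- c(retained_idx, which(
        markers$chrom == ri$chrom[i] &
          markers$pos >= ri$start[i] & markers$pos <= ri$end[i]))
    }
  }

  geno <- matrix(0L, nrow = config$n_lines, ncol = n_mark)
  for (ln in seq_len(config$n_lines)) {
    # haplotype pair per chromosome; F1 = donor / recipient
    h1 <- lapply(by_chrom, function(ix) rep(1L, length(ix)))
    h2 <- lapply(by_chrom, function(ix) rep(0L, length(ix)))
    gamete_from <- function(h1, h2, want_retained) {
      lapply(seq_along(by_chrom), function(ci) {
        ix <- by_chrom[[ci]]
        need <- intersect(retained_idx, ix)
        for (try in seq_len(1000)) {
          g <- sim_gamete(h1[[ci]], h2[[ci]], markers$pos[ix], len,
                          config$recomb_rate)
          if (!want_retained || !length(need) ||
              all(g[match(need, ix)] == 1L)) return(g)
        }
        g
      })
    }
    for (b in seq_len(config$n_backcrosses)) {
      h1 <- gamete_from(h1, h2, want_retained = TRUE)
      h2 <- lapply(by_chrom, function(ix) rep(0L, length(ix)))
    }
    for (s in seq_len(config$n_selfings)) {
      new1 <- gamete_from(h1, h2, want_retained = FALSE)
      new2 <- gamete_from(h1, h2, want_retained = FALSE)
      h1 <- new1; h2 <- new2
    }
    geno[ln, ] <- unlist(h1) + unlist(h2)
  }
  rownames(geno) <- sprintf("BIL%03d", seq_len(config$n_lines))
  colnames(geno) <- markers$marker

  qtl_index <- if (nrow(config$qtls)) {
    vapply(seq_len(nrow(config$qtls)), function(i) {
      cand <- which(markers$chrom == config$qtls$chrom[i])
      cand[which.min(abs(markers$pos[cand] - config$qtls$pos[i]))]
    }, integer(1))
  } else integer(0)

  # plant homozygous donor fragments, anchored on each QTL's nearest marker
  # so that carrier status and marker dosage always agree
  if (nrow(config$qtls)) {
    for (q in seq_len(nrow(config$qtls))) {
      qc <- config$qtls$chrom[q]
      qp <- markers$pos[qtl_index[q]]
      carrier <- stats::runif(config$n_lines) < config$qtl_freq
      flen <- stats::runif(config$n_lines, config$frag_min, config$frag_max)
      fstart <- qp - stats::runif(config$n_lines) * flen
      fend <- fstart + flen
      for (ln in which(carrier)) {
        hit <- markers$chrom == qc & markers$pos >= fstart[ln] &
          markers$pos <= fend[ln]
        geno[ln, hit] <- 2L
        geno[ln, qtl_index[q]] <- 2L
      }
    }
  }

  structure(
    list(genotypes = geno, markers = markers, qtl_index = qtl_index,
         config = config),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d lines x %d markers on %d chromosome(s), %d QTL(s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              x$config$n_chromosomes, nrow(x$config$qtls)))
  invisible(x)
}

# genetic damage AUC per line: baseline minus summed QTL effects by dosage
genetic_auc <- function(truth) {
  cfg <- truth$config
  auc <- rep(cfg$baseline_auc, nrow(truth$genotypes))
  if (length(truth$qtl_index)) {
    dosage <- truth$genotypes[, truth$qtl_index, drop = FALSE]
    auc <- auc - as.vector(dosage %*% (cfg$qtls$effect / 2))
  }
  stats::setNames(auc, rownames(truth$genotypes))
}

#' Simulate daily damage scores for every line
#'
#' Each line's genetic damage AUC is `baseline_auc - sum(effect * dosage /
#' 2)` over the configured QTLs. Daily scores are reconstructed as a linear
#' ramp whose trapezoid AUC equals the genetic value, then perturbed with
#' i.i.d. Gaussian noise per day and clamped to the SES `[1, 9]` scale.
#'
#' @param truth a `sim_truth` from [simulate_bil_population()].
#' @param n_days scoring days (>= 2; default 5).
#' @param n_reps replicates per line x population (default 3).
#' @param populations character vector of BPH population ids.
#' @param noise_sd per-day score SD (defaults to the config value).
#' @param seed RNG seed (defaults to config seed + 1).
#' @return a wide tibble `line`, `population`, `replicate`, `d1..dN`.
#' @export
simulate_damage_scores <- function(truth, n_days = 5, n_reps = 3,
                                   populations = c("CNT", "TPY", "UBN"),
                                   noise_sd = truth$config$noise_sd,
                                   seed = truth$config$seed + 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_days < 2) {
    config_abort("n_days", "AUC is undefined on fewer than 2 time points")
  }
  set.seed(seed)
  g_auc <- genetic_auc(truth)
  lines <- names(g_auc)
  mean_level <- g_auc / (n_days - 1)          # trapezoid AUC of a ramp = mean * (n-1)
  slope <- pmax(pmin(2 * pmin(mean_level - 1, 9 - mean_level) / (n_days - 1), 1), 0)
  day_offset <- seq_len(n_days) - (n_days + 1) / 2
  grid <- tidyr::expand_grid(line = lines, population = populations,
                             replicate = seq_len(n_reps))
  ramp <- outer(mean_level[grid$line], rep(1, n_days)) +
    outer(slope[grid$line], day_offset)
  noisy <- ramp + matrix(stats::rnorm(length(ramp), 0, noise_sd), nrow = nrow(ramp))
  noisy <- pmin(pmax(noisy, 1), 9)
  colnames(noisy) <- paste0("d", seq_len(n_days))
  dplyr::bind_cols(grid, tibble::as_tibble(round(noisy, 2)))
}

#' Simulate pooled (and individual) sequencing allele depths
#'
#' For each marker site and each pool, the true donor-allele frequency is
#' the mean donor dosage of the member lines divided by 2; sequencing depth
#' is Poisson around `mean_depth` and donor-allele reads are binomial at the
#' pool frequency. Each pool member is also emitted as an individual sample
#' (its own dosage/2 frequency), mirroring the individual-extremes analysis.
#'
#' @param truth a `sim_truth`.
#' @param pool_assignment data frame `line`, `pool`
#'   (`resistant`/`susceptible`), e.g. from [select_extremes()] with its
#'   `line` column.
#' @param mean_depth mean per-site per-sample depth (defaults to config).
#' @param include_individuals also emit per-line samples (default TRUE).
#' @param seed RNG seed (defaults to config seed + 2).
#' @return a long site x sample tibble matching [read_variants()] output
#'   (`sample` is `pool_resistant`, `pool_susceptible`, or the line id;
#'   `sample_type` distinguishes pools from individuals). Site and base
#'   qualities are set high (60/40): quality failures are not part of this
#'   generator's scope.
#' @export
simulate_pool_seq <- function(truth, pool_assignment,
                              mean_depth = truth$config$mean_depth,
                              include_individuals = TRUE,
                              seed = truth$config$seed + 2) {
  stopifnot(inherits(truth, "sim_truth"), is.data.frame(pool_assignment))
  if (!all(c("line", "pool") %in% names(pool_assignment))) {
    data_abort("`pool_assignment` needs columns line, pool")
  }
  missing <- setdiff(pool_assignment$line, rownames(truth$genotypes))
  if (length(missing)) {
    data_abort("pool member(s) absent from truth: %s",
               paste(utils::head(missing, 3), collapse = ", "))
  }
  for (p in c("resistant", "susceptible")) {
    if (!any(pool_assignment$pool == p)) data_abort("empty %s pool", p)
  }
  set.seed(seed)
  mk <- truth$markers
  n_site <- nrow(mk)
  draw_sample <- function(freq, sample_id, sample_type) {
    depth <- stats::rpois(n_site, mean_depth)
    donor <- stats::rbinom(n_site, depth, freq)
    tibble::tibble(
      chrom = paste0("chr", mk$chrom), pos = mk$pos,
      ref_allele = mk$ref_allele, donor_allele = mk$donor_allele,
      site_quality = 60, base_quality = 40,
      sample = sample_id, sample_type = sample_type,
      ref_depth = depth - donor, donor_depth = donor
    )
  }
  out <- purrr::map_dfr(c("resistant", "susceptible"), function(p) {
    members <- pool_assignment$line[pool_assignment$pool == p]
    freq <- colMeans(truth$genotypes[members, , drop = FALSE]) / 2
    draw_sample(freq, paste0("pool_", p), "pool")
  })
  if (include_individuals) {
    ind <- purrr::map_dfr(pool_assignment$line, function(ln) {
      draw_sample(truth$genotypes[ln, ] / 2, ln, "individual")
    })
    out <- dplyr::bind_rows(out, ind)
  }
  out
}

#' Simulate a fast-neutron mutant population
#'
#' Each line carries a Poisson number of mutations, placed uniformly over
#' the genome; mutation types are drawn from `mutation_type_mix` (56% SBS,
#' 23% deletion, 21% insertion by default). If gene intervals are supplied,
#' each mutation is labelled with the gene it falls in.
#'
#' @param config a [sim_config()].
#' @param n_lines number of mutant lines (default `config$n_lines`).
#' @param gene_intervals optional data frame `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param seed RNG seed (defaults to `config$seed + 3`).
#' @return a tibble with one row per mutation: `line`, `chrom`, `pos`,
#'   `type` (`sbs`/`deletion`/`insertion`), `gene_id` (NA if intergenic or
#'   no intervals given). Lines with zero mutations do not appear.
#' @export
simulate_mutant_population <- function(config, n_lines = config$n_lines,
                                       gene_intervals = NULL,
                                       seed = config$seed + 3) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  counts <- stats::rpois(n_lines, config$mutation_rate_per_line)
  total <- sum(counts)
  if (total == 0) {
    return(tibble::tibble(line = character(), chrom = integer(),
                          pos = double(), type = character(),
                          gene_id = character()))
  }
  out <- tibble::tibble(
    line = rep(sprintf("MUT%04d", seq_len(n_lines)), counts),
    chrom = sample.int(config$n_chromosomes, total, replace = TRUE),
    pos = ceiling(stats::runif(total, 0, config$chrom_length_bp)),
    type = sample(c("sbs", "deletion", "insertion"), total, replace = TRUE,
                  prob = config$mutation_type_mix),
    gene_id = NA_character_
  )
  if (!is.null(gene_intervals)) {
    for (i in seq_len(nrow(gene_intervals))) {
      hit <- out$chrom == gene_intervals$chrom[i] &
        out$pos >= gene_intervals$start[i] & out$pos <= gene_intervals$end[i]
      out$gene_id[hit] <- gene_intervals$gene_id[i]
    }
  }
  out
}
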