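no_qtls <- tibble::tibble(chrom = integer(), pos = double(), effect = double())

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_lines = 0), "n_lines")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(recomb_rate = -1), "recomb_rate")
  expect_error(sim_config(mutation_type_mix = c(0.5, 0.3, 0.3)),
               "mutation_type_mix")
  expect_error(sim_config(mutation_rate_per_line = -2), "mutation_rate")
  expect_error(sim_config(pool_sizes = c(resistant = 60, susceptible = 60)),
               "pool_sizes")
  expect_error(sim_config(qtls = tibble::tibble(chrom = 99L, pos = 1e6,
                                                effect = 5)), "qtls")
  expect_error(sim_config(qtl_freq = 1.5), "qtl_freq")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})

test_that("every simulate_* output is reproducible from the seed", {
  cfg <- sim_config(seed = 9, n_lines = 20, n_chromosomes = 2,
                    chrom_length_bp = 5e6, marker_spacing_bp = 2.5e5,
                    qtls = tibble::tibble(chrom = 1L, pos = 2e6, effect = 10),
                    pool_sizes = c(resistant = 5, susceptible = 5))
  t1 <- simulate_bil_population(cfg)
  t2 <- simulate_bil_population(cfg)
  expect_identical(t1$genotypes, t2$genotypes)
  expect_identical(simulate_damage_scores(t1), simulate_damage_scores(t2))
  pa <- tibble::tibble(line = rownames(t1$genotypes)[1:6],
                       pool = rep(c("resistant", "susceptible"), 3))
  expect_identical(simulate_pool_seq(t1, pa), simulate_pool_seq(t2, pa))
  expect_identical(simulate_mutant_population(cfg, n_lines = 10),
                   simulate_mutant_population(cfg, n_lines = 10))
})

test_that("an F1 population is heterozygous at every marker", {
  cfg <- sim_config(seed = 2, n_lines = 10, n_backcrosses = 0, n_selfings = 0,
                    n_chromosomes = 1, chrom_length_bp = 2e6,
                    marker_spacing_bp = 2e5, qtls = no_qtls,
                    pool_sizes = c(resistant = 2, susceptible = 2))
  truth <- simulate_bil_population(cfg)
  expect_true(all(truth$genotypes == 1L))
})

test_that("without recombination, donor content is chromosome-wise all-or-none", {
  cfg <- sim_config(seed = 4, n_lines = 500, recomb_rate = 0,
                    n_backcrosses = 3, n_selfings = 0, n_chromosomes = 2,
                    chrom_length_bp = 5e6, marker_spacing_bp = 1e6,
                    qtls = no_qtls,
                    pool_sizes = c(resistant = 5, susceptible = 5))
  truth <- simulate_bil_population(cfg)
  per_chrom <- split(seq_len(nrow(truth$markers)), truth$markers$chrom)
  for (ix in per_chrom) {
    g <- truth$genotypes[, ix, drop = FALSE]
    expect_true(all(apply(g, 1, function(r) length(unique(r)) == 1)))
  }
  # BC3F1 marginal donor-allele frequency = (1/2)^4 = 1/16, within 3 SE
  frac <- rowMeans(truth$genotypes) / 2
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 1 / 16), 3 * se + 1e-12)
})

test_that("donor genome fraction follows (1/2)^(b+1) for b backcrosses", {
  for (b in 1:3) {
    cfg <- sim_config(seed = 100 + b, n_lines = 400, n_backcrosses = b,
                      n_selfings = 0, n_chromosomes = 2,
                      chrom_length_bp = 10e6, marker_spacing_bp = 5e5,
                      qtls = no_qtls,
                      pool_sizes = c(resistant = 5, susceptible = 5))
    truth <- simulate_bil_population(cfg)
    frac <- rowMeans(truth$genotypes) / 2
    se <- stats::sd(frac) / sqrt(length(frac))
    expect_lt(abs(mean(frac) - 0.5^(b + 1)), 3 * se)
  }
})

test_that("heterozygosity declines with each selfing generation", {
  het <- vapply(c(0, 2, 4), function(s) {
    cfg <- sim_config(seed = 11, n_lines = 150, n_selfings = s,
                      n_chromosomes = 2, chrom_length_bp = 10e6,
                      marker_spacing_bp = 5e5, qtls = no_qtls,
                      pool_sizes = c(resistant = 5, susceptible = 5))
    mean(simulate_bil_population(cfg)$genotypes == 1L)
  }, numeric(1))
  expect_true(all(diff(het) < 0))
})

test_that("foreground selection retains the requested donor interval", {
  cfg <- sim_config(seed = 13, n_lines = 40, n_chromosomes = 1,
                    chrom_length_bp = 10e6, marker_spacing_bp = 5e5,
                    qtls = no_qtls,
                    pool_sizes = c(resistant = 5, susceptible = 5),
                    n_selfings = 0,
                    retained_intervals = tibble::tibble(chrom = 1, start = 4e6,
                                                        end = 5e6))
  truth <- simulate_bil_population(cfg)
  inside <- truth$markers$pos >= 4e6 & truth$markers$pos <= 5e6
  expect_true(all(truth$genotypes[, inside] >= 1L))
})

test_that("damage scores are a deterministic function of genotype when noise-free", {
  cfg <- sim_config(seed = 15, n_lines = 30, noise_sd = 0, qtls = no_qtls,
                    n_chromosomes = 1, chrom_length_bp = 2e6,
                    marker_spacing_bp = 2e5,
                    pool_sizes = c(resistant = 5, susceptible = 5))
  truth <- simulate_bil_population(cfg)
  auc <- damage_auc(simulate_damage_scores(truth, n_reps = 1))
  expect_equal(length(unique(round(auc$auc, 9))), 1) # no variance source
  expect_equal(unique(round(auc$auc, 6)), cfg$baseline_auc)
})

test_that("a planted QTL of effect 15 separates donor and recipient AUC by 15", {
  cfg <- sim_config(seed = 16, n_lines = 60, noise_sd = 0,
                    n_chromosomes = 1, chrom_length_bp = 2e6,
                    marker_spacing_bp = 1e5,
                    qtls = tibble::tibble(chrom = 1L, pos = 1e6, effect = 15),
                    qtl_freq = 0.5,
                    pool_sizes = c(resistant = 5, susceptible = 5))
  truth <- simulate_bil_population(cfg)
  dos <- truth$genotypes[, truth$qtl_index]
  skip_if(!any(dos == 2) || !any(dos == 0)) # needs both classes drawn
  auc <- damage_auc(simulate_damage_scores(truth, n_reps = 1))
  auc1 <- average_auc(auc)
  donor_line <- rownames(truth$genotypes)[which(dos == 2)[1]]
  rec_line <- rownames(truth$genotypes)[which(dos == 0)[1]]
  expect_equal(auc1$mean_auc[auc1$line == rec_line] -
                 auc1$mean_auc[auc1$line == donor_line], 15)
})

test_that("scores respect the SES bounds and the short-series contract", {
  cfg <- sim_config(seed = 17, n_lines = 120, noise_sd = 4,
                    n_chromosomes = 1, chrom_length_bp = 3e6,
                    marker_spacing_bp = 1e5,
                    qtls = tibble::tibble(chrom = 1L, pos = 1.5e6, effect = 10),
                    pool_sizes = c(resistant = 19, susceptible = 16))
  truth <- simulate_bil_population(cfg)
  sc <- simulate_damage_scores(truth, n_days = 10, n_reps = 3)
  m <- as.matrix(sc[grep("^d", names(sc))])
  expect_gte(min(m), 1)
  expect_lte(max(m), 9)
  expect_gt(length(m), 10000)
  expect_error(simulate_damage_scores(truth, n_days = 1),
               class = "hopperqtl_config_error")
})

test_that("pooled depths follow the member allele frequencies", {
  # pool fixed for the donor allele: every read is a donor read
  g <- matrix(2L, nrow = 4, ncol = 50)
  truth <- manual_truth(g)
  pa <- tibble::tibble(line = rownames(truth$genotypes),
                       pool = c("resistant", "resistant",
                                "susceptible", "susceptible"))
  sites <- simulate_pool_seq(truth, pa, mean_depth = 20,
                             include_individuals = FALSE, seed = 5)
  expect_true(all(sites$ref_depth == 0L))
  expect_true(all(sites$donor_depth >= 0L))
  # frequency 1/2, mean depth 100: CLT bound over 1,000 sites
  g2 <- rbind(matrix(2L, 2, 1000), matrix(0L, 2, 1000))
  truth2 <- manual_truth(g2)
  pa2 <- tibble::tibble(line = rownames(truth2$genotypes),
                        pool = c("resistant", "susceptible",
                                 "resistant", "susceptible"))
  sites2 <- simulate_pool_seq(truth2, pa2, mean_depth = 100,
                              include_individuals = FALSE, seed = 6)
  res <- sites2[sites2$sample == "pool_resistant", ]
  frac <- mean(res$donor_depth / (res$ref_depth + res$donor_depth))
  expect_gt(frac, 0.49); expect_lt(frac, 0.51)
  # empty pool rejected; unknown members rejected
  expect_error(simulate_pool_seq(truth, pa[pa$pool == "resistant", ]),
               class = "hopperqtl_data_error")
  expect_error(simulate_pool_seq(truth, tibble::tibble(line = "nope",
                                                       pool = "resistant")),
               class = "hopperqtl_data_error")
})

test_that("pooled donor fractions are exchangeable across equal-frequency sites", {
  g <- rbind(matrix(2L, 5, 1000), matrix(0L, 5, 1000))
  truth <- manual_truth(g)
  pa <- tibble::tibble(line = rownames(truth$genotypes),
                       pool = rep(c("resistant", "susceptible"), each = 5))
  sites <- simulate_pool_seq(truth, pa, mean_depth = 30,
                             include_individuals = FALSE, seed = 8)
  res <- sites[sites$sample == "pool_resistant", ]
  frac <- res$donor_depth / (res$ref_depth + res$donor_depth)
  ks <- suppressWarnings(stats::ks.test(frac[1:500], frac[501:1000]))
  expect_gt(ks$p.value, 0.01)
})

test_that("mutant populations reproduce the configured mutation spectrum", {
  cfg <- sim_config(seed = 19, mutation_rate_per_line = 10)
  # rate zero -> no mutations at all
  cfg0 <- sim_config(seed = 19, mutation_rate_per_line = 0)
  expect_equal(nrow(simulate_mutant_population(cfg0, n_lines = 50)), 0)
  # 10,000+ mutations match the 56/23/21 mix within a multinomial bound
  mut <- simulate_mutant_population(cfg, n_lines = 1100, seed = 20)
  expect_gt(nrow(mut), 10000)
  props <- prop.table(table(mut$type))[c("sbs", "deletion", "insertion")]
  expect_true(all(abs(props - c(0.56, 0.23, 0.21)) < 0.02))
  # per-line counts look Poisson: variance/mean ratio near 1
  counts <- table(factor(mut$line, levels = sprintf("MUT%04d", 1:1100)))
  expect_lt(abs(stats::var(as.numeric(counts)) / mean(counts) - 1), 0.2)
  # gene hits land inside their intervals
  gi <- tibble::tibble(gene_id = c("gA", "gB"), chrom = c(1L, 2L),
                       start = c(1e6, 2e6), end = c(1.2e6, 2.4e6))
  mut2 <- simulate_mutant_population(cfg, n_lines = 400, gene_intervals = gi,
                                     seed = 21)
  hits <- mut2[!is.na(mut2$gene_id), ]
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    g <- gi[gi$gene_id == hits$gene_id[i], ]
    expect_true(hits$chrom[i] == g$chrom && hits$pos[i] >= g$start &&
                  hits$pos[i] <= g$end)
  }
})
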