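test_that("gene models enforce CDS structure", {
  expect_error(
    suppressWarnings(gene_model("g", "chr1", "+",
                                data.frame(start = 1, end = 10), "ATGGCAGCTA")),
    class = "hopperqtl_config_error") # length not divisible by 3
  expect_error(
    gene_model("g", "chr1", "+",
               data.frame(start = c(1, 5), end = c(6, 12)), "ATGGCAGCTTAA"),
    class = "hopperqtl_config_error") # overlapping segments
  expect_warning(
    gene_model("g", "chr1", "+", data.frame(start = 1, end = 6), "CCCTAA"),
    "ATG")
  g <- gene_model("g", "chr1", "-", data.frame(start = 11, end = 22),
                  "ATGGCAGCTTAA")
  expect_s3_class(g, "gene_model")
})

test_that("cds_coordinate accumulates offsets across segments, strand-aware", {
  cds99 <- random_cds(33, seed = 2)
  expect_equal(nchar(cds99), 99)
  g1 <- suppressWarnings(gene_model("g1", "chr1", "+",
                                    data.frame(start = 101, end = 199), cds99))
  expect_equal(cds_coordinate(g1, 101), 1L)
  expect_equal(cds_coordinate(g1, 199), 99L)
  expect_true(is.na(cds_coordinate(g1, 100)))
  cds100 <- random_cds(34, seed = 3) # 102 bp; use two segments of 50 + 52
  g2 <- suppressWarnings(gene_model(
    "g2", "chr1", "+", data.frame(start = c(101, 201), end = c(150, 252)),
    cds100))
  expect_equal(cds_coordinate(g2, 201), 51L)
  expect_equal(cds_coordinate(g2, c(101, 150, 252)), c(1L, 50L, 102L))
  expect_true(is.na(cds_coordinate(g2, 175)))
  g3 <- suppressWarnings(gene_model(
    "g3", "chr1", "-", data.frame(start = c(101, 201), end = c(150, 252)),
    cds100))
  expect_equal(cds_coordinate(g3, 252), 1L)
  expect_equal(cds_coordinate(g3, 201), 52L)
  expect_equal(cds_coordinate(g3, 150), 53L)
  expect_equal(cds_coordinate(g3, 101), 102L)
})

test_that("codon coordinates reproduce the printed conventions", {
  # missense at CDS position 568 of a 1527-bp CDS -> codon 190 of 508 aa
  set.seed(10)
  cds <- random_cds(509)
  expect_equal(nchar(cds), 1527)
  substr(cds, 568, 570) <- "GCT" # Ala at codon 190
  g <- suppressWarnings(gene_model("pht", "chr4", "+",
                                   data.frame(start = 5867001, end = 5867001 + 1526),
                                   cds))
  eff <- annotate_effect(g, 5867001 + 567, "G", "C") # GCT -> CCT, A>P
  expect_equal(eff$cds_pos, 568L)
  expect_equal(eff$codon_index, 190L)
  expect_equal(eff$protein_length, 508)
  expect_equal(eff$effect_class, "missense")
  expect_equal(paste0(eff$ref_aa, ">", eff$alt_aa), "A>P")

  # stop gained at CDS position 201 of a 216-bp CDS -> codon 67 of 71 aa
  set.seed(11)
  cds2 <- random_cds(72)
  expect_equal(nchar(cds2), 216)
  substr(cds2, 199, 201) <- "TAC" # Tyr at codon 67
  g2 <- suppressWarnings(gene_model("thionin", "chr4", "+",
                                    data.frame(start = 6069700, end = 6069700 + 215),
                                    cds2))
  eff2 <- annotate_effect(g2, 6069700 + 200, "C", "A") # TAC -> TAA
  expect_equal(eff2$cds_pos, 201L)
  expect_equal(eff2$codon_index, 67L)
  expect_equal(eff2$protein_length, 71)
  expect_equal(eff2$effect_class, "stop_gained")
})

test_that("indels classify by frame and length", {
  set.seed(12)
  cds <- random_cds(472)
  substr(cds, 477, 477) <- "T"
  g <- suppressWarnings(gene_model("stps2", "chr4", "+",
                                   data.frame(start = 16214300, end = 16214300 + nchar(cds) - 1),
                                   cds))
  ins21 <- annotate_effect(g, 16214300 + 476, "T",
                           paste0("T", strrep("GCA", 7))) # 21-bp insertion
  expect_equal(ins21$effect_class, "inframe_indel")
  expect_equal(ins21$codon_index, 159L)
  expect_match(ins21$aa_change, "7-aa-ins")
  del2 <- annotate_effect(g, 16214300 + 476, "TGC", "T")
  expect_equal(del2$effect_class, "frameshift")
})

test_that("sites outside the CDS come back non-coding, not as errors", {
  g <- suppressWarnings(gene_model("g", "chr1", "+",
                                   data.frame(start = 101, end = 112),
                                   "ATGGCAGCTTAA"))
  eff <- annotate_effect(g, 300, "A", "G")
  expect_equal(eff$effect_class, "non_coding")
  expect_true(is.na(eff$cds_pos))
})

test_that("annotate_effect agrees with the full-CDS translation oracle", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  for (i in 1:300) {
    n_codons <- sample(5:60, 1)
    cds <- random_cds(n_codons)
    strand <- sample(c("+", "-"), 1)
    offset <- sample(1000:5000, 1)
    g <- suppressWarnings(gene_model("fz", "chr1", strand,
                                     data.frame(start = offset,
                                                end = offset + nchar(cds) - 1),
                                     cds))
    cpos <- sample(nchar(cds), 1)
    ref_cds_base <- substr(cds, cpos, cpos)
    alt_cds_base <- sample(setdiff(bases, ref_cds_base), 1)
    # genomic position and plus-strand alleles for this CDS edit
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (strand == "+") {
      gpos <- offset + cpos - 1
      ref_g <- ref_cds_base; alt_g <- alt_cds_base
    } else {
      gpos <- offset + nchar(cds) - cpos
      ref_g <- unname(comp[ref_cds_base]); alt_g <- unname(comp[alt_cds_base])
    }
    eff <- annotate_effect(g, gpos, ref_g, alt_g)
    orc <- oracle_effect(cds, cpos, alt_cds_base)
    expect_equal(eff$effect_class, orc$class)
    expect_equal(eff$codon_index, orc$codon_index)
    if (orc$class != "synonymous") {
      expect_equal(eff$ref_aa, orc$ref_aa)
      expect_equal(eff$alt_aa, orc$alt_aa)
    }
    expect_equal(eff$codon_index, ceiling(eff$cds_pos / 3))
  }
})

test_that("variant tables round-trip through VCF with per-sample AD", {
  cfg <- sim_config(seed = 31, n_chromosomes = 1, chrom_length_bp = 2e6,
                    marker_spacing_bp = 2e5,
                    qtls = tibble::tibble(chrom = 1L, pos = 1e6, effect = 10))
  truth <- simulate_bil_population(cfg)
  pa <- tibble::tibble(line = rownames(truth$genotypes)[1:6],
                       pool = rep(c("resistant", "susceptible"), 3))
  sites <- simulate_pool_seq(truth, pa)
  f <- tempfile(fileext = ".vcf")
  on.exit(unlink(f), add = TRUE)
  write_variants(sites, f)
  back <- read_variants(f)
  cols <- c("chrom", "pos", "ref_allele", "donor_allele", "sample",
            "ref_depth", "donor_depth")
  orig <- dplyr::arrange(sites[cols], chrom, pos, sample)
  got <- dplyr::arrange(back[cols], chrom, pos, sample)
  expect_equal(as.data.frame(got), as.data.frame(orig))
  expect_true(all(back$site_quality == 60))
  expect_true(all(back$base_quality == 40))
})

test_that("header-only VCF yields an empty collection; TSV path works", {
  f <- tempfile(fileext = ".vcf")
  on.exit(unlink(f), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"), f)
  expect_equal(nrow(read_variants(f)), 0)
  t <- tempfile(fileext = ".tsv")
  on.exit(unlink(t), add = TRUE)
  tab <- tibble::tibble(chrom = "chr1", pos = 10L, ref_allele = "A",
                        donor_allele = "G", sample = "p1",
                        ref_depth = 3L, donor_depth = 17L)
  readr::write_tsv(tab, t)
  got <- read_variants(t)
  expect_equal(got$ref_depth, 3L)
  expect_equal(got$donor_depth, 17L)
  expect_error(read_variants(tempfile()), class = "hopperqtl_data_error")
})

test_that("multiallelic records are skipped with a warning", {
  f <- tempfile(fileext = ".vcf")
  on.exit(unlink(f), add = TRUE)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:3,17",
    "chr1\t200\t.\tA\tG,T\t50\tPASS\t.\tGT:AD\t0/1:3,10,7"
  ), f)
  expect_warning(out <- read_variants(f), "multiallelic")
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 100L)
  expect_equal(out$ref_depth, 3L)
  expect_equal(out$donor_depth, 17L)
})

test_that("filter_sites applies the quality and coverage rules", {
  mk_site <- function(pos, sq = 60, bq = 40, d1 = 10, d2 = 10) {
    tibble::tibble(chrom = "chr1", pos = pos, ref_allele = "A",
                   donor_allele = "G", site_quality = sq, base_quality = bq,
                   sample = c("pool_resistant", "pool_susceptible"),
                   ref_depth = c(d1, d2), donor_depth = 0L)
  }
  sites <- dplyr::bind_rows(
    purrr::map_dfr(1:6 * 100, mk_site), # six clean sites
    mk_site(700, sq = 10),           # fails site quality
    mk_site(800, bq = 15),           # fails base quality
    mk_site(900, d1 = 5),            # fails depth in one pool
    mk_site(1000, d2 = 3)            # fails depth in the other pool
  )
  expect_message(kept <- filter_sites(sites), "6/10 sites retained")
  expect_equal(sort(unique(kept$pos)), 1:6 * 100)
  # identity filter at zero thresholds
  expect_message(all_kept <- filter_sites(sites, 0, 0, 0), "10/10")
  expect_equal(nrow(all_kept), nrow(sites))
  # output is a subset, independent of row order
  shuf <- sites[sample(nrow(sites)), ]
  expect_message(kept2 <- filter_sites(shuf), "6/10")
  expect_setequal(unique(kept2$pos), unique(kept$pos))
  expect_error(filter_sites(sites, min_depth = -1),
               class = "hopperqtl_config_error")
})
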