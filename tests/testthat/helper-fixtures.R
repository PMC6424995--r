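# fixture builders shared across test files; everything is generated in code

# random CDS of n_codons coding codons plus a stop, no internal stops
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codons <- names(Biostrings::GENETIC_CODE)
  coding <- codons[Biostrings::GENETIC_CODE != "*"]
  stops <- codons[Biostrings::GENETIC_CODE == "*"]
  paste0("ATG",
         paste(sample(coding, n_codons - 2, replace = TRUE), collapse = ""),
         sample(stops, 1))
}

# single-segment plus-strand gene carrying the given CDS at genomic offset
toy_gene <- function(cds, gene_id = "toy", chrom = "chr1", offset = 1000,
                     strand = "+") {
  n <- nchar(cds)
  seq_genomic <- if (strand == "+") cds else revcomp(cds)
  suppressWarnings(gene_model(
    gene_id, chrom, strand,
    data.frame(start = offset + 1, end = offset + n),
    cds
  ))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# full-CDS translation oracle: classify a substitution by translating the
# whole CDS before and after the edit and diffing the proteins
oracle_effect <- function(cds, cds_pos, alt_base) {
  mutated <- cds
  substr(mutated, cds_pos, cds_pos) <- alt_base
  p0 <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "X"))
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(mutated),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "X"))
  idx <- ceiling(cds_pos / 3)
  aa0 <- substr(p0, idx, idx); aa1 <- substr(p1, idx, idx)
  list(
    class = if (identical(p0, p1)) "synonymous"
            else if (aa1 == "*" && aa0 != "*") "stop_gained"
            else "missense",
    ref_aa = aa0, alt_aa = aa1, codon_index = idx
  )
}

# tiny deterministic BIL truth object without running the full simulator
manual_truth <- function(genotypes, positions = NULL, chrom = 1L) {
  n_mark <- ncol(genotypes)
  if (is.null(positions)) positions <- seq_len(n_mark) * 1e5
  markers <- tibble::tibble(
    marker = sprintf("M%03d", seq_len(n_mark)),
    chrom = chrom, pos = positions,
    ref_allele = rep("A", n_mark), donor_allele = rep("G", n_mark)
  )
  colnames(genotypes) <- markers$marker
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("L%02d", seq_len(nrow(genotypes)))
  }
  structure(
    list(genotypes = genotypes, markers = markers, qtl_index = integer(0),
         config = sim_config(seed = 1)),
    class = "sim_truth"
  )
}

# genotype dosage matrix -> allele-string tibble for mine_hp/painting
dosage_to_alleles <- function(truth, marker_idx) {
  mk <- truth$markers[marker_idx, ]
  out <- lapply(seq_along(marker_idx), function(k) {
    i <- marker_idx[k]
    c(mk$ref_allele[k], "H", mk$donor_allele[k])[truth$genotypes[, i] + 1]
  })
  names(out) <- mk$marker
  dplyr::bind_cols(tibble::tibble(line = rownames(truth$genotypes)),
                   tibble::as_tibble(out))
}

std_pools <- tibble::tibble(
  sample = c("pool_resistant", "pool_susceptible"),
  pool = c("resistant", "susceptible")
)

# inbred genotype vectors from two-locus haplotype class counts:
# each line is homozygous for one haplotype
geno_from_haps <- function(n_AB, n_Ab, n_aB, n_ab) {
  g1 <- c(rep(2, n_AB), rep(2, n_Ab), rep(0, n_aB), rep(0, n_ab))
  g2 <- c(rep(2, n_AB), rep(0, n_Ab), rep(2, n_aB), rep(0, n_ab))
  list(g1 = g1, g2 = g2)
}
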