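#' Construct a gene model for coding-effect annotation
#'
#' A gene model carries the ordered CDS segments of one transcript and the
#' spliced CDS sequence. Segments are given in genomic coordinates (1-based,
#' inclusive) and are reordered internally 5'->3' on the coding strand.
#'
#' @param gene_id locus identifier (e.g. `LOC_Os04g10800`).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param segments data frame with columns `start`, `end` (1-based inclusive,
#'   non-overlapping).
#' @param cds_seq spliced CDS sequence, 5'->3' on the coding strand; its
#'   length must equal the summed segment widths and be divisible by 3. A
#'   missing start codon triggers a warning, not an error.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, segments, cds_seq) {
  stopifnot(is.data.frame(segments), all(c("start", "end") %in% names(segments)))
  if (!strand %in% c("+", "-")) config_abort("strand", "must be '+' or '-'")
  segments <- segments[order(segments$start), c("start", "end")]
  if (any(segments$end < segments$start)) {
    config_abort("segments", "each segment needs end >= start")
  }
  if (nrow(segments) > 1 &&
      any(segments$start[-1] <= segments$end[-nrow(segments)])) {
    config_abort("segments", "CDS segments must not overlap")
  }
  cds_seq <- toupper(as.character(cds_seq))
  width <- sum(segments$end - segments$start + 1)
  if (nchar(cds_seq) != width) {
    config_abort("cds_seq", sprintf("length %d does not match segment span %d",
                                    nchar(cds_seq), width))
  }
  if (nchar(cds_seq) %% 3 != 0) {
    config_abort("cds_seq", "CDS length must be divisible by 3")
  }
  if (substr(cds_seq, 1, 3) != "ATG") {
    warn(sprintf("%s: CDS does not begin with ATG", gene_id))
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         segments = tibble::as_tibble(segments), cds_seq = cds_seq),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s%s, %d CDS segment(s), %d bp (%d aa + stop)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$segments),
              nchar(x$cds_seq), nchar(x$cds_seq) / 3 - 1))
  invisible(x)
}

#' Map a genomic position to its CDS coordinate
#'
#' Accumulates offsets across CDS segments in coding order; on the minus
#' strand, position 1 of the CDS is the 3'-most genomic base of the gene.
#'
#' @param gene a [gene_model()].
#' @param genomic_pos vector of 1-based genomic positions.
#' @return integer vector of 1-based CDS positions; `NA` where the position
#'   is intronic or outside the gene (non-coding).
#' @export
cds_coordinate <- function(gene, genomic_pos) {
  stopifnot(inherits(gene, "gene_model"))
  seg <- gene$segments
  w <- seg$end - seg$start + 1
  before <- cumsum(c(0, w))[seq_len(nrow(seg))]
  vapply(genomic_pos, function(p) {
    i <- which(p >= seg$start & p <= seg$end)
    if (!length(i)) return(NA_integer_)
    if (gene$strand == "+") {
      as.integer(before[i] + (p - seg$start[i] + 1))
    } else {
      # coding order runs from the last genomic segment backwards
      after <- rev(cumsum(c(0, rev(w))))[-1]
      as.integer(after[i] + (seg$end[i] - p + 1))
    }
  }, integer(1))
}

#' Annotate the coding effect of a variant on a gene model
#'
#' For SNPs, the affected codon is translated before and after substitution
#' with the standard genetic code: identical amino acids give `synonymous`, a
#' gained stop gives `stop_gained`, any other change `missense`. Indels whose
#' length change is divisible by 3 are `inframe_indel`, otherwise
#' `frameshift`. Alleles are supplied on the plus genomic strand and are
#' complemented internally for minus-strand genes. Positions outside the CDS
#' return a `non_coding` row rather than an error.
#'
#' @param gene a [gene_model()].
#' @param pos 1-based genomic position of the variant (for indels, the
#'   position of the first affected base).
#' @param ref_allele,donor_allele reference and donor allele strings on the
#'   plus strand (equal-length 1 for SNPs; an insertion has
#'   `nchar(donor) > nchar(ref)`).
#' @return a one-row tibble: `gene_id`, `pos`, `cds_pos`, `cds_length`,
#'   `codon_index` (`ceiling(cds_pos / 3)`), `ref_aa`, `alt_aa`,
#'   `effect_class`, `protein_length` (`cds_length / 3 - 1`, stop codon
#'   excluded) and an `aa_change` label like `"A>P 190/508"`.
#' @examples
#' g <- gene_model("toy", "chr1", "+",
#'                 data.frame(start = 101, end = 112), "ATGGCAGCTTAA")
#' annotate_effect(g, 105, "C", "G")
#' @export
annotate_effect <- function(gene, pos, ref_allele, donor_allele) {
  stopifnot(inherits(gene, "gene_model"))
  cds_len <- nchar(gene$cds_seq)
  prot_len <- cds_len / 3 - 1
  cpos <- cds_coordinate(gene, pos)
  base_row <- tibble::tibble(
    gene_id = gene$gene_id, pos = pos, cds_pos = cpos,
    cds_length = cds_len, codon_index = NA_integer_,
    ref_aa = NA_character_, alt_aa = NA_character_,
    effect_class = NA_character_, protein_length = prot_len,
    aa_change = NA_character_
  )
  if (is.na(cpos)) {
    base_row$effect_class <- "non_coding"
    return(base_row)
  }
  ref_allele <- toupper(ref_allele)
  donor_allele <- toupper(donor_allele)
  codon_index <- as.integer(ceiling(cpos / 3))
  base_row$codon_index <- codon_index

  if (nchar(ref_allele) != nchar(donor_allele)) {
    shift <- abs(nchar(donor_allele) - nchar(ref_allele))
    base_row$effect_class <- if (shift %% 3 == 0) "inframe_indel" else "frameshift"
    base_row$aa_change <- sprintf("%s %d/%d",
                                  if (shift %% 3 == 0) {
                                    sprintf("%d-aa-%s", shift %/% 3,
                                            if (nchar(donor_allele) > nchar(ref_allele)) "ins" else "del")
                                  } else "frameshift",
                                  codon_index, prot_len)
    return(base_row)
  }
  if (nchar(ref_allele) != 1L) {
    data_abort("multi-base substitutions are not supported (%s>%s)",
               ref_allele, donor_allele)
  }
  if (gene$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    ref_allele <- unname(comp[ref_allele])
    donor_allele <- unname(comp[donor_allele])
  }
  if (substr(gene$cds_seq, cpos, cpos) != ref_allele) {
    warn(sprintf("%s: CDS base at cds_pos %d is %s, not the stated reference %s",
                 gene$gene_id, cpos, substr(gene$cds_seq, cpos, cpos), ref_allele))
  }
  codon_start <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(gene$cds_seq, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cpos - codon_start + 1L, cpos - codon_start + 1L) <- donor_allele
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  eff <- if (ref_aa == alt_aa) "synonymous"
         else if (alt_aa == "*" && ref_aa != "*") "stop_gained"
         else "missense"
  base_row$ref_aa <- ref_aa
  base_row$alt_aa <- alt_aa
  base_row$effect_class <- eff
  base_row$aa_change <- if (eff == "synonymous") {
    sprintf("%d/%d", codon_index, prot_len)
  } else if (eff == "stop_gained") {
    sprintf("stop codon %d/%d", codon_index, prot_len)
  } else {
    sprintf("%s>%s %d/%d", ref_aa, alt_aa, codon_index, prot_len)
  }
  base_row
}

# standard genetic code via Biostrings; "*" for stop
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Annotate many sites against a list of gene models
#'
#' @param sites data frame with `chrom`, `pos`, `ref_allele`, `donor_allele`
#'   (one row per site; per-sample depth rows should be deduplicated first).
#' @param genes list of [gene_model()] objects.
#' @return a tibble of [annotate_effect()] rows for every site falling in a
#'   gene's CDS footprint (sites hitting no gene are returned with
#'   `effect_class = "intergenic"` and `gene_id = NA`).
#' @export
annotate_effects <- function(sites, genes) {
  stopifnot(is.data.frame(sites))
  sites <- dplyr::distinct(sites, .data$chrom, .data$pos,
                           .data$ref_allele, .data$donor_allele)
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    row <- sites[i, ]
    hits <- purrr::keep(genes, function(g) {
      g$chrom == row$chrom && any(row$pos >= g$segments$start & row$pos <= g$segments$end)
    })
    if (!length(hits)) {
      return(tibble::tibble(
        gene_id = NA_character_, pos = row$pos, cds_pos = NA_integer_,
        cds_length = NA_integer_, codon_index = NA_integer_,
        ref_aa = NA_character_, alt_aa = NA_character_,
        effect_class = "intergenic", protein_length = NA_real_,
        aa_change = NA_character_, chrom = row$chrom
      ))
    }
    purrr::map_dfr(hits, annotate_effect, pos = row$pos,
                   ref_allele = row$ref_allele,
                   donor_allele = row$donor_allele) %>%
      dplyr::mutate(chrom = row$chrom)
  }) %>%
    dplyr::relocate("chrom")
}

#' Read variant allele depths
#'
#' Reads a VCF 4.x file with per-sample `AD` (ref,alt depth) fields, or a
#' tabular TSV with columns `chrom`, `pos`, `ref_allele`, `donor_allele`,
#'   `sample`, `ref_depth`, `donor_depth` (optional `site_quality`,
#'   `base_quality`). Multiallelic VCF records are skipped with a warning:
#' the analysis is strictly biallelic.
#'
#' @param path input file; `.vcf` extension selects VCF parsing.
#' @return a long tibble, one row per site x sample: `chrom`, `pos`,
#'   `ref_allele`, `donor_allele`, `site_quality`, `base_quality`, `sample`,
#'   `ref_depth`, `donor_depth`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) data_abort("file not found: %s", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_variants_vcf(path)
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("chrom", "pos", "ref_allele", "donor_allele",
              "sample", "ref_depth", "donor_depth")
    missing <- setdiff(need, names(tab))
    if (length(missing)) {
      data_abort("variant table lacks column(s): %s", paste(missing, collapse = ", "))
    }
    if (!"site_quality" %in% names(tab)) tab$site_quality <- NA_real_
    if (!"base_quality" %in% names(tab)) tab$base_quality <- NA_real_
    tibble::as_tibble(tab[c(need[1:4], "site_quality", "base_quality", need[5:7])])
  }
}

read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), ref_allele = character(),
      donor_allele = character(), site_quality = double(),
      base_quality = double(), sample = character(),
      ref_depth = integer(), donor_depth = integer()
    ))
  }
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warn(sprintf("skipping %d multiallelic record(s)", sum(multi)))
  }
  fmt <- v@gt[, 1]
  has_ad <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "AD" %in% f, logical(1))
  if (!all(has_ad)) {
    data_abort("record(s) without AD field (first at %s:%s)",
               fix$CHROM[!has_ad][1], fix$POS[!has_ad][1])
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  bq <- suppressWarnings(vcfR::extract.info(v, element = "BQ", as.numeric = TRUE))
  keep <- which(!multi)
  out <- purrr::map_dfr(colnames(ad), function(s) {
    parts <- strsplit(ad[keep, s], ",", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) {
      data_abort("malformed AD for sample %s at %s:%s", s,
                 fix$CHROM[keep][bad][1], fix$POS[keep][bad][1])
    }
    m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
    tibble::tibble(
      chrom = fix$CHROM[keep],
      pos = as.integer(fix$POS[keep]),
      ref_allele = fix$REF[keep],
      donor_allele = fix$ALT[keep],
      site_quality = suppressWarnings(as.numeric(fix$QUAL[keep])),
      base_quality = if (is.null(bq)) NA_real_ else bq[keep],
      sample = s,
      ref_depth = m[, 1],
      donor_depth = m[, 2]
    )
  })
  dplyr::arrange(out, .data$chrom, .data$pos, .data$sample)
}

#' Write variant allele depths as VCF 4.2
#'
#' Emits a minimal plain-text VCF with `QUAL` from `site_quality`, an
#' `INFO/BQ` base-quality annotation and per-sample `GT:AD` fields, so that
#' [read_variants()] round-trips every site.
#'
#' @param sites long tibble as produced by [read_variants()] or
#'   [simulate_pool_seq()].
#' @param path output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_variants <- function(sites, path) {
  stopifnot(is.data.frame(sites))
  samples <- unique(sites$sample)
  wide <- sites %>%
    dplyr::mutate(ad = paste0("0/1:", .data$ref_depth, ",", .data$donor_depth)) %>%
    dplyr::select("chrom", "pos", "ref_allele", "donor_allele",
                  "site_quality", "base_quality", "sample", "ad") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "ad") %>%
    dplyr::arrange(.data$chrom, .data$pos)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Minimum supporting base quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(
    wide$chrom, wide$pos, ".", wide$ref_allele, wide$donor_allele,
    ifelse(is.na(wide$site_quality), ".", format(wide$site_quality, trim = TRUE)),
    "PASS",
    ifelse(is.na(wide$base_quality), ".",
           paste0("BQ=", format(wide$base_quality, trim = TRUE))),
    "GT:AD",
    do.call(paste, c(unname(as.list(wide[samples])), list(sep = "\t"))),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter variant sites on quality and coverage
#'
#' Retains sites with `site_quality >= min_site_quality`,
#' `base_quality >= min_base_quality`, and total depth
#' `>= min_depth` in every sample/pool (a site failing coverage in any
#' pool is dropped everywhere, since the downstream delta-SNP-index needs
#' both pools). Missing quality values pass. Filter counts are reported via
#' a message.
#'
#' @param sites long tibble from [read_variants()].
#' @param min_site_quality,min_base_quality,min_depth thresholds (defaults
#'   15, 20, 6 — a Phred-15 site filter, Q20 base filter and the 6x
#'   reduced-representation coverage floor).
#' @return the retained subset of `sites`, same columns.
#' @export
filter_sites <- function(sites, min_site_quality = 15, min_base_quality = 20,
                         min_depth = 6) {
  stopifnot(is.data.frame(sites))
  if (min_site_quality < 0 || min_base_quality < 0 || min_depth < 0) {
    config_abort("thresholds", "must be non-negative")
  }
  if (nrow(sites) == 0) return(sites)
  keyed <- sites %>%
    dplyr::group_by(.data$chrom, .data$pos) %>%
    dplyr::mutate(
      .fail_sq = any(!is.na(.data$site_quality) & .data$site_quality < min_site_quality),
      .fail_bq = any(!is.na(.data$base_quality) & .data$base_quality < min_base_quality),
      .fail_dp = any(.data$ref_depth + .data$donor_depth < min_depth)
    ) %>%
    dplyr::ungroup()
  n_sites <- nrow(dplyr::distinct(sites, .data$chrom, .data$pos))
  fails <- dplyr::distinct(keyed, .data$chrom, .data$pos,
                           .data$.fail_sq, .data$.fail_bq, .data$.fail_dp)
  inform(sprintf(
    "filter_sites: %d/%d sites retained (%d fail site quality, %d base quality, %d depth)",
    sum(!(fails$.fail_sq | fails$.fail_bq | fails$.fail_dp)), n_sites,
    sum(fails$.fail_sq), sum(fails$.fail_bq), sum(fails$.fail_dp)
  ))
  keyed %>%
    dplyr::filter(!.data$.fail_sq, !.data$.fail_bq, !.data$.fail_dp) %>%
    dplyr::select(-dplyr::starts_with(".fail_"))
}
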