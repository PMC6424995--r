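#' Mine haplotype patterns (HPs) for one gene
#'
#' A haplotype pattern is the ordered vector of marker alleles a line carries
#' across the markers of a single gene. The wild-type line's vector is always
#' HP1; remaining patterns (observed among lines with complete calls) are
#' numbered by descending member count, ties broken lexicographically by the
#' collapsed allele vector. Heterozygous calls (`"H"`) are a distinct allele
#' state, never collapsed to a homozygote. A line with missing calls (`"-"`
#' or `NA`) is assigned to a pattern only when its non-missing alleles match
#' exactly one mined pattern; otherwise it stays unassigned (`hp_number` NA).
#'
#' @param genotypes a data frame with a `line` column followed by one column
#'   per marker of this gene, in map order, holding allele strings (`"H"` for
#'   heterozygous, `"-"` or `NA` for missing).
#' @param wt_line id of the wild-type line; it must have a complete vector.
#' @param gene optional gene id label carried into the output.
#' @return a tibble with one row per line: `gene`, `line`, `hp_number`
#'   (integer, NA when unassignable), `pattern` (alleles collapsed with
#'   `"/"`).
#' @export
mine_hp <- function(genotypes, wt_line, gene = NA_character_) {
  stopifnot(is.data.frame(genotypes), "line" %in% names(genotypes))
  marker_cols <- setdiff(names(genotypes), "line")
  if (length(marker_cols) == 0) data_abort("no marker columns in `genotypes`")
  if (!wt_line %in% genotypes$line) {
    data_abort("wild-type line '%s' not present in genotype table", wt_line)
  }
  g <- as.matrix(genotypes[marker_cols])
  mode(g) <- "character"
  g[g %in% c("-", "")] <- NA_character_
  rownames(g) <- as.character(genotypes$line)

  wt_vec <- g[as.character(wt_line), , drop = TRUE]
  if (anyNA(wt_vec)) {
    data_abort("wild-type line '%s' has missing calls; HP1 is undefined", wt_line)
  }

  collapse <- function(v) paste(v, collapse = "/")
  complete <- !apply(g, 1L, anyNA)
  pat <- apply(g, 1L, collapse)
  wt_pat <- collapse(wt_vec)

  # patterns observed among complete lines, WT first, then count desc / lexicographic
  tab <- table(pat[complete])
  others <- setdiff(names(tab), wt_pat)
  others <- others[order(-tab[others], others)]
  hp_levels <- c(wt_pat, others)
  hp_of <- stats::setNames(seq_along(hp_levels), hp_levels)

  assign_one <- function(i) {
    if (complete[i]) return(unname(hp_of[pat[i]]))
    v <- g[i, ]
    keep <- !is.na(v)
    if (!any(keep)) return(NA_integer_)
    hits <- which(vapply(
      hp_levels,
      function(p) all(strsplit(p, "/", fixed = TRUE)[[1]][keep] == v[keep]),
      logical(1)
    ))
    if (length(hits) == 1L) unname(hp_of[hp_levels[hits]]) else NA_integer_
  }
  hp_num <- vapply(seq_len(nrow(g)), assign_one, integer(1))

  tibble::tibble(
    gene = gene,
    line = genotypes$line,
    hp_number = hp_num,
    pattern = ifelse(is.na(hp_num), NA_character_, hp_levels[hp_num])
  )
}

#' Summarise mined haplotype patterns
#'
#' @param assignments the per-line tibble returned by [mine_hp()].
#' @return a tibble with one row per HP: `gene`, `hp_number`, `pattern`,
#'   `n_members`, `frequency` (fraction of assigned lines) and `members`
#'   (comma-collapsed line ids).
#' @export
hp_table <- function(assignments) {
  stopifnot(is.data.frame(assignments))
  assigned <- dplyr::filter(assignments, !is.na(.data$hp_number))
  assigned %>%
    dplyr::group_by(.data$gene, .data$hp_number, .data$pattern) %>%
    dplyr::summarise(
      n_members = dplyr::n(),
      members = paste(.data$line, collapse = ","),
      .groups = "drop"
    ) %>%
    dplyr::mutate(frequency = .data$n_members / sum(.data$n_members)) %>%
    dplyr::arrange(.data$hp_number) %>%
    dplyr::select("gene", "hp_number", "pattern", "n_members", "frequency", "members")
}

#' Damage-reducing ratio
#'
#' DRR of a haplotype pattern is its mean damage AUC divided by the mean
#' damage AUC of the wild-type pattern within the same BPH population.
#' Values below 1 mean the pattern reduces damage (confers resistance);
#' above 1, it increases damage. Reported to three decimals.
#'
#' @param mean_auc_hp mean AUC of the pattern of interest (vectorised).
#' @param mean_auc_wt mean AUC of the wild-type pattern; must be positive.
#' @return numeric ratio(s) rounded to 3 decimals.
#' @examples
#' drr(28.333, 52.923) # 0.535
#' @export
drr <- function(mean_auc_hp, mean_auc_wt) {
  if (any(!is.finite(mean_auc_wt)) || any(mean_auc_wt <= 0)) {
    data_abort("wild-type mean AUC must be positive and finite")
  }
  round(mean_auc_hp / mean_auc_wt, 3)
}

#' Paint donor introgression segments from marker genotypes
#'
#' Classifies every informative marker of every line as donor, recipient or
#' heterozygous by comparison with the two parental lines, then merges
#' maximal runs of one class into segments. Segment boundaries between
#' adjacent markers of differing class are placed at the midpoint of the two
#' marker positions; terminal boundaries sit on the first/last informative
#' marker. Markers monomorphic between the parents are dropped with a
#' warning.
#'
#' @param genotypes data frame: `line` column plus one column per marker
#'   (allele strings, `"H"` het, `"-"`/`NA` missing). Must include the two
#'   parental lines.
#' @param marker_map data frame with `marker`, `chrom`, `pos` for every
#'   marker column.
#' @param donor_line,recipient_line parental line ids.
#' @return a tibble of segments: `line`, `chrom`, `start`, `end`, `origin`
#'   (`donor`/`recipient`/`heterozygous`/`unknown`), `n_markers`, ordered and
#'   non-overlapping within each line x chromosome.
#' @export
paint_introgression <- function(genotypes, marker_map, donor_line, recipient_line) {
  stopifnot(is.data.frame(genotypes), "line" %in% names(genotypes))
  marker_cols <- setdiff(names(genotypes), "line")
  if (!all(marker_cols %in% marker_map$marker)) {
    data_abort("marker_map does not cover every marker column")
  }
  for (p in c(donor_line, recipient_line)) {
    if (!p %in% genotypes$line) data_abort("parental line '%s' absent", p)
  }
  g <- as.matrix(genotypes[marker_cols]); mode(g) <- "character"
  g[g %in% c("-", "")] <- NA_character_
  rownames(g) <- as.character(genotypes$line)
  don <- g[as.character(donor_line), ]
  rec <- g[as.character(recipient_line), ]

  poly <- !is.na(don) & !is.na(rec) & don != rec & don != "H" & rec != "H"
  if (!all(poly)) {
    warn(sprintf("dropping %d marker(s) uninformative between parents",
                 sum(!poly)))
  }
  if (!any(poly)) data_abort("no informative markers between parents")
  keep <- marker_cols[poly]

  mm <- marker_map[match(keep, marker_map$marker), ]
  ord <- order(mm$chrom, mm$pos)
  keep <- keep[ord]; mm <- mm[ord, ]
  don <- don[keep]; rec <- rec[keep]

  lines <- setdiff(rownames(g), c(as.character(donor_line), as.character(recipient_line)))
  purrr::map_dfr(c(as.character(donor_line), as.character(recipient_line), lines), function(ln) {
    calls <- g[ln, keep]
    cls <- dplyr::case_when(
      is.na(calls) ~ "unknown",
      calls == "H" ~ "heterozygous",
      calls == don ~ "donor",
      calls == rec ~ "recipient",
      TRUE ~ "unknown"
    )
    purrr::map_dfr(unique(mm$chrom), function(ch) {
      idx <- which(mm$chrom == ch)
      if (!length(idx)) return(NULL)
      pos <- mm$pos[idx]; cc <- cls[idx]
      r <- rle(cc)
      ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1L
      # midpoint boundaries between runs; terminal bounds at outermost markers
      bounds <- c(pos[1], (pos[ends_i[-length(ends_i)]] + pos[starts_i[-1]]) / 2,
                  pos[length(pos)])
      tibble::tibble(
        line = ln, chrom = ch,
        start = bounds[-length(bounds)], end = bounds[-1],
        origin = r$values, n_markers = r$lengths
      )
    })
  })
}

#' Per-line donor genome summary from painted segments
#'
#' @param segments output of [paint_introgression()].
#' @return a tibble per line: total painted span, donor span (heterozygous
#'   segments counted half) and donor fraction of the painted span.
#' @export
introgression_summary <- function(segments) {
  segments %>%
    dplyr::group_by(.data$line) %>%
    dplyr::summarise(
      painted_bp = sum(.data$end - .data$start),
      donor_bp = sum((.data$end - .data$start) *
                       (.data$origin == "donor") +
                       0.5 * (.data$end - .data$start) * (.data$origin == "heterozygous")),
      donor_fraction = ifelse(.data$painted_bp > 0,
                              .data$donor_bp / .data$painted_bp, NA_real_),
      .groups = "drop"
    )
}
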