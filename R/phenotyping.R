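#' Trapezoid-rule area under a damage-score curve
#'
#' Integrates an ordered series of daily seedling damage scores (SES 1-9
#' scale) by the trapezoid rule, the standard summary for brown planthopper
#' screens: `auc = sum((s[i] + s[i+1]) / 2 * day_spacing)`. Lower AUC means
#' less cumulative damage, i.e. a more resistant line.
#'
#' @param scores numeric vector of daily damage scores, length >= 2, each in
#'   `[0, 9]`.
#' @param day_spacing time between consecutive scores in days (default 1).
#' @return a single numeric AUC in score-days. A constant series `s` over `n`
#'   days gives `s * (n - 1) * day_spacing`, so a 5-day screen maxes out at 36
#'   and an 8-day screen at 63.
#' @examples
#' auc_trapezoid(c(1, 3, 5, 7, 9)) # 20
#' auc_trapezoid(rep(9, 5))        # 36
#' @export
auc_trapezoid <- function(scores, day_spacing = 1) {
  if (length(scores) < 2) {
    data_abort("damage series has %d score(s); AUC needs at least 2 daily scores",
               length(scores))
  }
  if (anyNA(scores) || any(scores < 0 | scores > 9)) {
    data_abort("damage scores must be non-missing and within [0, 9]")
  }
  if (!is.numeric(day_spacing) || day_spacing <= 0) {
    config_abort("day_spacing", "must be a positive number")
  }
  n <- length(scores)
  sum((scores[-n] + scores[-1]) / 2) * day_spacing
}

#' Compute damage AUC for every line x population x replicate record
#'
#' Takes the wide phenotype layout (`line`, `population`, `replicate`,
#' `d1..dN`) produced by [read_damage_scores()] or
#' [simulate_damage_scores()] and reduces each daily series to its
#' trapezoid-rule AUC.
#'
#' @param scores a data frame with identifier columns `line`, `population`,
#'   `replicate` and one numeric column per scoring day named `d1`, `d2`, ...
#' @param day_spacing time between consecutive scores in days.
#' @return a tibble with columns `line`, `population`, `replicate`, `n_days`,
#'   `auc`.
#' @export
damage_auc <- function(scores, day_spacing = 1) {
  stopifnot(is.data.frame(scores))
  day_cols <- grep("^d[0-9]+$", names(scores), value = TRUE)
  if (length(day_cols) < 2) {
    data_abort("found %d day column(s) (d1, d2, ...); need at least 2",
               length(day_cols))
  }
  day_cols <- day_cols[order(as.integer(sub("^d", "", day_cols)))]
  mat <- as.matrix(scores[day_cols])
  scores %>%
    dplyr::select(dplyr::all_of(c("line", "population", "replicate"))) %>%
    tibble::as_tibble() %>%
    dplyr::mutate(
      n_days = length(day_cols),
      auc = apply(mat, 1L, auc_trapezoid, day_spacing = day_spacing)
    )
}

#' Cross-population mean AUC per line
#'
#' Replicates are first averaged to one AUC per line x population; the
#' per-population means are then averaged with equal weight per population
#' and reported to one decimal, the convention used for parental and BIL
#' summaries (e.g. a susceptible recipient around 34.6 and a resistant donor
#' around 11.3 over six populations).
#'
#' @param auc a data frame with columns `line`, `population`, `auc`
#'   (replicate-level rows allowed; a `replicate` column is ignored).
#' @return a tibble with `line`, `n_populations`, `mean_auc` (rounded to one
#'   decimal), sorted by `line`.
#' @export
average_auc <- function(auc) {
  stopifnot(is.data.frame(auc))
  if (nrow(auc) == 0) data_abort("no AUC records supplied")
  auc %>%
    dplyr::group_by(.data$line, .data$population) %>%
    dplyr::summarise(pop_auc = mean(.data$auc), .groups = "drop") %>%
    dplyr::group_by(.data$line) %>%
    dplyr::summarise(
      n_populations = dplyr::n(),
      mean_auc = round(mean(.data$pop_auc), 1)
    ) %>%
    dplyr::arrange(.data$line)
}

#' Select extreme lines for resistant and susceptible pools
#'
#' Picks the `n_resistant` lowest-AUC lines (least damaged) and the
#' `n_susceptible` highest-AUC lines for bulked-segregant pools. Ties are
#' broken by ascending line id, so membership is deterministic and invariant
#' to input row order.
#'
#' @param auc_summary a data frame with columns `line` and `mean_auc` (one
#'   row per line), e.g. the output of [average_auc()].
#' @param n_resistant,n_susceptible pool sizes; their sum must not exceed the
#'   number of lines.
#' @return a tibble with columns `line`, `mean_auc`, `pool`
#'   (`"resistant"`/`"susceptible"`), containing only selected lines.
#' @export
select_extremes <- function(auc_summary, n_resistant, n_susceptible) {
  stopifnot(is.data.frame(auc_summary))
  if (anyDuplicated(auc_summary$line)) {
    data_abort("`auc_summary` must have one row per line")
  }
  n <- nrow(auc_summary)
  if (n_resistant < 0 || n_susceptible < 0) {
    config_abort("n_resistant/n_susceptible", "pool sizes must be non-negative")
  }
  if (n_resistant + n_susceptible > n) {
    data_abort("requested %d + %d pool members from only %d lines",
               n_resistant, n_susceptible, n)
  }
  ord_r <- auc_summary[order(auc_summary$mean_auc, auc_summary$line), ]
  res <- utils::head(ord_r, n_resistant)
  remaining <- auc_summary[!(auc_summary$line %in% res$line), ]
  ord_s <- remaining[order(-remaining$mean_auc, remaining$line), ]
  sus <- utils::head(ord_s, n_susceptible)
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(res[c("line", "mean_auc")]), pool = "resistant"),
    dplyr::mutate(tibble::as_tibble(sus[c("line", "mean_auc")]), pool = "susceptible")
  )
}

#' Read a phenotype score table
#'
#' Expects the tab-separated layout `line`, `population`, `replicate`,
#' `d1..dN` with one damage score column per day.
#'
#' @param path path to a TSV file.
#' @return a tibble in the wide daily-score layout.
#' @export
read_damage_scores <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write AUC tables
#'
#' @param auc a data frame of per-replicate or per-line AUC values.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_auc <- function(auc, path) {
  readr::write_tsv(auc, path, progress = FALSE)
  invisible(path)
}
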