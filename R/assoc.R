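#' Single-marker association with damage AUC
#'
#' One-way ANOVA / simple linear regression of line AUC on a marker
#' genotype. A numeric genotype column is treated as allele dosage and fit
#' by regression; a character/factor column as unordered classes by one-way
#' ANOVA. In the two-class case the two routes give identical
#' `PVE = 100 * SSB/SST = 100 * R^2` and the ANOVA F equals the squared
#' pooled-variance t statistic.
#'
#' @param data a data frame with one row per line.
#' @param genotype,auc column names (unquoted) holding the marker genotype
#'   and the line AUC.
#' @param marker optional marker id label.
#' @return an object of class `hopper_assoc`; see [tidy.hopper_assoc()] for
#'   per-group summaries and [glance.hopper_assoc()] for the fit statistics.
#' @export
single_marker_assoc <- function(data, genotype = genotype, auc = auc,
                                marker = NA_character_) {
  stopifnot(is.data.frame(data))
  g <- dplyr::pull(data, {{ genotype }})
  y <- dplyr::pull(data, {{ auc }})
  if (length(g) != length(y)) data_abort("genotype and AUC lengths differ")
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]; y <- y[keep]
  if (length(y) < 3) data_abort("need at least 3 observations")
  classes <- unique(g)
  if (length(classes) < 2) {
    abort("marker has a single genotype class; no variation to test",
          class = "hopperqtl_no_variation")
  }
  numeric_geno <- is.numeric(g)
  fit <- if (numeric_geno) stats::lm(y ~ g) else stats::lm(y ~ factor(g))
  a <- stats::anova(fit)
  p <- a[["Pr(>F)"]][1]
  pve <- 100 * summary(fit)$r.squared
  groups <- tibble::tibble(group = as.character(g), auc = y) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(mean_auc = mean(.data$auc), n = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::arrange(.data$group)
  structure(
    list(marker = marker, fit = fit, groups = groups, p_value = p,
         pve = pve, n = length(y),
         model = if (numeric_geno) "regression" else "anova"),
    class = "hopper_assoc"
  )
}

signif_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' @export
print.hopper_assoc <- function(x, ...) {
  cat(sprintf("<hopper_assoc> %s (%s): P = %.4g%s, PVE = %.1f%%, n = %d\n",
              x$marker, x$model, x$p_value, signif_stars(x$p_value),
              x$pve, x$n))
  print(x$groups)
  invisible(x)
}

#' Tidy a single-marker association fit
#'
#' @param x a `hopper_assoc` object.
#' @param ... unused.
#' @return a tibble with one row per genotype class: `marker`, `group`,
#'   `mean_auc`, `n`.
#' @method tidy hopper_assoc
#' @export
tidy.hopper_assoc <- function(x, ...) {
  dplyr::mutate(x$groups, marker = x$marker, .before = 1)
}

#' One-row summary of a single-marker association fit
#'
#' @param x a `hopper_assoc` object.
#' @param ... unused.
#' @return a tibble: `marker`, `p_value`, `pve`, `stars`, `n_groups`, `n`,
#'   `model`.
#' @method glance hopper_assoc
#' @export
glance.hopper_assoc <- function(x, ...) {
  tibble::tibble(marker = x$marker, p_value = x$p_value, pve = x$pve,
                 stars = signif_stars(x$p_value),
                 n_groups = nrow(x$groups), n = x$n, model = x$model)
}

#' Haplotype-pattern association with damage AUC
#'
#' One-way ANOVA of line AUC across the haplotype patterns of one gene
#' within one BPH population. Every non-wild-type HP is compared with the
#' wild-type pattern (pairwise t test on the pooled ANOVA variance), and the
#' damage-reducing ratio (DRR, [drr()]) is reported for HPs whose pairwise
#' comparison is significant at `alpha`.
#'
#' @param data a data frame with columns `hp_number` and `auc`, one row per
#'   line (lines with `NA` `hp_number` are dropped).
#' @param wt_hp wild-type HP number (default 1). If absent from the data,
#'   DRRs are skipped with a warning and only the ANOVA is reported.
#' @param alpha significance level for flagging HPs (default 0.05).
#' @param gene,population optional labels.
#' @return an object of class `hopper_hp_assoc` with [tidy()] /[glance()]
#'   methods.
#' @export
hp_assoc <- function(data, wt_hp = 1, alpha = 0.05, gene = NA_character_,
                     population = NA_character_) {
  stopifnot(is.data.frame(data), all(c("hp_number", "auc") %in% names(data)))
  d <- dplyr::filter(data, !is.na(.data$hp_number), !is.na(.data$auc))
  hps <- sort(unique(d$hp_number))
  if (length(hps) < 2) data_abort("need at least 2 haplotype patterns")
  fit <- stats::lm(auc ~ factor(hp_number), data = d)
  a <- stats::anova(fit)
  p <- a[["Pr(>F)"]][1]
  pve <- 100 * summary(fit)$r.squared
  mse <- a["Residuals", "Mean Sq"]
  df_res <- a["Residuals", "Df"]
  groups <- d %>%
    dplyr::group_by(.data$hp_number) %>%
    dplyr::summarise(mean_auc = mean(.data$auc), n = dplyr::n(),
                     .groups = "drop")
  has_wt <- wt_hp %in% groups$hp_number
  if (!has_wt) warn(sprintf("wild-type HP %s absent; DRR skipped", wt_hp))
  wt_mean <- if (has_wt) groups$mean_auc[groups$hp_number == wt_hp] else NA_real_
  wt_n <- if (has_wt) groups$n[groups$hp_number == wt_hp] else NA_integer_
  groups <- groups %>%
    dplyr::mutate(
      p_vs_wt = ifelse(
        rep(has_wt, dplyr::n()) & .data$hp_number != wt_hp & df_res > 0 & mse > 0,
        2 * stats::pt(-abs((.data$mean_auc - wt_mean) /
                             sqrt(mse * (1 / .data$n + 1 / wt_n))), df_res),
        NA_real_),
      significant = !is.na(.data$p_vs_wt) & .data$p_vs_wt < alpha,
      drr = if (has_wt && is.finite(wt_mean) && wt_mean > 0) {
        ifelse(.data$significant, drr(.data$mean_auc, wt_mean), NA_real_)
      } else NA_real_
    )
  structure(
    list(gene = gene, population = population, fit = fit, groups = groups,
         p_value = p, pve = pve, n = nrow(d), wt_hp = wt_hp,
         has_wt = has_wt),
    class = "hopper_hp_assoc"
  )
}

#' @export
print.hopper_hp_assoc <- function(x, ...) {
  cat(sprintf("<hopper_hp_assoc> %s / %s: P = %.4g%s, PVE = %.1f%%, n = %d\n",
              x$gene, x$population, x$p_value, signif_stars(x$p_value),
              x$pve, x$n))
  print(x$groups)
  invisible(x)
}

#' Tidy an HP association fit
#'
#' @param x a `hopper_hp_assoc` object.
#' @param ... unused.
#' @return per-HP tibble: `gene`, `population`, `hp_number`, `mean_auc`,
#'   `n`, `p_vs_wt`, `significant`, `drr`.
#' @method tidy hopper_hp_assoc
#' @export
tidy.hopper_hp_assoc <- function(x, ...) {
  dplyr::mutate(x$groups, gene = x$gene, population = x$population,
                .before = 1)
}

#' One-row summary of an HP association fit
#'
#' @param x a `hopper_hp_assoc` object.
#' @param ... unused.
#' @return tibble: `gene`, `population`, `p_value`, `pve`, `stars`,
#'   `n_hps`, `n`.
#' @method glance hopper_hp_assoc
#' @export
glance.hopper_hp_assoc <- function(x, ...) {
  tibble::tibble(gene = x$gene, population = x$population,
                 p_value = x$p_value, pve = x$pve,
                 stars = signif_stars(x$p_value),
                 n_hps = nrow(x$groups), n = x$n)
}

#' Tukey HSD compact letter display
#'
#' Runs all pairwise Tukey honest-significant-difference comparisons across
#' groups and summarises them as letters via the insert-and-absorb
#' compact-letter-display algorithm: two groups share at least one letter
#' if and only if their pairwise test is non-significant. With zero pooled
#' variance, groups with unequal means are all declared distinct.
#'
#' @param data a data frame.
#' @param group,value unquoted column names of the grouping labels and the
#'   response.
#' @param alpha significance level (default 0.05).
#' @return a tibble ordered by descending group mean: `group`, `mean`, `n`,
#'   `letters`.
#' @export
tukey_letters <- function(data, group = group, value = value, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  gl <- as.character(dplyr::pull(data, {{ group }}))
  y <- dplyr::pull(data, {{ value }})
  keep <- !is.na(gl) & !is.na(y)
  gl <- gl[keep]; y <- y[keep]
  groups <- unique(gl)
  if (length(groups) < 2) data_abort("need at least 2 groups")
  means <- tapply(y, gl, mean)
  ns <- tapply(y, gl, length)
  ord <- names(sort(means, decreasing = TRUE))

  fit <- stats::aov(y ~ factor(gl))
  mse <- stats::deviance(fit) / stats::df.residual(fit)
  if (!is.finite(mse) || mse <= .Machine$double.eps * max(1, stats::var(y))) {
    # degenerate: no within-group variance; distinct means = distinct groups
    sig_pair <- function(a, b) means[a] != means[b]
  } else {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)[[1]]
    pnames <- rownames(tk)
    pmat <- stats::setNames(tk[, "p adj"], pnames)
    sig_pair <- function(a, b) {
      key1 <- paste(a, b, sep = "-"); key2 <- paste(b, a, sep = "-")
      p <- if (key1 %in% pnames) pmat[key1] else pmat[key2]
      isTRUE(p < alpha)
    }
  }

  # insert-and-absorb over groups ordered by descending mean
  cols <- list(ord)
  for (i in seq_along(ord)[-length(ord)]) {
    for (j in seq((i + 1), length(ord))) {
      if (!sig_pair(ord[i], ord[j])) next
      for (ci in seq_along(cols)) {
        cl <- cols[[ci]]
        if (all(c(ord[i], ord[j]) %in% cl)) {
          cols[[ci]] <- setdiff(cl, ord[j])
          cols <- c(cols, list(setdiff(cl, ord[i])))
        }
      }
      # absorb columns that are subsets of another; drop emptied columns
      cols <- cols[lengths(cols) > 0]
      keep_col <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && keep_col[a] && keep_col[b] &&
            all(cols[[a]] %in% cols[[b]]) &&
            !(all(cols[[b]] %in% cols[[a]]) && a < b)) {
          keep_col[a] <- FALSE
        }
      }
      cols <- cols[keep_col]
    }
  }
  # letter columns ordered by their best-ranked member
  first_rank <- vapply(cols, function(cl) min(match(cl, ord)), numeric(1))
  cols <- cols[order(first_rank)]
  letter_of <- function(g) paste(letters[which(vapply(cols, function(cl)
    g %in% cl, logical(1)))], collapse = "")
  tibble::tibble(
    group = ord,
    mean = as.numeric(means[ord]),
    n = as.integer(ns[ord]),
    letters = vapply(ord, letter_of, character(1), USE.NAMES = FALSE)
  )
}

#' Classify lines as resistant / moderately resistant / susceptible
#'
#' Anchors the classification on two checks present in a compact letter
#' display: a line sharing a letter with the resistant check and none with
#' the susceptible check is `R`; sharing with the susceptible check but not
#' the resistant one is `S`; anything else (including sharing with both) is
#' `MR`. If the two checks share a letter the assay lacks resolution and
#' classification is refused.
#'
#' @param letters_df output of [tukey_letters()] (columns `group`,
#'   `letters`).
#' @param resistant_check,susceptible_check group labels of the two checks.
#' @return `letters_df` with a `class` column (`R`/`MR`/`S`; the checks are
#'   classified too).
#' @export
classify_resistance <- function(letters_df, resistant_check,
                                susceptible_check) {
  stopifnot(is.data.frame(letters_df),
            all(c("group", "letters") %in% names(letters_df)))
  lookup <- stats::setNames(letters_df$letters, letters_df$group)
  for (chk in c(resistant_check, susceptible_check)) {
    if (!chk %in% letters_df$group) data_abort("check '%s' absent", chk)
  }
  chars <- function(s) strsplit(s, "")[[1]]
  r_set <- chars(lookup[[resistant_check]])
  s_set <- chars(lookup[[susceptible_check]])
  if (length(intersect(r_set, s_set))) {
    data_abort("checks share a letter; assay lacks resolution to classify")
  }
  letters_df %>%
    dplyr::mutate(class = vapply(unname(.data$letters), function(l) {
      ls <- chars(l)
      with_r <- length(intersect(ls, r_set)) > 0
      with_s <- length(intersect(ls, s_set)) > 0
      if (with_r && !with_s) "R" else if (with_s && !with_r) "S" else "MR"
    }, character(1), USE.NAMES = FALSE))
}
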