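#' Run the analysis stages end to end
#'
#' Orchestrates the package's stages over a YAML (or list) configuration:
#' `simulate` (synthetic BIL cross), `phenotype` (damage AUC + pool
#' selection), `qtlscan` (SNP-index windows, null thresholds, QTL calls),
#' `assoc` (marker association at the QTL peak markers), `hpmine`
#' (haplotype patterns at the peak markers), `ldblocks` (LD pairs and
#' Gabriel blocks around the first called QTL) and `paint` (introgression
#' painting). Stage outputs are TSVs under `out_dir`; a JSON manifest
#' records inputs, parameters, seed, row counts and file checksums, so a
#' rerun with the same config reproduces identical tables.
#'
#' @param config path to a YAML file or a named list. Recognised fields:
#'   `out_dir` (required), `seed`, `sim` (arguments to [sim_config()]),
#'   `window_size`, `step`, `min_snps`, `n_sims`, `level`, and optional
#'   input paths `variants`, `phenotypes` (used instead of simulated data
#'   when given).
#' @param stages ordered character subset of `c("simulate", "phenotype",
#'   "qtlscan", "assoc", "hpmine", "ldblocks", "paint")`.
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "phenotype", "qtlscan",
                                    "assoc", "hpmine", "ldblocks", "paint")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) config_abort("out_dir", "is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  known <- c("simulate", "phenotype", "qtlscan", "assoc", "hpmine",
             "ldblocks", "paint")
  bad <- setdiff(stages, known)
  if (length(bad)) config_abort("stages", paste("unknown:", paste(bad, collapse = ", ")))
  stages <- known[known %in% stages]

  env <- new.env(parent = emptyenv())
  outputs <- list()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, path, progress = FALSE)
    outputs[[name]] <<- list(path = path, rows = nrow(df),
                             md5 = unname(tools::md5sum(path)))
  }
  need <- function(what, stage) {
    if (is.null(env[[what]])) {
      data_abort("stage '%s' needs '%s'; run its producing stage first",
                 stage, what)
    }
    env[[what]]
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        sim_args <- config$sim %||% list()
        sim_args$seed <- sim_args$seed %||% seed
        if (!is.null(sim_args$qtls)) {
          sim_args$qtls <- tibble::as_tibble(sim_args$qtls)
        }
        if (!is.null(sim_args$pool_sizes)) {
          sim_args$pool_sizes <- unlist(sim_args$pool_sizes)
        }
        cfg <- do.call(sim_config, sim_args)
        env$truth <- simulate_bil_population(cfg)
        env$scores <- simulate_damage_scores(env$truth)
        emit(env$scores, "damage_scores")
        geno <- tibble::as_tibble(env$truth$genotypes)
        geno$line <- rownames(env$truth$genotypes)
        emit(dplyr::relocate(geno, "line"), "genotypes")
        emit(env$truth$markers, "markers")
      },
      phenotype = {
        if (is.null(env$scores) && !is.null(config$phenotypes)) {
          env$scores <- read_damage_scores(config$phenotypes)
        }
        scores <- need("scores", "phenotype")
        env$auc <- damage_auc(scores)
        env$auc_summary <- average_auc(env$auc)
        cfgp <- env$truth$config$pool_sizes %||% c(resistant = 19, susceptible = 16)
        env$pools <- select_extremes(env$auc_summary,
                                     cfgp[["resistant"]], cfgp[["susceptible"]])
        emit(env$auc, "auc")
        emit(env$auc_summary, "auc_summary")
        emit(env$pools, "pools")
      },
      qtlscan = {
        if (is.null(env$sites) && !is.null(config$variants)) {
          env$sites <- read_variants(config$variants)
        }
        if (is.null(env$sites) && !is.null(env$truth)) {
          pools <- need("pools", "qtlscan")
          env$sites <- simulate_pool_seq(
            env$truth, dplyr::rename(pools, pool = "pool")[c("line", "pool")])
        }
        sites <- need("sites", "qtlscan")
        pools <- need("pools", "qtlscan")
        sites_f <- filter_sites(sites)
        manifest_pools <- tibble::tibble(
          sample = c("pool_resistant", "pool_susceptible"),
          pool = c("resistant", "susceptible"))
        snp_tab <- snp_index_table(sites_f, manifest_pools)
        lens <- env$truth$config$chrom_length_bp %||% config$chrom_length
        chrom_lengths <- stats::setNames(
          rep(lens, length(unique(snp_tab$chrom))), unique(snp_tab$chrom))
        win <- sliding_windows(snp_tab, chrom_lengths,
                               window_size = config$window_size %||% 2e6,
                               step = config$step %||% 1e4,
                               min_snps = config$min_snps %||% 3)
        thr <- null_thresholds(
          sum(pools$pool == "resistant"), sum(pools$pool == "susceptible"),
          donor_freq = mean(snp_tab$si_resistant + snp_tab$si_susceptible,
                            na.rm = TRUE) / 2,
          n_sims = config$n_sims %||% 2000,
          snps_per_window = stats::median(win$n_snps[!win$masked]),
          seed = seed + 10)
        win <- attach_thresholds(win, thr)
        env$windows <- win
        env$qtl_calls <- call_qtl(win, level = config$level %||% 0.95)
        emit(snp_tab, "snp_index")
        emit(tibble::as_tibble(win), "windows")
        emit(env$qtl_calls, "qtl_calls")
        env$snp_tab <- snp_tab
      },
      assoc = {
        truth <- need("truth", "assoc")
        auc_summary <- need("auc_summary", "assoc")
        idx <- truth$qtl_index
        res <- purrr::map_dfr(idx, function(i) {
          mk <- truth$markers$marker[i]
          d <- tibble::tibble(line = rownames(truth$genotypes),
                              genotype = truth$genotypes[, i]) %>%
            dplyr::inner_join(auc_summary, by = "line")
          fit <- single_marker_assoc(d, genotype, mean_auc, marker = mk)
          glance(fit)
        })
        env$assoc <- res
        emit(res, "assoc")
      },
      hpmine = {
        truth <- need("truth", "hpmine")
        auc_summary <- need("auc_summary", "hpmine")
        idx <- truth$qtl_index
        hp_rows <- purrr::map_dfr(seq_along(idx), function(k) {
          i <- idx[k]
          mk <- truth$markers$marker[i]
          allele <- c("0" = truth$markers$ref_allele[i], "1" = "H",
                      "2" = truth$markers$donor_allele[i])
          gm <- tibble::tibble(
            line = c("WT", rownames(truth$genotypes)),
            a1 = c(truth$markers$ref_allele[i],
                   unname(allele[as.character(truth$genotypes[, i])])))
          names(gm)[2] <- mk
          asn <- mine_hp(gm, wt_line = "WT", gene = paste0("QTL", k))
          d <- dplyr::inner_join(asn, auc_summary, by = "line")
          fit <- hp_assoc(dplyr::rename(d, auc = "mean_auc"), gene = paste0("QTL", k))
          tidy(fit)
        })
        env$hp <- hp_rows
        emit(hp_rows, "hp_assoc")
      },
      ldblocks = {
        truth <- need("truth", "ldblocks")
        calls <- need("qtl_calls", "ldblocks")
        if (nrow(calls) == 0) {
          emit(tibble::tibble(), "ld_pairs"); emit(tibble::tibble(), "ld_blocks")
        } else {
          reg <- calls[1, ]
          mm <- truth$markers
          sel <- which(paste0("chr", mm$chrom) == reg$chrom &
                         mm$pos >= reg$start & mm$pos <= reg$end)
          sel <- sel[seq(1, length(sel), length.out = min(20, length(sel)))]
          geno <- tibble::as_tibble(truth$genotypes[, sel, drop = FALSE])
          geno$line <- rownames(truth$genotypes)
          pairs <- ld_matrix(geno, marker_map = mm[sel, c("marker", "chrom", "pos")])
          blocks <- gabriel_blocks(pairs, mm[sel, c("marker", "chrom", "pos")])
          emit(pairs, "ld_pairs")
          emit(blocks, "ld_blocks")
        }
      },
      paint = {
        truth <- need("truth", "paint")
        mm <- truth$markers
        sub <- seq(1, nrow(mm), length.out = min(84, nrow(mm)))
        sub <- unique(round(sub))
        code_to_allele <- function(code, i) {
          c(mm$ref_allele[i], "H", mm$donor_allele[i])[code + 1]
        }
        gmat <- vapply(sub, function(i) code_to_allele(truth$genotypes[, i], i),
                       character(nrow(truth$genotypes)))
        colnames(gmat) <- mm$marker[sub]
        gdf <- dplyr::bind_rows(
          tibble::tibble(line = "DONOR", !!!stats::setNames(
            as.list(mm$donor_allele[sub]), mm$marker[sub])),
          tibble::tibble(line = "RECIPIENT", !!!stats::setNames(
            as.list(mm$ref_allele[sub]), mm$marker[sub])),
          dplyr::bind_cols(tibble::tibble(line = rownames(truth$genotypes)),
                           tibble::as_tibble(gmat))
        )
        seg <- paint_introgression(gdf, mm[sub, c("marker", "chrom", "pos")],
                                   "DONOR", "RECIPIENT")
        env$segments <- seg
        emit(seg, "introgression_segments")
        emit(introgression_summary(seg), "introgression_summary")
      }
    )
  }
  manifest <- list(
    seed = seed,
    stages = stages,
    parameters = config[setdiff(names(config), "out_dir")],
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
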