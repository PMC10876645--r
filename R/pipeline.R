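#' Pipeline configuration
#'
#' Collects paths, thresholds and options for a full reproducible run.
#' Either `plex_tsvs` (per-plex intensity tables, converted to
#' reference ratios and merged) or `matrix_tsv` (an already-merged linear
#' ratio matrix) must be given, plus the design TSV.
#'
#' @param design_tsv Design TSV (as written by [write_design_tsv()]).
#' @param plex_tsvs Named list of per-plex intensity TSV paths (names =
#'   plex ids).
#' @param matrix_tsv Merged linear-ratio matrix TSV.
#' @param out_dir Output directory (created if absent).
#' @param marker_gmt Optional GMT of marker sets for module enrichment.
#' @param ora_gmt Optional GMT of annotation sets for over-representation
#'   of each module.
#' @param comparator_a_tsv,comparator_b_tsv Optional external per-gene
#'   tables (`gene_symbol`, `log_fc`, `call` or `p`, optional `cluster`)
#'   for the cross-dataset stage.
#' @param fc_up,fc_down,p_cut Differential-abundance gates.
#' @param max_missing_fraction Missingness filter threshold (default 0 =
#'   complete case).
#' @param network A [network_params()].
#' @param pick_power Pick the soft power by scale-free fit (default TRUE).
#' @param assoc_alpha Cross-clustering significance bar (default 0.001).
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design_tsv, plex_tsvs = NULL, matrix_tsv = NULL,
                            out_dir = "coabund_out", marker_gmt = NULL,
                            ora_gmt = NULL, comparator_a_tsv = NULL,
                            comparator_b_tsv = NULL, fc_up = 1.2,
                            fc_down = 1 / 1.2, p_cut = 0.05,
                            max_missing_fraction = 0,
                            network = network_params(), pick_power = TRUE,
                            assoc_alpha = 0.001, seed = 1L) {
  if (is.null(plex_tsvs) && is.null(matrix_tsv)) {
    abort("either plex_tsvs or matrix_tsv is required",
          class = "coabund_schema_error")
  }
  structure(list(design_tsv = design_tsv, plex_tsvs = plex_tsvs,
                 matrix_tsv = matrix_tsv, out_dir = out_dir,
                 marker_gmt = marker_gmt, ora_gmt = ora_gmt,
                 comparator_a_tsv = comparator_a_tsv,
                 comparator_b_tsv = comparator_b_tsv,
                 fc_up = fc_up, fc_down = fc_down, p_cut = p_cut,
                 max_missing_fraction = max_missing_fraction,
                 network = network, pick_power = pick_power,
                 assoc_alpha = assoc_alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes ingest (reference ratios, merge, missingness filter, log2),
#' differential abundance (per-timepoint t tests with the joint gate,
#' per-protein ANOVA, altered-set overlaps, sample PCA), the weighted
#' co-abundance network (power pick, modules, eigenproteins, kME, temporal
#' profiles), marker enrichment, and — when comparator tables are supplied —
#' the cross-dataset stage.  Every stage writes its outputs before the next
#' starts, so partial results survive downstream failures; given the same
#' config and seed the non-timestamp outputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `run_artifacts` object: `manifest` tibble (`stage`, `file`,
#'   `md5`), the key in-memory results, and the config echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(stage, path) {
    hash <- unname(tools::md5sum(path))
    manifest[[length(manifest) + 1]] <<-
      tibble(stage = stage, file = basename(path), md5 = hash)
  }
  results <- list()

  # -- ingest ---------------------------------------------------------------
  design <- read_design_tsv(config$design_tsv)
  if (!is.null(config$plex_tsvs)) {
    ratio_tables <- imap(config$plex_tsvs, function(path, p) {
      tab <- read_tsv_strict(path)
      reference_ratios(tab, design$reference_channels[[p]])
    })
    mat <- merge_plexes(ratio_tables, design)
  } else {
    mat <- read_abundance_tsv(config$matrix_tsv, design, "linear_ratio")
  }
  mat <- filter_missing(mat, config$max_missing_fraction)
  lmat <- log_transform(mat)
  f <- file.path(config$out_dir, "abundance_log2.tsv")
  write_abundance_tsv(lmat, f); emit("ingest", f)
  results$matrix <- lmat

  # -- differential abundance ----------------------------------------------
  comparisons <- default_comparisons(design)
  de <- map(comparisons, function(cmp) {
    classify_de(pairwise_de(lmat, cmp), fc_up = config$fc_up,
                fc_down = config$fc_down, p_cut = config$p_cut)
  }) %>% bind_rows()
  f <- file.path(config$out_dir, "de.tsv")
  write_tsv_plain(de %>% select(-df), f); emit("diffabund", f)
  results$de <- de

  anova <- protein_anova(lmat)
  f <- file.path(config$out_dir, "anova.tsv")
  write_tsv_plain(anova, f); emit("diffabund", f)
  results$anova <- anova

  for (dir_call in c("up", "down")) {
    sets <- de %>% filter(call == dir_call) %>%
      split(.$comparison) %>% map("protein_id")
    if (length(sets) >= 2) {
      ov <- overlap_sets(sets) %>%
        mutate(members = map_chr(members, paste, collapse = ";"))
      f <- file.path(config$out_dir, sprintf("overlap_%s.tsv", dir_call))
      write_tsv_plain(ov, f); emit("diffabund", f)
    }
  }

  pca <- sample_pca(lmat, k = 5)
  f <- file.path(config$out_dir, "pca_scores.tsv")
  write_tsv_plain(pca$scores, f); emit("diffabund", f)
  results$pca <- pca

  # -- co-abundance network -------------------------------------------------
  fit <- wcna(lmat, params = config$network, pick_power = config$pick_power)
  f <- file.path(config$out_dir, "modules.tsv")
  write_tsv_plain(fit$assignment, f); emit("conet", f)
  f <- file.path(config$out_dir, "eigenproteins.tsv")
  write_tsv_plain(as_tibble(fit$eigenproteins$values,
                            rownames = "sample_id"), f)
  emit("conet", f)
  if (!is.null(fit$soft_threshold)) {
    f <- file.path(config$out_dir, "soft_threshold.tsv")
    write_tsv_plain(fit$soft_threshold$fit_table, f); emit("conet", f)
  }
  profiles <- module_profiles(lmat, fit$assignment)
  f <- file.path(config$out_dir, "module_profiles.tsv")
  write_tsv_plain(profiles, f); emit("conet", f)
  if (requireNamespace("ape", quietly = TRUE)) {
    f <- file.path(config$out_dir, "dendrogram.nwk")
    write_newick(fit$tree, f); emit("conet", f)
  }
  results$wcna <- fit

  # -- enrichment -----------------------------------------------------------
  if (!is.null(config$marker_gmt)) {
    markers <- read_gmt(config$marker_gmt)
    enr <- module_set_enrichment(fit$assignment, markers)
    f <- file.path(config$out_dir, "enrichment.tsv")
    write_tsv_plain(enr, f); emit("enrich", f)
    results$enrichment <- enr
  }
  if (!is.null(config$ora_gmt)) {
    anno <- read_gmt(config$ora_gmt)
    bg <- fit$assignment$protein_id
    ora_all <- map(setdiff(unique(fit$assignment$module), "grey"),
                   function(m) {
      q <- fit$assignment$protein_id[fit$assignment$module == m]
      ora(q, anno, bg) %>% mutate(module = m, .before = 1)
    }) %>% bind_rows()
    f <- file.path(config$out_dir, "ora.tsv")
    write_tsv_plain(ora_all, f); emit("enrich", f)
    results$ora <- ora_all
  }

  # -- cross-dataset --------------------------------------------------------
  if (!is.null(config$comparator_a_tsv) && !is.null(config$comparator_b_tsv)) {
    ca <- read_tsv_strict(config$comparator_a_tsv)
    cb <- read_tsv_strict(config$comparator_b_tsv)
    joined <- harmonize_identifiers(ca, cb)
    if (all(c("log_fc_a", "log_fc_b", "call_a", "call_b") %in%
              names(joined))) {
      conc <- direction_concordance(joined)
      f <- file.path(config$out_dir, "concordance.tsv")
      write_tsv_plain(conc$summary, f); emit("crossmap", f)
      results$concordance <- conc
    }
    if ("cluster" %in% names(ca) && "cluster" %in% names(cb)) {
      assoc <- module_module_association(ca, cb, alpha = config$assoc_alpha)
      f <- file.path(config$out_dir, "module_association.tsv")
      write_tsv_plain(as_tibble(assoc), f); emit("crossmap", f)
      results$association <- assoc
    }
  }

  manifest <- bind_rows(manifest)
  cfg_echo <- config
  cfg_echo$network <- unclass(cfg_echo$network)
  f <- file.path(config$out_dir, "config_echo.json")
  jsonlite::write_json(unclass(cfg_echo), f, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  manifest <- bind_rows(manifest,
                        tibble(stage = "pipeline", file = basename(f),
                               md5 = unname(tools::md5sum(f))))
  f <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, pretty = TRUE)
  structure(list(manifest = manifest, results = results, config = config),
            class = "run_artifacts")
}

#' @export
print.run_artifacts <- function(x, ...) {
  cat(sprintf("<run_artifacts> %d files in %s\n", nrow(x$manifest),
              x$config$out_dir))
  print(x$manifest)
  invisible(x)
}

#' Simulate a dataset and validate the full pipeline against ground truth
#'
#' Generates a synthetic dataset, runs the analysis chain in memory, and
#' scores it against the planted truth: module recovery (adjusted Rand
#' index over all analyzed proteins, grey matched to background),
#' differential-abundance sensitivity (planted effects recovered with the
#' right direction) and false-call rate on null proteins, and the kME
#' separation of members from background.  Failures (e.g. extreme noise
#' configurations) are reported as failed checks, not exceptions.
#'
#' @param config A [synth_config()].
#' @param thresholds Named list of pass thresholds: `ari`, `sensitivity`,
#'   `false_call_rate`.
#' @param pick_power Pick the soft power during the network stage.
#' @return A tibble report: `check`, `value`, `threshold`, `pass`.
#' @export
simulate_and_validate <- function(config,
                                  thresholds = list(ari = 0.8,
                                                    sensitivity = 0.9,
                                                    false_call_rate = 0.06),
                                  pick_power = TRUE) {
  sim <- simulate_dataset(config)
  design <- config$design
  ratio_tables <- imap(sim$plexes, function(tab, p) {
    reference_ratios(tab, design$reference_channels[[p]])
  })
  lmat <- log_transform(filter_missing(merge_plexes(ratio_tables, design), 0))
  truth <- sim$truth

  report <- list()
  add <- function(check, value, threshold, pass) {
    report[[length(report) + 1]] <<- tibble(
      check = check, value = value, threshold = threshold, pass = pass)
  }

  # differential abundance vs planted truth
  de <- map(default_comparisons(design), function(cmp) {
    classify_de(pairwise_de(lmat, cmp))
  }) %>% bind_rows()
  tp_of <- sub(".*?_(.*)_vs_.*", "\\1", de$comparison)
  truth_key <- paste(truth$de_status$protein_id, truth$de_status$timepoint)
  idx <- match(paste(de$protein_id, tp_of), truth_key)
  de$true_status <- truth$de_status$status[idx]
  de$true_log2_effect <- truth$de_status$true_log2_effect[idx]
  # sensitivity is scored on peak-magnitude planted effects; planted shifts
  # below the fold-change gate are undetectable by design
  planted <- de %>% filter(true_status %in% c("up", "down"),
                           abs(true_log2_effect) >=
                             config$effect_size_log2 - 1e-9)
  nulls <- de %>% filter(true_status == "null", call != "untestable")
  if (nrow(planted) > 0) {
    sens <- mean(planted$call == planted$true_status)
    add("de_sensitivity", sens, thresholds$sensitivity,
        sens >= thresholds$sensitivity)
  }
  if (nrow(nulls) > 0) {
    fcr <- mean(nulls$call %in% c("up", "down"))
    add("de_false_call_rate", fcr, thresholds$false_call_rate,
        fcr <= thresholds$false_call_rate)
  }

  # module recovery
  fit <- tryCatch(wcna(lmat, pick_power = pick_power), error = function(e) e)
  if (inherits(fit, "error")) {
    add("module_recovery_ari", NA_real_, thresholds$ari, FALSE)
  } else {
    tr <- truth$modules$module_id[match(fit$assignment$protein_id,
                                        truth$modules$protein_id)]
    ari <- mclust::adjustedRandIndex(fit$assignment$module, tr)
    add("module_recovery_ari", ari, thresholds$ari, ari >= thresholds$ari)
    kme_own <- fit$kme %>%
      mutate(truth_module = truth$modules$module_id[
        match(protein_id, truth$modules$protein_id)])
    seps <- map_dbl(setdiff(unique(kme_own$truth_module), "background"),
                    function(m) {
      rec <- first_recovered_module(kme_own, m)
      if (is.na(rec)) return(-Inf)
      per_mod <- kme_own %>% filter(module == rec)
      med_mem <- median(per_mod$kme[per_mod$truth_module == m], na.rm = TRUE)
      med_bg <- median(per_mod$kme[per_mod$truth_module == "background"],
                       na.rm = TRUE)
      med_mem - med_bg
    })
    add("kme_separation_min", min(seps), 0, min(seps) > 0)
  }
  bind_rows(report)
}

# the recovered module label that best matches a planted module
first_recovered_module <- function(kme_tbl, truth_module) {
  tab <- kme_tbl %>% filter(truth_module == !!truth_module,
                            own_module == module) %>% count(module, sort = TRUE)
  if (nrow(tab) == 0) return(NA_character_)
  tab$module[1]
}
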