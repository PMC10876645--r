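#' Configuration for the synthetic longitudinal TMT simulator
#'
#' Defines the generative model for a multi-plex longitudinal proteomics
#' experiment with planted co-abundance modules.  Protein `i`'s log2
#' abundance offset in sample `s` is
#'
#' \deqn{x_{is} = \mathrm{shift}_{m(i)}(s) + \ell_i \, z_{m(i)}(s) + \varepsilon_{is}}
#'
#' where `shift_m(s)` is the module template's planted (genotype, timepoint)
#' offset, `z_m` is a latent module factor shared by all members (scaled so
#' that within-module correlation approaches `module_correlation`), loadings
#' `l_i ~ U(0.5, 1)` (a configurable fraction negated), and the noise is
#' Gaussian on the log2 scale.  Background proteins have no planted shift and
#' (optionally) a weak common factor giving pairwise correlation
#' `background_correlation`.  Channel intensities are emitted on the linear
#' scale; each plex carries one reference channel generated as the pooled
#' control expectation.
#'
#' @param n_proteins Total number of proteins.
#' @param module_spec Tibble with columns `module_id`, `size`, `template_id`;
#'   module sizes must sum to at most `n_proteins`.
#' @param design A `study_design` from [generate_design()].
#' @param noise_sd Additive noise sd on the log2 scale.
#' @param module_correlation Target within-module Pearson correlation of log2
#'   ratios (drives the latent-factor scale); 0 plants independent proteins
#'   that still carry the template shift.
#' @param background_correlation Pairwise correlation among background
#'   proteins in `[0, 1)`.
#' @param plex_effect_sd Sd of the per-(protein, plex) additive log2 batch
#'   offset applied to biological channels (the reference is constructed per
#'   plex from the pooled expectation, so this offset survives into ratios as
#'   a residual batch effect).
#' @param missing_plex_prob Probability that a protein is unobserved in a
#'   given plex (all channels of that plex absent for it).
#' @param effect_size_log2 Peak planted shift magnitude (used to scale the
#'   built-in templates when `templates` is not supplied).
#' @param templates Named list of [profile_template()] objects; defaults to
#'   [builtin_templates()] scaled by `effect_size_log2`.
#' @param neg_loading_frac Fraction of module loadings negated (default 0,
#'   keeping planted modules coherent under a signed network transform).
#' @param noisy_reference Add log2 noise of sd `noise_sd` to the reference
#'   channel (default `FALSE`: noiseless pooled expectation, which isolates
#'   the correctness of the ratio computation from reference noise).
#' @param baseline_log2_mean,baseline_log2_sd Log2 baseline intensity
#'   distribution (log-normal intensities).
#' @param seed Integer seed; all randomness flows from it, with per-plex
#'   sub-streams so that plex-level draws are stable under config edits.
#' @return A `synth_config` object (validated list).
#' @seealso [simulate_dataset()], [default_synth_config()]
#' @export
synth_config <- function(n_proteins,
                         module_spec,
                         design,
                         noise_sd = 0.3,
                         module_correlation = 0.7,
                         background_correlation = 0,
                         plex_effect_sd = 0,
                         missing_plex_prob = 0,
                         effect_size_log2 = 0.585,
                         templates = NULL,
                         neg_loading_frac = 0,
                         noisy_reference = FALSE,
                         baseline_log2_mean = 16,
                         baseline_log2_sd = 1.5,
                         seed = 1L) {
  module_spec <- as_tibble(module_spec)
  if (nrow(module_spec) > 0) {
    stopifnot(all(c("module_id", "size", "template_id") %in% names(module_spec)),
              all(module_spec$size >= 1))
    if (sum(module_spec$size) > n_proteins) {
      abort("sum of module sizes exceeds n_proteins",
            class = "coabund_config_error")
    }
  }
  stopifnot(noise_sd >= 0, plex_effect_sd >= 0,
            missing_plex_prob >= 0, missing_plex_prob < 1,
            module_correlation >= 0, module_correlation < 1,
            background_correlation >= 0, background_correlation < 1,
            neg_loading_frac >= 0, neg_loading_frac <= 1)
  validate_study_design(design)
  if (is.null(templates)) {
    geno <- sort(unique(design$samples$genotype))
    templates <- builtin_templates(
      effect_size_log2,
      control_timepoints = order_timepoints(
        design$samples$timepoint[design$samples$genotype == geno[1]]),
      disease_timepoints = order_timepoints(
        design$samples$timepoint[design$samples$genotype == geno[2]]),
      genotypes = geno)
  }
  if (nrow(module_spec) > 0 &&
      !all(module_spec$template_id %in% names(templates))) {
    abort("module_spec references unknown template_id",
          class = "coabund_config_error")
  }
  structure(list(
    n_proteins = as.integer(n_proteins), module_spec = module_spec,
    design = design, noise_sd = noise_sd,
    module_correlation = module_correlation,
    background_correlation = background_correlation,
    plex_effect_sd = plex_effect_sd, missing_plex_prob = missing_plex_prob,
    effect_size_log2 = effect_size_log2, templates = templates,
    neg_loading_frac = neg_loading_frac, noisy_reference = noisy_reference,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd, seed = as.integer(seed)),
    class = "synth_config")
}

#' Default study-scale synthetic configuration
#'
#' The reference conditions used throughout validation: 2000 proteins, six
#' planted modules of sizes 150/120/100/80/50/30 carrying the six built-in
#' profile archetypes, a 45-sample 5-plex longitudinal design (5 replicates
#' in 4 control and 5 disease groups, reference channel 131), log2 noise sd
#' 0.3, target within-module correlation 0.7.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @export
default_synth_config <- function(seed = 42L, ...) {
  design <- generate_design(
    5, c("1wk", "2wk", "4wk", "6wk"), c("1wk", "2wk", "4wk", "6wk", "rec"),
    n_plexes = 5, channels_per_plex = 10, reference_channel = "131",
    seed = seed)
  spec <- tibble(
    module_id = paste0("M", 1:6),
    size = c(150L, 120L, 100L, 80L, 50L, 30L),
    template_id = c("progressive_down_partial_recovery", "early_maintained_up",
                    "late_up_partial_reversal", "late_up_persisting",
                    "age_up", "transient_early_up"))
  args <- list(n_proteins = 2000L, module_spec = spec, design = design,
               noise_sd = 0.3, module_correlation = 0.7, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

#' Simulate a multi-plex dataset with known ground truth
#'
#' Draws per-plex channel intensity tables on the linear scale from a
#' [synth_config()], together with the planted truth.  The reference channel
#' of each plex is the pooled control expectation (noiseless unless
#' `noisy_reference`); per-plex batch offsets and protein-by-plex dropout are
#' applied to biological channels.  Fully reproducible given the config seed.
#'
#' @param config A `synth_config`.
#' @return List with `plexes` (named list of tibbles: `protein_id` plus one
#'   column per channel, reference included), `truth` (see below) and
#'   `config`.  `truth` is a list with `modules` (tibble: `protein_id`,
#'   `module_id` — `"background"` for unplanted proteins — and
#'   `template_id`), and `de_status` (tibble: `protein_id`, `genotype`,
#'   `timepoint`, `status` in up/down/null, `true_log2_effect`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  samples <- cf$design$samples
  n <- cf$n_proteins
  n_samp <- nrow(samples)
  protein_id <- sprintf("P%05d", seq_len(n))

  module_of <- rep("background", n)
  template_of <- rep(NA_character_, n)
  if (nrow(cf$module_spec) > 0) {
    idx <- 1L
    for (r in seq_len(nrow(cf$module_spec))) {
      sz <- cf$module_spec$size[r]
      module_of[idx:(idx + sz - 1L)] <- cf$module_spec$module_id[r]
      template_of[idx:(idx + sz - 1L)] <- cf$module_spec$template_id[r]
      idx <- idx + sz
    }
  }

  # latent-factor scale from the target within-module correlation (typical
  # loading 0.75), anchored at the reference noise level 0.3 so that raising
  # noise_sd degrades the realized correlation instead of being compensated
  l0 <- 0.75
  ref_noise <- 0.3
  factor_sd <- if (cf$module_correlation > 0) {
    sqrt(ref_noise^2 * cf$module_correlation /
           (l0^2 * (1 - cf$module_correlation)))
  } else 0
  bg_coef <- if (cf$background_correlation > 0) {
    cf$noise_sd * sqrt(cf$background_correlation / (1 - cf$background_correlation))
  } else 0

  # planted shift per (module template, sample)
  shift_of_sample <- function(tid) {
    tpl <- cf$templates[[tid]]
    map_dbl(seq_len(n_samp), function(s)
      template_value(tpl, samples$genotype[s], samples$timepoint[s]))
  }
  shift_by_template <- lapply(
    setNames(nm = unique(stats::na.omit(template_of))), shift_of_sample)

  # global stream: structural parameters and module factors
  glob <- withr_seed(cf$seed, {
    mu <- rnorm(n, cf$baseline_log2_mean, cf$baseline_log2_sd)
    load <- runif(n, 0.5, 1)
    if (cf$neg_loading_frac > 0) {
      flip <- runif(n) < cf$neg_loading_frac
      load[flip] <- -load[flip]
    }
    mods <- unique(module_of[module_of != "background"])
    z <- matrix(rnorm(length(mods) * n_samp, 0, factor_sd),
                nrow = length(mods), ncol = n_samp,
                dimnames = list(mods, samples$sample_id))
    g <- rnorm(n_samp, 0, 1)
    list(mu = mu, load = load, z = z, g = g)
  })

  # expected log2 offset x0 (no noise) for every protein x sample
  x0 <- matrix(0, n, n_samp, dimnames = list(protein_id, samples$sample_id))
  for (m in rownames(glob$z)) {
    rows <- which(module_of == m)
    tid <- template_of[rows[1]]
    x0[rows, ] <- matrix(shift_by_template[[tid]], length(rows), n_samp,
                         byrow = TRUE) +
      outer(glob$load[rows], glob$z[m, ])
  }
  bg_rows <- which(module_of == "background")
  if (bg_coef > 0 && length(bg_rows) > 0) {
    x0[bg_rows, ] <- x0[bg_rows, ] + outer(rep(bg_coef, length(bg_rows)), glob$g)
  }

  # reference = pooled control expectation per protein
  ctl_genotype <- sort(unique(samples$genotype))[1]
  ctl_expect <- rep(0, n)
  has_tpl <- !is.na(template_of)
  if (any(has_tpl)) {
    ctl_samples <- which(samples$genotype == ctl_genotype)
    for (tid in names(shift_by_template)) {
      rows <- which(template_of == tid)
      ctl_expect[rows] <- mean(shift_by_template[[tid]][ctl_samples])
    }
  }

  plex_ids <- names(cf$design$reference_channels)
  plexes <- setNames(vector("list", length(plex_ids)), plex_ids)
  for (pi in seq_along(plex_ids)) {
    p <- plex_ids[pi]
    sub <- samples[samples$plex == p, , drop = FALSE]
    plex_seed <- (cf$seed %% 100000L) * 10000L + pi * 97L
    tabs <- withr_seed(plex_seed, {
      eps <- matrix(rnorm(n * nrow(sub), 0, cf$noise_sd), n)
      offs <- rnorm(n, 0, cf$plex_effect_sd)
      keep <- runif(n) >= cf$missing_plex_prob
      ref_noise <- if (cf$noisy_reference) rnorm(n, 0, cf$noise_sd) else rep(0, n)
      list(eps = eps, offs = offs, keep = keep, ref_noise = ref_noise)
    })
    log2_bio <- glob$mu + x0[, sub$sample_id, drop = FALSE] + tabs$eps + tabs$offs
    log2_ref <- glob$mu + ctl_expect + tabs$ref_noise
    tab <- as_tibble(as.data.frame(2^log2_bio))
    names(tab) <- sub$channel
    tab[[cf$design$reference_channels[[p]]]] <- 2^log2_ref
    tab <- tibble(protein_id = protein_id) %>% dplyr::bind_cols(tab)
    plexes[[p]] <- tab[tabs$keep, , drop = FALSE]
  }

  # ground truth DE status per disease timepoint (vs pooled control baseline)
  dis_genotype <- setdiff(sort(unique(samples$genotype)), ctl_genotype)
  de_status <- tidyr::expand_grid(
    protein_id = protein_id,
    genotype = dis_genotype,
    timepoint = unique(samples$timepoint[samples$genotype %in% dis_genotype]))
  eff <- numeric(nrow(de_status))
  pid_tpl <- setNames(template_of, protein_id)
  for (tid in names(shift_by_template)) {
    tpl <- cf$templates[[tid]]
    sel <- which(pid_tpl[de_status$protein_id] == tid)
    if (length(sel) > 0) {
      key <- paste(de_status$genotype[sel], de_status$timepoint[sel])
      uk <- unique(key)
      val <- setNames(map_dbl(strsplit(uk, " ", fixed = TRUE),
                              ~ template_value(tpl, .x[1], paste(.x[-1], collapse = " "))),
                      uk)
      eff[sel] <- val[key] - ctl_expect[match(de_status$protein_id[sel], protein_id)]
    }
  }
  de_status$true_log2_effect <- eff
  de_status$status <- case_when(eff > 0 ~ "up", eff < 0 ~ "down", TRUE ~ "null")

  truth <- list(
    modules = tibble(protein_id = protein_id, module_id = module_of,
                     template_id = template_of),
    de_status = de_status)
  list(plexes = plexes, truth = truth, config = cf)
}
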