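#' Generate a multiplexed longitudinal study design
#'
#' Lays out a TMT-style experiment: `n_per_group` biological replicates per
#' (genotype, timepoint) cell, distributed over `n_plexes` isobaric plexes of
#' `channels_per_plex` channels each, with one channel per plex reserved for
#' the pooled reference.  The control genotype contributes one group per
#' `control_timepoints` label and the disease genotype one per
#' `disease_timepoints` label, emulating a longitudinal disease-course design
#' (e.g. 5 mice in each of 4 control and 5 disease groups spread over five
#' 10-plexes with channel 131 as the common reference).
#'
#' Sample-to-plex placement is randomized by `seed` so that groups are not
#' confounded with plexes by construction; pass `randomize = FALSE` to get
#' the deterministic fill order (a deliberately confounded layout for batch
#' effect studies).
#'
#' @param n_per_group Biological replicates per (genotype, timepoint) group.
#' @param control_timepoints,disease_timepoints Character vectors of timepoint
#'   labels for the control and disease arms.
#' @param n_plexes Number of plexes.
#' @param channels_per_plex Channels per plex, including the reference.
#' @param reference_channel Label of the reference channel.  `"131"` with 10
#'   channels selects the conventional TMT10 channel names; otherwise channels
#'   are labelled `c1..cK` and `reference_channel` must be one of them.
#' @param seed Integer seed controlling the randomized placement.
#' @param genotypes Length-2 character vector: control then disease genotype
#'   labels.
#' @param randomize Randomize sample-to-plex placement (default `TRUE`).
#'
#' @return A `study_design`: list with `samples` (tibble: `sample_id`, `plex`,
#'   `channel`, `genotype`, `timepoint`) and `reference_channels` (named
#'   character vector, one entry per plex).
#' @examples
#' d <- generate_design(5, c("1wk", "2wk", "4wk", "6wk"),
#'                      c("1wk", "2wk", "4wk", "6wk", "rec"),
#'                      n_plexes = 5, channels_per_plex = 10,
#'                      reference_channel = "131", seed = 1)
#' nrow(d$samples) # 45
#' @export
generate_design <- function(n_per_group,
                            control_timepoints,
                            disease_timepoints,
                            n_plexes,
                            channels_per_plex,
                            reference_channel = "131",
                            seed = 1L,
                            genotypes = c("control", "rNLS8"),
                            randomize = TRUE) {
  stopifnot(n_per_group >= 1, n_plexes >= 1, channels_per_plex >= 2,
            length(genotypes) == 2)
  channels <- tmt_channel_labels(channels_per_plex, reference_channel)
  if (!reference_channel %in% channels) {
    abort(sprintf("reference channel '%s' is not among the %d channel labels",
                  reference_channel, channels_per_plex),
          class = "coabund_design_error")
  }
  groups <- bind_rows(
    tidyr::expand_grid(genotype = genotypes[1], timepoint = control_timepoints),
    tidyr::expand_grid(genotype = genotypes[2], timepoint = disease_timepoints)
  )
  n_samples <- nrow(groups) * n_per_group
  capacity <- n_plexes * (channels_per_plex - 1L)
  if (n_samples > capacity) {
    abort(sprintf(
      "design needs %d biological channels but %d plexes x %d channels provide %d",
      n_samples, n_plexes, channels_per_plex - 1L, capacity),
      class = "coabund_sizing_error")
  }
  samples <- groups %>%
    tidyr::uncount(n_per_group) %>%
    group_by(genotype, timepoint) %>%
    mutate(sample_id = paste(genotype, timepoint, row_number(), sep = "_")) %>%
    ungroup()

  bio_channels <- setdiff(channels, reference_channel)
  slots <- tidyr::expand_grid(plex = paste0("plex", seq_len(n_plexes)),
                              channel = bio_channels)
  idx <- seq_len(n_samples)
  if (randomize) {
    idx <- withr_seed(seed, sample.int(n_samples))
  }
  samples <- samples[idx, , drop = FALSE]
  samples$plex <- slots$plex[seq_len(n_samples)]
  samples$channel <- slots$channel[seq_len(n_samples)]
  samples <- samples %>% select(sample_id, plex, channel, genotype, timepoint)
  if (anyDuplicated(samples[c("plex", "channel")]) > 0) {
    abort("duplicate (plex, channel) assignment", class = "coabund_design_error")
  }
  new_study_design(samples,
                   setNames(rep(reference_channel, n_plexes),
                            paste0("plex", seq_len(n_plexes))))
}

new_study_design <- function(samples, reference_channels) {
  structure(list(samples = as_tibble(samples),
                 reference_channels = reference_channels),
            class = "study_design")
}

validate_study_design <- function(design) {
  s <- design$samples
  stopifnot(is_tibble(s),
            all(c("sample_id", "plex", "channel", "genotype", "timepoint")
                %in% names(s)))
  if (anyDuplicated(s$sample_id) > 0) {
    abort("duplicate sample_id in design", class = "coabund_design_error")
  }
  if (anyDuplicated(s[c("plex", "channel")]) > 0) {
    abort("duplicate (plex, channel) in design", class = "coabund_design_error")
  }
  ref <- design$reference_channels
  if (!all(unique(s$plex) %in% names(ref))) {
    abort("every plex must have a reference channel",
          class = "coabund_design_error")
  }
  bad <- s$channel == ref[s$plex]
  if (any(bad)) {
    abort("biological sample assigned to a reference channel",
          class = "coabund_design_error")
  }
  invisible(design)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d biological samples, %d plexes (reference: %s)\n",
              nrow(x$samples), length(x$reference_channels),
              paste(unique(x$reference_channels), collapse = ", ")))
  print(count(x$samples, genotype, timepoint))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.study_design <- function(x, ...) x$samples

# TMT10 channel labels when the conventional reference "131" is used
tmt_channel_labels <- function(k, reference_channel) {
  tmt10 <- c("126", "127N", "127C", "128N", "128C",
             "129N", "129C", "130N", "130C", "131")
  if (k == 10 && reference_channel %in% tmt10) tmt10 else paste0("c", seq_len(k))
}

# natural order for timepoint labels: by leading number where present
# (1wk < 2wk < 4wk < 6wk), purely alphabetic labels (e.g. "rec") last
order_timepoints <- function(tp) {
  tp <- unique(tp)
  num <- suppressWarnings(as.numeric(sub("^([0-9.]+).*$", "\\1", tp)))
  tp[order(is.na(num), num, tp)]
}

# evaluate expr under a temporary seed without disturbing the global RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
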