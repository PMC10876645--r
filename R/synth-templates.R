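#' Planted abundance-profile templates
#'
#' A profile template maps each (genotype, timepoint) group to an expected
#' log2 offset relative to the control baseline.  The built-in archetypes
#' mirror the temporal behaviours seen in longitudinal disease-course
#' proteomics modules: a transient early increase, an early increase that is
#' maintained through disease but returns to control levels in recovery, a
#' late increase that persists into recovery, a late increase that partially
#' reverses, a progressive decrease with partial recovery, and an
#' age-associated drift affecting both genotypes.
#'
#' @param template_id Label for the template.
#' @param shift Tibble with columns `genotype`, `timepoint`, `log2_offset`.
#' @return A `profile_template` object.
#' @export
profile_template <- function(template_id, shift) {
  shift <- as_tibble(shift)
  stopifnot(all(c("genotype", "timepoint", "log2_offset") %in% names(shift)))
  if (anyDuplicated(shift[c("genotype", "timepoint")]) > 0) {
    abort("duplicate (genotype, timepoint) in template shift table")
  }
  structure(list(template_id = template_id, shift = shift),
            class = "profile_template")
}

#' @export
print.profile_template <- function(x, ...) {
  cat(sprintf("<profile_template> %s\n", x$template_id))
  print(tidyr::pivot_wider(x$shift, names_from = timepoint,
                           values_from = log2_offset))
  invisible(x)
}

#' Look up the planted offset of a template
#'
#' @param template A [profile_template()].
#' @param genotype,timepoint Group labels.
#' @return The deterministic planted log2 offset for that group.
#' @export
template_value <- function(template, genotype, timepoint) {
  stopifnot(inherits(template, "profile_template"))
  hit <- template$shift$genotype == genotype &
    template$shift$timepoint == timepoint
  if (!any(hit)) {
    abort(sprintf("template '%s' does not define (%s, %s)",
                  template$template_id, genotype, timepoint),
          class = "coabund_lookup_error")
  }
  template$shift$log2_offset[which(hit)[1]]
}

#' Built-in profile archetypes
#'
#' Returns the standard archetype templates scaled by `effect_size_log2`,
#' over the canonical 1wk/2wk/4wk/6wk(/rec) timepoints.  Control offsets are
#' zero for all disease archetypes; the `age_up` archetype drifts upward with
#' age in both genotypes, emulating age-associated modules.
#'
#' @param effect_size_log2 Peak planted shift magnitude on the log2 scale.
#' @param control_timepoints,disease_timepoints Timepoint vocabularies.
#' @param genotypes Control and disease genotype labels.
#' @return Named list of [profile_template()] objects:
#'   `transient_early_up`, `early_maintained_up`, `late_up_persisting`,
#'   `late_up_partial_reversal`, `progressive_down_partial_recovery`,
#'   `age_up`.
#' @export
builtin_templates <- function(effect_size_log2 = 1,
                              control_timepoints = c("1wk", "2wk", "4wk", "6wk"),
                              disease_timepoints = c("1wk", "2wk", "4wk", "6wk", "rec"),
                              genotypes = c("control", "rNLS8")) {
  ctl <- genotypes[1]; dis <- genotypes[2]
  # multipliers over the canonical 5 disease timepoints (last = recovery)
  arch <- list(
    transient_early_up                = c(1, 1, 0, 0, 0),
    early_maintained_up               = c(1, 1, 1, 1, 0),
    late_up_persisting                = c(0, 0, 0.5, 1, 1),
    late_up_partial_reversal          = c(0, 0, 0.5, 1, 0.4),
    progressive_down_partial_recovery = c(0, -1 / 3, -2 / 3, -1, -1 / 3)
  )
  nd <- length(disease_timepoints)
  templates <- imap(arch, function(mult, id) {
    mult <- mult[seq_len(min(nd, length(mult)))]
    if (nd > length(mult)) mult <- c(mult, rep(mult[length(mult)], nd - length(mult)))
    profile_template(id, bind_rows(
      tibble(genotype = ctl, timepoint = control_timepoints, log2_offset = 0),
      tibble(genotype = dis, timepoint = disease_timepoints,
             log2_offset = effect_size_log2 * mult)
    ))
  })
  # age-associated drift: both genotypes rise with time; recovery (aged) stays high
  nc <- length(control_timepoints)
  age_ctl <- effect_size_log2 * seq(0, 1, length.out = max(nc, 2))[seq_len(nc)]
  age_dis <- c(effect_size_log2 * seq(0, 1, length.out = max(nc, 2))[seq_len(min(nd, nc))],
               rep(effect_size_log2, max(0L, nd - nc)))
  templates$age_up <- profile_template("age_up", bind_rows(
    tibble(genotype = ctl, timepoint = control_timepoints, log2_offset = age_ctl),
    tibble(genotype = dis, timepoint = disease_timepoints, log2_offset = age_dis)
  ))
  templates
}
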