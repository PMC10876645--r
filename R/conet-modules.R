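#' Module eigenproteins
#'
#' Summarises each module by its first principal component across samples:
#' member profiles are standardized (mean 0, sd 1 across samples), the first
#' right-singular vector of the standardized member matrix is taken as the
#' eigenprotein, and its sign is fixed so the mean correlation with member
#' proteins is nonnegative.  Proteins with missing entries are mean-imputed
#' (per protein) for this computation only, and the imputation count is
#' reported.
#'
#' @param matrix A log2-scale `abundance_matrix`.
#' @param assignment A `module_assignment` (or tibble with `protein_id`,
#'   `module`); `"grey"` proteins are ignored.
#' @return An `eigenprotein_table`: list with `values` (samples x modules
#'   matrix of unit-norm eigenproteins), `summary` (tibble: `module`,
#'   `var_explained`, `n_proteins`, `n_imputed`).
#' @export
module_eigenproteins <- function(matrix, assignment) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (matrix$scale != "log2_ratio") {
    abort("module_eigenproteins expects log2 ratios",
          class = "coabund_value_error")
  }
  mods <- setdiff(unique(assignment$module), "grey")
  if (length(mods) == 0) abort("no assigned modules",
                               class = "coabund_degenerate_error")
  x <- matrix$values
  values <- matrix(NA_real_, ncol(x), length(mods),
                   dimnames = list(colnames(x), mods))
  summ <- map(mods, function(m) {
    ids <- assignment$protein_id[assignment$module == m]
    xm <- x[intersect(ids, rownames(x)), , drop = FALSE]
    if (nrow(xm) < 2) {
      abort(sprintf("module '%s' has fewer than 2 profiled proteins", m),
            class = "coabund_degenerate_error")
    }
    n_imp <- sum(is.na(xm))
    if (n_imp > 0) {
      rm <- rowMeans(xm, na.rm = TRUE)
      xm[is.na(xm)] <- rm[row(xm)[is.na(xm)]]
    }
    sds <- apply(xm, 1, sd)
    keep <- sds > 0
    if (sum(keep) < 2) {
      abort(sprintf("module '%s' is degenerate (zero-variance profiles)", m),
            class = "coabund_degenerate_error")
    }
    xs <- (xm[keep, , drop = FALSE] - rowMeans(xm[keep, , drop = FALSE])) /
      sds[keep]
    sv <- svd(xs)
    v <- sv$v[, 1]
    if (mean(xs %*% v) < 0) v <- -v
    values[, m] <<- v
    tibble(module = m, var_explained = sv$d[1]^2 / sum(sv$d^2),
           n_proteins = nrow(xm), n_imputed = n_imp)
  }) %>% bind_rows()
  if (any(summ$n_imputed > 0)) {
    inform(sprintf("module_eigenproteins: mean-imputed %d missing value(s)",
                   sum(summ$n_imputed)))
  }
  structure(list(values = values, summary = summ),
            class = "eigenprotein_table")
}

#' @export
print.eigenprotein_table <- function(x, ...) {
  cat(sprintf("<eigenprotein_table> %d modules x %d samples\n",
              ncol(x$values), nrow(x$values)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.eigenprotein_table <- function(x, ...) {
  as_tibble(x$values, rownames = "sample_id") %>%
    tidyr::pivot_longer(-sample_id, names_to = "module",
                        values_to = "eigen_value")
}

#' @export
glance.eigenprotein_table <- function(x, ...) {
  tibble(n_modules = ncol(x$values),
         mean_var_explained = mean(x$summary$var_explained),
         min_var_explained = min(x$summary$var_explained))
}

#' Module membership (kME)
#'
#' Correlation of every protein's profile with every module eigenprotein.
#' High own-module kME defines a module's hub proteins.
#'
#' @param matrix A log2-scale `abundance_matrix`.
#' @param eigenproteins An `eigenprotein_table`.
#' @param assignment Optional `module_assignment`; when given, each row
#'   gains the protein's own module and, for members, a hub rank by
#'   descending own-module kME.
#' @return Tibble: `protein_id`, `module`, `kme`, and (with `assignment`)
#'   `own_module`, `rank_own`.  Zero-variance proteins get `NA` kME.
#' @export
module_membership_kme <- function(matrix, eigenproteins, assignment = NULL) {
  stopifnot(inherits(matrix, "abundance_matrix"),
            inherits(eigenproteins, "eigenprotein_table"))
  x <- matrix$values
  kme <- suppressWarnings(
    cor(t(x), eigenproteins$values, use = "pairwise.complete.obs"))
  out <- as_tibble(kme, rownames = "protein_id") %>%
    tidyr::pivot_longer(-protein_id, names_to = "module", values_to = "kme")
  if (!is.null(assignment)) {
    out <- out %>%
      left_join(assignment %>% select(protein_id, own_module = module),
                by = "protein_id") %>%
      group_by(module) %>%
      mutate(rank_own = rank(-ifelse(own_module == module, kme, NA_real_),
                             na.last = "keep")) %>%
      ungroup()
  }
  out
}

#' Top hub proteins per module
#'
#' @param kme Tibble from [module_membership_kme()] (with assignment).
#' @param n Number of hubs per module (default 6).
#' @return Tibble of the top-`n` members of each module by own-module kME.
#' @export
hub_proteins <- function(kme, n = 6) {
  stopifnot("rank_own" %in% names(kme))
  kme %>% filter(!is.na(rank_own), rank_own <= n) %>%
    arrange(module, rank_own)
}

#' Module temporal profiles
#'
#' For each protein, the mean log2 ratio in every (genotype, timepoint)
#' group minus its mean in the reference group; per module and group, the
#' distribution of member values is summarised by the median, quartiles and
#' whiskers at 1.5 x IQR (the box-and-whisker convention).
#'
#' @param matrix A log2-scale `abundance_matrix`.
#' @param assignment A `module_assignment`.
#' @param reference_group Tibble of (genotype, timepoint) cells defining the
#'   baseline; default: all groups of the alphabetically first genotype.
#' @return Tibble: `module`, `genotype`, `timepoint`, `n_proteins`,
#'   `median`, `q1`, `q3`, `lower`, `upper`, `mean`.
#' @export
module_profiles <- function(matrix, assignment, reference_group = NULL) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (matrix$scale != "log2_ratio") {
    abort("module_profiles expects log2 ratios", class = "coabund_value_error")
  }
  s <- matrix$design$samples
  if (is.null(reference_group)) {
    g0 <- sort(unique(s$genotype))[1]
    reference_group <- s %>% filter(genotype == g0) %>%
      distinct(genotype, timepoint)
  }
  ref_ids <- resolve_samples(matrix$design, as_tibble(reference_group))
  if (length(ref_ids) == 0) {
    abort("reference group is empty", class = "coabund_design_error")
  }
  x <- matrix$values
  ref_mean <- rowMeans(x[, ref_ids, drop = FALSE], na.rm = TRUE)
  groups <- s %>% distinct(genotype, timepoint)
  per_protein <- map(seq_len(nrow(groups)), function(gi) {
    ids <- resolve_samples(matrix$design, groups[gi, ])
    tibble(protein_id = rownames(x),
           genotype = groups$genotype[gi], timepoint = groups$timepoint[gi],
           value = rowMeans(x[, ids, drop = FALSE], na.rm = TRUE) - ref_mean)
  }) %>% bind_rows()
  per_protein %>%
    inner_join(as_tibble(assignment), by = "protein_id") %>%
    filter(module != "grey", !is.na(value)) %>%
    group_by(module, genotype, timepoint) %>%
    summarise(n_proteins = n(),
              mean = mean(value),
              median = median(value),
              q1 = quantile(value, 0.25, names = FALSE),
              q3 = quantile(value, 0.75, names = FALSE),
              .groups = "drop") %>%
    mutate(lower = q1 - 1.5 * (q3 - q1), upper = q3 + 1.5 * (q3 - q1))
}

#' Plot module temporal profiles
#'
#' @param profiles Tibble from [module_profiles()].
#' @return A ggplot: per-module median and quartile ribbons over timepoints,
#'   split by genotype.
#' @export
plot_module_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(timepoint, median, group = genotype,
                               colour = genotype, fill = genotype)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q1, ymax = q3), alpha = 0.25,
                         colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(y = "log2 fold change vs reference group") +
    ggplot2::theme_minimal()
}
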