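#' Define a two-group comparison
#'
#' Groups are sets of (genotype, timepoint) design cells, e.g. one disease
#' timepoint against all control groups pooled.
#'
#' @param group_a,group_b Tibbles/data frames with columns `genotype` and
#'   `timepoint` (group A is the baseline: fold changes are B over A).
#' @param label Comparison label used in output tables.
#' @return A `comparison_spec`.
#' @export
comparison_spec <- function(group_a, group_b, label) {
  group_a <- as_tibble(group_a); group_b <- as_tibble(group_b)
  stopifnot(all(c("genotype", "timepoint") %in% names(group_a)),
            all(c("genotype", "timepoint") %in% names(group_b)))
  if (nrow(inner_join(group_a, group_b, by = c("genotype", "timepoint"))) > 0) {
    abort("comparison groups must be disjoint", class = "coabund_design_error")
  }
  structure(list(group_a = group_a, group_b = group_b, label = label),
            class = "comparison_spec")
}

#' Comparisons of each disease timepoint against pooled controls
#'
#' The default longitudinal contrast set: every (disease genotype, timepoint)
#' cell versus all control-genotype groups pooled.
#'
#' @param design A `study_design`.
#' @param control_genotype,disease_genotype Genotype labels; defaults are the
#'   alphabetically first/second genotype in the design.
#' @return List of [comparison_spec()] objects, one per disease timepoint.
#' @export
default_comparisons <- function(design, control_genotype = NULL,
                                disease_genotype = NULL) {
  g <- sort(unique(design$samples$genotype))
  if (is.null(control_genotype)) control_genotype <- g[1]
  if (is.null(disease_genotype)) disease_genotype <- setdiff(g, control_genotype)[1]
  ctl <- design$samples %>% filter(genotype == control_genotype) %>%
    distinct(genotype, timepoint)
  tps <- order_timepoints(
    design$samples$timepoint[design$samples$genotype == disease_genotype])
  map(tps, function(tp) {
    comparison_spec(ctl, tibble(genotype = disease_genotype, timepoint = tp),
                    label = paste0(disease_genotype, "_", tp, "_vs_",
                                   control_genotype))
  }) %>% setNames(tps)
}

resolve_samples <- function(design, cells) {
  design$samples %>% inner_join(cells, by = c("genotype", "timepoint")) %>%
    pull(sample_id)
}

#' Per-protein two-group differential abundance
#'
#' Two-sided two-sample Student t test (pooled variance) on log2 ratios, with
#' the overall fold change as the geometric mean of the per-sample ratios
#' (equivalently `2^(mean_b - mean_a)` on the log2 scale).  Missing values
#' are removed per protein; proteins with fewer than 2 observations in
#' either group — or zero pooled variance with unequal means — are flagged
#' untestable rather than tested.
#'
#' @param matrix A log2-scale `abundance_matrix`.
#' @param comparison A [comparison_spec()].
#' @param welch Use Welch's unequal-variance t instead of the pooled Student
#'   t (default `FALSE`).
#' @return Tibble (one row per protein): `protein_id`, `comparison`, `n_a`,
#'   `n_b`, `log2fc`, `fold_change`, `t_stat`, `df`, `p_value`, `call`
#'   (`"untestable"` or `NA` pending [classify_de()]).
#' @examples
#' # closed-form pooled-t check: t = 12.247 on 4 df
#' a <- c(-0.1, 0, 0.1); b <- c(0.9, 1.0, 1.1)
#' @export
pairwise_de <- function(matrix, comparison, welch = FALSE) {
  stopifnot(inherits(matrix, "abundance_matrix"),
            inherits(comparison, "comparison_spec"))
  if (matrix$scale != "log2_ratio") {
    abort("pairwise_de expects log2 ratios (run log_transform first)",
          class = "coabund_value_error")
  }
  ids_a <- resolve_samples(matrix$design, comparison$group_a)
  ids_b <- resolve_samples(matrix$design, comparison$group_b)
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    abort("each comparison group needs at least 2 samples",
          class = "coabund_design_error")
  }
  st_a <- group_stats(matrix$values[, ids_a, drop = FALSE])
  st_b <- group_stats(matrix$values[, ids_b, drop = FALSE])
  n_a <- st_a$n; n_b <- st_b$n
  delta <- st_b$mean - st_a$mean
  if (welch) {
    se2 <- st_a$var / n_a + st_b$var / n_b
    df <- se2^2 / ((st_a$var / n_a)^2 / (n_a - 1) + (st_b$var / n_b)^2 / (n_b - 1))
    t_stat <- delta / sqrt(se2)
  } else {
    sp2 <- ((n_a - 1) * st_a$var + (n_b - 1) * st_b$var) / (n_a + n_b - 2)
    df <- n_a + n_b - 2
    t_stat <- delta / sqrt(sp2 * (1 / n_a + 1 / n_b))
  }
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  untestable <- n_a < 2 | n_b < 2
  # degenerate variance: equal means -> t = 0; unequal means -> untestable
  sp_zero <- !untestable & ((!welch & ((n_a - 1) * st_a$var + (n_b - 1) * st_b$var) == 0) |
                              (welch & (st_a$var + st_b$var) == 0))
  t_stat[sp_zero & delta == 0] <- 0
  p[sp_zero & delta == 0] <- 1
  untestable <- untestable | (sp_zero & delta != 0)
  t_stat[untestable] <- NA_real_
  p[untestable] <- NA_real_
  tibble(protein_id = rownames(matrix$values),
         comparison = comparison$label,
         n_a = unname(n_a), n_b = unname(n_b),
         log2fc = unname(delta), fold_change = unname(2^delta),
         t_stat = unname(t_stat), df = unname(df), p_value = unname(p),
         call = unname(ifelse(untestable, "untestable", NA_character_)))
}

group_stats <- function(x) {
  obs <- !is.na(x)
  n <- rowSums(obs)
  x0 <- ifelse(obs, x, 0)
  s <- rowSums(x0)
  m <- s / n
  v <- (rowSums(x0^2) - n * m^2) / pmax(n - 1, 1)
  v <- pmax(v, 0)  # guard tiny negative round-off
  list(n = n, mean = m, var = v)
}

#' Apply the joint fold-change and p-value gate
#'
#' A protein is called up when `fold_change > fc_up` and `p < p_cut`, down
#' when `fold_change < fc_down` and `p < p_cut`, otherwise not significant.
#' The default gates are a 1.20-fold increase or its reciprocal decrease at
#' t-test p < 0.05, the conventional joint criterion used in TMT studies in
#' place of multiple-testing correction (ratio compression makes the fold
#' gate the binding constraint).  `fc_down` defaults to `1/fc_up` (symmetric
#' on the log scale); pass `fc_down = 0.83` for the literal printed cut.
#'
#' @param table A DE tibble from [pairwise_de()].
#' @param fc_up,fc_down,p_cut Gate thresholds (`0 < fc_down < 1 < fc_up`).
#' @param adjust Optional p-adjustment method (`"BH"`) applied across the
#'   table before gating; default none.
#' @return The table with `call` filled in (`up`/`down`/`ns`/`untestable`);
#'   up/down counts are messaged.
#' @export
classify_de <- function(table, fc_up = 1.2, fc_down = 1 / fc_up, p_cut = 0.05,
                        adjust = NULL) {
  stopifnot(fc_down > 0, fc_down < 1, fc_up > 1, p_cut > 0)
  p <- table$p_value
  if (!is.null(adjust)) p <- p.adjust(p, method = adjust)
  call <- case_when(
    !is.na(table$call) & table$call == "untestable" ~ "untestable",
    table$fold_change > fc_up & p < p_cut ~ "up",
    table$fold_change < fc_down & p < p_cut ~ "down",
    TRUE ~ "ns")
  out <- table
  out$call <- call
  inform(sprintf("classify_de [%s]: %d up, %d down of %d testable",
                 out$comparison[1] %||% "", sum(call == "up"),
                 sum(call == "down"), sum(call != "untestable")))
  out
}

#' Per-protein one-way ANOVA across all groups
#'
#' Fixed-effects one-way ANOVA on log2 ratios, carried out separately for
#' each protein over the (genotype, timepoint) groups.  A protein is
#' testable when, after missing removal, at least two groups retain two or
#' more samples; zero within-group variance everywhere is reported as
#' untestable, not an error.
#'
#' @param matrix A log2-scale `abundance_matrix`.
#' @param grouping Optional factor/character vector over the design's
#'   samples; defaults to the (genotype, timepoint) interaction.
#' @return Tibble: `protein_id`, `F_stat`, `df1`, `df2`, `p_value`,
#'   `testable`, `reason`.
#' @export
protein_anova <- function(matrix, grouping = NULL) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (matrix$scale != "log2_ratio") {
    abort("protein_anova expects log2 ratios", class = "coabund_value_error")
  }
  s <- matrix$design$samples
  if (is.null(grouping)) grouping <- paste(s$genotype, s$timepoint, sep = ":")
  stopifnot(length(grouping) == ncol(matrix$values))
  G <- stats::model.matrix(~ 0 + factor(grouping))
  x <- matrix$values
  obs <- !is.na(x)
  x0 <- ifelse(obs, x, 0)
  n_ig <- obs %*% G                      # proteins x groups counts
  s_ig <- x0 %*% G
  n_tot <- rowSums(n_ig)
  grand <- rowSums(s_ig)
  ss_tot <- rowSums(x0^2) - grand^2 / n_tot
  nz <- n_ig > 0
  ssb <- rowSums(ifelse(nz, s_ig^2 / pmax(n_ig, 1), 0)) - grand^2 / n_tot
  ssw <- pmax(ss_tot - ssb, 0)
  k_eff <- rowSums(nz)
  df1 <- k_eff - 1
  df2 <- n_tot - k_eff
  testable <- rowSums(n_ig >= 2) >= 2 & df1 >= 1 & df2 >= 1
  zero_within <- testable & ssw == 0
  F_stat <- ifelse(testable & !zero_within, (ssb / df1) / (ssw / df2), NA_real_)
  p <- ifelse(is.na(F_stat), NA_real_, pf(F_stat, df1, df2, lower.tail = FALSE))
  reason <- case_when(
    !testable ~ "fewer than 2 groups with 2+ samples",
    zero_within ~ "zero within-group variance",
    TRUE ~ NA_character_)
  tibble(protein_id = rownames(x), F_stat = unname(F_stat),
         df1 = unname(df1), df2 = unname(df2), p_value = unname(p),
         testable = unname(testable & !zero_within), reason = unname(reason))
}

#' Exclusive set intersections
#'
#' Computes the exact exclusive-intersection cell counts over named sets (the
#' quantities behind Venn and UpSet displays): every element of the union is
#' assigned to exactly one cell keyed by the sets containing it; only
#' nonempty cells are reported.
#'
#' @param sets Named list of character vectors (2 or more sets).
#' @return Tibble: `intersection` (labels joined by `&`), `degree`, `count`,
#'   `members` (list-column), ordered by decreasing count.
#' @examples
#' overlap_sets(list(A = c("1", "2", "3"), B = c("2", "3", "4"), C = "3"))
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- map(sets, unique)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  split_members <- split(universe, key)
  tibble(intersection = names(split_members),
         degree = unname(lengths(strsplit(names(split_members), "&",
                                          fixed = TRUE))),
         count = unname(lengths(split_members)),
         members = unname(split_members)) %>%
    arrange(desc(count), intersection)
}

#' Sample-level principal component analysis
#'
#' Column-mean-centred SVD of the samples x proteins matrix (complete-case
#' proteins only; excluded rows are counted).  Reports sample scores and the
#' proportion of variance per component.
#'
#' @param matrix A log2-scale `abundance_matrix`.
#' @param k Number of components to keep (truncated to the rank, with a
#'   message, when larger).
#' @return A `pca_result`: list with `scores` (tibble: sample metadata +
#'   `PC1..PCk`), `prop_var`, `n_proteins_used`, `n_excluded`.
#' @export
sample_pca <- function(matrix, k = 5) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  keep <- complete.cases(matrix$values)
  n_excluded <- sum(!keep)
  x <- t(matrix$values[keep, , drop = FALSE])
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (k > rank) {
    inform(sprintf("sample_pca: k = %d exceeds rank %d; truncated", k, rank))
    k <- rank
  }
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE]) %>%
    mutate(sample_id = rownames(pc$x), .before = 1) %>%
    left_join(matrix$design$samples, by = "sample_id")
  structure(list(scores = scores, prop_var = prop[seq_len(k)],
                 n_proteins_used = sum(keep), n_excluded = n_excluded),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components over %d proteins (%d excluded)\n",
              length(x$prop_var), x$n_proteins_used, x$n_excluded))
  cat("proportion of variance:",
      paste(sprintf("%.3f", x$prop_var), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  x$scores %>%
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "pc",
                        values_to = "score")
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_components = length(x$prop_var),
         n_proteins_used = x$n_proteins_used, n_excluded = x$n_excluded,
         var_explained = sum(x$prop_var))
}

#' @export
#' @rdname plot_coabund
autoplot.pca_result <- function(object, x = "PC1", y = "PC2", ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[x]], .data[[y]],
                               colour = genotype, shape = timepoint)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", x,
                  100 * object$prop_var[as.integer(sub("PC", "", x))]),
      y = sprintf("%s (%.1f%%)", y,
                  100 * object$prop_var[as.integer(sub("PC", "", y))])) +
    ggplot2::theme_minimal()
}
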