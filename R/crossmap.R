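#' Harmonize gene identifiers across two datasets
#'
#' Joins two per-gene summary tables on gene symbol, case-insensitively by
#' default so that mouse/human orthograph pairs (Stmn2 / STMN2) match
#' without an orthology service; an explicit two-column mapping table
#' (`symbol_a`, `symbol_b`) overrides the default for non-trivial orthology.
#' One-to-many collisions keep every pair and are flagged.
#'
#' @param a,b Tibbles with a `gene_symbol` column (plus any per-gene
#'   columns: `log_fc`, `call`, `cluster`, ...).
#' @param mapping Optional tibble with columns `symbol_a`, `symbol_b`.
#' @return Tibble of joined rows; columns from each dataset suffixed `_a` /
#'   `_b`, plus `gene_key` and `collision`.  Attributes `n_joined`,
#'   `n_unjoined_a`, `n_unjoined_b` report coverage.
#' @export
harmonize_identifiers <- function(a, b, mapping = NULL) {
  a <- as_tibble(a); b <- as_tibble(b)
  stopifnot("gene_symbol" %in% names(a), "gene_symbol" %in% names(b),
            all(nzchar(a$gene_symbol)), all(nzchar(b$gene_symbol)))
  a2 <- a %>% rename_with(~ paste0(.x, "_a"))
  b2 <- b %>% rename_with(~ paste0(.x, "_b"))
  if (is.null(mapping)) {
    a2$gene_key <- toupper(a$gene_symbol)
    b2$gene_key <- toupper(b$gene_symbol)
  } else {
    stopifnot(all(c("symbol_a", "symbol_b") %in% names(mapping)))
    a2$gene_key <- mapping$symbol_b[match(a$gene_symbol, mapping$symbol_a)]
    b2$gene_key <- b$gene_symbol
  }
  joined <- inner_join(a2, b2, by = "gene_key",
                       relationship = "many-to-many") %>%
    group_by(gene_key) %>%
    mutate(collision = n() > 1) %>%
    ungroup()
  out <- joined %>% select(gene_key, dplyr::everything())
  attr(out, "n_joined") <- length(unique(joined$gene_key))
  attr(out, "n_unjoined_a") <- sum(!a2$gene_key %in% b2$gene_key |
                                     is.na(a2$gene_key))
  attr(out, "n_unjoined_b") <- sum(!b2$gene_key %in% a2$gene_key)
  out
}

#' Intersections of altered-gene sets across datasets
#'
#' Exclusive-intersection counts (UpSet-style cells) over two or more named
#' altered-gene sets; delegates to [overlap_sets()].
#'
#' @param datasets Named list of character vectors.
#' @return Tibble as from [overlap_sets()].
#' @export
intersect_alterations <- function(datasets) {
  overlap_sets(datasets)
}

#' Direction-of-change concordance between two datasets
#'
#' Categorises every joined gene by the sign agreement of its fold changes:
#' concordant-up, concordant-down, discordant, or one-sided (changed in only
#' one dataset); non-significant calls count as unchanged.
#'
#' @param joined Tibble from [harmonize_identifiers()] with `log_fc_a`,
#'   `log_fc_b`, `call_a`, `call_b` columns.
#' @return List with `genes` (per-gene tibble: `gene_key`, `category`) and
#'   `summary` (tibble: `category`, `n`, `fraction` over genes changed in
#'   both).
#' @export
direction_concordance <- function(joined) {
  stopifnot(nrow(joined) > 0,
            all(c("log_fc_a", "log_fc_b", "call_a", "call_b") %in%
                  names(joined)))
  sgn <- function(lfc, call) {
    ifelse(call %in% c("ns", "absent", "unchanged"), 0, sign(lfc))
  }
  genes <- joined %>%
    mutate(sa = sgn(log_fc_a, call_a), sb = sgn(log_fc_b, call_b),
           category = case_when(
             sa > 0 & sb > 0 ~ "concordant-up",
             sa < 0 & sb < 0 ~ "concordant-down",
             sa != 0 & sb != 0 ~ "discordant",
             sa != 0 | sb != 0 ~ "one-sided",
             TRUE ~ "unchanged")) %>%
    select(gene_key, category)
  both <- genes %>% filter(category %in%
                             c("concordant-up", "concordant-down", "discordant"))
  summary <- genes %>% count(category, name = "n") %>%
    mutate(fraction = ifelse(category %in% c("concordant-up",
                                             "concordant-down", "discordant"),
                             n / max(nrow(both), 1), NA_real_))
  list(genes = genes, summary = summary)
}

#' Module-module association between two clusterings
#'
#' For every pair of clusters (X from dataset A, Y from dataset B) over a
#' shared gene universe, builds the 2x2 membership table, tests association
#' with a two-sided Fisher exact test, Holm-adjusts across all tested
#' pairs, and reports the overlap, percent similarity
#' (`overlap / min(|X|, |Y|) * 100`), and a significance flag at
#' `p_adj < alpha` (default 0.001, the conventional bar for calling a
#' cross-dataset module correspondence highly indicative).
#'
#' Genes in the universe missing from a clustering take its `unassigned`
#' label; by default unassigned labels appear in the table but are excluded
#' from testing (and from the Holm family).
#'
#' @param assign_a,assign_b Tibbles with `gene_symbol` and `cluster`.
#' @param universe Character vector; default: genes present in both.
#' @param alpha Flag threshold on adjusted p (default 0.001).
#' @param unassigned_label Reserved label (default `"grey"`).
#' @param test_unassigned Include unassigned labels in testing (default
#'   `FALSE`).
#' @param similarity_denom `"min"` (default), `"a"`, `"b"`, or `"jaccard"`.
#' @return A `module_association` tibble: `cluster_a`, `cluster_b`,
#'   `overlap`, `size_a`, `size_b`, `pct_similarity`, `p`, `p_adj`,
#'   `direction` (enriched/depleted relative to independence),
#'   `significant`, `degenerate`, `tested`.
#' @export
module_module_association <- function(assign_a, assign_b, universe = NULL,
                                      alpha = 0.001,
                                      unassigned_label = "grey",
                                      test_unassigned = FALSE,
                                      similarity_denom = c("min", "a", "b",
                                                           "jaccard")) {
  similarity_denom <- match.arg(similarity_denom)
  assign_a <- as_tibble(assign_a); assign_b <- as_tibble(assign_b)
  stopifnot(all(c("gene_symbol", "cluster") %in% names(assign_a)),
            all(c("gene_symbol", "cluster") %in% names(assign_b)))
  if (is.null(universe)) {
    universe <- intersect(assign_a$gene_symbol, assign_b$gene_symbol)
  }
  universe <- unique(universe)
  if (length(universe) == 0) {
    abort("empty gene universe", class = "coabund_value_error")
  }
  la <- assign_a$cluster[match(universe, assign_a$gene_symbol)]
  lb <- assign_b$cluster[match(universe, assign_b$gene_symbol)]
  la[is.na(la)] <- unassigned_label
  lb[is.na(lb)] <- unassigned_label
  N <- length(universe)
  ca <- sort(unique(la)); cb <- sort(unique(lb))
  grid <- tidyr::expand_grid(cluster_a = ca, cluster_b = cb)
  rows <- pmap(grid, function(cluster_a, cluster_b) {
    ina <- la == cluster_a; inb <- lb == cluster_b
    x <- sum(ina & inb); sa <- sum(ina); sb <- sum(inb)
    degenerate <- sa == 0 || sb == 0 || sa == N || sb == N
    p <- if (degenerate) 1 else
      fisher.test(matrix(c(x, sa - x, sb - x, N - sa - sb + x), 2))$p.value
    denom <- switch(similarity_denom,
                    min = min(sa, sb), a = sa, b = sb,
                    jaccard = sa + sb - x)
    tibble(cluster_a = cluster_a, cluster_b = cluster_b, overlap = x,
           size_a = sa, size_b = sb,
           pct_similarity = if (denom > 0) 100 * x / denom else NA_real_,
           p = p, degenerate = degenerate,
           direction = case_when(x > sa * sb / N ~ "enriched",
                                 x < sa * sb / N ~ "depleted",
                                 TRUE ~ "none"),
           tested = !degenerate &
             (test_unassigned | (cluster_a != unassigned_label &
                                   cluster_b != unassigned_label)))
  }) %>% bind_rows()
  rows$p_adj <- NA_real_
  rows$p_adj[rows$tested] <- adjust_pvalues(rows$p[rows$tested], "holm")
  rows$significant <- !is.na(rows$p_adj) & rows$p_adj < alpha
  class(rows) <- c("module_association", class(rows))
  attr(rows, "universe_size") <- N
  rows
}

#' Heatmap of cross-dataset module similarity
#'
#' @param assoc A `module_association` tibble.
#' @return A ggplot tile map of percent similarity with significance stars.
#' @export
plot_module_association <- function(assoc) {
  ggplot2::ggplot(assoc, ggplot2::aes(cluster_b, cluster_a,
                                      fill = pct_similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(significant, "*", "")),
                       size = 6) +
    ggplot2::scale_fill_gradient(low = "white", high = "red") +
    ggplot2::labs(x = "dataset B clusters", y = "dataset A clusters",
                  fill = "% similarity") +
    ggplot2::theme_minimal()
}
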