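#' Weighted co-abundance network analysis
#'
#' Runs the full network chain on a log2 abundance matrix: pairwise Pearson
#' correlation, signed soft-thresholded adjacency (power picked by
#' scale-free fit unless fixed), topological overlap, average-linkage
#' clustering of the TOM distance, dynamic hybrid tree cut, module
#' eigenproteins, and kME module membership.
#'
#' @param matrix A log2-scale `abundance_matrix` (complete cases are the
#'   convention; run [filter_missing()] first).
#' @param params A [network_params()]; `params$beta` is used only when
#'   `pick_power = FALSE`.
#' @param pick_power Choose the soft power by scale-free fit (default
#'   `TRUE`).
#' @param powers Candidate powers for the pick.
#' @return A `wcna_fit`: list with `assignment` (tibble `protein_id`,
#'   `module`, `own_kme`), `eigenproteins`, `kme`, `soft_threshold` (or
#'   `NULL`), `beta`, `tree` (`hclust`), `params`, and module `sizes`.
#' @export
wcna <- function(matrix, params = network_params(), pick_power = TRUE,
                 powers = 1:20) {
  stopifnot(inherits(matrix, "abundance_matrix"),
            inherits(params, "network_params"))
  cc <- correlation_matrix(matrix)
  soft <- NULL
  beta <- params$beta
  if (pick_power) {
    soft <- pick_soft_threshold(cc, powers = powers, rsq_cut = params$rsq_cut,
                                variant = params$adjacency_variant,
                                is_correlation = TRUE)
    beta <- soft$beta
  }
  adj <- signed_adjacency(cc, beta = beta, variant = params$adjacency_variant)
  tom <- topological_overlap(adj)
  tree <- cluster_tree(tom$dist)
  assignment <- dynamic_tree_cut(tree, tom$dist,
                                 min_cluster_size = params$min_cluster_size,
                                 deep_split = params$deep_split,
                                 pam_stage = params$pam_stage)
  eig <- module_eigenproteins(matrix, assignment)
  kme <- module_membership_kme(matrix, eig, assignment)
  own <- kme %>% filter(own_module == module) %>%
    select(protein_id, own_kme = kme)
  assignment2 <- as_tibble(assignment) %>% left_join(own, by = "protein_id")
  structure(list(assignment = assignment2, eigenproteins = eig, kme = kme,
                 soft_threshold = soft, beta = beta, tree = tree,
                 params = params,
                 sizes = assignment2 %>% filter(module != "grey") %>%
                   count(module, sort = TRUE, name = "size")),
            class = "wcna_fit")
}

#' @export
print.wcna_fit <- function(x, ...) {
  n <- nrow(x$assignment)
  ng <- sum(x$assignment$module == "grey")
  cat(sprintf("<wcna_fit> beta = %d; %d of %d proteins in %d modules (%d grey)\n",
              x$beta, n - ng, n, nrow(x$sizes), ng))
  print(x$sizes)
  invisible(x)
}

#' @export
tidy.wcna_fit <- function(x, ...) x$assignment

#' @export
glance.wcna_fit <- function(x, ...) {
  tibble(beta = x$beta,
         power_reached = if (is.null(x$soft_threshold)) NA else
           x$soft_threshold$reached,
         n_modules = nrow(x$sizes),
         n_assigned = sum(x$assignment$module != "grey"),
         n_grey = sum(x$assignment$module == "grey"),
         mean_var_explained = mean(x$eigenproteins$summary$var_explained))
}

#' @export
#' @rdname plot_coabund
autoplot.wcna_fit <- function(object, ...) {
  sizes <- object$sizes %>% mutate(module = factor(module, levels = module))
  ggplot2::ggplot(sizes, ggplot2::aes(module, size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(y = "module size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
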