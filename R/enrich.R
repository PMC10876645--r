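#' Restrict gene sets to a background universe
#'
#' Marker and annotation sets are intersected with the analysis background
#' (e.g. the full list of module proteins) before any enrichment test, so
#' that identifiers never contribute to a contingency table unless they were
#' observable in the experiment.  Sets left empty are dropped with a
#' message.
#'
#' @param sets Tibble with `set_id`, `description`, `members` (list-column),
#'   as from [read_gmt()].
#' @param background Character vector of identifiers.
#' @return The restricted sets tibble with an added `n_retained` column.
#' @export
restrict_to_background <- function(sets, background) {
  stopifnot(length(background) > 0)
  background <- unique(background)
  out <- sets %>%
    mutate(members = map(members, ~ intersect(.x, background)),
           n_retained = lengths(members))
  dropped <- out$set_id[out$n_retained == 0]
  if (length(dropped) > 0) {
    inform(sprintf("restrict_to_background: dropped %d empty set(s): %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  out %>% filter(n_retained > 0)
}

#' Marker-set enrichment of a module by Fisher's exact test
#'
#' Builds the 2x2 table of module membership against marker membership over
#' an explicit background, reports the enrichment ratio
#' `observed/expected = x * N / (m * K)` (so depletion gives a ratio below
#' 1), the sample odds ratio, and the two-sided Fisher exact p-value
#' (probability-mass rule: outcomes no more likely than the observed table).
#'
#' @param module_members Character vector of module identifiers (subset of
#'   `background`).
#' @param marker_set Character vector of marker identifiers (subset of
#'   `background`).
#' @param background Character vector: the test universe.
#' @param module,set_id Optional labels carried into the output.
#' @return One-row tibble: `module`, `set_id`, `x`, `m`, `K`, `N`,
#'   `enrichment_ratio`, `odds_ratio`, `p`, `direction`
#'   (enriched/depleted/none).
#' @examples
#' bg <- sprintf("g%03d", 1:100)
#' fisher_enrichment(bg[1:20], bg[c(1:6, 30:33)], bg)
#' @export
fisher_enrichment <- function(module_members, marker_set, background,
                              module = "module", set_id = "set") {
  background <- unique(background)
  module_members <- unique(module_members)
  marker_set <- unique(marker_set)
  if (!all(module_members %in% background) ||
      !all(marker_set %in% background)) {
    abort("module and marker set must be subsets of the background",
          class = "coabund_value_error")
  }
  N <- length(background)
  m <- length(module_members)
  K <- length(marker_set)
  x <- length(intersect(module_members, marker_set))
  if (m == 0 || K == 0) {
    return(tibble(module = module, set_id = set_id, x = x, m = m, K = K,
                  N = N, enrichment_ratio = NA_real_, odds_ratio = NA_real_,
                  p = 1, direction = "none"))
  }
  tab <- matrix(c(x, K - x, m - x, N - m - K + x), 2)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  ratio <- x * N / (m * K)
  or <- (x * (N - m - K + x)) / ((m - x) * (K - x))
  tibble(module = module, set_id = set_id, x = x, m = m, K = K, N = N,
         enrichment_ratio = ratio, odds_ratio = or, p = min(p, 1),
         direction = case_when(ratio > 1 ~ "enriched",
                               ratio < 1 ~ "depleted",
                               TRUE ~ "none"))
}

#' Cell-type (marker-set) enrichment of every module
#'
#' Applies [fisher_enrichment()] to each module x marker-set pair after
#' restricting the sets to the background (all assigned module proteins by
#' default), then adjusts p-values across all pairs.
#'
#' @param assignment A `module_assignment` tibble (`protein_id`, `module`).
#' @param sets Marker sets tibble (`set_id`, `description`, `members`).
#' @param background Test universe; default: all non-grey assigned proteins.
#' @param adjust P-adjustment method (`"BH"` default, or `"holm"`, `"none"`).
#' @return Tibble of [fisher_enrichment()] rows with `p_adj`.
#' @export
module_set_enrichment <- function(assignment, sets, background = NULL,
                                  adjust = "BH") {
  asg <- as_tibble(assignment) %>% filter(module != "grey")
  if (is.null(background)) background <- unique(asg$protein_id)
  sets <- restrict_to_background(sets, background)
  mods <- unique(asg$module)
  out <- map(mods, function(mo) {
    mem <- intersect(asg$protein_id[asg$module == mo], background)
    map(seq_len(nrow(sets)), function(si) {
      fisher_enrichment(mem, sets$members[[si]], background,
                        module = mo, set_id = sets$set_id[si])
    }) %>% bind_rows()
  }) %>% bind_rows()
  out$p_adj <- if (adjust == "none") out$p else adjust_pvalues(out$p, adjust)
  arrange(out, p)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a query set against each annotation set
#' (`p = P(X >= x)`), with Benjamini-Hochberg adjustment across sets —
#' the generic over-representation machinery behind gene-ontology style
#' analyses, applied to user-supplied GMT collections.
#'
#' @param query_set Character vector of identifiers.
#' @param annotation_sets Tibble (`set_id`, `description`, `members`).
#' @param background Test universe; query and sets are restricted to it.
#' @return Tibble sorted by p: `set_id`, `description`, `x`, `m`, `K`, `N`,
#'   `enrichment_ratio`, `p`, `p_adj`.
#' @export
ora <- function(query_set, annotation_sets, background) {
  background <- unique(background)
  query_set <- intersect(unique(query_set), background)
  if (nrow(annotation_sets) == 0) {
    return(tibble(set_id = character(), description = character(),
                  x = integer(), m = integer(), K = integer(), N = integer(),
                  enrichment_ratio = double(), p = double(), p_adj = double()))
  }
  sets <- restrict_to_background(annotation_sets, background)
  N <- length(background)
  m <- length(query_set)
  out <- map(seq_len(nrow(sets)), function(si) {
    mem <- sets$members[[si]]
    K <- length(mem)
    x <- length(intersect(query_set, mem))
    p <- phyper(x - 1, K, N - K, m, lower.tail = FALSE)
    tibble(set_id = sets$set_id[si], description = sets$description[si],
           x = x, m = m, K = K, N = N,
           enrichment_ratio = if (m * K > 0) x * N / (m * K) else NA_real_,
           p = p)
  }) %>% bind_rows()
  out$p_adj <- adjust_pvalues(out$p, "bh")
  arrange(out, p)
}

#' Multiple-testing adjustment
#'
#' Holm step-down family-wise error control or Benjamini-Hochberg step-up
#' false-discovery-rate control, preserving input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"holm"` or `"bh"` (case-insensitive).
#' @return Adjusted p-values (capped at 1) in the input order.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- tolower(method[1])
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]", class = "coabund_value_error")
  }
  p.adjust(p, method = c(holm = "holm", bh = "BH")[[method]])
}
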