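#' Dynamic hybrid tree cut
#'
#' Cuts an average-linkage TOM dendrogram into modules of adaptive height,
#' in the spirit of the dynamic hybrid procedure: branches qualify as
#' clusters by a joint size / tightness / separation test, and leftover
#' proteins may then be adopted by a nearby cluster.
#'
#' Stage 1 walks the merge tree bottom-up.  A branch qualifies as a cluster
#' candidate when (i) it completes below `cut_height`, (ii) it has at least
#' `min_cluster_size` members, (iii) its *core scatter* — the mean of its
#' internal merge heights, i.e. the average linkage distance inside the
#' branch — is below a ceiling, and (iv) its *gap* — the difference between
#' the height at which the branch attaches to the rest of the tree and its
#' core scatter — exceeds a floor.  Ceiling and floor are set from
#' `deep_split` (0-4; larger = more, smaller clusters) on the scale between
#' the 5% quantile of merge heights and `cut_height`, following the
#' conventional parameterization.  When none of a branch's sub-branches
#' qualifies but the branch does, it becomes a cluster; a cluster then
#' grows upward over merges below the scatter ceiling (adopting stragglers)
#' until two clusters meet or the attachment heights leave the ceiling.
#'
#' Stage 2 (on by default) assigns each unlabelled protein to the cluster
#' with the smallest mean TOM distance, provided that distance is within the
#' cluster's assignment radius (the largest mean within-cluster distance of
#' any member); proteins failing both stages get the reserved `"grey"`
#' label.
#'
#' @param dendrogram `hclust` tree over the same proteins as `tom_distance`.
#' @param tom_distance Symmetric TOM distance matrix (zero diagonal).
#' @param min_cluster_size Minimum module size (default 20).
#' @param deep_split Split sensitivity 0-4 (default 2).
#' @param pam_stage Run stage 2 (default `TRUE`).
#' @param cut_height Maximum merge height considered; default 0.99 of the
#'   tallest merge.
#' @return A `module_assignment`: tibble with `protein_id` and `module`
#'   (size-ranked colour labels; `"grey"` = unassigned), with attributes
#'   `n_stage1`, `n_stage2`, `params`.
#' @export
dynamic_tree_cut <- function(dendrogram, tom_distance, min_cluster_size = 20,
                             deep_split = 2, pam_stage = TRUE,
                             cut_height = NULL) {
  stopifnot(inherits(dendrogram, "hclust"), deep_split %in% 0:4,
            min_cluster_size >= 2)
  n <- length(dendrogram$order)
  labels <- dendrogram$labels %||% as.character(seq_len(n))
  stopifnot(nrow(tom_distance) == n)
  merge <- dendrogram$merge
  height <- dendrogram$height
  if (is.null(cut_height)) cut_height <- 0.99 * max(height)

  ref <- unname(quantile(height, 0.05, names = FALSE))
  max_scatter_rel <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  min_gap_rel <- (1 - max_scatter_rel) * 3 / 4
  span <- max(cut_height - ref, 0)
  max_scatter_abs <- ref + max_scatter_rel * span
  min_gap_abs <- min_gap_rel * span

  nm <- nrow(merge)
  members <- vector("list", nm)
  size <- integer(nm)
  scat_sum <- numeric(nm)   # sum of internal merge heights
  scat_n <- integer(nm)
  parent_height <- rep(Inf, nm)
  for (j in seq_len(nm)) {
    for (child in merge[j, ]) if (child > 0) parent_height[child] <- height[j]
  }
  get_members <- function(child) {
    if (child < 0) -child else members[[child]]
  }
  clusters <- vector("list", nm)  # each: list of member index vectors
  for (j in seq_len(nm)) {
    ml <- get_members(merge[j, 1]); mr <- get_members(merge[j, 2])
    members[[j]] <- c(ml, mr)
    size[j] <- length(members[[j]])
    child_stats <- function(child) {
      if (child < 0) c(0, 0) else c(scat_sum[child], scat_n[child])
    }
    st <- child_stats(merge[j, 1]) + child_stats(merge[j, 2])
    scat_sum[j] <- st[1] + height[j]
    scat_n[j] <- st[2] + 1L

    sub <- c(if (merge[j, 1] > 0) clusters[[merge[j, 1]]] else list(),
             if (merge[j, 2] > 0) clusters[[merge[j, 2]]] else list())
    scatter <- scat_sum[j] / scat_n[j]
    qualifies <- height[j] <= cut_height &&
      size[j] >= min_cluster_size &&
      scatter <= max_scatter_abs &&
      (parent_height[j] - scatter) >= min_gap_abs
    clusters[j] <- list(if (length(sub) >= 2) {
      sub
    } else if (qualifies && (length(sub) == 0 || height[j] <= max_scatter_abs)) {
      # a qualifying branch becomes a cluster; it keeps growing upward over
      # merges that stay below the scatter ceiling, so stragglers join at
      # stage 1 while loosely attached (background-level) objects do not
      list(members[[j]])
    } else {
      sub
    })
  }
  found <- clusters[[nm]]

  assignment <- rep(0L, n)
  for (i in seq_along(found)) assignment[found[[i]]] <- i
  n_stage1 <- sum(assignment > 0)

  n_stage2 <- 0L
  if (pam_stage && length(found) > 0 && any(assignment == 0)) {
    ind <- vapply(seq_along(found), function(i) assignment == i,
                  logical(n))                       # n x k membership
    sizes <- colSums(ind)
    dsum <- tom_distance %*% ind                    # n x k distance sums
    mean_to <- sweep(dsum, 2, sizes, "/")           # mean distance to cluster
    # member i's mean distance to the *other* members of its own cluster
    radius <- vapply(seq_along(found), function(i) {
      mem <- which(ind[, i])
      if (length(mem) < 2) return(0)
      max((dsum[mem, i]) / (sizes[i] - 1))
    }, numeric(1))
    un <- which(assignment == 0)
    best <- max.col(-mean_to[un, , drop = FALSE], ties.method = "first")
    bestd <- mean_to[cbind(un, best)]
    adopt <- bestd < radius[best]
    assignment[un[adopt]] <- best[adopt]
    n_stage2 <- sum(adopt)
  }

  # size-ranked colour labels; ties broken by first-protein order
  lab <- rep("grey", n)
  if (max(assignment) > 0) {
    first_idx <- vapply(seq_len(max(assignment)),
                        function(i) min(which(assignment == i)), numeric(1))
    csize <- tabulate(assignment, max(assignment))
    ord <- order(-csize, first_idx)
    colors <- module_colors(length(ord))
    for (r in seq_along(ord)) lab[assignment == ord[r]] <- colors[r]
  }
  out <- tibble(protein_id = labels, module = lab)
  attr(out, "n_stage1") <- n_stage1
  attr(out, "n_stage2") <- n_stage2
  attr(out, "params") <- list(min_cluster_size = min_cluster_size,
                              deep_split = deep_split, pam_stage = pam_stage,
                              cut_height = cut_height)
  class(out) <- c("module_assignment", class(out))
  out
}

#' Standard module colour sequence
#'
#' Size-ranked module labels drawn from the conventional colour sequence
#' (`"grey"` is reserved for unassigned proteins and never returned).
#'
#' @param n Number of labels.
#' @return Character vector of length `n`.
#' @export
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen",
            "darkturquoise", "darkgrey", "orange", "darkorange", "white",
            "skyblue", "saddlebrown", "steelblue")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("module", seq_len(n - length(base))))
}
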