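#' Network construction parameters
#'
#' @param beta Soft-threshold power (positive integer).
#' @param rsq_cut Scale-free topology fit threshold used when picking the
#'   power automatically (default 0.85).
#' @param min_cluster_size Minimum module size for the tree cut (default 20).
#' @param adjacency_variant `"signed_shifted"` (default,
#'   `((1 + cor)/2)^beta`) or `"absolute"` (`|cor|^beta`).
#' @param pam_stage Run the stage-2 assignment of leftover proteins to
#'   nearby clusters (default `TRUE`).
#' @param deep_split Split-sensitivity level 0-4 of the tree cut (default 2).
#' @return A `network_params` list.
#' @export
network_params <- function(beta = 8L, rsq_cut = 0.85, min_cluster_size = 20L,
                           adjacency_variant = c("signed_shifted", "absolute"),
                           pam_stage = TRUE, deep_split = 2L) {
  adjacency_variant <- match.arg(adjacency_variant)
  stopifnot(beta >= 1, rsq_cut > 0, rsq_cut <= 1, min_cluster_size >= 2,
            deep_split %in% 0:4)
  structure(list(beta = as.integer(beta), rsq_cut = rsq_cut,
                 min_cluster_size = as.integer(min_cluster_size),
                 correlation = "pearson",
                 adjacency_variant = adjacency_variant,
                 tom_variant = "standard",
                 pam_stage = pam_stage, deep_split = as.integer(deep_split)),
            class = "network_params")
}

#' Protein-protein correlation matrix
#'
#' Pairwise-complete Pearson correlations of log2 profiles.  Pairs sharing
#' fewer than `min_shared` samples, and rows involving zero-variance
#' proteins, cannot be estimated; those entries are set to 0 (no evidence of
#' co-abundance) and the counts are messaged and attached as attributes.
#'
#' @param matrix A log2-scale `abundance_matrix`, or a plain proteins x
#'   samples numeric matrix.
#' @param min_shared Minimum shared samples per pair (default 3).
#' @return Symmetric correlation matrix with unit diagonal; attributes
#'   `n_low_overlap` and `n_zero_variance`.
#' @export
correlation_matrix <- function(matrix, min_shared = 3) {
  x <- if (inherits(matrix, "abundance_matrix")) {
    if (matrix$scale != "log2_ratio") {
      abort("correlation_matrix expects log2 ratios",
            class = "coabund_value_error")
    }
    matrix$values
  } else matrix
  cc <- suppressWarnings(cor(t(x), use = "pairwise.complete.obs"))
  shared <- tcrossprod(!is.na(x))
  low <- shared < min_shared
  diag(low) <- FALSE
  zv <- is.na(diag(cc))
  n_zv <- sum(zv)
  n_low <- sum(low[upper.tri(low)])
  if (n_low > 0 || n_zv > 0) {
    inform(sprintf(
      "correlation_matrix: %d pair(s) below %d shared samples and %d zero-variance protein(s); entries set to 0",
      n_low, min_shared, n_zv))
  }
  cc[low] <- 0
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  attr(cc, "n_low_overlap") <- n_low
  attr(cc, "n_zero_variance") <- n_zv
  cc
}

#' Signed soft-thresholded adjacency
#'
#' The signed transform `a_ij = ((1 + cor_ij)/2)^beta` maps correlation 1 to
#' adjacency 1 and correlation -1 to 0, so anticorrelated proteins are
#' dissimilar rather than similar; `variant = "absolute"` gives the unsigned
#' `|cor|^beta` alternative.  Diagonal is 1.
#'
#' @param cor Correlation matrix from [correlation_matrix()].
#' @param beta Soft power (>= 1).
#' @param variant `"signed_shifted"` or `"absolute"`.
#' @return Adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(cor, beta = 8,
                             variant = c("signed_shifted", "absolute")) {
  variant <- match.arg(variant)
  stopifnot(beta >= 1)
  a <- switch(variant,
              signed_shifted = ((1 + cor) / 2)^beta,
              absolute = abs(cor)^beta)
  diag(a) <- 1
  a
}

#' Network connectivity
#'
#' @param adjacency Adjacency matrix.
#' @return Per-protein connectivity `k_i = sum_{j != i} a_ij`.
#' @export
connectivity <- function(adjacency) {
  rowSums(adjacency) - diag(adjacency)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivities into `n_bins` equal-width bins and regresses
#' `log10(frequency)` on `log10(mean connectivity)` over nonempty bins.  The
#' signed fit index is `-sign(slope) * R^2`, positive when the connectivity
#' distribution is decreasing (the scale-free regime).
#'
#' @param k Connectivity vector (nonnegative).
#' @param n_bins Number of equal-width bins (default 10).
#' @return Tibble row: `signed_r2`, `slope`, `mean_k`, `n_bins_used`;
#'   `signed_r2` is `NA` when fewer than 3 nonempty bins remain.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  stopifnot(all(k >= 0), length(k) >= n_bins)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  kmean <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(ok) < 3) {
    return(tibble(signed_r2 = NA_real_, slope = NA_real_, mean_k = mean(k),
                  n_bins_used = sum(ok)))
  }
  y <- log10(freq[ok])
  if (sd(y) < 1e-10) {
    # flat connectivity distribution: no trend to fit
    return(tibble(signed_r2 = 0, slope = 0, mean_k = mean(k),
                  n_bins_used = sum(ok)))
  }
  fit <- lm(y ~ log10(kmean[ok]))
  slope <- unname(coef(fit)[2])
  # exact log-log-linear inputs trigger the "essentially perfect fit" warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(signed_r2 = -sign(slope) * r2, slope = slope, mean_k = mean(k),
         n_bins_used = sum(ok))
}

#' Choose the soft-threshold power
#'
#' Evaluates candidate powers and returns the smallest whose signed
#' scale-free fit reaches `rsq_cut`; if none reaches it, the power with the
#' best defined fit is returned with `reached = FALSE`.  The full fit table
#' is always attached.
#'
#' @param matrix Log2 `abundance_matrix`, plain matrix, or a precomputed
#'   correlation matrix (`is_correlation = TRUE`).
#' @param powers Candidate powers (default 1..20).
#' @param rsq_cut Fit threshold (default 0.85).
#' @param variant Adjacency variant.
#' @param n_bins Bins for [scale_free_fit()].
#' @param is_correlation Treat `matrix` as an already-computed correlation
#'   matrix.
#' @return A `soft_threshold` object: list with `beta`, `reached`, and
#'   `fit_table` (power, signed_r2, slope, mean_k).
#' @export
pick_soft_threshold <- function(matrix, powers = 1:20, rsq_cut = 0.85,
                                variant = "signed_shifted", n_bins = 10,
                                is_correlation = FALSE) {
  cc <- if (is_correlation) matrix else correlation_matrix(matrix)
  base <- switch(variant,
                 signed_shifted = (1 + cc) / 2,
                 absolute = abs(cc))
  diag(base) <- 0   # exclude self from connectivity
  fits <- map(powers, function(b) {
    k <- rowSums(base^b)
    mutate(scale_free_fit(k, n_bins = n_bins), power = b, .before = 1)
  }) %>% bind_rows()
  defined <- !is.na(fits$signed_r2)
  if (!any(defined)) {
    abort("scale-free fit undefined for every candidate power",
          class = "coabund_degenerate_error")
  }
  hit <- which(defined & fits$signed_r2 >= rsq_cut)
  if (length(hit) > 0) {
    beta <- fits$power[hit[1]]; reached <- TRUE
  } else {
    beta <- fits$power[which.max(ifelse(defined, fits$signed_r2, -Inf))]
    reached <- FALSE
  }
  structure(list(beta = beta, reached = reached, rsq_cut = rsq_cut,
                 fit_table = fits),
            class = "soft_threshold")
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat(sprintf("<soft_threshold> beta = %d (rsq_cut %.2f %s)\n", x$beta,
              x$rsq_cut, if (x$reached) "reached" else "NOT reached"))
  print(x$fit_table, n = 5)
  invisible(x)
}

#' @export
tidy.soft_threshold <- function(x, ...) x$fit_table

#' @export
glance.soft_threshold <- function(x, ...) {
  tibble(beta = x$beta, reached = x$reached, rsq_cut = x$rsq_cut,
         best_signed_r2 = max(x$fit_table$signed_r2, na.rm = TRUE))
}

#' Diagnostic plots for coabund result objects
#'
#' @param object A result object (`soft_threshold`, `pca_result`,
#'   `module_set`, or module profile table).
#' @param x,y Score columns for the PCA plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plot_coabund
#' @export
autoplot.soft_threshold <- function(object, ...) {
  ggplot2::ggplot(object$fit_table,
                  ggplot2::aes(power, signed_r2)) +
    ggplot2::geom_hline(yintercept = object$rsq_cut, linetype = 2,
                        colour = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "soft-threshold power",
                  y = expression("signed scale-free fit" ~ R^2)) +
    ggplot2::theme_minimal()
}
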