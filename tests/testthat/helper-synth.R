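# shared fixture builders (everything generated in code)

# run the ingest chain on a simulated dataset, quietly
ingest_sim <- function(cfg, max_missing = 0) {
  sim <- simulate_dataset(cfg)
  rt <- purrr::imap(sim$plexes, function(tab, p) {
    reference_ratios(tab, cfg$design$reference_channels[[p]])
  })
  lmat <- suppressMessages(
    log_transform(filter_missing(merge_plexes(rt, cfg$design), max_missing)))
  list(lmat = lmat, sim = sim)
}

# the canonical 45-sample longitudinal design
tiny_design <- function(seed = 1) {
  generate_design(5, c("1wk", "2wk", "4wk", "6wk"),
                  c("1wk", "2wk", "4wk", "6wk", "rec"),
                  n_plexes = 5, channels_per_plex = 10,
                  reference_channel = "131", seed = seed)
}

# a design for plain matrices: k samples in one plex, generic labels
flat_design <- function(n_samples, prefix = "s") {
  ids <- paste0(prefix, seq_len(n_samples))
  coabund:::new_study_design(
    tibble::tibble(sample_id = ids, plex = "plex1",
                   channel = paste0("c", seq_len(n_samples)),
                   genotype = "g", timepoint = "t"),
    c(plex1 = paste0("c", n_samples + 1)))
}

# wrap a bare numeric matrix as a log2 abundance_matrix
as_log2_mat <- function(x, ids = NULL) {
  if (is.null(rownames(x))) {
    rownames(x) <- ids %||% sprintf("p%03d", seq_len(nrow(x)))
  }
  d <- flat_design(ncol(x))
  colnames(x) <- d$samples$sample_id
  abundance_matrix(x, d, scale = "log2_ratio")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# block-structured distance matrix: two tight blocks, far apart
two_block_dist <- function(n_per = 50, within = 0.1, between = 0.9) {
  n <- 2 * n_per
  d <- matrix(between, n, n)
  d[seq_len(n_per), seq_len(n_per)] <- within
  d[n_per + seq_len(n_per), n_per + seq_len(n_per)] <- within
  diag(d) <- 0
  dimnames(d) <- list(sprintf("p%03d", 1:n), sprintf("p%03d", 1:n))
  d
}

# brute-force TOM oracle: triple loop over the formula
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# two-sided Fisher p by full hypergeometric enumeration
fisher_oracle <- function(x, m, K, N) {
  support <- max(0, m + K - N):min(m, K)
  probs <- dhyper(support, K, N - K, m)
  obs <- dhyper(x, K, N - K, m)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# deterministic hub-structured correlation matrix whose scale-free fit
# first crosses 0.85 at soft power 8 (rank-1 loadings c_i = (i/n)^9)
hub_correlation <- function(n = 300, alpha = 9) {
  c_i <- (seq_len(n) / n)^alpha
  cc <- outer(c_i, c_i)
  diag(cc) <- 1
  cc
}
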