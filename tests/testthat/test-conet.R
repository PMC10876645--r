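test_that("correlation matrix handles exact, degenerate and sparse pairs", {
  set.seed(3)
  x <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(paste0("p", 1:5), NULL))
  x[2, ] <- -x[1, ]                     # exact anticorrelation
  x[4, ] <- 1                           # zero variance
  x[5, c(3:6)] <- NA                    # only 2 shared samples with others
  cc <- suppressMessages(correlation_matrix(as_log2_mat(x)))
  expect_equal(diag(cc), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cc[1, 2], -1, tolerance = 1e-12)
  # hand-computed Pearson for the (1,3) pair
  r13 <- sum((x[1, ] - mean(x[1, ])) * (x[3, ] - mean(x[3, ]))) /
    sqrt(sum((x[1, ] - mean(x[1, ]))^2) * sum((x[3, ] - mean(x[3, ]))^2))
  expect_equal(cc[1, 3], r13, tolerance = 1e-12)
  expect_equal(cc[4, 1], 0)             # zero-variance row zeroed
  expect_equal(cc[5, 1], 0)             # < 3 shared samples zeroed
  expect_equal(attr(cc, "n_zero_variance"), 1)
})

test_that("signed adjacency maps endpoints and powers correctly", {
  cc <- matrix(c(1, 0, -1, 0.5,
                 0, 1, 0, 0,
                 -1, 0, 1, 0,
                 0.5, 0, 0, 1), 4)
  a8 <- signed_adjacency(cc, beta = 8)
  expect_equal(a8[1, 3], 0)
  expect_equal(a8[1, 2], 0.5^8)
  expect_equal(a8[1, 2], 0.00390625)
  a1 <- signed_adjacency(cc, beta = 1)
  expect_equal(a1[1, 4], 0.75)
  expect_equal(diag(a8), rep(1, 4))
  # absolute variant keeps anticorrelation similar
  expect_equal(signed_adjacency(cc, 2, variant = "absolute")[1, 3], 1)
})

test_that("signed adjacency is monotone in correlation and in beta", {
  r <- seq(-0.99, 1, length.out = 50)
  for (b in c(1, 4, 8)) {
    a <- ((1 + r) / 2)^b
    expect_true(all(diff(a) > 0))
  }
  for (ri in c(-0.5, 0, 0.8)) {
    ab <- vapply(1:12, function(b) ((1 + ri) / 2)^b, numeric(1))
    expect_true(all(diff(ab) < 0))      # higher power shrinks sub-unit edges
  }
})

test_that("connectivity sums off-diagonal adjacency", {
  a <- matrix(1, 5, 5)
  expect_equal(connectivity(a), rep(4, 5))
  z <- diag(5)
  expect_equal(connectivity(z), rep(0, 5))
  set.seed(4)
  r <- matrix(runif(100), 10); r <- (r + t(r)) / 2; diag(r) <- 1
  k <- connectivity(r)
  k_loop <- vapply(1:10, function(i) sum(r[i, -i]), numeric(1))
  expect_equal(k, k_loop, tolerance = 1e-15)
})

test_that("scale-free fit recovers perfect, flat and increasing laws", {
  # perfect: bin counts exactly proportional to (bin centre)^-1
  centres <- c(10, 30, 50, 70, 90)
  k_perfect <- rep(centres, 6300 / centres)
  fit <- scale_free_fit(k_perfect, n_bins = 5)
  expect_equal(fit$signed_r2, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -1, tolerance = 1e-12)

  # exactly uniform frequencies: slope 0, signed R^2 0
  k_unif <- rep(centres, each = 50)
  fit_u <- scale_free_fit(k_unif, n_bins = 5)
  expect_equal(fit_u$signed_r2, 0)
  expect_equal(fit_u$slope, 0)

  # increasing p(k): negative signed R^2
  k_inc <- rep(centres, centres)
  fit_i <- scale_free_fit(k_inc, n_bins = 5)
  expect_lt(fit_i$signed_r2, 0)
})

test_that("soft-threshold selection honours the cut and the fallback", {
  cc <- hub_correlation()
  st <- pick_soft_threshold(cc, is_correlation = TRUE)
  expect_true(st$reached)
  expect_equal(st$beta, 8)   # calibrated hub construction crosses at 8
  expect_true(all(diff(st$fit_table$power) > 0))

  st0 <- pick_soft_threshold(cc, is_correlation = TRUE, rsq_cut = 1e-9)
  expect_equal(st0$beta, 1)

  st_hi <- pick_soft_threshold(cc, is_correlation = TRUE, rsq_cut = 0.99999)
  expect_false(st_hi$reached)
  expect_equal(st_hi$beta,
               st_hi$fit_table$power[which.max(st_hi$fit_table$signed_r2)])
})

test_that("TOM matches hand evaluation and the triple-loop oracle", {
  # 3-node hand example
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.8
  a[1, 3] <- a[3, 1] <- 0.6
  a[2, 3] <- a[3, 2] <- 0.4
  diag(a) <- 1
  tom <- topological_overlap(a)$tom
  expect_equal(tom[1, 2], 1.04 / 1.4, tolerance = 1e-12)

  # endpoints
  cg <- matrix(1, 6, 6)
  expect_equal(max(abs(topological_overlap(cg)$tom - 1)), 0)
  expect_equal(max(abs(topological_overlap(diag(6))$tom - diag(6))), 0)

  # random adjacencies vs brute force
  set.seed(5)
  for (i in 1:3) {
    r <- matrix(runif(50 * 50), 50); r <- (r + t(r)) / 2; diag(r) <- 1
    tomv <- topological_overlap(r)$tom
    expect_lt(max(abs(tomv - tom_oracle(r))), 1e-10)
    expect_true(all(tomv >= 0 & tomv <= 1))
    expect_equal(tomv, t(tomv), tolerance = 1e-12)
  }
})

test_that("UPGMA tree follows the hand-computed merge order", {
  d <- matrix(c(0, 0.2, 0.8,
                0.2, 0, 0.8,
                0.8, 0.8, 0), 3, dimnames = list(paste0("p", 1:3),
                                                 paste0("p", 1:3)))
  h <- cluster_tree(d)
  expect_equal(h$height, c(0.2, 0.8), tolerance = 1e-12)
  expect_equal(sort(h$merge[1, ]), c(-2, -1))
  expect_true(all(diff(h$height) >= 0))

  ident <- matrix(0, 4, 4, dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  expect_equal(cluster_tree(ident)$height, rep(0, 3))

  dn <- d; dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(cluster_tree(dn), class = "coabund_value_error")
})

test_that("dynamic tree cut recovers clean blocks exactly", {
  d <- two_block_dist(50)
  h <- cluster_tree(d)
  asg <- dynamic_tree_cut(h, d, min_cluster_size = 20)
  expect_equal(sum(asg$module == "grey"), 0)
  expect_equal(dplyr::n_distinct(asg$module), 2)
  # blocks never mix
  expect_equal(dplyr::n_distinct(asg$module[1:50]), 1)
  expect_equal(dplyr::n_distinct(asg$module[51:100]), 1)
  expect_false(asg$module[1] == asg$module[51])
  # labels are size-ranked colours
  expect_setequal(unique(asg$module), c("turquoise", "blue"))
})

test_that("undersized branches and oversized minima go grey", {
  d <- two_block_dist(10)
  h <- cluster_tree(d)
  asg <- dynamic_tree_cut(h, d, min_cluster_size = 20)
  expect_true(all(asg$module == "grey"))

  d2 <- two_block_dist(30)
  h2 <- cluster_tree(d2)
  asg2 <- dynamic_tree_cut(h2, d2, min_cluster_size = 100)
  expect_true(all(asg2$module == "grey"))
})

test_that("duplicated proteins are never split across modules", {
  set.seed(6)
  res <- ingest_sim(default_synth_config(21, n_proteins = 600,
                                         module_spec = tibble::tibble(
                                           module_id = c("M1", "M2"),
                                           size = c(60L, 40L),
                                           template_id = c("early_maintained_up",
                                                           "late_up_persisting"))))
  x <- res$lmat$values
  x <- rbind(x, dup_of_p1 = x["P00001", ])
  m <- as_log2_mat(x)
  cc <- suppressMessages(correlation_matrix(m))
  tomd <- topological_overlap(signed_adjacency(cc, 8))$dist
  h <- cluster_tree(tomd)
  asg <- dynamic_tree_cut(h, tomd, min_cluster_size = 20)
  expect_equal(asg$module[asg$protein_id == "P00001"],
               asg$module[asg$protein_id == "dup_of_p1"])
})

test_that("module assignment is deterministic", {
  res <- ingest_sim(default_synth_config(31))
  f1 <- suppressMessages(wcna(res$lmat, pick_power = FALSE))
  f2 <- suppressMessages(wcna(res$lmat, pick_power = FALSE))
  expect_identical(f1$assignment, f2$assignment)
})

test_that("eigenproteins are first principal components with aligned sign", {
  # identical standardized profiles: explained variance 1, kME 1
  d <- flat_design(10)
  v <- rnorm(10)
  x <- outer(rep(1, 8), v) + outer(rnorm(8, 0, 0), v)
  rownames(x) <- sprintf("p%02d", 1:8); colnames(x) <- d$samples$sample_id
  m <- abundance_matrix(x, d, scale = "log2_ratio")
  asg <- tibble::tibble(protein_id = rownames(x), module = "turquoise")
  eig <- module_eigenproteins(m, asg)
  expect_equal(eig$summary$var_explained, 1, tolerance = 1e-12)
  kme <- module_membership_kme(m, eig)
  expect_equal(kme$kme, rep(1, 8), tolerance = 1e-10)

  # two orthogonal equal halves: explained variance 1/2
  set.seed(8)
  s1 <- scale(rnorm(10)); s2 <- scale(residuals(lm(rnorm(10) ~ s1)))
  x2 <- rbind(outer(rep(1, 4), as.vector(s1)), outer(rep(1, 4), as.vector(s2)))
  dimnames(x2) <- dimnames(x)
  eig2 <- module_eigenproteins(
    abundance_matrix(x2, d, scale = "log2_ratio"), asg)
  expect_equal(eig2$summary$var_explained, 0.5, tolerance = 1e-10)
})

test_that("eigenprotein equals the leading covariance eigenvector", {
  set.seed(9)
  d <- flat_design(20)
  x <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(sprintf("p%02d", 1:30), d$samples$sample_id))
  m <- abundance_matrix(x, d, scale = "log2_ratio")
  asg <- tibble::tibble(protein_id = rownames(x), module = "blue")
  eig <- module_eigenproteins(m, asg)
  xs <- t(scale(t(x)))
  ev <- eigen(crossprod(xs), symmetric = TRUE)$vectors[, 1]
  cosang <- abs(sum(eig$values[, "blue"] * ev))
  expect_equal(cosang, 1, tolerance = 1e-8)

  # first-PC optimality: no member profile explains more variance
  total <- sum(xs^2)
  member_expl <- apply(xs, 1, function(r) {
    u <- r / sqrt(sum(r^2))
    sum((xs %*% u)^2) / total
  })
  expect_true(all(eig$summary$var_explained >= member_expl - 1e-12))
})

test_that("kME separates members from background on planted data", {
  res <- ingest_sim(default_synth_config(17))
  fit <- suppressMessages(wcna(res$lmat, pick_power = FALSE))
  tr <- res$sim$truth$modules
  kme <- fit$kme |>
    dplyr::mutate(truth = tr$module_id[match(protein_id, tr$protein_id)])
  for (m in unique(fit$assignment$module[fit$assignment$module != "grey"])) {
    per <- kme[kme$module == m, ]
    planted <- names(which.max(table(per$truth[per$own_module == m])))
    med_mem <- median(per$kme[per$truth == planted], na.rm = TRUE)
    med_bg <- median(per$kme[per$truth == "background"], na.rm = TRUE)
    expect_gt(med_mem, med_bg)
  }
  # orthogonality/duplication endpoints
  hubs <- hub_proteins(fit$kme, n = 3)
  expect_true(all(hubs$rank_own <= 3))
})

test_that("module profiles reflect the planted temporal templates", {
  # module_correlation = 0 removes the shared-factor group noise, so the
  # recovered profile must match the planted template closely
  res <- ingest_sim(default_synth_config(23, module_correlation = 0))
  tr <- res$sim$truth$modules
  asg <- tibble::tibble(protein_id = tr$protein_id,
                        module = tr$module_id) |>
    dplyr::mutate(module = ifelse(module == "background", "grey", module))
  prof <- module_profiles(res$lmat, asg)
  # transient-early-up module (M6): elevated at rNLS8 1wk/2wk only
  m6 <- prof[prof$module == "M6", ]
  early <- m6$median[m6$genotype == "rNLS8" & m6$timepoint %in% c("1wk", "2wk")]
  late <- m6$median[m6$genotype == "rNLS8" & m6$timepoint %in% c("4wk", "6wk", "rec")]
  ctl <- m6$median[m6$genotype == "control"]
  expect_equal(early, rep(0.585, 2), tolerance = 0.2)
  expect_true(all(abs(late) < 0.12))
  expect_true(all(abs(ctl) < 0.12))
  # progressive-down module (M1): full decrease at 6wk, partial at 4wk
  m1 <- prof[prof$module == "M1", ]
  expect_equal(m1$median[m1$genotype == "rNLS8" & m1$timepoint == "6wk"],
               -0.585, tolerance = 0.2)
  expect_lt(m1$median[m1$genotype == "rNLS8" & m1$timepoint == "4wk"],
            m1$median[m1$genotype == "rNLS8" & m1$timepoint == "2wk"])
})

test_that("zero planted effects give flat module profiles", {
  cfg <- default_synth_config(27, effect_size_log2 = 0, module_correlation = 0)
  res <- ingest_sim(cfg)
  tr <- res$sim$truth$modules
  asg <- tibble::tibble(protein_id = tr$protein_id, module = tr$module_id) |>
    dplyr::mutate(module = ifelse(module == "background", "grey", module))
  prof <- module_profiles(res$lmat, asg)
  expect_lt(max(abs(prof$median)), 0.25)
  expect_lt(mean(abs(prof$median)), 0.1)
})
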