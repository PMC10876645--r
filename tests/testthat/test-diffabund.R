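mk_two_group <- function(a, b) {
  # one-protein matrix over length(a)+length(b) samples in two design cells
  n <- length(a) + length(b)
  ids <- paste0("s", seq_len(n))
  d <- coabund:::new_study_design(
    tibble::tibble(sample_id = ids, plex = "plex1",
                   channel = paste0("c", seq_len(n)),
                   genotype = rep(c("control", "rNLS8"), c(length(a), length(b))),
                   timepoint = "t1"),
    c(plex1 = paste0("c", n + 1)))
  x <- matrix(c(a, b), 1, n, dimnames = list("p1", ids))
  list(mat = abundance_matrix(x, d, scale = "log2_ratio"),
       cmp = comparison_spec(tibble::tibble(genotype = "control", timepoint = "t1"),
                             tibble::tibble(genotype = "rNLS8", timepoint = "t1"),
                             "b_vs_a"))
}

test_that("pooled t matches the closed-form worked example", {
  tg <- mk_two_group(c(-0.1, 0, 0.1), c(0.9, 1.0, 1.1))
  de <- pairwise_de(tg$mat, tg$cmp)
  # t = delta / (s_p * sqrt(2/3)) with s_p = 0.1, delta = 1
  expect_equal(de$t_stat, 1 / (0.1 * sqrt(2 / 3)), tolerance = 1e-10)
  expect_equal(de$t_stat, 12.247, tolerance = 1e-3)
  expect_equal(de$df, 4)
  expect_equal(de$fold_change, 2, tolerance = 1e-12)
  # cross-check against stats::t.test with pooled variance
  tt <- t.test(c(0.9, 1.0, 1.1), c(-0.1, 0, 0.1), var.equal = TRUE)
  expect_equal(de$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("fold change is the geometric mean of ratio quotients", {
  # ratios {2, 0.5} vs baseline {1, 1}: GM of fold changes = 1
  tg <- mk_two_group(log2(c(1, 1)), log2(c(2, 0.5)))
  de <- pairwise_de(tg$mat, tg$cmp)
  expect_equal(de$fold_change, 1, tolerance = 1e-12)
  # and is invariant to the log base used for testing: GM computed directly
  gm <- exp(mean(log(c(2, 0.5))) - mean(log(c(1, 1))))
  expect_equal(de$fold_change, gm, tolerance = 1e-12)
})

test_that("degenerate variance follows the declared contract", {
  tg_eq <- mk_two_group(c(0.5, 0.5), c(0.5, 0.5))
  de_eq <- pairwise_de(tg_eq$mat, tg_eq$cmp)
  expect_equal(de_eq$t_stat, 0)
  expect_equal(de_eq$p_value, 1)

  tg_ne <- mk_two_group(c(0, 0), c(1, 1))
  de_ne <- pairwise_de(tg_ne$mat, tg_ne$cmp)
  expect_equal(de_ne$call, "untestable")
  expect_true(is.na(de_ne$p_value))
})

test_that("one sample left in a group makes the protein untestable", {
  tg <- mk_two_group(c(0.1, NA, NA), c(0.9, 1.0, 1.1))
  de <- pairwise_de(tg$mat, tg$cmp)
  expect_equal(de$call, "untestable")
})

test_that("classification applies the joint fold-change and p gate", {
  tab <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"), comparison = "x",
    n_a = 5, n_b = 5,
    log2fc = log2(c(1.25, 1.19, 0.80, 1.5)),
    fold_change = c(1.25, 1.19, 0.80, 1.5),
    t_stat = 1, df = 8,
    p_value = c(0.01, 0.0001, 0.04, 0.2),
    call = NA_character_)
  out <- suppressMessages(classify_de(tab))
  expect_equal(out$call, c("up", "ns", "down", "ns"))
})

test_that("classification is monotone in its thresholds", {
  set.seed(1)
  tab <- tibble::tibble(
    protein_id = sprintf("p%03d", 1:200), comparison = "x",
    n_a = 5, n_b = 5, log2fc = rnorm(200, 0, 0.5),
    t_stat = 1, df = 8, p_value = runif(200), call = NA_character_) |>
    dplyr::mutate(fold_change = 2^log2fc)
  base <- suppressMessages(classify_de(tab, fc_up = 1.3, p_cut = 0.03))
  wide <- suppressMessages(classify_de(tab, fc_up = 1.1, p_cut = 0.10))
  called <- base$call %in% c("up", "down")
  expect_true(all(wide$call[called] == base$call[called]))
})

test_that("per-protein ANOVA matches stats::aov and the t^2 identity", {
  set.seed(7)
  d <- tiny_design()
  x <- matrix(rnorm(45 * 30), 30, 45,
              dimnames = list(sprintf("p%03d", 1:30), d$samples$sample_id))
  x[1, 4] <- NA
  m <- abundance_matrix(x, d, scale = "log2_ratio")
  res <- protein_anova(m)
  grp <- paste(d$samples$genotype, d$samples$timepoint, sep = ":")
  for (i in c(1, 5, 17)) {
    ref <- anova(stats::aov(x[i, ] ~ factor(grp)))
    expect_equal(res$F_stat[i], ref[1, "F value"], tolerance = 1e-10)
    expect_equal(res$p_value[i], ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
  # two-group ANOVA F equals pooled-t squared
  tg <- mk_two_group(rnorm(5), rnorm(5, 0.4))
  f2 <- protein_anova(tg$mat)
  t2 <- pairwise_de(tg$mat, tg$cmp)
  expect_equal(f2$F_stat, t2$t_stat^2, tolerance = 1e-10)
})

test_that("ANOVA flags untestable cases instead of erroring", {
  d <- tiny_design()
  x <- matrix(rnorm(45 * 2), 2, 45,
              dimnames = list(c("a", "b"), d$samples$sample_id))
  # protein a observed in a single sample of each group but one
  x["a", -(1:3)] <- NA
  # protein b constant everywhere: zero within-group variance
  x["b", ] <- 1
  res <- protein_anova(abundance_matrix(x, d, scale = "log2_ratio"))
  expect_false(res$testable[res$protein_id == "a"])
  expect_false(res$testable[res$protein_id == "b"])
  expect_match(res$reason[res$protein_id == "b"], "variance")
})

test_that("overlap_sets enumerates exclusive intersection cells", {
  ov <- overlap_sets(list(A = c("1", "2", "3"), B = c("2", "3", "4"), C = "3"))
  cells <- setNames(ov$count, ov$intersection)
  expect_equal(cells[["A"]], 1)
  expect_equal(cells[["A&B"]], 1)
  expect_equal(cells[["A&B&C"]], 1)
  expect_equal(cells[["B"]], 1)
  expect_equal(sum(ov$count), 4)        # cells partition the union
  expect_equal(sort(ov$members[[which(ov$intersection == "A&B&C")]]), "3")

  ident <- overlap_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(ident$intersection, "A&B")
  expect_equal(ident$count, 2)

  disj <- overlap_sets(list(A = c("x"), B = c("y", "z")))
  expect_setequal(disj$intersection, c("A", "B"))
  expect_equal(sum(disj$count), 3)
})

test_that("sample PCA matches the covariance eigen-decomposition", {
  set.seed(11)
  d <- flat_design(12)
  x <- matrix(rnorm(12 * 40), 40, 12,
              dimnames = list(sprintf("p%03d", 1:40), d$samples$sample_id))
  m <- abundance_matrix(x, d, scale = "log2_ratio")
  pc <- sample_pca(m, k = 5)
  ev <- eigen(stats::cov(t(x)), symmetric = TRUE)$values
  expect_equal(pc$prop_var, (ev / sum(ev))[1:5], tolerance = 1e-10)
  expect_true(all(diff(pc$prop_var) <= 1e-12))

  # rank-1 data: first component carries everything
  r1 <- outer(rnorm(40), rnorm(12))
  dimnames(r1) <- dimnames(x)
  pr <- suppressMessages(sample_pca(
    abundance_matrix(r1, d, scale = "log2_ratio"), k = 2))
  expect_equal(pr$prop_var[1], 1, tolerance = 1e-10)

  # duplicated samples contribute no extra variance direction
  dup <- x; dup[, 2] <- dup[, 1]
  pd <- sample_pca(abundance_matrix(dup, d, scale = "log2_ratio"), k = 5)
  expect_equal(sum(pd$prop_var), sum((eigen(stats::cov(t(dup)))$values /
                                        sum(eigen(stats::cov(t(dup)))$values))[1:5]),
               tolerance = 1e-10)
})

test_that("PCA uses complete-case proteins and counts exclusions", {
  d <- flat_design(6)
  x <- matrix(rnorm(6 * 10), 10, 6,
              dimnames = list(sprintf("p%02d", 1:10), d$samples$sample_id))
  x[c(2, 5), 1] <- NA
  pc <- sample_pca(abundance_matrix(x, d, scale = "log2_ratio"), k = 3)
  expect_equal(pc$n_proteins_used, 8)
  expect_equal(pc$n_excluded, 2)
})
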