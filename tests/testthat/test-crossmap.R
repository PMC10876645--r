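test_that("identifier harmonization folds case and reports coverage", {
  a <- tibble::tibble(gene_symbol = c("Stmn2", "Gfap", "Tardbp"),
                      log_fc = c(1, -1, 0.5), call = c("up", "down", "up"))
  b <- tibble::tibble(gene_symbol = c("STMN2", "MOG"),
                      log_fc = c(0.8, 0.2), call = c("up", "ns"))
  j <- harmonize_identifiers(a, b)
  expect_equal(nrow(j), 1)
  expect_equal(j$gene_key, "STMN2")
  expect_equal(attr(j, "n_joined"), 1)
  expect_equal(attr(j, "n_unjoined_a"), 2)
  expect_equal(attr(j, "n_unjoined_b"), 1)

  # disjoint symbol sets
  j0 <- harmonize_identifiers(
    tibble::tibble(gene_symbol = "Aaa", log_fc = 1, call = "up"),
    tibble::tibble(gene_symbol = "Bbb", log_fc = 1, call = "up"))
  expect_equal(nrow(j0), 0)

  # duplicated symbols emit every pair, flagged
  adup <- tibble::tibble(gene_symbol = c("Dup", "DUP"), log_fc = c(1, 2),
                         call = "up")
  jd <- harmonize_identifiers(adup, tibble::tibble(gene_symbol = "dup",
                                                   log_fc = 3, call = "up"))
  expect_equal(nrow(jd), 2)
  expect_true(all(jd$collision))
})

test_that("an explicit mapping table overrides the case-insensitive join", {
  a <- tibble::tibble(gene_symbol = "MouseOnlyName", log_fc = 1, call = "up")
  b <- tibble::tibble(gene_symbol = "HUMANNAME", log_fc = 1, call = "up")
  expect_equal(nrow(harmonize_identifiers(a, b)), 0)
  map <- tibble::tibble(symbol_a = "MouseOnlyName", symbol_b = "HUMANNAME")
  expect_equal(nrow(harmonize_identifiers(a, b, mapping = map)), 1)
})

test_that("alteration intersections enumerate UpSet cells", {
  ov <- intersect_alterations(list(A = c("g1", "g2"), B = c("g2", "g3"),
                                   C = "g2"))
  cells <- setNames(ov$count, ov$intersection)
  expect_equal(cells[["A"]], 1)
  expect_equal(cells[["A&B&C"]], 1)
  expect_equal(cells[["B"]], 1)

  ident <- intersect_alterations(list(X = c("a", "b"), Y = c("a", "b"),
                                      Z = c("a", "b")))
  expect_equal(ident$intersection, "X&Y&Z")
  expect_equal(ident$count, 2)
})

test_that("direction concordance categorises sign agreement", {
  a <- tibble::tibble(gene_symbol = paste0("G", 1:6),
                      log_fc = c(1, -1, 1, -1, 1, 0.5),
                      call = c("up", "down", "up", "down", "up", "ns"))
  b <- tibble::tibble(gene_symbol = paste0("G", 1:6),
                      log_fc = c(2, -2, -1, 1, 0.1, 1),
                      call = c("up", "down", "down", "up", "ns", "up"))
  conc <- direction_concordance(harmonize_identifiers(a, b))
  got <- setNames(conc$genes$category, conc$genes$gene_key)
  expect_equal(unname(got[c("G1", "G2", "G3", "G4", "G5", "G6")]),
               c("concordant-up", "concordant-down", "discordant",
                 "discordant", "one-sided", "one-sided"))
  s <- conc$summary
  expect_equal(s$n[s$category == "discordant"], 2)
  expect_equal(s$fraction[s$category == "concordant-up"], 0.25)

  # self-join: fully concordant among significant genes
  self <- direction_concordance(harmonize_identifiers(a, a))
  expect_false(any(self$genes$category == "discordant"))
  # flipped signs: fully discordant among shared calls
  aflip <- a |> dplyr::mutate(log_fc = -log_fc,
                              call = c(down = "up", up = "down",
                                       ns = "ns")[call])
  flip <- direction_concordance(harmonize_identifiers(a, aflip))
  expect_false(any(flip$genes$category %in%
                     c("concordant-up", "concordant-down")))
  expect_equal(sum(flip$genes$category == "discordant"), 5)
})

test_that("identical clusterings give diagonal associations only", {
  genes <- sprintf("g%03d", 1:100)
  asg <- tibble::tibble(gene_symbol = genes,
                        cluster = rep(c("c1", "c2"), each = 50))
  out <- module_module_association(asg, asg)
  diag_rows <- out[out$cluster_a == out$cluster_b, ]
  off_rows <- out[out$cluster_a != out$cluster_b, ]
  expect_equal(diag_rows$overlap, c(50, 50))
  expect_equal(off_rows$overlap, c(0, 0))
  expect_true(all(diag_rows$p_adj < 0.001))
  expect_true(all(diag_rows$significant))
  expect_equal(diag_rows$pct_similarity, c(100, 100))
  expect_true(all(diag_rows$direction == "enriched"))
  expect_true(all(off_rows$direction == "depleted"))
})

test_that("association matrix is symmetric under dataset swap", {
  set.seed(14)
  genes <- sprintf("g%03d", 1:120)
  a <- tibble::tibble(gene_symbol = genes,
                      cluster = sample(c("a1", "a2", "a3"), 120, TRUE))
  b <- tibble::tibble(gene_symbol = genes,
                      cluster = sample(c("b1", "b2"), 120, TRUE))
  ab <- module_module_association(a, b)
  ba <- module_module_association(b, a)
  merged <- dplyr::inner_join(
    ab, ba, by = c(cluster_a = "cluster_b", cluster_b = "cluster_a"))
  expect_equal(merged$p.x, merged$p.y, tolerance = 1e-12)
  expect_equal(merged$overlap.x, merged$overlap.y)
})

test_that("degenerate margins and unassigned handling follow the contract", {
  genes <- sprintf("g%02d", 1:40)
  whole <- tibble::tibble(gene_symbol = genes, cluster = "all")
  two <- tibble::tibble(gene_symbol = genes,
                        cluster = rep(c("x", "y"), each = 20))
  out <- module_module_association(whole, two)
  expect_true(all(out$degenerate))
  expect_true(all(out$p == 1))
  expect_false(any(out$significant))

  # genes absent from one clustering take its unassigned label
  partial <- tibble::tibble(gene_symbol = genes[1:30],
                            cluster = rep(c("x", "y"), each = 15))
  out2 <- module_module_association(two, partial, universe = genes)
  expect_true("grey" %in% out2$cluster_b)
  grey_rows <- out2[out2$cluster_b == "grey", ]
  expect_true(all(!grey_rows$tested))
  expect_equal(sum(grey_rows$overlap), 10)
})

test_that("overlap counts over all label pairs partition the universe", {
  set.seed(15)
  genes <- sprintf("g%03d", 1:150)
  a <- tibble::tibble(gene_symbol = genes,
                      cluster = sample(c("a1", "a2", "grey"), 150, TRUE))
  b <- tibble::tibble(gene_symbol = genes,
                      cluster = sample(c("b1", "b2", "b3"), 150, TRUE))
  out <- module_module_association(a, b)
  expect_equal(sum(out$overlap), 150)
})
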