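test_that("the GMT reader agrees with fgsea on gene sets and keeps source tags", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("fibrinolysis\tGO:Process\tSERPINE1\tPLAUR\tPLG",
               "p53 signaling\tKEGG\tTP53\tMDM2\tCDKN1A\tBAX"), f)
  pw <- read_gmt(f)
  expect_equal(pw$ids, c("fibrinolysis", "p53 signaling"))
  expect_equal(pw$source, c("GO:Process", "KEGG"))
  ref <- fgsea::gmtPathways(f)
  expect_equal(unname(pw$genes), unname(ref[pw$ids]), ignore_attr = TRUE)
  # round trip through write_gmt
  f2 <- tempfile(fileext = ".gmt")
  write_gmt(pw, f2)
  expect_equal(read_gmt(f2), pw)
})

test_that("pathway set validation rejects empty and duplicated gene sets", {
  expect_error(pathway_set("p1", list(character(0))), "empty gene set")
  expect_error(pathway_set("p1", list(c("A", "a"))), "duplicate gene")
  expect_error(pathway_set(c("p1", "p1"), list("A", "B")), "duplicate pathway")
})

test_that("the minimum-potency / five-target rule is enforced", {
  genes <- paste0("g", 1:6)
  vals <- matrix(inactive_sentinel(), 1, 6,
                 dimnames = list("chem1", paste0("a", 1:6)))
  ann <- round_robin_annotations(colnames(vals), "x")
  ann$gene_symbol <- genes
  # 4 distinct active genes: below the threshold, undefined
  v4 <- vals; v4[1, 1:4] <- c(10, 2, 50, 7)
  ps <- perturbation_score(potency_matrix(v4), "chem1", ann, genes)
  expect_equal(ps$n_active_targets, 4)
  expect_true(is.na(ps$score))
  # 5 genes: minimum of the hits
  v5 <- vals; v5[1, 1:5] <- c(10, 2, 50, 7, 30)
  ps5 <- perturbation_score(potency_matrix(v5), "chem1", ann, genes)
  expect_equal(ps5$n_active_targets, 5)
  expect_equal(ps5$score, 2)
})

test_that("gene-level deduplication counts one gene across multiple assays", {
  vals <- matrix(c(5, 1), 1, 2,
                 dimnames = list("chem1", c("a1", "a2")))
  ann <- round_robin_annotations(c("a1", "a2"), "x")
  ann$gene_symbol <- c("SERPINE1", "serpine1")  # same gene, two platforms
  ps <- perturbation_score(potency_matrix(vals), "chem1", ann,
                           "SERPINE1", min_targets = 1)
  expect_equal(ps$n_active_targets, 1)
  expect_equal(ps$score, 1)
})

test_that("scores match the brute-force oracle on random sparse data", {
  set.seed(41)
  m <- random_pm(20, 30, hit_rate = 0.25)
  ann <- round_robin_annotations(colnames(m), "x")
  ann$gene_symbol <- paste0("g", rep(1:15, 2))   # two assays per gene
  pws <- pathway_set(paste0("p", 1:6),
                     lapply(1:6, function(i) sample(paste0("g", 1:15), 8)),
                     source = "GO:Process")
  tab <- suppressMessages(score_pathways(m, ann, pws, min_targets = 3))
  for (i in seq_len(nrow(tab))) {
    ref <- naive_pathway_score(m, ann, pws$genes[[tab$pathway[i]]],
                               tab$chemical[i], 3)
    expect_equal(tab$n_active_targets[i], ref$n)
    expect_equal(tab$score[i], ref$score)
  }
})

test_that("degenerate thresholds and inactive matrices behave", {
  set.seed(42)
  m <- random_pm(5, 8, hit_rate = 0.4)
  ann <- round_robin_annotations(colnames(m), "x")
  ann$gene_symbol <- paste0("g", 1:8)
  pw <- pathway_set("all", list(paste0("g", 1:8)))
  # min_targets = 1: score is the plain per-pathway minimum hit potency
  tab <- score_pathways(m, ann, pw, min_targets = 1)
  for (i in seq_len(nrow(tab))) {
    v <- unclass(m)[tab$chemical[i], ]
    hv <- v[v < inactive_sentinel()]
    expect_equal(tab$score[i], if (length(hv)) min(hv) else NA_real_)
  }
  # all-inactive matrix: everything undefined, zero active targets
  m0 <- potency_matrix(matrix(inactive_sentinel(), 2, 8,
                              dimnames = list(c("c1", "c2"), colnames(m))))
  tab0 <- score_pathways(m0, ann, pw)
  expect_true(all(is.na(tab0$score)))
  expect_true(all(tab0$n_active_targets == 0))
})

test_that("score and definedness are monotone in pathway extension and threshold", {
  set.seed(43)
  m <- random_pm(6, 10, hit_rate = 0.5)
  ann <- round_robin_annotations(colnames(m), "x")
  ann$gene_symbol <- paste0("g", 1:10)
  small <- paste0("g", 1:4)
  big <- paste0("g", 1:6)
  for (ch in rownames(m)) {
    s1 <- perturbation_score(m, ch, ann, small, min_targets = 2)
    s2 <- perturbation_score(m, ch, ann, big, min_targets = 2)
    expect_true(s2$n_active_targets >= s1$n_active_targets)
    if (!is.na(s1$score)) {
      expect_false(is.na(s2$score))
      expect_true(s2$score <= s1$score)
    }
    # definedness monotone non-increasing in min_targets
    def <- vapply(1:6, function(k)
      !is.na(perturbation_score(m, ch, ann, big, min_targets = k)$score),
      logical(1))
    expect_true(all(diff(def) <= 0))
    # a defined score never exceeds any individual hit on the pathway
    if (!is.na(s2$score)) {
      in_path <- ann$assay_id[tolower(ann$gene_symbol) %in% tolower(big)]
      hv <- unclass(m)[ch, in_path]
      expect_true(all(s2$score <= hv[hv < inactive_sentinel()]))
    }
  }
})

test_that("duplicated pathways give identical rows and orphans are logged", {
  set.seed(44)
  m <- random_pm(3, 6, hit_rate = 0.5)
  ann <- round_robin_annotations(colnames(m), "x")
  ann$gene_symbol <- paste0("g", 1:6)
  pws <- pathway_set(c("p", "p_copy"),
                     list(paste0("g", 1:3), paste0("g", 1:3)))
  expect_message(tab <- score_pathways(m, ann, pws, min_targets = 1),
                 "absent from all pathways")
  a <- tab[tab$pathway == "p", c("n_active_targets", "score")]
  b <- tab[tab$pathway == "p_copy", c("n_active_targets", "score")]
  expect_equal(unname(a), unname(b), ignore_attr = TRUE)
})
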