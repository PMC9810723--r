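marker_fixture <- function() {
  # three cell types, overlapping candidates, genes at the 0.25 boundary
  data.frame(
    celltype = rep(c("t1", "t2", "t3"), each = 5),
    gene = c("a", "b", "shared", "edge", "c",
             "d", "shared", "e", "f", "g",
             "h", "i", "j", "k", "absent"),
    log2fc = c(1.0, 0.8, 0.6, 0.25, 0.5,
               1.2, 0.9, 0.7, 0.26, 0.3,
               2.0, 1.5, 1.0, 0.5, 0.4),
    stringsAsFactors = FALSE)
}

test_that("signature derivation filters, dedups and intersects as declared", {
  universe <- c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "k",
                "shared", "edge")
  sigs <- derive_signatures(marker_fixture(), top_n = 100, universe = universe)
  # log2fc exactly 0.25 is excluded (strictly over)
  expect_false("edge" %in% sigs$t1$genes)
  # gene in two cell types' candidate lists is absent from both
  expect_false("shared" %in% sigs$t1$genes)
  expect_false("shared" %in% sigs$t2$genes)
  # genes absent from the universe are dropped
  expect_false("absent" %in% sigs$t3$genes)
  expect_setequal(sigs$t1$genes, c("a", "b", "c"))
  expect_setequal(sigs$t2$genes, c("d", "e", "f", "g"))
})

test_that("signature derivation equals the brute-force pipeline on a random fixture", {
  set.seed(31)
  types <- paste0("ct", 1:3)
  tab <- data.frame(
    celltype = rep(types, each = 150),
    gene = unlist(lapply(1:3, function(i)
      sample(sprintf("g%03d", 1:200), 150))),
    log2fc = runif(450, -0.5, 2),
    stat = runif(450))
  universe <- sprintf("g%03d", 1:150)
  got <- derive_signatures(tab, top_n = 20, universe = universe,
                           rank_col = "stat")
  # independent brute force
  cand <- list()
  for (tt in types) {
    sub <- tab[tab$celltype == tt & tab$log2fc > 0.25, ]
    sub <- sub[order(-sub$stat), ]
    cand[[tt]] <- unique(sub$gene)[seq_len(min(20, length(unique(sub$gene))))]
  }
  pool <- unlist(cand)
  dup <- unique(pool[duplicated(pool)])
  for (tt in types) {
    want <- setdiff(cand[[tt]], dup)
    want <- want[want %in% universe]
    expect_identical(got[[tt]]$genes, want)
  }
})

test_that("top_n truncation applies after the fold-change filter", {
  tab <- data.frame(celltype = "t1",
                    gene = sprintf("g%02d", 1:30),
                    log2fc = seq(2, 0.3, length.out = 30),
                    stat = 30:1)
  sigs <- derive_signatures(tab, top_n = 10, universe = tab$gene,
                            rank_col = "stat")
  expect_identical(sigs$t1$genes, sprintf("g%02d", 1:10))
  expect_error(derive_signatures(tab, top_n = 10, universe = "other"),
               "no surviving")
})

test_that("module score is zero on a constant matrix and deterministic", {
  m <- matrix(3, 10, 40,
              dimnames = list(paste0("c", 1:10), sprintf("g%02d", 1:40)))
  s <- module_score(m, gene_set("S", c("g01", "g02")), seed = 1)
  expect_equal(unname(s), rep(0, 10))
  set.seed(999)  # module_score must not depend on the global stream
  m2 <- matrix(rnorm(400, 5), 10, 40,
               dimnames = dimnames(m))
  s1 <- module_score(m2, gene_set("S", c("g01", "g02")), seed = 7)
  s2 <- module_score(m2, gene_set("S", c("g01", "g02")), seed = 7)
  expect_identical(s1, s2)
})

test_that("one bin with n_ctrl = all genes gives mean(sig) - mean(all)", {
  m <- matrix(c(1, 2,   4, 8,   0, 1,   3, 5), 2, 4,
              dimnames = list(c("c1", "c2"), c("g1", "g2", "g3", "g4")))
  s <- module_score(m, gene_set("S", c("g1", "g2")), n_bins = 1, n_ctrl = 4,
                    seed = 1)
  expect_equal(s[["c1"]], mean(c(1, 4)) - mean(c(1, 4, 0, 3)))
  expect_equal(s[["c2"]], mean(c(2, 8)) - mean(c(2, 8, 1, 5)))
})

test_that("module score of background-identical signatures is centred at zero", {
  set.seed(5)
  m <- matrix(rnorm(200 * 300, mean = 2), 200, 300,
              dimnames = list(sprintf("c%03d", 1:200),
                              sprintf("g%03d", 1:300)))
  s <- module_score(m, gene_set("S", sprintf("g%03d", 1:30)), seed = 3)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s)), 3 * max(se, 1 / sqrt(30 * 200)))
})

test_that("cluster enrichment equals per-cluster means and ignores cell order", {
  set.seed(8)
  scores <- matrix(rnorm(60), 20, 3,
                   dimnames = list(sprintf("c%02d", 1:20),
                                   paste0("sig", 1:3)))
  labels <- setNames(rep(c("k1", "k2"), 10), rownames(scores))
  tab <- cluster_enrichment(scores, labels)
  for (k in c("k1", "k2")) {
    expect_equal(tab$cluster_enrichment[k, ],
                 colMeans(scores[labels == k, ]), tolerance = 1e-12)
  }
  perm <- sample(20)
  tab2 <- cluster_enrichment(scores[perm, ], labels[perm])
  expect_equal(tab2$cluster_enrichment, tab$cluster_enrichment)
  # single-cell clusters reproduce the cell's own score row
  one <- cluster_enrichment(scores[1:2, ], c("a", "b"))
  expect_equal(unname(one$cluster_enrichment["a", ]), unname(scores[1, ]))
})

test_that("margin rule assigns only well-separated clusters", {
  enr <- rbind(k1 = c(A = 0.5, B = 0.1),
               k2 = c(A = 0.5, B = 0.4))
  tab <- structure(list(cells = c("x", "y"),
                        cluster_labels = c(x = "k1", y = "k2"),
                        signatures = c("A", "B"),
                        cell_scores = enr, cluster_enrichment = enr),
                   class = "signature_score_table")
  out <- assign_clusters(tab, margin = 0.2)
  expect_identical(out$label, c("A", "AMBIGUOUS"))
  expect_equal(out$gap, c(0.4, 0.1))
  expect_identical(out$runner_up, c("B", "B"))
  # margin extremes
  expect_true(all(assign_clusters(tab, margin = Inf)$label == "AMBIGUOUS"))
  expect_identical(assign_clusters(tab, margin = 0)$label, c("A", "A"))
  # absolute-floor variant assigns on the max score alone
  expect_identical(assign_clusters(tab, margin = 0.2,
                                   rule = "absolute")$label, c("A", "A"))
})

score_and_assign <- function(sim, margin = 0.2) {
  scores <- vapply(sim$signatures, function(s)
    module_score(sim$lognorm, s, seed = sim$seed),
    numeric(nrow(sim$lognorm)))
  assign_clusters(cluster_enrichment(scores, sim$cluster_labels),
                  margin = margin)
}

test_that("planted strong signatures are recovered end to end; null abstains", {
  for (s in 1:5) {
    sim <- simulate_cells(cells_per_cluster = rep(30, 4), genes = 400,
                          sig_size = 20, fold_change = 8, noise_sd = 0.1,
                          seed = s)
    out <- score_and_assign(sim)
    expect_identical(out$label, paste0("type", 1:4))
  }
  sim0 <- simulate_cells(cells_per_cluster = rep(30, 4), genes = 400,
                         sig_size = 20, fold_change = 1, noise_sd = 0.1,
                         seed = 1)
  expect_true(all(score_and_assign(sim0)$label == "AMBIGUOUS"))
})

test_that("manual curation overrides are explicit and flagged", {
  enr <- rbind(k1 = c(A = 1, B = 0), k2 = c(A = 0, B = 1))
  tab <- structure(list(cells = c("x", "y"),
                        cluster_labels = c(x = "k1", y = "k2"),
                        signatures = c("A", "B"),
                        cell_scores = enr, cluster_enrichment = enr),
                   class = "signature_score_table")
  out <- assign_clusters(tab)
  cur <- curate_assignments(out, data.frame(cluster = "k2", label = "A"))
  expect_identical(cur$label, c("A", "A"))
  expect_identical(cur$overridden, c(FALSE, TRUE))
  expect_error(curate_assignments(out, data.frame(cluster = "zz", label = "A")),
               "unknown cluster")
})
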