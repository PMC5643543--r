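two_otu_table <- function(x, y, ids = c("x", "y")) {
  m <- rbind(x, y)
  dimnames(m) <- list(ids, paste0("s", seq_along(x)))
  otu_table(m, mode = "counts")
}

test_that("Spearman rho matches the classic rank formula", {
  # perfect monotone / anti-monotone
  t1 <- two_otu_table(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(pairwise_correlation(t1)$rho["x", "y"], 1)
  t2 <- two_otu_table(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(pairwise_correlation(t2)$rho["x", "y"], -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d = rank differences
  t3 <- two_otu_table(c(1, 2, 3, 4), c(1, 3, 2, 4))
  d <- rank(c(1, 2, 3, 4)) - rank(c(1, 3, 2, 4))
  expect_equal(1 - 6 * sum(d^2) / (4 * 15), 0.8) # frozen from the formula
  expect_equal(pairwise_correlation(t3)$rho["x", "y"], 0.8)
})

test_that("p-values agree with cor.test's t approximation, ties included", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- sample(0:8, n, replace = TRUE)    # ties guaranteed
    y <- x + sample(0:6, n, replace = TRUE)
    tab <- two_otu_table(x, y)
    for (method in c("spearman", "pearson")) {
      got <- pairwise_correlation(tab, method = method)
      ref <- suppressWarnings(
        stats::cor.test(x, y, method = method, exact = FALSE))
      expect_equal(got$rho["x", "y"], unname(ref$estimate), tolerance = 1e-12)
      expect_equal(got$p["x", "y"], ref$p.value, tolerance = 1e-9)
    }
  }
})

test_that("correlation requires >= 3 samples and drops zero-variance OTUs", {
  m <- matrix(c(1, 2, 3, 4, 5, 5, 5, 5, 2, 1, 4, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "flat", "b"), paste0("s", 1:4)))
  tab <- otu_table(m, mode = "counts")
  expect_warning(res <- pairwise_correlation(tab), "zero-variance")
  expect_equal(res$otu_ids, c("a", "b"))
  expect_equal(res$dropped, "flat")
  expect_error(pairwise_correlation(
    otu_table(m[, 1:2], mode = "counts")), "3 samples")
})

test_that("BH adjustment reproduces the worked examples and the oracle", {
  expect_equal(adjust_fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr_bh(0.03), 0.03)
  expect_equal(adjust_fdr_bh(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(adjust_fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(adjust_fdr_bh(p), oracle_bh(p))
  }
})

test_that("q dominates p and preserves its ordering", {
  tab <- make_otu_counts(12, 30, seed = 5)
  res <- pairwise_correlation(tab)
  ut <- upper.tri(res$p)
  expect_true(all(res$q[ut] >= res$p[ut] - 1e-12))
  ord <- order(res$p[ut])
  expect_true(all(diff(res$q[ut][ord]) >= -1e-12))
  expect_true(isSymmetric(res$rho) && isSymmetric(unname(res$q)))
  expect_equal(unname(diag(res$rho)), rep(1, 12))
})

test_that("network edges are exactly the significant signed pairs", {
  tab <- make_otu_counts(10, 40, seed = 9)
  res <- pairwise_correlation(tab)
  # alpha below every q: all nodes, no edges
  net0 <- build_network(res, tab, alpha = min(res$q, na.rm = TRUE) / 2)
  expect_equal(igraph::vcount(net0), length(res$otu_ids))
  expect_equal(igraph::ecount(net0), 0)
  # a negative significant pair gets a "-" edge
  net <- build_network(res, tab, alpha = 1)
  e <- igraph::as_data_frame(net)
  expect_equal(nrow(e), choose(10, 2))
  expect_equal(e$sign, ifelse(e$rho > 0, "+", "-"))
  expect_true(all(e$q <= 1))
  expect_error(build_network(res, tab, alpha = 0), "alpha")
})

test_that("edge sets grow monotonically with alpha", {
  tab <- make_otu_counts(15, 25, seed = 3)
  res <- pairwise_correlation(tab)
  alphas <- c(0.01, 0.05, 0.2, 1)
  edge_keys <- lapply(alphas, function(a) {
    e <- igraph::as_data_frame(build_network(res, tab, alpha = a))
    sort(paste(e$from, e$to))
  })
  for (i in seq_len(length(alphas) - 1))
    expect_true(all(edge_keys[[i]] %in% edge_keys[[i + 1]]))
})

test_that("Spearman networks are invariant to monotone row transforms", {
  tab <- make_otu_counts(8, 50,
    blocks = list(list(members = 1:3, rho = 0.8)), seed = 13)
  res1 <- pairwise_correlation(tab)
  v <- tab$values
  v[2, ] <- v[2, ]^2                 # strictly increasing on non-negatives
  v[5, ] <- v[5, ] * 3 + 7
  res2 <- pairwise_correlation(otu_table(v, mode = "counts"))
  expect_equal(res1$rho, res2$rho)
  expect_equal(res1$q, res2$q)
})

test_that("planted correlation blocks yield exactly the within-block edges", {
  tab <- make_otu_counts(6, 200,
    blocks = list(list(members = 1:3, rho = 0.95),
                  list(members = 4:6, rho = -0.45)),
    seed = 1)
  net <- build_network(pairwise_correlation(tab), tab)
  e <- igraph::as_data_frame(net)
  expect_setequal(paste(e$from, e$to),
                  c("OTU001 OTU002", "OTU001 OTU003", "OTU002 OTU003",
                    "OTU004 OTU005", "OTU004 OTU006", "OTU005 OTU006"))
  expect_equal(e$sign[e$from %in% c("OTU001", "OTU002", "OTU003")],
               rep("+", 3))
  expect_equal(e$sign[e$from %in% c("OTU004", "OTU005", "OTU006")],
               rep("-", 3))
})

test_that("network exports round-trip through edge list, SIF and GraphML", {
  tab <- make_otu_counts(6, 200,
    blocks = list(list(members = 1:3, rho = 0.9)), seed = 4)
  net <- build_network(pairwise_correlation(tab), tab)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, tsv); write_sif(net, sif); write_graphml(net, gml)
  e <- read.delim(tsv)
  expect_equal(nrow(e), igraph::ecount(net))
  expect_named(e, c("otu_a", "otu_b", "rho", "p", "q", "sign"))
  sif_lines <- readLines(sif)
  expect_equal(sum(grepl("\tpp\t|\tnp\t", sif_lines)), igraph::ecount(net))
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(net))
  expect_setequal(igraph::E(g2)$sign, igraph::E(net)$sign)
})
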