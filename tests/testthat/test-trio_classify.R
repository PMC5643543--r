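test_that("the type vocabulary has exactly the 19 labels of the scheme", {
  lab <- trio_type_labels()
  expect_equal(nrow(lab), 19)
  expect_equal(anyDuplicated(lab$label), 0)
  expect_equal(as.vector(table(lab$category)[trio_categories_order <-
    c("with_MAO", "without_MAO", "SLM", "DLM", "TLM")]),
    c(6, 4, 2, 3, 4))
  expect_setequal(unique(lab$class), c("no_handle", "handle"))
})

test_that("focal identification takes the top summed relative abundance", {
  m <- matrix(c(6L, 3L, 1L), ncol = 1, dimnames = list(c("A", "B", "C"), "s1"))
  tab <- otu_table(m, mode = "counts")
  expect_equal(identify_focal(tab), "A")
  # lexicographic tie-break
  m2 <- matrix(c(5L, 5L), ncol = 1, dimnames = list(c("B", "A"), "s1"))
  expect_equal(identify_focal(otu_table(m2, mode = "counts")), "A")
  expect_equal(identify_focal(tab, rule = "explicit", explicit_id = "C"), "C")
  expect_error(identify_focal(tab, rule = "explicit", explicit_id = "Z"),
               "present in the table")
  # ranking is by summed relative abundance, not by raw read totals:
  # A has 10 of 11 reads in s1 (rel 0.91); C has all 6 reads of s2 (rel 1)
  m3 <- matrix(c(10L, 1L, 0L, 0L, 0L, 6L), nrow = 3,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(identify_focal(otu_table(m3, mode = "counts")), "C")
})

test_that("triangle enumeration matches exhaustive triple checking", {
  k3 <- make_test_net(c("a", "a", "b"), c("b", "c", "c"), rep("+", 3))
  expect_equal(nrow(enumerate_triangles(k3)), 1)
  path <- make_test_net(c("a", "b"), c("b", "c"), rep("+", 2))
  expect_equal(nrow(enumerate_triangles(path)), 0)
  k4p <- utils::combn(letters[1:4], 2)
  k4 <- make_test_net(k4p[1, ], k4p[2, ], rep("-", 6))
  expect_equal(nrow(enumerate_triangles(k4)), 4)

  for (s in 1:10) {
    g <- make_signed_graph(40, edge_prob = 0.2, seed = s)
    tri <- enumerate_triangles(g)
    expect_equal(anyDuplicated(apply(tri, 1, paste, collapse = "|")), 0)
    S <- dense_sign_matrix(g)
    combs <- utils::combn(igraph::V(g)$name, 3)
    n_brute <- sum(S[t(combs[1:2, ])] != 0 & S[t(combs[c(1, 3), ])] != 0 &
                   S[t(combs[2:3, ])] != 0)
    expect_equal(nrow(tri), n_brute)
  }
})

test_that("with-MAO triangles are typed by signs and the focal position", {
  case <- function(fx, fy, xy) {
    net <- make_test_net(c("f", "f", "x"), c("x", "y", "y"), c(fx, fy, xy))
    classify_triangle(c("f", "x", "y"), net, "f")
  }
  expect_equal(case("+", "-", "-")$label, "with_MAO:1A")
  expect_equal(case("-", "-", "+")$label, "with_MAO:1B")
  expect_equal(case("+", "+", "-")$label, "with_MAO:2A")
  expect_equal(case("+", "-", "+")$label, "with_MAO:2B")
  expect_equal(case("-", "-", "-")$label, "with_MAO:3")
  expect_equal(case("+", "+", "+")$label, "with_MAO:4")
  expect_equal(case("+", "-", "-")$category, "with_MAO")
  expect_equal(case("+", "-", "-")$class, "no_handle")
})

test_that("handle trios are typed by handle-link signs only", {
  # all-positive triangle x,y,z; focal linked to x by one negative edge
  slm <- make_test_net(c("x", "x", "y", "f"), c("y", "z", "z", "x"),
                       c("+", "+", "+", "-"))
  rec <- classify_triangle(c("x", "y", "z"), slm, "f")
  expect_equal(rec$label, "SLM:-")
  expect_equal(rec$class, "handle")
  expect_equal(rec$internal_signs, "+++")   # recorded but not typed on

  tlm <- make_test_net(c("x", "x", "y", "f", "f", "f"),
                       c("y", "z", "z", "x", "y", "z"),
                       c("+", "+", "+", "-", "+", "+"))
  expect_equal(classify_triangle(c("x", "y", "z"), tlm, "f")$label, "TLM:-++")
  # same internal triangle, focal absent entirely
  far <- make_test_net(c("x", "x", "y"), c("y", "z", "z"), c("+", "-", "-"),
                       nodes = "f")
  expect_equal(classify_triangle(c("x", "y", "z"), far, "f")$label,
               "without_MAO:+--")
  dlm <- make_test_net(c("x", "x", "y", "f", "f"),
                       c("y", "z", "z", "x", "y"),
                       c("+", "+", "+", "-", "+"))
  expect_equal(classify_triangle(c("x", "y", "z"), dlm, "f")$label, "DLM:-+")

  expect_error(classify_triangle(c("x", "y", "f"), far, "f"),
               "not a triangle")
})

test_that("census counts every triangle in exactly one category", {
  empty <- make_test_net(character(0), character(0), character(0),
                         nodes = c("a", "b", "f"))
  cen <- trio_census(empty, "f")
  expect_equal(cen$total_triangles, 0)
  expect_true(all(cen$counts == 0))

  g <- make_signed_graph(6, edge_prob = 0,
                         planted = c("with_MAO:4" = 1), seed = 1)
  cen <- trio_census(g, "MAO")
  expect_equal(unname(cen$counts[["with_MAO:4"]]), 1)
  expect_equal(cen$total_triangles, 1)
  expect_equal(sum(cen$counts), 1)

  for (s in 1:8) {
    g <- make_signed_graph(45, edge_prob = 0.18, seed = 100 + s)
    cen <- trio_census(g, "MAO")
    expect_equal(sum(cen$category_totals), cen$total_triangles)
    expect_equal(unname(sum(cen$class_totals)), cen$total_triangles)
    expect_equal(cen$total_triangles, nrow(enumerate_triangles(g)))
  }
})

test_that("census equals the brute-force classification oracle", {
  for (s in 1:6) {
    g <- make_signed_graph(40, edge_prob = 0.2, sign_prob_positive = 0.4,
                           seed = 200 + s)
    expect_equal(trio_census(g, "MAO")$counts, oracle_census(g, "MAO"))
    # focal alternative: a non-hub background node
    expect_equal(trio_census(g, "N0007")$counts, oracle_census(g, "N0007"))
  }
})

test_that("global sign negation mirrors the census", {
  for (s in 1:6) {
    g <- make_signed_graph(35, edge_prob = 0.22, sign_prob_positive = 0.6,
                           seed = 300 + s)
    cen <- trio_census(g, "MAO")$counts
    neg <- trio_census(negate_signs(g), "MAO")$counts
    expect_equal(unname(neg[mirror_map[names(cen)]]), unname(cen))
    expect_equal(sum(neg), sum(cen))
  }
})

test_that("census is invariant to relabeling non-focal nodes", {
  g <- make_signed_graph(30, edge_prob = 0.25, seed = 17)
  ids <- igraph::V(g)$name
  others <- setdiff(ids, "MAO")
  perm <- setNames(ids, ids)
  perm[others] <- sample(others)        # random permutation of non-focal ids
  g2 <- igraph::set_vertex_attr(g, "name", value = unname(perm[ids]))
  expect_equal(trio_census(g2, "MAO")$counts, trio_census(g, "MAO")$counts)
})

test_that("total triangles do not depend on the focal choice", {
  g <- make_signed_graph(30, edge_prob = 0.25, seed = 23)
  totals <- vapply(c("MAO", "N0003", "N0011"), function(f)
    trio_census(g, f)$total_triangles, numeric(1))
  expect_equal(unname(diff(totals)), c(0, 0))
})

test_that("an isolated focal node pushes all trios outside the MAO categories", {
  g <- make_signed_graph(25, edge_prob = 0.3, seed = 31)
  g <- igraph::add_vertices(g, 1, name = "lonely", abundance = 0)
  expect_message(cen <- trio_census(g, "lonely"), "no edges")
  expect_equal(unname(cen$category_totals[["without_MAO"]]),
               cen$total_triangles)
})
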