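# Independent brute-force oracles and small builders used across tests.
# These deliberately avoid the package's own code paths (sparse sign
# adjacency, igraph triangle enumeration, p.adjust): the oracle works from
# a dense matrix and first principles.

# Build a signed network directly from an edge list (for hand-constructed
# examples).
make_test_net <- function(from, to, sign, nodes = NULL) {
  nodes <- union(nodes, union(from, to))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, sign = sign, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, abundance = 1,
                          stringsAsFactors = FALSE))
  igraph::set_graph_attr(g, "signed_network", TRUE)
}

# Dense +1/-1/0 sign matrix from a network's edge data frame.
dense_sign_matrix <- function(net) {
  ids <- igraph::V(net)$name
  ed <- igraph::as_data_frame(net, what = "edges")
  S <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(ed)) {
    s <- ifelse(ed$sign == "+", 1, -1)
    S[cbind(ed$from, ed$to)] <- s
    S[cbind(ed$to, ed$from)] <- s
  }
  S
}

# Classify one triangle from first principles (scalar, if-chain logic).
oracle_label <- function(tri, S, focal) {
  s12 <- S[tri[1], tri[2]]; s13 <- S[tri[1], tri[3]]; s23 <- S[tri[2], tri[3]]
  stopifnot(s12 != 0, s13 != 0, s23 != 0)
  s <- c(s12, s13, s23)
  if (focal %in% tri) {
    np <- sum(s > 0)
    if (np == 3) return("with_MAO:4")
    if (np == 0) return("with_MAO:3")
    others <- setdiff(tri, focal)
    fp <- sum(c(S[focal, others[1]], S[focal, others[2]]) > 0)
    if (np == 1) return(if (fp == 1) "with_MAO:1A" else "with_MAO:1B")
    return(if (fp == 2) "with_MAO:2A" else "with_MAO:2B")
  }
  h <- S[focal, tri]
  k <- sum(h != 0)
  if (k == 0)
    return(paste0("without_MAO:", c("---", "+--", "++-", "+++")[sum(s > 0) + 1]))
  hp <- sum(h > 0)
  if (k == 1) return(paste0("SLM:", c("-", "+")[hp + 1]))
  if (k == 2) return(paste0("DLM:", c("--", "-+", "++")[hp + 1]))
  paste0("TLM:", c("---", "--+", "-++", "+++")[hp + 1])
}

# Exhaustive census over all C(n, 3) node triples.
oracle_census <- function(net, focal) {
  ids <- igraph::V(net)$name
  S <- dense_sign_matrix(net)
  counts <- setNames(numeric(19), trio_type_labels()$label)
  if (length(ids) < 3) return(counts)
  combs <- utils::combn(seq_along(ids), 3)
  # vectorised triangle detection; classification stays scalar
  s12 <- S[cbind(combs[1, ], combs[2, ])]
  s13 <- S[cbind(combs[1, ], combs[3, ])]
  s23 <- S[cbind(combs[2, ], combs[3, ])]
  tri_cols <- which(s12 != 0 & s13 != 0 & s23 != 0)
  for (c in tri_cols) {
    label <- oracle_label(ids[combs[, c]], S, focal)
    counts[label] <- counts[label] + 1
  }
  counts
}

# Brute-force Benjamini-Hochberg: sort, scale by m/rank, enforce the
# step-up monotone minimum, cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in seq(m - 1, 1, length.out = max(0, m - 1)))
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Negate every edge sign of a signed network.
negate_signs <- function(net) {
  igraph::set_edge_attr(net, "sign",
                        value = ifelse(igraph::E(net)$sign == "+", "-", "+"))
}

# Sign-mirror map on type labels induced by global sign negation.
mirror_map <- c(
  "with_MAO:4" = "with_MAO:3", "with_MAO:3" = "with_MAO:4",
  "with_MAO:1A" = "with_MAO:2B", "with_MAO:2B" = "with_MAO:1A",
  "with_MAO:1B" = "with_MAO:2A", "with_MAO:2A" = "with_MAO:1B",
  "without_MAO:+++" = "without_MAO:---", "without_MAO:---" = "without_MAO:+++",
  "without_MAO:+--" = "without_MAO:++-", "without_MAO:++-" = "without_MAO:+--",
  "SLM:+" = "SLM:-", "SLM:-" = "SLM:+",
  "DLM:++" = "DLM:--", "DLM:--" = "DLM:++", "DLM:-+" = "DLM:-+",
  "TLM:+++" = "TLM:---", "TLM:---" = "TLM:+++",
  "TLM:-++" = "TLM:--+", "TLM:--+" = "TLM:-++")

# Latent correlation matrix planting k focal-anchored trios as star blocks:
# spokes (focal, x_i, y_i) with signs (focal-x, focal-y, x-y) * a.
star_block <- function(k, a, pat) {
  R <- diag(2 * k + 1)
  for (i in seq_len(k)) {
    x <- 2 * i; y <- 2 * i + 1
    R[1, x] <- R[x, 1] <- pat[1] * a
    R[1, y] <- R[y, 1] <- pat[2] * a
    R[x, y] <- R[y, x] <- pat[3] * a
  }
  R
}

# Write a small counts table to a temporary TSV, returning the path.
write_temp_table <- function(mat, ...) {
  tab <- otu_table(mat, ...)
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write_otu_table(tab, path)
  path
}
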