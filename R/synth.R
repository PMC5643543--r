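# Synthetic inputs: random signed graphs with planted trio motifs, and
# Gaussian-copula negative-binomial OTU count tables with planted
# correlation blocks. Both are deterministic given a seed, so the whole
# pipeline is testable without any external dataset.

# Edge signs realising each plantable motif. Triangle members are x, y, z
# (x, y for with-MAO trios, where the third member is the focal node);
# handle trios get an all-positive internal triangle, since handle types
# are defined by the handle-link signs alone.
planted_recipes <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  category <- parts[1]; type <- parts[2]
  sgn <- function(ch) ifelse(ch == "+", "+", "-")
  if (category == "with_MAO") {
    signs <- switch(type,
      "4"  = c(fx = "+", fy = "+", xy = "+"),
      "3"  = c(fx = "-", fy = "-", xy = "-"),
      "1A" = c(fx = "+", fy = "-", xy = "-"),
      "1B" = c(fx = "-", fy = "-", xy = "+"),
      "2A" = c(fx = "+", fy = "+", xy = "-"),
      "2B" = c(fx = "+", fy = "-", xy = "+"),
      stop("unknown with_MAO type: ", type))
    return(list(category = category, triangle = signs, handle = character(0)))
  }
  if (category == "without_MAO") {
    ch <- strsplit(type, "")[[1]]
    return(list(category = category,
                triangle = c(xy = sgn(ch[1]), xz = sgn(ch[2]), yz = sgn(ch[3])),
                handle = character(0)))
  }
  if (category %in% c("SLM", "DLM", "TLM")) {
    ch <- strsplit(type, "")[[1]]
    expected <- c(SLM = 1L, DLM = 2L, TLM = 3L)[category]
    if (length(ch) != expected) stop("bad ", category, " pattern: ", type)
    return(list(category = category,
                triangle = c(xy = "+", xz = "+", yz = "+"),
                handle = vapply(ch, sgn, character(1))))
  }
  stop("unknown trio label: ", label)
}

#' Random signed graph with planted trio motifs
#'
#' Generates an Erdos-Renyi background graph over `n_nodes` nodes (the
#' focal node included), each edge present with probability `edge_prob` and
#' positive with probability `sign_prob_positive`, then plants the
#' requested trio motifs on fresh nodes disjoint from the background and
#' from each other. Because planted structures share no non-focal nodes,
#' each planted label's count is a lower bound on the census count and is
#' exact when `edge_prob = 0`. (A planted double- or triple-link handle
#' trio additionally contributes one or three with-MAO trios: the focal
#' node plus two linked triangle members always close a triangle of their
#' own.)
#'
#' @param n_nodes number of background nodes, focal node included.
#' @param edge_prob background edge probability in \[0, 1\].
#' @param sign_prob_positive probability that an edge is positive.
#' @param planted named numeric vector: trio label (see
#'   [trio_type_labels()]) -> number of copies to plant.
#' @param focal id of the focal node (default `"MAO"`).
#' @param seed integer seed.
#' @return a signed network (igraph) with graph attribute `focal`.
#' @export
make_signed_graph <- function(n_nodes, edge_prob = 0,
                              sign_prob_positive = 0.5,
                              planted = NULL, focal = "MAO", seed = NULL) {
  stopifnot(n_nodes >= 1, edge_prob >= 0, edge_prob <= 1,
            sign_prob_positive >= 0, sign_prob_positive <= 1)
  if (!is.null(planted)) {
    if (is.null(names(planted)) || any(planted < 0))
      stop("`planted` must be a named vector of non-negative counts")
    bad <- setdiff(names(planted), trio_type_labels()$label)
    if (length(bad))
      stop("unknown trio labels in `planted`: ", paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    bg <- c(focal, sprintf("N%04d", seq_len(max(0, n_nodes - 1L))))
    from <- character(0); to <- character(0); sgn <- character(0)
    if (n_nodes >= 2 && edge_prob > 0) {
      pairs <- utils::combn(bg, 2)
      keep <- stats::runif(ncol(pairs)) < edge_prob
      if (any(keep)) {
        from <- pairs[1, keep]; to <- pairs[2, keep]
        sgn <- ifelse(stats::runif(sum(keep)) < sign_prob_positive, "+", "-")
      }
    }
    fresh <- 0L
    extra_nodes <- character(0)
    for (label in names(planted)) {
      recipe <- planted_recipes(label)
      for (copy in seq_len(planted[[label]])) {
        fresh <- fresh + 1L
        if (recipe$category == "with_MAO") {
          x <- sprintf("P%04d_x", fresh); y <- sprintf("P%04d_y", fresh)
          extra_nodes <- c(extra_nodes, x, y)
          from <- c(from, focal, focal, x)
          to <- c(to, x, y, y)
          sgn <- c(sgn, recipe$triangle[["fx"]], recipe$triangle[["fy"]],
                   recipe$triangle[["xy"]])
        } else {
          x <- sprintf("P%04d_x", fresh); y <- sprintf("P%04d_y", fresh)
          z <- sprintf("P%04d_z", fresh)
          extra_nodes <- c(extra_nodes, x, y, z)
          from <- c(from, x, x, y)
          to <- c(to, y, z, z)
          sgn <- c(sgn, recipe$triangle[["xy"]], recipe$triangle[["xz"]],
                   recipe$triangle[["yz"]])
          if (length(recipe$handle)) {
            members <- c(x, y, z)[seq_along(recipe$handle)]
            from <- c(from, rep(focal, length(members)))
            to <- c(to, members)
            sgn <- c(sgn, unname(recipe$handle))
          }
        }
      }
    }
    nodes <- c(bg, extra_nodes)
    abundance <- stats::setNames(stats::runif(length(nodes), 0, 0.5), nodes)
    abundance[focal] <- 1
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, sign = sgn,
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = nodes,
                            abundance = as.numeric(abundance),
                            stringsAsFactors = FALSE))
    g <- igraph::set_graph_attr(g, "signed_network", TRUE)
    g <- igraph::set_graph_attr(g, "focal", focal)
    g
  })
}

#' Synthetic OTU count table with planted correlation blocks
#'
#' Draws a latent multivariate Gaussian with a block correlation structure,
#' maps it through the Gaussian copula, and quantile-transforms each OTU to
#' negative-binomial counts. The monotone transform preserves the latent
#' rank (Spearman) structure, so planted blocks surface as signed edges in
#' the downstream network. One designated OTU can be boosted to make it
#' the abundance maximum (the MAO).
#'
#' @param n_otus,n_samples table dimensions.
#' @param blocks list of blocks, each a list with `members` (OTU ids or
#'   indices) and `rho` (either a single pairwise latent correlation in
#'   (-1, 1), or a symmetric unit-diagonal correlation matrix over the
#'   members, which is how mixed-sign trios such as Type-1A are planted).
#'   Block memberships must be disjoint; the assembled latent correlation
#'   matrix must be positive definite (checked).
#' @param mao OTU id (or index) to boost, or `NULL` for no boost.
#' @param mao_boost multiplier applied on top of the maximum base mean so
#'   the designated OTU's expected abundance is strictly maximal.
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param depth target mean total reads per sample.
#' @param seed integer seed.
#' @return a counts-mode [otu_table()].
#' @export
make_otu_counts <- function(n_otus, n_samples, blocks = list(),
                            mao = NULL, mao_boost = 5, dispersion = 10,
                            depth = 5000, seed = NULL) {
  stopifnot(n_otus >= 2, n_samples >= 3, dispersion > 0, depth > 0)
  ids <- sprintf("OTU%03d", seq_len(n_otus))
  resolve <- function(m) {
    if (is.character(m)) {
      idx <- match(m, ids)
      if (anyNA(idx)) stop("unknown OTU id in block: ",
                           paste(m[is.na(idx)], collapse = ", "))
      idx
    } else as.integer(m)
  }
  C <- diag(n_otus)
  used <- integer(0)
  for (b in blocks) {
    idx <- resolve(b$members)
    if (length(intersect(idx, used)))
      stop("block memberships must be disjoint")
    used <- c(used, idx)
    m <- length(idx)
    if (m < 2) stop("a block needs at least 2 members")
    R <- b$rho
    if (is.matrix(R)) {
      if (!all(dim(R) == m) || !isSymmetric(unname(R)) ||
          any(abs(diag(R) - 1) > 1e-12))
        stop("block `rho` matrix must be symmetric with unit diagonal")
      if (any(abs(R[upper.tri(R)]) >= 1))
        stop("latent correlations must lie strictly within (-1, 1)")
    } else {
      if (abs(R) >= 1)
        stop("latent correlations must lie strictly within (-1, 1)")
      R <- matrix(R, m, m); diag(R) <- 1
    }
    C[idx, idx] <- R
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("assembled latent correlation matrix is not positive definite; ",
         "use weaker within-block correlations or smaller blocks")
  with_seed(seed, {
    mu <- stats::rlnorm(n_otus, meanlog = 0, sdlog = 1)
    if (!is.null(mao)) {
      mi <- resolve(mao)
      stopifnot(length(mi) == 1L)
      mu[mi] <- mao_boost * max(mu)
    }
    mu <- mu / sum(mu) * depth
    L <- chol(C)
    Z <- matrix(stats::rnorm(n_otus * n_samples), nrow = n_otus)
    X <- t(L) %*% Z
    U <- stats::pnorm(X)
    counts <- matrix(0, n_otus, n_samples)
    for (i in seq_len(n_otus))
      counts[i, ] <- stats::qnbinom(U[i, ], size = dispersion, mu = mu[i])
    dimnames(counts) <- list(ids, sprintf("S%03d", seq_len(n_samples)))
    otu_table(counts, mode = "counts")
  })
}

#' Bind per-group tables into one grouped table
#'
#' Column-binds OTU tables that share the same OTU ids, renaming samples to
#' `<group>_<sample>` and attaching the group labels, ready for
#' [run_pipeline()].
#'
#' @param tables named list of counts-mode [otu_table()]s; names are the
#'   group labels.
#' @return a single [otu_table()] with `groups` set.
#' @export
merge_sample_groups <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2, !is.null(names(tables)))
  ids <- otu_ids(tables[[1]])
  mats <- lapply(names(tables), function(g) {
    t <- tables[[g]]
    stopifnot(inherits(t, "otu_table"))
    if (!identical(otu_ids(t), ids))
      stop("all tables must share the same OTU ids in the same order")
    v <- t$values
    colnames(v) <- paste(g, colnames(v), sep = "_")
    v
  })
  values <- do.call(cbind, mats)
  groups <- stats::setNames(
    rep(names(tables), vapply(tables, function(t) ncol(t$values), 1L)),
    colnames(values))
  otu_table(values, mode = tables[[1]]$mode, groups = groups)
}
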