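#' Pairwise OTU correlation with p-values
#'
#' Computes all N(N-1)/2 pairwise correlations between OTU abundance
#' profiles across samples. Spearman (default) uses average ranks for ties;
#' p-values come from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom for
#' either method. OTUs with zero variance across samples carry no rank
#' information and are dropped with a warning before testing.
#'
#' @param table an [otu_table()] with at least 3 samples.
#' @param method `"spearman"` or `"pearson"`.
#' @return an object of class `otu_correlation`: list with `otu_ids`,
#'   symmetric matrices `rho` (unit diagonal), `p` and BH-adjusted `q`
#'   (diagonal `NA`), `method`, `n_samples`, and `dropped` (ids of
#'   zero-variance OTUs removed).
#' @seealso [adjust_fdr_bh()], [build_network()]
#' @export
pairwise_correlation <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "otu_table"))
  v <- table$values
  n <- ncol(v)
  if (n < 3L) stop("need at least 3 samples to test correlations")
  if (any(!is.finite(v))) stop("non-finite abundance values")
  vars <- apply(v, 1, stats::var)
  dropped <- rownames(v)[vars == 0]
  if (length(dropped)) {
    warning(length(dropped), " zero-variance OTU(s) dropped from correlation: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
    v <- v[vars > 0, , drop = FALSE]
  }
  if (nrow(v) < 2L) stop("fewer than 2 OTUs with nonzero variance")
  x <- if (method == "spearman") t(apply(v, 1, rank)) else v
  rho <- stats::cor(t(x))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  # two-sided p from the t approximation; |rho| = 1 gives p = 0
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  p <- pmin(p, 1)
  diag(p) <- NA_real_
  ut <- upper.tri(p)
  q <- p
  q[ut] <- adjust_fdr_bh(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  dimnames(rho) <- dimnames(p) <- dimnames(q) <-
    list(rownames(v), rownames(v))
  structure(list(otu_ids = rownames(v), rho = rho, p = p, q = q,
                 method = method, n_samples = n, dropped = dropped),
            class = "otu_correlation")
}

#' @export
print.otu_correlation <- function(x, ...) {
  m <- length(x$otu_ids)
  cat(sprintf("otu_correlation: %s over %d OTUs, %d samples (%d pairs)\n",
              x$method, m, x$n_samples, m * (m - 1) / 2))
  if (length(x$dropped))
    cat("dropped zero-variance OTUs:", length(x$dropped), "\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Adjusts a vector of p-values by the Benjamini-Hochberg step-up procedure:
#' \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}, capped at 1. Applied
#' jointly to all unique OTU pairs of a network during
#' [pairwise_correlation()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return vector of adjusted values (q), same order as the input.
#' @export
adjust_fdr_bh <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Build a signed co-occurrence network
#'
#' Step (iii) of the pipeline: keep the OTU pairs whose BH-adjusted p-value
#' q is at most `alpha` (default 0.05) and, optionally, whose |rho| reaches
#' `min_abs_rho`; connect them with an edge signed by the direction of the
#' correlation. Nodes are all tested OTUs, each carrying an abundance score
#' (summed relative abundance across the samples). A significant pair with
#' rho exactly 0 has no sign and is excluded.
#'
#' @param corr an `otu_correlation` from [pairwise_correlation()].
#' @param table the [otu_table()] the correlations came from (used for node
#'   abundance scores; counts tables are converted to relative abundance).
#' @param alpha significance threshold on q, in (0, 1].
#' @param min_abs_rho minimum |rho| for an edge (default 0: no filter).
#' @param use_q if `FALSE`, threshold the raw p-values instead of q
#'   (sensitivity analysis only).
#' @return an [igraph][igraph::igraph-package] graph with vertex attributes
#'   `name` and `abundance`, edge attributes `sign` ("+" or "-"), `rho`,
#'   `p`, `q`, and graph attributes `alpha`, `method`, `signed_network`.
#' @export
build_network <- function(corr, table, alpha = 0.05, min_abs_rho = 0,
                          use_q = TRUE) {
  stopifnot(inherits(corr, "otu_correlation"), inherits(table, "otu_table"))
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]")
  if (!all(corr$otu_ids %in% otu_ids(table)))
    stop("correlation result and table disagree on OTU ids")
  rel <- if (table$mode == "counts") to_relative_abundance(table) else table
  abundance <- rowSums(rel$values)[corr$otu_ids]

  crit <- if (use_q) corr$q else corr$p
  ut <- which(upper.tri(crit), arr.ind = TRUE)
  keep <- crit[ut] <= alpha & abs(corr$rho[ut]) >= min_abs_rho &
    corr$rho[ut] != 0
  ut <- ut[keep, , drop = FALSE]
  ids <- corr$otu_ids
  edges <- data.frame(
    from = ids[ut[, 1]], to = ids[ut[, 2]],
    rho = corr$rho[ut], p = corr$p[ut], q = corr$q[ut],
    sign = ifelse(corr$rho[ut] > 0, "+", "-"),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, abundance = as.numeric(abundance),
                          stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  g <- igraph::set_graph_attr(g, "method", corr$method)
  g <- igraph::set_graph_attr(g, "signed_network", TRUE)
  g
}

assert_signed_network <- function(net) {
  if (!igraph::is_igraph(net) ||
      !isTRUE(igraph::graph_attr(net, "signed_network")))
    stop("expected a signed network built by build_network() or ",
         "make_signed_graph()")
  invisible(net)
}

#' Export a signed network
#'
#' `write_edge_list()` writes a TSV (`otu_a`, `otu_b`, `rho`, `p`, `q`,
#' `sign`); `write_sif()` writes Cytoscape SIF with interaction types `pp`
#' (positive) and `np` (negative); `write_graphml()` writes GraphML.
#'
#' @param net a signed network from [build_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  assert_signed_network(net)
  e <- igraph::as_data_frame(net, what = "edges")
  for (col in c("rho", "p", "q")) if (is.null(e[[col]])) e[[col]] <- NA_real_
  df <- data.frame(otu_a = e$from, otu_b = e$to, rho = e$rho, p = e$p,
                   q = e$q, sign = e$sign, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_sif <- function(net, path) {
  assert_signed_network(net)
  e <- igraph::as_data_frame(net, what = "edges")
  lines <- if (nrow(e)) {
    paste(e$from, ifelse(e$sign == "+", "pp", "np"), e$to, sep = "\t")
  } else character(0)
  iso <- setdiff(igraph::V(net)$name, c(e$from, e$to))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  assert_signed_network(net)
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
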