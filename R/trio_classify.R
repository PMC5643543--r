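# Three-level trio classification:
#   class    -- handle absent / present (is the focal node wired to the
#               triangle from outside?)
#   category -- no_handle: with_MAO (focal is a member) or without_MAO;
#               handle: SLM / DLM / TLM by the number of focal links
#   type     -- sign pattern; for with_MAO also the position of the focal
#               node relative to the signs (A/B subtypes)
# Triangle sign patterns are written plus-first ("+--"); handle-link sign
# patterns minus-first ("-+"), following the usual table notation.

#' The 19 trio type labels
#'
#' Returns the full classification vocabulary: 6 types in the with-MAO
#' category, 4 without-MAO, 2 single-link (SLM), 3 double-link (DLM) and 4
#' triple-link (TLM) handle types.
#'
#' @return data.frame with columns `class` (`"no_handle"`/`"handle"`),
#'   `category` (`"with_MAO"`, `"without_MAO"`, `"SLM"`, `"DLM"`, `"TLM"`),
#'   `type` (sign pattern or named type), and `label`
#'   (`"<category>:<type>"`), one row per type, 19 rows.
#' @export
trio_type_labels <- function() {
  df <- rbind(
    data.frame(class = "no_handle", category = "with_MAO",
               type = c("1A", "1B", "2A", "2B", "3", "4")),
    data.frame(class = "no_handle", category = "without_MAO",
               type = c("---", "+--", "++-", "+++")),
    data.frame(class = "handle", category = "SLM", type = c("-", "+")),
    data.frame(class = "handle", category = "DLM", type = c("--", "-+", "++")),
    data.frame(class = "handle", category = "TLM",
               type = c("---", "--+", "-++", "+++")))
  df$label <- paste(df$category, df$type, sep = ":")
  df
}

trio_categories <- c("with_MAO", "without_MAO", "SLM", "DLM", "TLM")

# canonical sign strings from a count of "+" signs
triangle_pattern <- c("---", "+--", "++-", "+++")   # index nplus + 1
handle_pattern <- list(
  `1` = c("-", "+"),                                 # index nplus + 1
  `2` = c("--", "-+", "++"),
  `3` = c("---", "--+", "-++", "+++"))

#' Identify the focal OTU (MAO)
#'
#' Under the `"mao"` rule the focal node is the most abundant OTU: the one
#' with the largest summed relative abundance across the table's samples,
#' ties broken by lexicographic OTU id so the choice is deterministic. The
#' `"explicit"` rule accepts any OTU id, which is the hook for alternative
#' focal-node semantics (most dominant OTU, hubs, ...) defined elsewhere.
#'
#' @param table an [otu_table()]; counts are converted to relative
#'   abundance for the ranking.
#' @param rule `"mao"` or `"explicit"`.
#' @param explicit_id OTU id, required when `rule = "explicit"`.
#' @param within optional character vector restricting the candidates (for
#'   example to the OTUs that made it into a network).
#' @return a single OTU id.
#' @export
identify_focal <- function(table, rule = c("mao", "explicit"),
                           explicit_id = NULL, within = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(table, "otu_table"))
  if (rule == "explicit") {
    if (is.null(explicit_id) || !explicit_id %in% otu_ids(table))
      stop("`explicit_id` must name an OTU present in the table")
    return(explicit_id)
  }
  rel <- if (table$mode == "counts") to_relative_abundance(table) else table
  score <- rowSums(rel$values)
  if (!is.null(within)) {
    score <- score[names(score) %in% within]
    if (!length(score)) stop("no candidate OTUs left after `within` filter")
  }
  cand <- names(score)[score == max(score)]
  sort(cand)[1]
}

#' Enumerate all triangles of a network
#'
#' Lists every 3-clique exactly once as a sorted triple of node ids.
#'
#' @param net a signed network ([build_network()] / [make_signed_graph()]).
#' @return character matrix with 3 columns, one row per triangle, rows in
#'   lexicographic order.
#' @export
enumerate_triangles <- function(net) {
  assert_signed_network(net)
  tri <- igraph::triangles(net)
  if (length(tri) == 0)
    return(matrix(character(0), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c"))))
  m <- matrix(igraph::V(net)$name[as.integer(tri)], ncol = 3, byrow = TRUE)
  m <- t(apply(m, 1, sort))
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  colnames(m) <- c("a", "b", "c")
  m
}

# signed adjacency (+1 / -1 / 0) used by the classifier
sign_adjacency <- function(net) {
  s <- ifelse(igraph::E(net)$sign == "+", 1, -1)
  net <- igraph::set_edge_attr(net, ".s", value = s)
  igraph::as_adjacency_matrix(net, attr = ".s", sparse = TRUE)
}

# Vectorised classification of triangles (rows of a 3-column id matrix).
classify_triangles_mat <- function(tri, net, focal) {
  assert_signed_network(net)
  ids <- igraph::V(net)$name
  if (!focal %in% ids) stop("focal node '", focal, "' is not in the network")
  if (!all(tri %in% ids)) stop("triangle node not present in the network")
  A <- sign_adjacency(net)
  i <- match(tri[, 1], ids); j <- match(tri[, 2], ids); k <- match(tri[, 3], ids)
  s_ij <- A[cbind(i, j)]; s_ik <- A[cbind(i, k)]; s_jk <- A[cbind(j, k)]
  if (any(s_ij == 0 | s_ik == 0 | s_jk == 0))
    stop("a listed triple is not a triangle in the network")
  f <- match(focal, ids)
  h_i <- A[cbind(rep(f, length(i)), i)]
  h_j <- A[cbind(rep(f, length(j)), j)]
  h_k <- A[cbind(rep(f, length(k)), k)]
  nplus <- (s_ij > 0) + (s_ik > 0) + (s_jk > 0)

  n <- nrow(tri)
  category <- character(n); type <- character(n)
  internal <- triangle_pattern[nplus + 1]
  handle <- character(n)

  has_focal <- i == f | j == f | k == f
  if (any(has_focal)) {
    w <- which(has_focal)
    # the two triangle edges incident to the focal member
    fs1 <- ifelse(i[w] == f, s_ij[w], ifelse(j[w] == f, s_ij[w], s_ik[w]))
    fs2 <- ifelse(i[w] == f, s_ik[w], ifelse(j[w] == f, s_jk[w], s_jk[w]))
    fplus <- (fs1 > 0) + (fs2 > 0)
    ty <- character(length(w))
    np <- nplus[w]
    ty[np == 3] <- "4"
    ty[np == 0] <- "3"
    ty[np == 1] <- ifelse(fplus[np == 1] == 1, "1A", "1B")
    ty[np == 2] <- ifelse(fplus[np == 2] == 2, "2A", "2B")
    category[w] <- "with_MAO"
    type[w] <- ty
  }
  if (any(!has_focal)) {
    w <- which(!has_focal)
    hi <- h_i[w]; hj <- h_j[w]; hk <- h_k[w]
    nlink <- (hi != 0) + (hj != 0) + (hk != 0)
    hplus <- (hi > 0) + (hj > 0) + (hk > 0)
    category[w] <- c("without_MAO", "SLM", "DLM", "TLM")[nlink + 1]
    type[w[nlink == 0]] <- internal[w[nlink == 0]]
    for (l in 1:3) {
      sel <- nlink == l
      if (any(sel)) {
        pat <- handle_pattern[[l]][hplus[sel] + 1]
        type[w[sel]] <- pat
        handle[w[sel]] <- pat
      }
    }
  }
  data.frame(a = tri[, 1], b = tri[, 2], c = tri[, 3],
             class = ifelse(category %in% c("SLM", "DLM", "TLM"),
                            "handle", "no_handle"),
             category = category, type = type,
             label = paste(category, type, sep = ":"),
             internal_signs = internal, handle_signs = handle,
             stringsAsFactors = FALSE)
}

#' Classify one triangle relative to a focal node
#'
#' Applies the three-level scheme to a single triangle. If the focal node is
#' a member, the internal sign pattern (and, for the mixed patterns, the
#' signs of the two focal-incident edges) picks one of Types 1A, 1B, 2A,
#' 2B, 3, 4. Otherwise the number of network links from the focal node to
#' the triangle's members decides the category (0: without-MAO; 1/2/3:
#' single-/double-/triple-link handle), and handle trios are typed by the
#' multiset of handle-link signs alone (internal signs are recorded but do
#' not enter the label).
#'
#' @param tri character vector of 3 node ids forming a triangle in `net`.
#' @param net a signed network.
#' @param focal focal node id (must be a network node).
#' @return a one-row data.frame: nodes `a`,`b`,`c` (sorted), `class`,
#'   `category`, `type`, `label`, `internal_signs`, `handle_signs`.
#' @export
classify_triangle <- function(tri, net, focal) {
  if (length(tri) != 3L || anyDuplicated(tri))
    stop("`tri` must be three distinct node ids")
  classify_triangles_mat(matrix(sort(tri), ncol = 3), net, focal)
}

#' Classified listing of all trios in a network
#'
#' @param net a signed network.
#' @param focal focal node id.
#' @return data.frame as in [classify_triangle()], one row per triangle.
#' @export
trio_records <- function(net, focal) {
  tri <- enumerate_triangles(net)
  if (nrow(tri) == 0) {
    out <- classify_triangles_mat(tri = matrix(character(0), ncol = 3),
                                  net = net, focal = focal)
    return(out)
  }
  classify_triangles_mat(tri, net, focal)
}

#' Trio census of a network
#'
#' Enumerates every triangle, classifies it under the 19-type scheme with
#' respect to `focal`, and tabulates counts per type, per category, and per
#' class. The five categories partition the triangles, so the category
#' totals always sum to the triangle count.
#'
#' @param net a signed network.
#' @param focal focal node id; see [identify_focal()].
#' @return object of class `trio_census`: list with `focal`, `counts`
#'   (named numeric over the 19 labels), `category_totals`, `class_totals`,
#'   `total_triangles`.
#' @export
trio_census <- function(net, focal) {
  assert_signed_network(net)
  if (!focal %in% igraph::V(net)$name)
    stop("focal node '", focal, "' is not in the network")
  if (igraph::degree(net, focal) == 0)
    message("focal node '", focal, "' has no edges; ",
            "all trios fall outside the with-MAO and handle categories")
  rec <- trio_records(net, focal)
  labels <- trio_type_labels()
  counts <- stats::setNames(numeric(nrow(labels)), labels$label)
  if (nrow(rec)) {
    tab <- table(rec$label)
    counts[names(tab)] <- as.numeric(tab)
  }
  new_trio_census(counts, focal)
}

new_trio_census <- function(counts, focal = NA_character_) {
  labels <- trio_type_labels()
  stopifnot(identical(sort(names(counts)), sort(labels$label)))
  counts <- counts[labels$label]
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("census counts must be finite and non-negative")
  cat_tot <- vapply(trio_categories, function(cg)
    sum(counts[labels$label[labels$category == cg]]), numeric(1))
  cls_tot <- vapply(c("no_handle", "handle"), function(cl)
    sum(counts[labels$label[labels$class == cl]]), numeric(1))
  structure(list(focal = focal, counts = counts,
                 category_totals = cat_tot, class_totals = cls_tot,
                 total_triangles = sum(counts)),
            class = "trio_census")
}

#' Build a census from a vector of per-type counts
#'
#' Wraps externally obtained per-type trio counts (for example published
#' count tables) into a `trio_census` so they can be fed to [rdht()].
#' Missing labels default to zero; counts may be non-integer (averaged
#' censuses from [balanced_census()] are).
#'
#' @param counts named numeric vector; names must be trio labels from
#'   [trio_type_labels()] (`"<category>:<type>"`).
#' @param focal optional focal node id, recorded for provenance.
#' @return a `trio_census`.
#' @export
trio_census_from_counts <- function(counts, focal = NA_character_) {
  labels <- trio_type_labels()$label
  if (is.null(names(counts)) || !all(names(counts) %in% labels))
    stop("count names must be trio labels (see trio_type_labels())")
  full <- stats::setNames(numeric(length(labels)), labels)
  full[names(counts)] <- as.numeric(counts)
  new_trio_census(full, focal)
}

#' @export
print.trio_census <- function(x, ...) {
  cat(sprintf("trio_census (focal = %s): %s triangles\n", x$focal,
              format(x$total_triangles)))
  ct <- x$category_totals
  cat(paste(sprintf("  %-12s %s", names(ct), format(ct)), collapse = "\n"),
      "\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) {
    cat("nonzero types:\n")
    cat(paste(sprintf("  %-16s %s", names(nz), format(nz)),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.trio_census <- function(x, ...) {
  labels <- trio_type_labels()
  data.frame(labels, count = as.numeric(x$counts[labels$label]),
             row.names = NULL)
}

#' Write a trio census to CSV
#'
#' One row per (class, category, type) with its count, followed by the five
#' category totals and the grand total.
#'
#' @param census a `trio_census`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(census, path) {
  stopifnot(inherits(census, "trio_census"))
  df <- as.data.frame(census)
  tot <- data.frame(class = "total", category = names(census$category_totals),
                    type = "sum", label = "", count = as.numeric(census$category_totals))
  all <- data.frame(class = "total", category = "all", type = "sum",
                    label = "", count = census$total_triangles)
  utils::write.csv(rbind(df, tot, all), path, row.names = FALSE)
  invisible(path)
}
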