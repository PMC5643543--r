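#' OTU abundance table
#'
#' Container for an OTU-by-sample abundance matrix. Tables are always stored
#' with OTUs as rows and samples as columns; readers normalise orientation.
#' The `mode` flag records whether entries are raw read counts or relative
#' abundances (each sample column summing to one).
#'
#' @param values numeric matrix, OTUs x samples, with unique rownames (OTU
#'   ids) and unique colnames (sample ids); all entries non-negative.
#' @param mode `"counts"` (integral entries) or `"relative"` (each column
#'   sums to 1; all-zero samples are disallowed).
#' @param groups optional named character vector mapping sample id to a
#'   group (treatment) label; names must be a subset of the sample ids.
#' @return an object of class `otu_table`: a list with elements `values`,
#'   `mode` and `groups`.
#' @export
otu_table <- function(values, mode = c("counts", "relative"), groups = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (OTUs x samples)")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty OTU table")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry OTU ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate OTU ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(!is.finite(values)))
    stop("non-finite abundance values")
  if (any(values < 0))
    stop("negative abundance values")
  if (mode == "counts" && !all(is_wholenumber(values)))
    stop("mode = \"counts\" requires integral entries")
  if (mode == "relative") {
    tot <- colSums(values)
    if (any(abs(tot - 1) > 1e-9))
      stop("mode = \"relative\" requires every sample column to sum to 1")
  }
  if (!is.null(groups)) {
    groups <- validate_groups(groups, colnames(values))
  }
  structure(list(values = values, mode = mode, groups = groups),
            class = "otu_table")
}

validate_groups <- function(groups, sample_ids) {
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("`groups` must be a named vector with unique sample ids as names")
  unknown <- setdiff(names(groups), sample_ids)
  if (length(unknown))
    stop("group labels for unknown samples: ", paste(unknown, collapse = ", "))
  stats::setNames(as.character(groups), names(groups))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (mode = %s)\n",
              nrow(x$values), ncol(x$values), x$mode))
  if (!is.null(x$groups))
    cat("groups:", paste(sprintf("%s (%d)", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), "\n")
  nz <- sum(rowSums(x$values) == 0)
  if (nz > 0) cat(sprintf("note: %d all-zero OTU row(s)\n", nz))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$values)

#' OTU and sample ids of a table
#' @param table an [otu_table()].
#' @return character vector of ids.
#' @export
otu_ids <- function(table) rownames(table$values)

#' @rdname otu_ids
#' @export
sample_ids <- function(table) colnames(table$values)

#' Subset the samples of an OTU table
#'
#' Keeps the OTU set unchanged (rows of all-zero abundance may appear; the
#' correlation step drops them). Counts stay counts; relative tables are
#' renormalised per column.
#'
#' @param table an [otu_table()].
#' @param samples character vector of sample ids to keep.
#' @return an [otu_table()] restricted to `samples`.
#' @export
subset_samples <- function(table, samples) {
  stopifnot(inherits(table, "otu_table"))
  missing <- setdiff(samples, sample_ids(table))
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  v <- table$values[, samples, drop = FALSE]
  g <- table$groups
  if (!is.null(g)) g <- g[intersect(names(g), samples)]
  if (table$mode == "relative") {
    tot <- colSums(v)
    if (any(tot <= 0)) stop("subset produced an all-zero sample")
    v <- sweep(v, 2, tot, "/")
  }
  otu_table(v, mode = table$mode, groups = if (length(g)) g else NULL)
}

#' Read an OTU abundance table from TSV
#'
#' Expects a tab-separated matrix with one header row and one id column.
#' With `orientation = "otus_as_rows"` (default) the header holds sample ids
#' and the first column OTU ids; `"samples_as_rows"` reads the transpose.
#' The mode is inferred: all-integral entries give a counts table; otherwise
#' the columns must sum to one (relative abundances) or the file is rejected.
#'
#' @param path path to a TSV file.
#' @param orientation `"otus_as_rows"` or `"samples_as_rows"`.
#' @param groups optional named character vector of sample group labels (see
#'   [read_sample_groups()]).
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path,
                           orientation = c("otus_as_rows", "samples_as_rows"),
                           groups = NULL) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty table: need a header row and data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop("ragged rows: every row must have the same number of fields")
  if (widths[1] < 2L) stop("empty table: need at least one data column")
  header <- cells[[1]][-1]
  ids <- vapply(cells[-1], `[[`, character(1), 1L)
  body <- t(vapply(cells[-1], function(r) {
    x <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(x)) stop("non-numeric entry in row '", r[1], "'")
    x
  }, numeric(widths[1] - 1L)))
  dimnames(body) <- list(ids, header)
  if (orientation == "samples_as_rows") body <- t(body)
  if (any(body < 0)) stop("negative abundance values")
  mode <- if (all(is_wholenumber(body))) "counts" else {
    if (all(abs(colSums(body) - 1) <= 1e-6)) "relative"
    else stop("non-integral entries whose sample columns do not sum to 1: ",
              "neither a counts nor a relative-abundance table")
  }
  if (mode == "relative") body <- sweep(body, 2, colSums(body), "/")
  otu_table(body, mode = mode, groups = groups)
}

#' Write an OTU table to TSV
#'
#' Inverse of [read_otu_table()] with `orientation = "otus_as_rows"`.
#'
#' @param table an [otu_table()].
#' @param path output path.
#' @param id_column name for the id column header cell.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, id_column = "otu_id") {
  stopifnot(inherits(table, "otu_table"))
  v <- table$values
  header <- paste(c(id_column, colnames(v)), collapse = "\t")
  fmt <- if (table$mode == "counts") function(x) format(x, scientific = FALSE, trim = TRUE)
         else function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], fmt(v[i, ])), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a sample-to-group metadata table
#'
#' Two-column TSV (`sample_id`, `group`) with a header row.
#'
#' @param path path to the metadata TSV.
#' @return named character vector: group labels named by sample id.
#' @export
read_sample_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("metadata must have two columns: sample_id, group")
  if (anyDuplicated(df[[1]])) stop("duplicate sample ids in metadata")
  stats::setNames(df[[2]], df[[1]])
}

#' Convert counts to relative abundances
#'
#' Divides each entry by its sample-column total (the reads of an OTU in a
#' sample over the total reads in that sample).
#'
#' @param table an [otu_table()] in counts mode.
#' @return an [otu_table()] in relative mode with identical ids.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (table$mode != "counts")
    stop("to_relative_abundance() expects a counts-mode table")
  tot <- colSums(table$values)
  if (any(tot <= 0)) {
    bad <- colnames(table$values)[tot <= 0]
    stop("sample(s) with zero total reads: ", paste(bad, collapse = ", "))
  }
  otu_table(sweep(table$values, 2, tot, "/"), mode = "relative",
            groups = table$groups)
}

#' Rarefy samples to a common depth
#'
#' Draws `depth` reads from each sample without replacement (multivariate
#' hypergeometric subsampling), the alternative to relative abundance for
#' unequal library sizes. Deterministic given `seed`.
#'
#' @param table an [otu_table()] in counts mode.
#' @param depth target reads per sample; must not exceed any sample total.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a counts-mode [otu_table()] whose columns each sum to `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (table$mode != "counts") stop("rarefy() expects a counts-mode table")
  depth <- as.integer(depth)
  if (length(depth) != 1L || is.na(depth) || depth <= 0L)
    stop("`depth` must be a positive integer")
  tot <- colSums(table$values)
  if (any(tot < depth)) {
    bad <- colnames(table$values)[tot < depth]
    stop("depth ", depth, " exceeds the total reads of sample(s): ",
         paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    v <- apply(table$values, 2, function(col) {
      n <- sum(col)
      if (n == depth) return(as.numeric(col))
      pool <- rep.int(seq_along(col), col)
      drawn <- pool[sample.int(length(pool), depth)]
      as.numeric(tabulate(drawn, nbins = length(col)))
    })
    dimnames(v) <- dimnames(table$values)
    otu_table(v, mode = "counts", groups = table$groups)
  })
}
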