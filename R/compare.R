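#' Ratio of disease to healthy trios (RDHT)
#'
#' For every trio type and every category, the count in the diseased
#' network divided by the count in the healthy network. A type absent from
#' both networks has no ratio (`NA`); a type present only in the diseased
#' network is `Infinite` (stored as `Inf`). The exact ratio is kept at full
#' precision; rounding to two decimals happens only when formatting
#' ([format_rdht()], [write_rdht_csv()]).
#'
#' @param disease,healthy `trio_census` objects ([trio_census()],
#'   [balanced_census()], or [trio_census_from_counts()]).
#' @return object of class `rdht_table`: a data.frame with columns `level`
#'   (`"category"` or `"type"`), `class`, `category`, `type`, `label`,
#'   `disease`, `healthy` (the raw counts) and `rdht` (numeric; `NA` for
#'   0/0, `Inf` for positive/0).
#' @export
rdht <- function(disease, healthy) {
  stopifnot(inherits(disease, "trio_census"), inherits(healthy, "trio_census"))
  labels <- trio_type_labels()
  ratio <- function(d, h) ifelse(d == 0 & h == 0, NA_real_,
                                 ifelse(h == 0, Inf, d / h))
  cat_class <- c(with_MAO = "no_handle", without_MAO = "no_handle",
                 SLM = "handle", DLM = "handle", TLM = "handle")
  cats <- data.frame(
    level = "category", class = unname(cat_class[trio_categories]),
    category = trio_categories, type = "sum",
    label = trio_categories,
    disease = as.numeric(disease$category_totals[trio_categories]),
    healthy = as.numeric(healthy$category_totals[trio_categories]),
    stringsAsFactors = FALSE)
  types <- data.frame(
    level = "type", class = labels$class, category = labels$category,
    type = labels$type, label = labels$label,
    disease = as.numeric(disease$counts[labels$label]),
    healthy = as.numeric(healthy$counts[labels$label]),
    stringsAsFactors = FALSE)
  out <- rbind(cats, types)
  out$rdht <- ratio(out$disease, out$healthy)
  class(out) <- c("rdht_table", "data.frame")
  out
}

#' Format RDHT values for reporting
#'
#' Two-decimal, half-up rounding; `NA` prints as `"NA"` and `Inf` as
#' `"Infinite"`, matching the conventional table layout.
#'
#' @param x numeric vector of ratios (from [rdht()]`$rdht`).
#' @return character vector.
#' @export
format_rdht <- function(x) {
  out <- ifelse(is.na(x), "NA",
                ifelse(is.infinite(x), "Infinite",
                       sprintf("%.2f", round_half_up(x, 2))))
  out
}

#' @export
print.rdht_table <- function(x, ...) {
  cat("rdht_table\n")
  df <- as.data.frame(x)
  df$rdht <- format_rdht(df$rdht)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an RDHT report to CSV
#'
#' One row per category and per type with the raw disease/healthy counts
#' (ratios alone can mislead when count magnitudes differ across types, so
#' counts are always reported beside them) and the formatted ratio
#' (`"NA"` / `"Infinite"` / two decimals). The unrounded ratio is kept in a
#' separate machine-readable column.
#'
#' @param x an `rdht_table` from [rdht()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rdht_csv <- function(x, path) {
  stopifnot(inherits(x, "rdht_table"))
  df <- as.data.frame(x)
  df$rdht_exact <- df$rdht
  df$rdht <- format_rdht(df$rdht)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Averaged trio census under balanced resampling
#'
#' When treatments have unequal sample sizes, the larger group is
#' repeatedly subsampled to the size of its counterpart: for each of
#' `reps` repetitions, `n_per_group` samples are drawn without replacement,
#' the full correlation -> FDR -> network -> census pipeline is run on the
#' draw, and the per-type counts are averaged over repetitions (averages
#' may be non-integer). The averaged census feeds [rdht()] directly.
#'
#' @param table a counts- or relative-mode [otu_table()] with group labels.
#' @param group the group (treatment) label to subsample.
#' @param n_per_group number of samples per draw; at most the group size.
#' @param reps number of repetitions (default 50).
#' @param seed integer seed; draws are deterministic given it.
#' @param ... pipeline settings passed to the census step: `method`,
#'   `alpha`, `normalization`, `rarefy_depth`, `min_abs_rho`, `use_q`,
#'   `focal_rule`, `focal_id` (see [run_pipeline()]).
#' @return a `trio_census` with averaged (possibly fractional) counts; the
#'   attribute `"reps"` records the number of repetitions and `"focals"`
#'   the focal node chosen in each.
#' @export
balanced_census <- function(table, group, n_per_group, reps = 50,
                            seed = NULL, ...) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(table$groups)) stop("`table` has no group labels")
  samples <- names(table$groups)[table$groups == group]
  if (!length(samples)) stop("unknown group label: ", group)
  if (n_per_group > length(samples))
    stop("n_per_group (", n_per_group, ") exceeds the size of group '",
         group, "' (", length(samples), ")")
  if (reps < 1) stop("`reps` must be at least 1")
  seeds <- child_seeds(seed, reps)
  acc <- NULL
  focals <- character(reps)
  for (r in seq_len(reps)) {
    drawn <- with_seed(seeds[r], sample(samples, n_per_group))
    sub <- subset_samples(table, drawn)
    res <- census_pipeline(sub, seed = seeds[r], ...)
    focals[r] <- res$focal
    cnt <- res$census$counts
    acc <- if (is.null(acc)) cnt else acc + cnt
  }
  avg <- acc / reps
  focal <- names(sort(table(focals), decreasing = TRUE))[1]
  out <- new_trio_census(avg, focal)
  attr(out, "reps") <- reps
  attr(out, "focals") <- focals
  out
}
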