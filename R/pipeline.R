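# Orchestration of the four pipeline steps:
#   (i) pairwise correlation, (ii) BH-FDR filtering, (iii) signed network
#   construction, (iv) trio census -- run per treatment group, then RDHT.

# One group's correlation -> FDR -> network -> census run. `table` holds
# only that group's samples.
census_pipeline <- function(table,
                            method = "spearman",
                            alpha = 0.05,
                            normalization = c("relative", "counts", "rarefy"),
                            rarefy_depth = NULL,
                            min_abs_rho = 0,
                            use_q = TRUE,
                            focal_rule = "mao",
                            focal_id = NULL,
                            seed = NULL) {
  normalization <- match.arg(normalization)
  work <- switch(normalization,
    relative = if (table$mode == "counts") to_relative_abundance(table)
               else table,
    counts = {
      if (table$mode != "counts")
        stop("normalization = \"counts\" requires a counts-mode table")
      table
    },
    rarefy = {
      if (is.null(rarefy_depth))
        stop("normalization = \"rarefy\" requires `rarefy_depth`")
      rarefy(table, rarefy_depth, seed = seed)
    })
  corr <- pairwise_correlation(work, method = method)
  net <- build_network(corr, work, alpha = alpha,
                       min_abs_rho = min_abs_rho, use_q = use_q)
  focal <- identify_focal(work, rule = focal_rule, explicit_id = focal_id,
                          within = igraph::V(net)$name)
  census <- trio_census(net, focal)
  m <- length(corr$otu_ids)
  list(census = census, network = net, corr = corr, focal = focal,
       stats = c(otus_tested = m, pairs_tested = m * (m - 1) / 2,
                 edges = igraph::ecount(net),
                 triangles = census$total_triangles))
}

#' Run the full disease-vs-healthy trio pipeline
#'
#' For each of the two treatment groups independently: subset the samples,
#' normalise abundances, compute all pairwise correlations, filter by
#' BH-adjusted significance, build the signed network, identify the focal
#' OTU and take the trio census. Then compare the two censuses with
#' [rdht()]. When `resample` is given, any group larger than
#' `resample$n_per_group` is repeatedly subsampled to that size and its
#' census averaged over the repetitions ([balanced_census()]).
#'
#' @param table a counts- or relative-mode [otu_table()], or a path to a
#'   TSV readable by [read_otu_table()].
#' @param groups named character vector mapping sample id to group label,
#'   or a path to a metadata TSV ([read_sample_groups()]); may be `NULL`
#'   if `table` already carries groups.
#' @param group_disease,group_healthy the two group labels to compare;
#'   each needs at least 3 samples.
#' @param method correlation method, `"spearman"` (default) or
#'   `"pearson"`.
#' @param alpha significance threshold on the BH-adjusted p-value
#'   (default 0.05).
#' @param normalization `"relative"` (default), `"counts"`, or
#'   `"rarefy"` (requires `rarefy_depth`); exactly one applies per run.
#' @param rarefy_depth reads per sample for `normalization = "rarefy"`.
#' @param min_abs_rho optional minimum |rho| for an edge (default 0).
#' @param use_q threshold adjusted q (default) or raw p if `FALSE`.
#' @param focal_rule `"mao"` or `"explicit"`; @param focal_id the id for
#'   `"explicit"`.
#' @param resample optional list `list(n_per_group =, reps = 50)` enabling
#'   balanced resampling of oversized groups.
#' @param out_dir optional directory; when given, writes per-group edge
#'   lists (TSV), GraphML, SIF, census CSVs, the RDHT CSV and a JSON run
#'   manifest recording configuration, seed and run statistics.
#' @param seed integer seed governing all randomness (rarefaction and
#'   resampling draws).
#' @return list with `networks` (disease/healthy; `NULL` for a resampled
#'   group), `censuses`, `rdht`, `focal`, `stats` (pairs tested, edges,
#'   triangles per group) and `config`.
#' @export
run_pipeline <- function(table, groups = NULL,
                         group_disease, group_healthy,
                         method = c("spearman", "pearson"),
                         alpha = 0.05,
                         normalization = c("relative", "counts", "rarefy"),
                         rarefy_depth = NULL,
                         min_abs_rho = 0,
                         use_q = TRUE,
                         focal_rule = c("mao", "explicit"),
                         focal_id = NULL,
                         resample = NULL,
                         out_dir = NULL,
                         seed = NULL) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  focal_rule <- match.arg(focal_rule)
  if (is.character(table)) table <- read_otu_table(table)
  if (is.character(groups)) groups <- read_sample_groups(groups)
  if (!is.null(groups)) table$groups <- validate_groups(groups, sample_ids(table))
  if (is.null(table$groups)) stop("no sample group labels provided")

  cfg <- list(method = method, alpha = alpha, normalization = normalization,
              rarefy_depth = rarefy_depth, min_abs_rho = min_abs_rho,
              use_q = use_q, focal_rule = focal_rule, focal_id = focal_id,
              resample = resample, seed = seed)
  pipeline_args <- cfg[c("method", "alpha", "normalization", "rarefy_depth",
                         "min_abs_rho", "use_q", "focal_rule", "focal_id")]

  group_names <- c(disease = group_disease, healthy = group_healthy)
  seeds <- child_seeds(seed, 2)
  runs <- list()
  for (idx in seq_along(group_names)) {
    g <- group_names[[idx]]
    members <- names(table$groups)[table$groups == g]
    if (!length(members)) stop("unknown group label: ", g)
    if (length(members) < 3) stop("group '", g, "' has fewer than 3 samples")
    sub <- subset_samples(table, members)
    if (!is.null(resample) && length(members) > resample$n_per_group) {
      reps <- if (is.null(resample$reps)) 50L else resample$reps
      census <- do.call(balanced_census,
                        c(list(table = sub, group = g,
                               n_per_group = resample$n_per_group,
                               reps = reps, seed = seeds[idx]),
                          pipeline_args))
      runs[[names(group_names)[idx]]] <-
        list(census = census, network = NULL, focal = census$focal,
             stats = c(otus_tested = NA, pairs_tested = NA, edges = NA,
                       triangles = census$total_triangles))
    } else {
      res <- do.call(census_pipeline,
                     c(list(table = sub, seed = seeds[idx]), pipeline_args))
      runs[[names(group_names)[idx]]] <- res
    }
  }
  comparison <- rdht(runs$disease$census, runs$healthy$census)
  out <- list(
    networks = list(disease = runs$disease$network,
                    healthy = runs$healthy$network),
    censuses = list(disease = runs$disease$census,
                    healthy = runs$healthy$census),
    rdht = comparison,
    focal = c(disease = runs$disease$focal, healthy = runs$healthy$focal),
    stats = rbind(disease = runs$disease$stats,
                  healthy = runs$healthy$stats),
    config = cfg)
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (g in c("disease", "healthy")) {
    net <- run$networks[[g]]
    if (!is.null(net)) {
      write_edge_list(net, file.path(out_dir, paste0(g, "_edges.tsv")))
      write_graphml(net, file.path(out_dir, paste0(g, "_network.graphml")))
      write_sif(net, file.path(out_dir, paste0(g, "_network.sif")))
    }
    write_census_csv(run$censuses[[g]],
                     file.path(out_dir, paste0(g, "_census.csv")))
  }
  write_rdht_csv(run$rdht, file.path(out_dir, "rdht.csv"))
  manifest <- list(config = run$config, focal = as.list(run$focal),
                   stats = apply(run$stats, 1, as.list))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(out_dir)
}

#' Load the bundled published trio-count tables
#'
#' Per-type trio counts reported for fifteen treatments across six human
#' microbiome case studies (gut HIV and IBD, lung cystic fibrosis, oral
#' periodontitis, skin atopic dermatitis, vaginal bacterial vaginosis),
#' bundled as the worked-example inputs for the RDHT arithmetic. These are
#' reported counts, not networks rebuilt by this package.
#'
#' @return data.frame with columns `site`, `treatment` and one column per
#'   trio label (19 label columns).
#' @export
hmp_trio_counts <- function() {
  path <- system.file("extdata", "hmp_trio_counts.tsv", package = "trionet",
                      mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(trio_type_labels()$label %in% names(df)))
  df
}

#' The bundled disease-vs-healthy comparison pairs
#'
#' The nine treatment pairs that go with [hmp_trio_counts()].
#'
#' @return data.frame with columns `site`, `comparison`, `disease`,
#'   `healthy`.
#' @export
hmp_comparisons <- function() {
  path <- system.file("extdata", "hmp_comparisons.tsv", package = "trionet",
                      mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' Census for one bundled treatment
#'
#' @param treatment a `treatment` value of [hmp_trio_counts()].
#' @return a `trio_census` built from the published counts.
#' @export
hmp_census <- function(treatment) {
  df <- hmp_trio_counts()
  row <- df[df$treatment == treatment, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown treatment '", treatment, "'; see hmp_trio_counts()$treatment")
  labels <- trio_type_labels()$label
  trio_census_from_counts(
    stats::setNames(as.numeric(row[1, labels]), labels))
}
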