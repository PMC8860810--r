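#' Read subscale scores from CSV
#'
#' Validates that the 16 expected subscale columns are present (matched by
#' name, order-insensitive, with an optional alias map), coerces scores to
#' integers, and drops rows with any missing cell (complete-case), reporting
#' the number dropped.
#'
#' @param path CSV file with a header row.
#' @param group_col optional column holding a group label; when given, one
#'   dataset per group is returned as a named list.
#' @param aliases named character vector mapping file column names to
#'   canonical subscale names.
#' @param expected character vector of required variable names; defaults to
#'   the canonical 16 subscales.
#' @return A [subscale_dataset()], or a named list of them when `group_col`
#'   is given.
#' @export
read_scores <- function(path, group_col = NULL, aliases = NULL,
                        expected = subscale_nodes()$name) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(aliases)) {
    hit <- match(colnames(df), names(aliases))
    colnames(df)[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  }
  missing_cols <- setdiff(expected, colnames(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         "; expected: ", paste(expected, collapse = ", "))
  }
  groups <- if (is.null(group_col)) rep("", nrow(df)) else {
    if (!group_col %in% colnames(df)) stop("group column '", group_col, "' not found")
    as.character(df[[group_col]])
  }
  sc <- df[, expected, drop = FALSE]
  for (v in expected) {
    col <- sc[[v]]
    if (is.character(col)) col <- suppressWarnings(as.numeric(trimws(col)))
    bad <- which(!is.na(col) & col != round(col))
    if (length(bad) == 0 && is.character(sc[[v]])) {
      nonnum <- which(!is.na(trimws(sc[[v]])) & nzchar(trimws(sc[[v]])) & is.na(col))
      if (length(nonnum)) {
        stop(sprintf("non-numeric cell at row %d, column '%s'", nonnum[1], v))
      }
    }
    sc[[v]] <- col
  }
  keep <- stats::complete.cases(sc)
  if (any(!keep)) {
    warning(sprintf("dropped %d row(s) with missing cells (complete-case)",
                    sum(!keep)))
  }
  sc <- sc[keep, , drop = FALSE]
  groups <- groups[keep]
  make_one <- function(rows, label) {
    m <- as.matrix(sc[rows, , drop = FALSE])
    rownames(m) <- NULL
    subscale_dataset(m,
                     group_label = label, provenance = "file",
                     provenance_detail = basename(path))
  }
  if (is.null(group_col)) return(make_one(seq_len(nrow(sc)), ""))
  lv <- unique(groups)
  stats::setNames(lapply(lv, function(g) make_one(which(groups == g), g)), lv)
}

#' Write subscale scores to CSV
#'
#' Inverse of [read_scores()]: header row of variable names (plus an optional
#' group column), one row per subject, integer cells.
#'
#' @param data a [subscale_dataset()] or named list of them.
#' @param path output CSV path.
#' @param group_col name for the group-label column; omitted when NULL and a
#'   single ungrouped dataset is written.
#' @return `path`, invisibly.
#' @export
write_scores <- function(data, path, group_col = "group") {
  if (inherits(data, "subscale_data")) data <- list(data)
  dfs <- lapply(data, function(d) {
    df <- as.data.frame(d$scores)
    if (!is.null(group_col)) df[[group_col]] <- d$group_label
    df
  })
  out <- do.call(rbind, dfs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a generator spec to JSON
#'
#' @param spec a [synthetic_spec()].
#' @param path output path; the partial-correlation matrix is stored
#'   row-major.
#' @return `path`, invisibly.
#' @export
write_spec_json <- function(spec, path) {
  obj <- list(
    node_names = spec$node_names,
    true_partial_corr = as.vector(t(spec$true_partial_corr)),
    means = unname(spec$means), sds = unname(spec$sds),
    score_bounds = list(min = spec$score_bounds[, 1],
                        max = spec$score_bounds[, 2]),
    n_subjects = spec$n_subjects, group_label = spec$group_label,
    seed = spec$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write network estimation artifacts
#'
#' Writes, with the given prefix: the p x p adjacency CSV (`_adjacency.csv`),
#' the nonzero upper-triangle edge list (`_edges.csv`), estimation metadata
#' JSON (`_meta.json`) and a GraphML export (`.graphml`).
#'
#' @param net a `pcor_network`.
#' @param prefix output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_network <- function(net, prefix) {
  adj <- file.path(paste0(prefix, "_adjacency.csv"))
  W <- as.data.frame(net$W)
  utils::write.csv(cbind(node = net$node_names, W), adj, row.names = FALSE,
                   quote = FALSE)
  edg <- paste0(prefix, "_edges.csv")
  utils::write.csv(coef(net), edg, row.names = FALSE, quote = FALSE)
  meta <- paste0(prefix, "_meta.json")
  jsonlite::write_json(
    list(group = net$group_label, n = net$n, p = net$p,
         n_edges = net$n_edges, lambda_selected = net$lambda_selected,
         gamma = net$gamma, method = net$method,
         n_lambda = net$n_lambda, min_ratio = net$min_ratio,
         psd_repaired = isTRUE(net$psd_repaired), refit = isTRUE(net$refit)),
    meta, auto_unbox = TRUE, digits = NA)
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(as_igraph(net), gml, format = "graphml")
  invisible(c(adj, edg, meta, gml))
}

#' Write shortest-pathway results to JSON
#'
#' @param pw a [shortest_pathways()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_pathways_json <- function(pw, path) {
  obj <- lapply(unname(pw$pairs), function(r) {
    list(source = r$source, target = r$target,
         reachable = r$reachable,
         distance = if (is.finite(r$distance)) r$distance else "Inf",
         hops = r$hops,
         routes = lapply(seq_along(r$paths), function(i) {
           list(nodes = r$paths[[i]],
                weights = r$edges[[i]]$weight)
         }))
  })
  jsonlite::write_json(list(pairs = obj, union_edges = pw$union_edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Validation: `gamma >=
#' 0`, `B >= 1`, `0 < ci < 1`, sources and targets disjoint.
#'
#' @param method correlation type.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,min_ratio penalty grid controls.
#' @param B bootstrap replicates (default 2500).
#' @param ci percentile CI level.
#' @param seed master seed; every stage derives its stream from it.
#' @param sources,targets pathway endpoints; NULL = CM nodes / ED-specific
#'   symptoms.
#' @param cutoffs CM occurrence cut-offs.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(method = "pearson", gamma = 0.5, n_lambda = 100L,
                            min_ratio = 0.01, B = 2500L, ci = 0.95,
                            seed = 1L, sources = NULL, targets = NULL,
                            cutoffs = cm_cutoffs()) {
  stopifnot(gamma >= 0, B >= 1, ci > 0, ci < 1)
  if (!is.null(sources) && !is.null(targets) &&
      length(intersect(sources, targets))) {
    stop("`sources` and `targets` must be disjoint")
  }
  structure(list(method = match.arg(method, c("pearson", "spearman")),
                 gamma = gamma, n_lambda = as.integer(n_lambda),
                 min_ratio = min_ratio, B = as.integer(B), ci = ci,
                 seed = as.integer(seed), sources = sources,
                 targets = targets, cutoffs = cutoffs),
            class = "pipeline_config")
}

#' Run the full per-group analysis pipeline
#'
#' For each group in the input: network estimation, edge-weight bootstrap,
#' shortest pathways; across the first two groups, the descriptive
#' comparison table. When `out_dir` is given every artifact is written to
#' disk (adjacency/edge-list CSVs, GraphML, bootstrap CSV, pathway JSON,
#' comparison CSV) together with a run manifest JSON capturing the
#' configuration, seed, package version and an MD5 checksum of the input, so
#' a run is fully regenerable from the manifest.
#'
#' @param data named list of [subscale_dataset()] (one per group), a single
#'   dataset, or a CSV path (read with [read_scores()] using `group_col`).
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or NULL to skip writing.
#' @param group_col used when `data` is a path.
#' @return Object of class `pcnet_pipeline`: per-group `networks`,
#'   `bootstraps`, `pathways`; `comparison`; `manifest`; `files`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL,
                         group_col = "group") {
  stopifnot(inherits(config, "pipeline_config"))
  input_md5 <- NA_character_
  if (is.character(data) && length(data) == 1) {
    input_md5 <- unname(tools::md5sum(data))
    data <- read_scores(data, group_col = group_col)
  }
  if (inherits(data, "subscale_data")) {
    data <- stats::setNames(list(data),
                            if (nzchar(data$group_label)) data$group_label else "all")
  }
  groups <- names(data)
  networks <- list(); bootstraps <- list(); pathways <- list()
  files <- character()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    message(sprintf("[pcnet] group %s: estimating network (n = %d)", g,
                    nrow(data[[g]]$scores)))
    t0 <- proc.time()[3]
    net <- estimate_network(data[[g]], method = config$method,
                            gamma = config$gamma, n_lambda = config$n_lambda,
                            min_ratio = config$min_ratio)
    message(sprintf("[pcnet]   %d edges selected (%.1fs)", net$n_edges,
                    proc.time()[3] - t0))
    t0 <- proc.time()[3]
    bt <- bootstrap_edges(data[[g]], B = config$B,
                          seed = replicate_seed(config$seed, gi, 0L),
                          ci = config$ci, method = config$method,
                          gamma = config$gamma, n_lambda = config$n_lambda,
                          min_ratio = config$min_ratio)
    message(sprintf("[pcnet]   bootstrap B = %d done (%.1fs)", config$B,
                    proc.time()[3] - t0))
    pw <- shortest_pathways(net, sources = config$sources,
                            targets = config$targets)
    networks[[g]] <- net; bootstraps[[g]] <- bt; pathways[[g]] <- pw
    if (!is.null(out_dir)) {
      prefix <- file.path(out_dir, paste0("net_", g))
      files <- c(files, write_network(net, prefix))
      bf <- file.path(out_dir, paste0("boots_", g, ".csv"))
      utils::write.csv(as.data.frame(bt), bf, row.names = FALSE, quote = FALSE)
      pf <- file.path(out_dir, paste0("paths_", g, ".json"))
      write_pathways_json(pw, pf)
      gmlf <- file.path(out_dir, paste0("paths_", g, ".graphml"))
      write_pathways_graphml(net, pw, gmlf)
      files <- c(files, bf, pf, gmlf)
    }
  }
  comparison <- NULL
  if (length(groups) >= 2) {
    comparison <- group_comparison(data[[1]], data[[2]],
                                   cutoffs = config$cutoffs)
    if (!is.null(out_dir)) {
      cf <- file.path(out_dir, "comparison_scores.csv")
      utils::write.csv(comparison$scores, cf, row.names = FALSE, quote = FALSE)
      of <- file.path(out_dir, "comparison_occurrence.csv")
      utils::write.csv(comparison$occurrence, of, row.names = FALSE,
                       quote = FALSE)
      files <- c(files, cf, of)
    }
  }
  manifest <- list(
    package = "pcnet",
    version = as.character(utils::packageVersion("pcnet")),
    config = unclass(config),
    groups = groups,
    group_sizes = vapply(data, function(d) nrow(d$scores), 0L),
    input_md5 = input_md5)
  if (!is.null(out_dir)) {
    mf <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    files <- c(files, mf)
  }
  structure(list(networks = networks, bootstraps = bootstraps,
                 pathways = pathways, comparison = comparison,
                 manifest = manifest, files = files),
            class = "pcnet_pipeline")
}

#' @export
print.pcnet_pipeline <- function(x, ...) {
  cat("pcnet pipeline run\n")
  for (g in names(x$networks)) {
    n <- x$networks[[g]]
    cat(sprintf("  %s: %d edges (n = %d), %d pathway pairs, B = %d\n", g,
                n$n_edges, n$n, length(x$pathways[[g]]$pairs),
                attr(x$bootstraps[[g]], "B")))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  comparison: %s vs %s over %d variables\n",
                x$comparison$group1, x$comparison$group2,
                nrow(x$comparison$scores)))
  }
  invisible(x)
}
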