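#' Pipeline configuration
#'
#' Collects every tunable of the analysis: window length L (in TRs), taper
#' width, penalty grid size, statistical parameters and seeds. Window lengths
#' of 6-10 TRs are the supported sensitivity range; 8 is the default
#' operating point.
#'
#' @param window_length window length L in TRs (default 8).
#' @param taper_sigma Gaussian taper width in TRs (default 2).
#' @param lambda_n_grid penalty grid size for cross-validation (default 20).
#' @param primary_p NBS primary edge threshold (default 0.05).
#' @param n_perm NBS permutation budget (default 10000).
#' @param q FDR level (default 0.05).
#' @param alpha family-wise significance level (default 0.05).
#' @param seed master seed for permutation and posterior sampling.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_length = 8, taper_sigma = 2,
                            lambda_n_grid = 20, primary_p = 0.05,
                            n_perm = 10000, q = 0.05, alpha = 0.05,
                            seed = 1L) {
  if (window_length < 2) stop_woiconn("window_length must be >= 2")
  structure(
    list(window_length = as.integer(window_length),
         taper_sigma = taper_sigma,
         lambda_n_grid = as.integer(lambda_n_grid),
         primary_p = primary_p, n_perm = as.integer(n_perm), q = q,
         alpha = alpha, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output YAML file.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full single-subject analysis
#'
#' Window assignment, tapered windowed covariances, penalty selection by
#' leave-one-window-out cross-validation, graphical-lasso fits, Fisher
#' transform, condition-mean GLM and graph metrics. Every intermediate can be
#' written to an output directory for audit.
#'
#' @param series an [roi_series()] (already conditioned, if desired).
#' @param events an [event_table()] for the same session.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, condition matrices,
#'   metrics, window table and a JSON log are written there.
#' @return Object of class `subject_result`: subject id, window table,
#'   `n_valid_events`, selected `lambda`, per-window fits summary, the four
#'   `condition_matrices` (Fisher-z scale) and `metrics` per condition.
#' @export
run_subject <- function(series, events, config = pipeline_config(),
                        output_dir = NULL) {
  L <- config$window_length
  wois <- assign_wois(events, L, series$run_boundaries)
  valid_events <- unique(wois$event_index[wois$valid])
  if (!length(valid_events)) {
    bad <- unique(wois[!wois$valid, c("event_index", "reason")])
    stop_woiconn("no valid events; reasons: ",
                 paste(sprintf("event %d: %s", bad$event_index, bad$reason),
                       collapse = "; "))
  }
  taper <- make_taper(L, config$taper_sigma)
  windows <- list(); conds <- character(0); ev_idx <- integer(0)
  for (e in valid_events) {
    for (cond in woi_conditions()) {
      row <- wois[wois$event_index == e & wois$condition == cond, ]
      windows[[length(windows) + 1]] <-
        windowed_covariance(series, c(row$start, row$end), taper)
      conds <- c(conds, cond)
      ev_idx <- c(ev_idx, e)
    }
  }
  grid <- lambda_grid(windows, config$lambda_n_grid)
  lambda <- select_lambda_cv(windows, grid)
  fits <- lapply(windows, glasso_fit, lambda = as.numeric(lambda))
  z_mats <- lapply(fits, function(f) fisher_transform_matrix(f$covariance))
  M <- condition_mean_glm(z_mats, conds)
  metrics <- lapply(M, metric_set)
  result <- structure(
    list(subject_id = series$subject_id,
         n_valid_events = length(valid_events),
         window_counts = table(conds),
         wois = wois, lambda = as.numeric(lambda),
         n_windows = length(windows),
         converged = vapply(fits, `[[`, logical(1), "converged"),
         condition_matrices = M, metrics = metrics,
         region_ids = series$region_ids),
    class = "subject_result")
  if (!is.null(output_dir)) write_subject_result(result, output_dir)
  result
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s: %d valid events, lambda %.4g\n",
              x$subject_id, x$n_valid_events, x$lambda))
  for (cond in woi_conditions())
    cat(sprintf("  %-8s integration %.4f\n", cond,
                x$metrics[[cond]]$integration))
  invisible(x)
}

write_subject_result <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in woi_conditions()) {
    write_matrix_tsv(result$condition_matrices[[cond]],
                     file.path(output_dir, paste0("condmat-", cond, ".tsv")),
                     meta = list(subject = result$subject_id,
                                 condition = cond, lambda = result$lambda))
  }
  met <- do.call(rbind, lapply(woi_conditions(), function(cond) {
    m <- result$metrics[[cond]]
    data.frame(condition = cond, region = result$region_ids,
               strength = m$strength, clustering = m$clustering,
               integration = m$integration)
  }))
  write.table(met, file.path(output_dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  write_wois_tsv(result$wois, file.path(output_dir, "wois.tsv"))
  jsonlite::write_json(
    list(subject = result$subject_id, lambda = result$lambda,
         n_valid_events = result$n_valid_events,
         n_windows = result$n_windows,
         all_converged = all(result$converged)),
    file.path(output_dir, "log.json"), auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' Multiscale group comparison of conditions
#'
#' Runs, for every pair of conditions, the network-level exact Wilcoxon test
#' on integration (FDR-corrected across the 6 pairs), node-level Wilcoxon
#' tests on strength and clustering (FDR-corrected across the N nodes per
#' measure and pair), and the edge-level network-based statistic on the
#' Fisher-z condition matrices; plus a one-sample NBS per condition with its
#' network density.
#'
#' @param subject_results list of `subject_result` objects (>= 2 subjects,
#'   identical region sets).
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for the JSON report.
#' @return Object of class `group_result` with elements `network` (data
#'   frame), `node` (data frame), `edge` (named list of `nbs_result`),
#'   `one_sample` (per condition: `nbs_result` plus `density`), `n_subjects`.
#' @export
run_group <- function(subject_results, config = pipeline_config(),
                      output_dir = NULL) {
  S <- length(subject_results)
  if (S < 2) stop_woiconn("group analysis needs at least 2 subjects")
  regions <- subject_results[[1]]$region_ids
  for (r in subject_results)
    if (!identical(r$region_ids, regions))
      stop_woiconn("subjects have mismatched region sets")
  N <- length(regions)
  conds <- woi_conditions()
  pairs <- combn(conds, 2)

  integ <- sapply(conds, function(cond)
    vapply(subject_results, function(r) r$metrics[[cond]]$integration,
           numeric(1)))
  strength <- lapply(conds, function(cond)
    t(vapply(subject_results, function(r) r$metrics[[cond]]$strength,
             numeric(N))))
  names(strength) <- conds
  clustering <- lapply(conds, function(cond)
    t(vapply(subject_results, function(r) r$metrics[[cond]]$clustering,
             numeric(N))))
  names(clustering) <- conds

  # network level: one family of 6 pairwise tests
  net <- data.frame(condition_a = pairs[1, ], condition_b = pairs[2, ],
                    stringsAsFactors = FALSE)
  net$p <- vapply(seq_len(ncol(pairs)), function(k)
    wilcoxon_signed_rank_exact(integ[, pairs[1, k]],
                               integ[, pairs[2, k]])$p.value, numeric(1))
  fdr <- fdr_bh(net$p, config$q)
  net$p_fdr <- fdr$adjusted
  net$significant <- fdr$rejected

  # node level: one family of N node p-values per measure x pair
  node_rows <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    for (meas in c("strength", "clustering")) {
      va <- get(meas)[[a]]; vb <- get(meas)[[b]]
      p <- vapply(seq_len(N), function(i)
        wilcoxon_signed_rank_exact(va[, i], vb[, i])$p.value, numeric(1))
      f <- fdr_bh(p, config$q)
      node_rows[[length(node_rows) + 1]] <- data.frame(
        condition_a = a, condition_b = b, measure = meas, region = regions,
        p = p, p_fdr = f$adjusted, significant = f$rejected,
        trend = f$rejected_q10, stringsAsFactors = FALSE)
    }
  }
  node <- do.call(rbind, node_rows)

  # edge level
  mats <- lapply(conds, function(cond)
    lapply(subject_results, function(r) r$condition_matrices[[cond]]))
  names(mats) <- conds
  edge <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    edge[[paste(a, b, sep = "_vs_")]] <-
      nbs_paired(mats[[a]], mats[[b]], primary_p = config$primary_p,
                 n_perm = config$n_perm, alpha = config$alpha,
                 seed = config$seed)
  }
  one_sample <- lapply(conds, function(cond) {
    res <- nbs_one_sample(mats[[cond]], primary_p = config$primary_p,
                          n_perm = config$n_perm, alpha = config$alpha,
                          seed = config$seed)
    sig_edges <- if (any(res$significant))
      sum(res$extents[res$significant]) else 0L
    list(nbs = res, density = network_density(sig_edges, N))
  })
  names(one_sample) <- conds

  out <- structure(
    list(network = net, node = node, edge = edge, one_sample = one_sample,
         n_subjects = S, regions = regions,
         mean_integration = colMeans(integ), seed = config$seed),
    class = "group_result")
  if (!is.null(output_dir)) write_group_result(out, output_dir, config)
  out
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %d subjects\n", x$n_subjects))
  cat("mean integration by condition:\n")
  print(round(x$mean_integration, 4))
  cat("network-level comparisons:\n")
  print(x$network, row.names = FALSE)
  invisible(x)
}

write_group_result <- function(result, output_dir, config) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  edge_summary <- lapply(result$edge, function(e)
    list(extents = e$extents, p_fwe = e$p_fwe, sign = e$sign,
         significant = e$significant, n_permutations = e$n_permutations,
         threshold_t = e$threshold_t))
  jsonlite::write_json(
    list(n_subjects = result$n_subjects,
         parameters = unclass(config),
         mean_integration = as.list(result$mean_integration),
         network = result$network, node = result$node,
         edge = edge_summary,
         density = lapply(result$one_sample, `[[`, "density"),
         seed = result$seed),
    file.path(output_dir, "group-report.json"), auto_unbox = TRUE,
    digits = NA)
  # edge lists of significant components
  for (nm in names(result$edge)) {
    e <- result$edge[[nm]]
    if (!any(e$significant)) next
    rows <- do.call(rbind, lapply(which(e$significant), function(ci) {
      data.frame(component = ci,
                 region_a = result$regions[e$components[[ci]][, 1]],
                 region_b = result$regions[e$components[[ci]][, 2]],
                 stringsAsFactors = FALSE)
    }))
    write.table(rows, file.path(output_dir, paste0("nbs-", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  }
  invisible(output_dir)
}

#' Window-length sensitivity analysis
#'
#' Repeats the subject and group analyses for several window lengths and
#' summarizes the per-condition mean integration and whether the condition
#' ordering agrees across lengths. A length at which a subject has no valid
#' events is skipped with a warning.
#'
#' @param cohort list of per-subject lists with `series` and `events` (as
#'   produced by [simulate_cohort()]).
#' @param config a [pipeline_config()]; its `window_length` is overridden.
#' @param L_values window lengths to try (default 6, 8, 10).
#' @return List with `table` (per-L, per-condition mean integration),
#'   `orderings` (condition order per L) and `consistent` (single logical).
#' @export
run_sensitivity <- function(cohort, config = pipeline_config(),
                            L_values = c(6, 8, 10)) {
  rows <- list(); orderings <- list()
  for (L in L_values) {
    cfg <- config
    cfg$window_length <- as.integer(L)
    res <- tryCatch(
      lapply(cohort, function(s) run_subject(s$series, s$events, cfg)),
      error = function(e) {
        warning(sprintf("window length %d skipped: %s", L, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    mi <- colMeans(do.call(rbind, lapply(res, function(r)
      vapply(woi_conditions(), function(cond) r$metrics[[cond]]$integration,
             numeric(1)))))
    rows[[length(rows) + 1]] <- data.frame(
      L = L, t(mi), check.names = FALSE)
    orderings[[as.character(L)]] <- names(sort(mi, decreasing = TRUE))
  }
  if (!length(rows)) stop_woiconn("no feasible window length")
  tab <- do.call(rbind, rows)
  consistent <- length(unique(vapply(orderings, paste, character(1),
                                     collapse = ">"))) == 1
  list(table = tab, orderings = orderings, consistent = consistent)
}

#' Export a graph to BrainNet Viewer text formats
#'
#' Writes the `.node` file (columns x, y, z, color, size, label;
#' space-delimited, one row per region) and the `.edge` file (N x N
#' space-delimited weight matrix).
#'
#' @param edge_matrix symmetric N x N weight matrix (zeros for absent edges).
#' @param region_table region table supplying coordinates and labels.
#' @param node_size per-region size column (default 1).
#' @param node_color per-region color code (default 1).
#' @param path_prefix output path without extension.
#' @return Named character vector with the two file paths, invisibly.
#' @export
export_brainnet <- function(edge_matrix, region_table, node_size = 1,
                            node_color = 1, path_prefix) {
  n <- nrow(region_table)
  if (!is.matrix(edge_matrix) || any(dim(edge_matrix) != n))
    stop_woiconn("edge matrix dimensions must match the region table")
  node_size <- rep_len(node_size, n)
  node_color <- rep_len(node_color, n)
  node_path <- paste0(path_prefix, ".node")
  edge_path <- paste0(path_prefix, ".edge")
  node_df <- data.frame(region_table$x, region_table$y, region_table$z,
                        node_color, node_size, region_ids_of(region_table))
  write.table(node_df, node_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  write.table(format(edge_matrix, digits = 10, trim = TRUE), edge_path,
              sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(node = node_path, edge = edge_path))
}

#' Read a BrainNet Viewer .edge file
#' @param path `.edge` file.
#' @return Numeric matrix.
#' @export
read_brainnet_edge <- function(path) {
  as.matrix(read.table(path, sep = "", header = FALSE))
}
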