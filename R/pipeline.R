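# End-to-end orchestration: synthesize (or load) a study, fit model
# parameters, scan for convergence, simulate the null, and write the
# report tables.

#' Build and validate a pipeline run configuration
#'
#' Exactly one input mode must be active: *real-input* mode (a directory of
#' per-gene FASTA alignments plus tree and design files) or *synth* mode
#' (parameters for [generate_study()]).
#'
#' @param alignments_dir,tree_file,design_file real-input mode paths.
#' @param synth list of arguments for [generate_study()] (synth mode).
#' @param min_shared_per_cluster CCS support threshold per cluster.
#' @param k gamma categories for fitting and the null simulation.
#' @param null_reps replicates of the simulation null (0 disables it).
#' @param fit_max_columns number of alignment columns (pooled across genes,
#'   in gene order) used to fit alpha and branch lengths; fitting cost grows
#'   with unique site patterns, so the fit uses a concatenated slice of the
#'   data rather than all of it.
#' @param seed master seed; each stage derives its own sub-seed from it.
#' @param out_dir output directory.
#' @return a validated `run_config` (list).
#' @export
run_config <- function(alignments_dir = NULL, tree_file = NULL,
                       design_file = NULL, synth = NULL,
                       min_shared_per_cluster = 3L, k = 4L,
                       null_reps = 50L, fit_max_columns = 2000L,
                       seed = 1L, out_dir = "ccs_run") {
  real <- !is.null(alignments_dir)
  if (real && (is.null(tree_file) || is.null(design_file)))
    stop("real-input mode needs `tree_file` and `design_file`")
  if (real == !is.null(synth))
    stop("exactly one of real-input mode and synth mode must be configured")
  structure(list(alignments_dir = alignments_dir, tree_file = tree_file,
                 design_file = design_file, synth = synth,
                 min_shared_per_cluster = min_shared_per_cluster, k = k,
                 null_reps = null_reps, fit_max_columns = fit_max_columns,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full convergence pipeline
#'
#' Stages, in order: load or synthesize the study; scan every gene with the
#' CCS caller and aggregate; fit alpha and branch lengths on a concatenated
#' slice of the data; simulate the convergence null under the fitted model
#' and estimate ancestral-inference accuracy; write `sites.tsv` (per-site
#' calls), `summary.tsv` and `run_log.txt` under `config$out_dir`. Outputs
#' are deterministic given the seed (row order: gene then column).
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `report` (a `convergence_report`), `fit`,
#'   `null` (data.frame), `accuracy`, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("# ccsconv pipeline run, seed = %d\n", config$seed),
      file = log_path)
  seeds <- config$seed + c(synth = 101L, fit = 202L, null = 303L)

  if (!is.null(config$synth)) {
    study <- do.call(generate_study,
                     utils::modifyList(config$synth,
                                       list(seed = seeds[["synth"]])))
    genes <- study$genes; tree <- study$tree; design <- study$design
    logf("stage synth: %d genes x %d columns", length(genes),
         ncol(genes[[1L]]))
  } else {
    files <- sort(list.files(config$alignments_dir, "\\.(fa|fasta)$",
                             full.names = TRUE))
    if (!length(files)) stop("no FASTA files in ", config$alignments_dir)
    genes <- lapply(files, read_alignment)
    names(genes) <- vapply(genes, attr, "", "gene_id")
    tree <- read_tree(config$tree_file)
    design <- read_design(config$design_file)
    logf("stage load: %d genes from %s", length(genes),
         config$alignments_dir)
  }

  calls <- lapply(genes, scan_gene, design = design,
                  min_shared_per_cluster = config$min_shared_per_cluster)
  report <- aggregate_calls(calls)
  logf("stage ccs: %d foreground, %d background calls (threshold %d)",
       report$foreground_count, report$background_count,
       config$min_shared_per_cluster)

  concat <- do.call(cbind, lapply(genes, unclass))
  concat <- concat[, seq_len(min(ncol(concat), config$fit_max_columns)),
                   drop = FALSE]
  fit <- fit_parameters(ortho_aln(concat, gene_id = "concat"), tree,
                        k = config$k)
  logf("stage fit: alpha = %.4f, logL = %.2f (%d columns, converged = %s)",
       fit$alpha, fit$log_likelihood, ncol(concat), fit$converged)

  null_df <- NULL
  accuracy <- NA_real_
  if (config$null_reps > 0L) {
    n_total <- sum(vapply(genes, ncol, 0L))
    null_df <- null_convergence(fit$tree, fit$model, design,
                                n_sites = n_total,
                                reps = config$null_reps,
                                seed = seeds[["null"]],
                                min_shared_per_cluster =
                                  config$min_shared_per_cluster)
    sim <- simulate_gene(fit$tree, fit$model, n_total,
                         seed = seeds[["null"]])
    accuracy <- ancestral_accuracy(sim, design)
    logf("stage null: %d reps of %d sites; mean fg = %.2f, bg = %.2f",
         config$null_reps, n_total, mean(null_df$foreground),
         mean(null_df$background))
    logf("stage null: ancestral accuracy = %.4f", accuracy)
  }

  sites_path <- file.path(config$out_dir, "sites.tsv")
  utils::write.table(report$calls, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_df <- data.frame(
    seed = config$seed,
    n_genes = length(genes),
    foreground_count = report$foreground_count,
    background_count = report$background_count,
    genes_with_foreground = report$genes_with_foreground,
    multi_site_genes = report$multi_site_genes,
    chi2_stat = report$chi2_stat,
    p_value = report$p_value,
    fitted_alpha = fit$alpha,
    null_fg_mean = if (is.null(null_df)) NA else mean(null_df$foreground),
    null_bg_mean = if (is.null(null_df)) NA else mean(null_df$background),
    null_fg_q95 = if (is.null(null_df)) NA
                  else stats::quantile(null_df$foreground, 0.95),
    ancestral_accuracy = accuracy)
  summary_path <- file.path(config$out_dir, "summary.tsv")
  utils::write.table(summary_df, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logf("wrote %s and %s", sites_path, summary_path)

  invisible(list(report = report, fit = fit, null = null_df,
                 accuracy = accuracy,
                 paths = c(sites = sites_path, summary = summary_path,
                           log = log_path)))
}
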