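# One-command orchestration of the full flow: windows -> features ->
# groups -> training -> group report -> hits -> exports.

#' Pipeline configuration with mode presets
#'
#' Bundles every tunable of the pipeline.  The `chip` mode preset (20
#' groups over the 5000 most discriminative features) targets single-TF
#' ChIP-seq experiments; the `dnase` preset (200 groups over 30000
#' features) targets open-chromatin maps, whose peaks mix binding
#' signals of many factors.  Any field can be overridden.
#'
#' @param mode `"chip"` or `"dnase"`.
#' @param ... named overrides of any configuration field (`k`,
#'   `max_run`, `n_top`, `G`, `width`, `flank_gap`, `fdr`,
#'   `min_examples`, `folds`, `seed`, `lambda1_grid`, `lambda2_grid`,
#'   `alpha`, `beta`, `max_n_frac`, `linkage`,
#'   `group_weight_exponent`).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("chip", "dnase"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode, k = 8, max_run = 2,
    n_top = if (mode == "chip") 5000 else 30000,
    G = if (mode == "chip") 20 else 200,
    width = 150, flank_gap = 300, max_n_frac = 0.1,
    fdr = 0.05, min_examples = 25, folds = 10, seed = 1,
    lambda1_grid = NULL, lambda2_grid = NULL,
    alpha = 1.5, beta = 1, linkage = "ward.D2",
    group_weight_exponent = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the full discriminative k-mer pipeline
#'
#' Extracts peak and flank windows (or takes pre-labeled sequences),
#' counts and selects wildcard k-mer features, clusters them into
#' groups, trains the sparse group lasso by cross-validated proximal
#' gradient descent, reports group class associations and significant
#' examples, localizes hits and exports motif-ready windows.  All
#' outputs plus a JSON manifest (configuration, seed, file checksums)
#' are written under `out_dir`; re-running with identical inputs and
#' seed reproduces identical files.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param seqs pre-labeled sequences (`labeled_seqs` or FASTA path);
#'   alternative to `peaks` + `genome`.
#' @param peaks peak file path or `peaks` data frame.
#' @param genome FASTA path or `DNAStringSet` (required with `peaks`).
#' @param peak_dialect `"bed6"` or `"narrowPeak"`.
#' @param cross_validate fit penalties by cross-validation (default
#'   TRUE); otherwise a single mid-path penalty pair is used.
#' @return list of class `peakgl_run`: fit, report, hits, file paths and
#'   the manifest.
#' @export
run_peakgl <- function(config = run_config(), out_dir, seqs = NULL,
                      peaks = NULL, genome = NULL,
                      peak_dialect = "narrowPeak",
                      cross_validate = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[", format(Sys.time(), "%H:%M:%S"),
                                     "] ", ...)

  if (is.null(seqs)) {
    if (is.null(peaks) || is.null(genome)) {
      stop("need either labeled sequences or peaks plus a genome")
    }
    if (is.character(peaks)) peaks <- read_peaks(peaks, peak_dialect)
    log_stage("windows: ", nrow(peaks), " peaks")
    seqs <- extract_windows(peaks, genome, width = config$width,
                            flank_gap = config$flank_gap,
                            max_n_frac = config$max_n_frac)
  } else if (is.character(seqs)) {
    seqs <- read_labeled_fasta(seqs)
  }
  seqs <- as_labeled_seqs(seqs)
  log_stage("sequences: ", sum(seqs$label > 0), " positive / ",
            sum(seqs$label < 0), " negative")
  write_sequences(seqs, file.path(out_dir, "sequences.fa"))

  space <- kmer_feature_space(config$k, config$max_run)
  M <- count_features(seqs, space)
  M <- select_features(M, config$n_top)
  log_stage("features: ", ncol(M$counts), " selected of ",
            length(space$patterns))

  A <- cluster_features(M, config$G, linkage = config$linkage)
  write_groups(A, file.path(out_dir, "groups.tsv"))
  log_stage("groups: ", A$G)

  if (cross_validate) {
    cv <- sgl_cv(M, A, config$lambda1_grid, config$lambda2_grid,
                 folds = config$folds, seed = config$seed,
                 group_weight_exponent = config$group_weight_exponent)
    fit <- cv$fit
    cv_table <- cv$cv_table
  } else {
    lmax <- sgl_lambda_max(M, A, config$group_weight_exponent)
    fit <- sgl_fit(M, A, 0.02 * lmax$lambda1_max, 0.02 * lmax$lambda2_max,
                   group_weight_exponent = config$group_weight_exponent)
    cv_table <- NULL
  }
  log_stage("model: ", sum(fit$w != 0), " nonzero weights, lambda1 = ",
            signif(fit$lambda1, 3), ", lambda2 = ", signif(fit$lambda2, 3))
  write_sgl_model(fit, file.path(out_dir, "model.json"))

  report <- group_report(fit, M, fdr = config$fdr,
                         min_examples = config$min_examples)
  utils::write.table(report$table, file.path(out_dir, "groups_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("report: ", sum(report$table$eligible_for_motif),
            " group(s) eligible for motif finding")

  all_hits <- list()
  pfms <- list()
  for (g in which(report$table$eligible_for_motif)) {
    det <- report$details[[g]]
    sig_ids <- det$id[det$significant]
    hits <- locate_hits(fit, M, seqs[seqs$id %in% sig_ids, , drop = FALSE],
                        g, q_values = stats::setNames(det$q, det$id))
    if (!nrow(hits)) next
    all_hits[[as.character(g)]] <- hits
    if (nrow(hits) >= config$min_examples) {
      pfms[[paste0("group_", g)]] <- build_group_pfm(
        hits, seqs, config$k, min_examples = config$min_examples)
    }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else NULL
  if (!is.null(hits)) {
    export_hit_windows(hits, seqs,
                       fasta_path = file.path(out_dir, "hit_windows.fa"),
                       bed_path = file.path(out_dir, "hit_windows.bed"))
    log_stage("hits: ", nrow(hits), " localized")
  }
  if (length(pfms)) write_meme(pfms, file.path(out_dir, "group_pfms.meme"))

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("peakgl")),
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    checksums = as.list(stats::setNames(
      vapply(files, .file_checksum, character(1)), basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(config = config, seqs = seqs, matrix = M,
                 assignment = A, fit = fit, report = report,
                 hits = hits, pfms = pfms, cv_table = cv_table,
                 out_dir = out_dir, manifest = manifest),
            class = "peakgl_run")
}

#' Serialize / load a fitted model as JSON
#'
#' @param fit an `sgl_fit`.
#' @param path JSON path.
#' @return `path` (write) or an `sgl_fit` (read).
#' @export
write_sgl_model <- function(fit, path) {
  obj <- list(
    features = names(fit$w), w = unname(fit$w),
    group_of = unname(fit$assignment$group_of),
    lambda1 = fit$lambda1, lambda2 = fit$lambda2,
    group_weight_exponent = fit$group_weight_exponent,
    converged = fit$converged, iterations = fit$iterations,
    final_objective = utils::tail(fit$objective_trace, 1))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sgl_model
#' @export
read_sgl_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- .as_group_assignment(stats::setNames(as.integer(obj$group_of),
                                            obj$features))
  structure(
    list(w = stats::setNames(obj$w, obj$features),
         lambda1 = obj$lambda1, lambda2 = obj$lambda2,
         objective_trace = obj$final_objective,
         converged = obj$converged, iterations = obj$iterations,
         assignment = A,
         group_weight_exponent = obj$group_weight_exponent),
    class = "sgl_fit")
}
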