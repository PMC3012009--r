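default_pipeline_params <- function() {
  list(iqr_top_n = 1500,          # variable-gene count for clustering
       linkage = "average",
       boot_B = 10000, boot_r = 1,
       fdr_max = 0.01,
       perm_B = 1000, perm_k = 5,
       set_min_size = 5,
       arm_p_threshold = 0.001, arm_min_genes = 20,
       sig_fdr_max = 1e-5, sig_min_fold = 2,
       top_sets = 30,
       center = "mean")
}

#' Run the full analysis on a synthetic cohort
#'
#' Executes the complete workflow in the order the analyses build on one
#' another: replicate averaging, matched-normal normalization, IQR
#' filtering, bootstrap-supported clustering of tumor samples, moderated-t
#' differential expression of the focal subtype against each other
#' subtype, the distinctness permutation test, per-sample gene set
#' enrichment with discriminant ranking, chromosome-arm bias calls,
#' overlap-dissimilarity clustering of the top discriminant sets,
#' signature derivation, and (when the cohort plants a coupling) the
#' driver-versus-enrichment correlation screen.  When ground truth is
#' available a recovery report juxtaposes planted and recovered structure.
#'
#' Every stage is a pure function of (inputs, parameters, seed); rerunning
#' with the same arguments reproduces identical outputs.
#'
#' @param cohort A `SyntheticCohort` (see [simulate_cohort()]), or a
#'   [cohort_design()] to simulate first.
#' @param params Named list overriding [default_pipeline_params()];
#'   unknown names are an error.
#' @param seed Integer seed for the resampling stages.
#' @param focal Label of the focal subtype (default: the cohort's first
#'   subtype).
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there as plain text along with `config.yaml` for provenance.
#' @return A list of class `PipelineResult`.
#' @export
run_pipeline <- function(cohort, params = list(), seed = 1L, focal = NULL,
                         out_dir = NULL) {
  if (inherits(cohort, "CohortDesign")) cohort <- simulate_cohort(cohort)
  stopifnot(inherits(cohort, "SyntheticCohort"))
  p <- default_pipeline_params()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) abort("unknown pipeline parameter(s): %s", quote_ids(unknown))
  p[names(params)] <- params

  sheet <- cohort$sheet
  m <- average_replicates(cohort$expression, sheet)
  sheet <- sheet[sheet$sample_id %in% sample_ids(m), , drop = FALSE]
  ratio <- normalize_to_reference(m, sheet, center = p$center, keep_normals = TRUE)
  tumors <- sheet$sample_id[!sheet$is_normal]
  ratio_t <- em_subset(ratio, samples = tumors)
  groups <- split(sheet$sample_id[!sheet$is_normal],
                  sheet$group[!sheet$is_normal])
  subtype_order <- unique(sheet$group[!sheet$is_normal])
  focal <- focal %||% subtype_order[1L]
  if (!focal %in% names(groups)) abort("unknown focal subtype '%s'", focal)
  others <- setdiff(subtype_order, focal)

  # clustering with bootstrap node support
  filt <- iqr_filter(ratio_t, "top_n", min(p$iqr_top_n, nrow(ratio_t$values)))
  boots <- bootstrap_support(filt, linkage = p$linkage, B = p$boot_B,
                             r = p$boot_r, seed = derive_seed(seed, "bootstrap"))

  # differential expression of focal vs each other subtype
  diffexp <- lapply(others, function(g)
    moderated_t(ratio_t, groups[[focal]], groups[[g]]))
  names(diffexp) <- others
  de_counts <- vapply(diffexp, count_significant, 0, fdr_max = p$fdr_max)

  # distinctness permutation against the largest other subtype
  pool_label <- others[which.max(lengths(groups[others]))]
  pool <- groups[[pool_label]]
  k <- min(p$perm_k, length(pool) - 2L)
  perm <- distinctness_permutation(ratio_t, groups[[focal]], pool, k = k,
                                   B = p$perm_B,
                                   seed = derive_seed(seed, "permutation"),
                                   fdr_max = p$fdr_max)

  # enrichment, discriminant sets, arm calls
  enr <- pgsea_scores(ratio_t, cohort$sets, min_size = p$set_min_size)
  disc <- discriminant_sets(enr, groups[[focal]], unlist(groups[others]))
  arms <- arm_bias_calls(ratio_t, cohort$annotation,
                         p_threshold = p$arm_p_threshold,
                         min_genes = p$arm_min_genes)

  # overlap structure of the top discriminant sets
  top <- utils::head(disc$set, p$top_sets)
  set_tree <- NULL; dmat <- NULL
  if (length(top) >= 2L) {
    dmat <- set_dissimilarity(
      gene_set_collection(cohort$sets$sets[top]),
      universe = gene_ids(ratio_t))
    set_tree <- cluster_sets(dmat)
  }

  # focal signature
  signature <- derive_signature(ratio_t, groups[[focal]], unlist(groups[others]),
                                fdr_max = p$sig_fdr_max,
                                min_fold = p$sig_min_fold,
                                name = paste0(focal, "_vs_rest"))

  # driver-vs-enrichment screen (tumors and normals: full dynamic range)
  screen <- NULL
  if (!is.null(cohort$truth$coupling)) {
    enr_all <- pgsea_scores(ratio, cohort$sets, min_size = p$set_min_size)
    screen <- correlate_gene_to_sets(ratio, cohort$truth$coupling$driver_gene,
                                     enr_all)
  }

  recovery <- recovery_report(cohort, focal, groups, boots, disc, arms,
                              signature, screen, p)

  result <- structure(list(params = p, seed = seed, focal = focal,
                           groups = groups, ratio = ratio_t,
                           bootstrap = boots, diffexp = diffexp,
                           de_counts = de_counts, permutation = perm,
                           enrichment = enr, discriminant = disc,
                           arm_calls = arms, set_dissimilarity = dmat,
                           set_tree = set_tree, signature = signature,
                           screen = screen, recovery = recovery),
                      class = "PipelineResult")
  if (!is.null(out_dir)) write_pipeline_outputs(result, cohort, out_dir)
  result
}

# compare recovered structure against planted truth
recovery_report <- function(cohort, focal, groups, boots, disc, arms,
                            signature, screen, p) {
  truth <- cohort$truth
  rep <- list()
  rep$focal_clade_bp <- node_bp(boots, groups[[focal]])

  planted <- character(0)
  if (!is.null(truth$set_events))
    planted <- unique(truth$set_events$set[truth$set_events$subtype == focal])
  if (length(planted))
    rep$planted_set_rank <- stats::setNames(match(planted, disc$set), planted)

  if (!is.null(truth$arm_events)) {
    ev <- truth$arm_events
    ev$arm_label <- paste0(ev$chromosome, ev$arm)
    key_truth <- paste(ev$sample_id, ev$arm_label)
    key_calls <- paste(arms$sample_id, arms$arm)
    hit <- match(key_truth, key_calls)
    ok <- !is.na(hit)
    called <- arms$call[hit[ok]]
    expected <- ifelse(ev$shift[ok] > 0, "gain", "loss")
    affected <- ev$drawn[ok]
    rep$arm_sensitivity <- if (any(affected))
      mean(called[affected] == expected[affected]) else NA_real_
    unaffected_keys <- setdiff(key_calls, key_truth[ev$drawn])
    rep$arm_null_call_rate <-
      mean(arms$call[paste(arms$sample_id, arms$arm) %in% unaffected_keys] != "none")
  }

  truth_up <- unique(c(
    if (length(truth$markers[[focal]]))
      truth$markers[[focal]]$gene_id[truth$markers[[focal]]$shift > 0],
    if (length(planted) && !is.null(truth$set_events))
      unlist(cohort$sets$sets[planted[truth$set_events$shift[
        match(planted, truth$set_events$set)] > 0]])))
  if (length(truth_up))
    rep$signature_up_recall <- mean(truth_up %in% signature$up)

  if (!is.null(screen) && !is.null(truth$coupling)) {
    hit <- match(truth$coupling$target_set, screen$set)
    rep$coupling <- list(target_set = truth$coupling$target_set,
                         rho_target = truth$coupling$rho_target,
                         rho_recovered = screen$rho[hit],
                         rank = screen$rank[hit])
  }
  rep
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n")
  cat(sprintf("  focal subtype: %s (%d samples)\n", x$focal,
              length(x$groups[[x$focal]])))
  cat(sprintf("  DE genes vs others (FDR < %g): %s\n", x$params$fdr_max,
              paste(sprintf("%s = %d", names(x$de_counts), x$de_counts),
                    collapse = ", ")))
  cat(sprintf("  focal clade BP: %s (B = %d)\n",
              format(x$recovery$focal_clade_bp), x$bootstrap$B))
  cat(sprintf("  distinctness: exceed_fraction = %.3f, p_bound = %.4g\n",
              x$permutation$exceed_fraction, x$permutation$p_bound))
  if (!is.null(x$recovery$planted_set_rank))
    cat(sprintf("  planted set rank(s): %s\n",
                paste(sprintf("%s = %d", names(x$recovery$planted_set_rank),
                              x$recovery$planted_set_rank), collapse = ", ")))
  if (!is.null(x$recovery$arm_sensitivity))
    cat(sprintf("  arm-call sensitivity: %.3f, null call rate: %.4f\n",
                x$recovery$arm_sensitivity, x$recovery$arm_null_call_rate))
  if (!is.null(x$recovery$coupling))
    cat(sprintf("  coupling: target %s, rho %.3f (planted %.2f), rank %d\n",
                x$recovery$coupling$target_set, x$recovery$coupling$rho_recovered,
                x$recovery$coupling$rho_target, x$recovery$coupling$rank))
  invisible(x)
}

write_pipeline_outputs <- function(result, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(params = result$params, seed = result$seed,
                        focal = result$focal),
                   file.path(out_dir, "config.yaml"))
  write_expression(result$ratio, file.path(out_dir, "normalized_ratio.tsv"))
  write_newick(result$bootstrap, file.path(out_dir, "dendrogram.newick"))
  utils::write.table(result$bootstrap$support,
                     file.path(out_dir, "node_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(result$diffexp))
    write_moderated_test(result$diffexp[[g]],
                         file.path(out_dir, sprintf("diffexp_%s_vs_%s.tsv",
                                                    result$focal, g)))
  write_permutation_trace(result$permutation,
                          file.path(out_dir, "permutation_trace.tsv"))
  write_enrichment(result$enrichment, file.path(out_dir, "enrichment.tsv"))
  utils::write.table(as.data.frame(result$discriminant),
                     file.path(out_dir, "discriminant_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(result$arm_calls),
                     file.path(out_dir, "arm_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$set_dissimilarity)) {
    write_dissimilarity(result$set_dissimilarity,
                        file.path(out_dir, "set_dissimilarity.tsv"))
    write_newick(result$set_tree, file.path(out_dir, "set_dendrogram.newick"))
  }
  write_signature(result$signature, file.path(out_dir, "signature.gmt"))
  if (!is.null(result$screen))
    write_correlation_screen(result$screen,
                             file.path(out_dir, "correlation_screen.tsv"))
  yaml::write_yaml(result$recovery, file.path(out_dir, "recovery_report.yaml"))
  invisible(out_dir)
}
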