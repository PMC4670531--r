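#' Evaluate one contig set against the gold-standard gene set
#'
#' Runs the full per-set evaluation: differential calls on genes and contigs,
#' fold-change pairing and Pearson correlation, co-identity of DECs with
#' DEGs, and the GO slim distribution comparison (KS + per-term Fisher).
#'
#' @param contigs Contig tibble for the (possibly deduplicated) set.
#' @param hits HSP-level hit tibble restricted or not — only hits whose query
#'   is in `contigs` are used.
#' @param gene_expr Gene expression tibble ([expression_table()]) for the
#'   gold standard.
#' @param contig_counts_a,contig_counts_b `count_table`s for the full contig
#'   universe; they are subset to `contigs`.
#' @param go_map Annotation tibble.
#' @param fc_threshold Differential-call threshold on `|log2fc|`.
#' @param alpha Fisher significance level.
#' @return A list: `contig_expr`, `assignments`, `paired`, and one-row
#'   `summary` (correlation, co-identity fields, KS and Fisher results).
#' @export
evaluate_contig_set <- function(contigs, hits, gene_expr, contig_counts_a,
                                contig_counts_b, go_map, fc_threshold = 1,
                                alpha = 0.05) {
  subset_counts <- function(ct) {
    new_count_table(
      ct$counts %>% filter(.data$feature_id %in% contigs$contig_id),
      ct$total_mapped
    )
  }
  contig_expr <- expression_table(
    subset_counts(contig_counts_a), subset_counts(contig_counts_b),
    contigs, fc_threshold
  )
  assignments <- best_hit_per_contig(
    hits %>% filter(.data$query_id %in% contigs$contig_id)
  )
  paired <- pair_fold_changes(gene_expr, contig_expr, assignments)
  dec_ids <- differential_ids(contig_expr)
  deg_ids <- differential_ids(gene_expr)
  coid <- co_identity(dec_ids, deg_ids, assignments)
  dec_genes <- assignments$gene_id[match(dec_ids, assignments$contig_id)]
  go_cmp <- compare_go_distributions(deg_ids, dec_genes, go_map, alpha)
  summary <- dplyr::bind_cols(
    tibble(
      n_contigs = nrow(contigs),
      correlation_all = fold_change_correlation(paired, "all"),
      correlation_matched = fold_change_correlation(paired, "matched")
    ),
    coid,
    glance(go_cmp) %>% select(
      "ks_statistic", "ks_pvalue", "n_significant_terms"
    )
  )
  list(
    contig_expr = contig_expr,
    assignments = assignments,
    paired = paired,
    go_comparison = go_cmp,
    summary = summary
  )
}

#' Run the complete redundancy-removal benchmark on synthetic data
#'
#' Simulates a study ([simulate_assembly()]), applies all three
#' redundancy-removal strategies, and evaluates the raw and each deduplicated
#' contig set against the gold-standard gene set.  The three report tables
#' mirror the structure of the standard published comparison: a length
#' summary per contig set, a classification summary per contig set, and an
#' evaluation summary (fold-change correlation, DEC/DEG co-identity, GO
#' distribution tests) per contig set.
#'
#' @param seed Top-level simulation seed.
#' @param fc_threshold Differential-call threshold on `|log2fc|`.
#' @param alpha Fisher significance level.
#' @param cluster Include the cluster-representative method (slowest step;
#'   default `TRUE`).
#' @param ... Passed on to [simulate_assembly()].
#' @return A `redundancy_benchmark` object: list with `sim`, `dedup` (named
#'   `dedup_result`s), `length_summary`, `classification_summary`,
#'   `evaluation_summary`, `evaluations` (per-set detail lists), `gene_expr`.
#' @export
run_redundancy_benchmark <- function(seed = 1, fc_threshold = 1, alpha = 0.05,
                                     cluster = TRUE, ...) {
  sim <- simulate_assembly(seed = seed, cluster = cluster, ...)
  sets <- list(raw = sim$contigs)
  dedups <- list(
    longest = select_longest_per_subcomponent(sim$contigs),
    annotated = select_annotated(sim$contigs, sim$hits)
  )
  if (cluster) {
    dedups$clustered <- select_cluster_representatives(sim$contigs, sim$clusters)
    dedups <- dedups[c("longest", "clustered", "annotated")]
  }
  for (nm in names(dedups)) {
    sets[[nm]] <- kept_contigs(sim$contigs, dedups[[nm]])
  }

  gene_expr <- expression_table(
    sim$counts$gene_counts_a, sim$counts$gene_counts_b,
    sim$genes %>% rename(feature_id = "gene_id"), fc_threshold
  )

  length_summary <- summarize_contig_sets(
    c(list(gene_dataset = sim$genes), sets)
  )
  assignments_all <- best_hit_per_contig(sim$hits)
  classification_summary <- purrr::imap(sets, function(cc, nm) {
    cls <- classify_contigs(
      cc, assignments_all %>% filter(.data$contig_id %in% cc$contig_id)
    )
    glance(cls) %>% mutate(contig_set = nm, .before = 1)
  }) %>% bind_rows()

  evaluations <- purrr::map(sets, function(cc) {
    evaluate_contig_set(
      cc, sim$hits, gene_expr,
      sim$counts$contig_counts_a, sim$counts$contig_counts_b,
      sim$go_map, fc_threshold, alpha
    )
  })
  evaluation_summary <- purrr::imap(evaluations, function(ev, nm) {
    ev$summary %>% mutate(contig_set = nm, .before = 1)
  }) %>% bind_rows()

  structure(
    list(
      sim = sim,
      dedup = dedups,
      sets = sets,
      gene_expr = gene_expr,
      length_summary = length_summary,
      classification_summary = classification_summary,
      evaluations = evaluations,
      evaluation_summary = evaluation_summary,
      fc_threshold = fc_threshold,
      alpha = alpha
    ),
    class = "redundancy_benchmark"
  )
}

#' @export
print.redundancy_benchmark <- function(x, ...) {
  cat(
    "<redundancy_benchmark> seed ", x$sim$seed, ": ",
    nrow(x$sim$contigs), " contigs over ", nrow(x$sim$genes), " genes\n\n",
    sep = ""
  )
  cat("Length summary:\n")
  print(x$length_summary %>% mutate(mean_len = round(.data$mean_len)))
  cat("\nEvaluation summary:\n")
  print(
    x$evaluation_summary %>%
      select(
        "contig_set", "n_contigs", "correlation_all", "n_dec_identical",
        "n_dec_nonidentical", "ks_statistic", "ks_pvalue",
        "n_significant_terms"
      )
  )
  invisible(x)
}

#' @rdname run_redundancy_benchmark
#' @param x A `redundancy_benchmark`.
#' @param ... Unused.
#' @export
glance.redundancy_benchmark <- function(x, ...) x$evaluation_summary

#' Write the benchmark report tables as TSV files
#'
#' Emits `length_summary.tsv`, `classification_summary.tsv` and
#' `evaluation_summary.tsv` (plus the per-set paired fold changes and
#' per-term GO tables under `detail/`) into a directory.
#'
#' @param benchmark A `redundancy_benchmark`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_benchmark_reports <- function(benchmark, outdir) {
  dir.create(file.path(outdir, "detail"), showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(benchmark$length_summary, file.path(outdir, "length_summary.tsv"))
  readr::write_tsv(
    benchmark$classification_summary,
    file.path(outdir, "classification_summary.tsv")
  )
  readr::write_tsv(
    benchmark$evaluation_summary,
    file.path(outdir, "evaluation_summary.tsv")
  )
  for (nm in names(benchmark$evaluations)) {
    ev <- benchmark$evaluations[[nm]]
    readr::write_tsv(
      ev$paired, file.path(outdir, "detail", paste0(nm, "_paired_fc.tsv"))
    )
    readr::write_tsv(
      tidy(ev$go_comparison),
      file.path(outdir, "detail", paste0(nm, "_go_terms.tsv"))
    )
  }
  invisible(outdir)
}
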