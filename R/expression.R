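#' Reads per kilobase of feature per million mapped reads
#'
#' `rpkm = count * 1e9 / (total_mapped * length)`, i.e. the read count
#' normalised by feature length in kilobases and library size in millions of
#' mapped reads.  Vectorised over all arguments.
#'
#' @param count Read count(s) for the feature.
#' @param length Feature length(s) in bases (>= 1).
#' @param total_mapped Mapped reads in the library (>= 1).
#' @return RPKM value(s).
#' @export
#' @examples
#' rpkm(10, 1000, 1e6) # 10
rpkm <- function(count, length, total_mapped) {
  if (any(total_mapped < 1)) {
    abort("total_mapped must be >= 1 to compute RPKM")
  }
  stopifnot(all(length >= 1), all(count >= 0))
  count * 1e9 / (total_mapped * length)
}

#' Pseudocounted log2 fold change between two RPKM values
#'
#' Each RPKM is incremented by 1 before taking the ratio, so features absent
#' from one library still yield a finite fold change:
#' `log2((rpkm_b + 1) / (rpkm_a + 1))`.
#'
#' @param rpkm_a,rpkm_b Non-negative RPKM values for conditions A and B.
#' @return log2 fold change (B over A).
#' @export
log2_fold_change <- function(rpkm_a, rpkm_b) {
  stopifnot(all(rpkm_a >= 0), all(rpkm_b >= 0))
  log2((rpkm_b + 1) / (rpkm_a + 1))
}

#' Per-feature expression table for a two-condition comparison
#'
#' Joins two count tables on a shared feature set, computes RPKM for each
#' condition, the pseudocounted log2 fold change, and the differential flag
#' (`|log2fc| > fc_threshold`, strict, both directions).
#'
#' @param counts_a,counts_b `count_table` objects ([read_counts()],
#'   [count_table()]) for conditions A and B.
#' @param lengths Tibble mapping `feature_id` (or `contig_id`) to `length` in
#'   bases; typically a contig tibble or gene FASTA table.
#' @param fc_threshold Differential-call threshold on `|log2fc|` (default 1,
#'   i.e. more than two-fold change after pseudocounting).
#' @return A tibble with columns `feature_id`, `length`, `count_a`, `count_b`,
#'   `rpkm_a`, `rpkm_b`, `log2fc`, `is_differential`.
#' @export
expression_table <- function(counts_a, counts_b, lengths, fc_threshold = 1) {
  stopifnot(inherits(counts_a, "count_table"), inherits(counts_b, "count_table"))
  if ("contig_id" %in% names(lengths) && !"feature_id" %in% names(lengths)) {
    lengths <- lengths %>% rename(feature_id = "contig_id")
  }
  stopifnot(all(c("feature_id", "length") %in% names(lengths)))
  tbl <- lengths %>%
    select("feature_id", "length") %>%
    left_join(counts_a$counts %>% rename(count_a = "count"), by = "feature_id") %>%
    left_join(counts_b$counts %>% rename(count_b = "count"), by = "feature_id") %>%
    mutate(
      count_a = dplyr::coalesce(.data$count_a, 0L),
      count_b = dplyr::coalesce(.data$count_b, 0L),
      rpkm_a = rpkm(.data$count_a, .data$length, counts_a$total_mapped),
      rpkm_b = rpkm(.data$count_b, .data$length, counts_b$total_mapped),
      log2fc = log2_fold_change(.data$rpkm_a, .data$rpkm_b)
    )
  call_differential(tbl, fc_threshold)
}

#' Flag differentially expressed features
#'
#' A feature is differential when its absolute pseudocounted log2 fold change
#' strictly exceeds the threshold; both up- and down-regulation qualify.  A
#' feature sitting exactly at the threshold is not called.
#'
#' @param records Expression tibble with a `log2fc` column.
#' @param fc_threshold Positive threshold on `|log2fc|` (default 1).
#' @return `records` with `is_differential` set (replaced when present).
#' @export
call_differential <- function(records, fc_threshold = 1) {
  stopifnot(fc_threshold > 0, "log2fc" %in% names(records))
  records %>% mutate(is_differential = abs(.data$log2fc) > fc_threshold)
}

#' Differential feature identifiers
#'
#' @param records Expression tibble with `feature_id` and `is_differential`
#'   (or `log2fc`, in which case [call_differential()] is applied first).
#' @param fc_threshold Threshold used when `is_differential` is absent.
#' @return Character vector of differential `feature_id`s.
#' @export
differential_ids <- function(records, fc_threshold = 1) {
  if (!"is_differential" %in% names(records)) {
    records <- call_differential(records, fc_threshold)
  }
  records %>% filter(.data$is_differential) %>% pull("feature_id")
}

#' Pair contig fold changes with their corresponding gene fold changes
#'
#' Builds the scatter of contig log2 fold change against the fold change of
#' the gene each contig is assigned to.  Genes with no assigned contig appear
#' as `gene_only` rows with the contig axis at 0 (no contig correlated with
#' the expressed gene); contigs with no gene assignment appear as
#' `contig_only` rows with the gene axis at 0 (erroneous contigs with no
#' homology).  When several contigs are assigned to one gene — a redundant,
#' non-deduplicated set — each contig contributes its own row against that
#' gene's fold change.
#'
#' @param gene_records Expression tibble for the gold-standard gene set.
#' @param contig_records Expression tibble for a contig set.
#' @param assignments Contig-to-gene assignments ([best_hit_per_contig()]).
#' @return A tibble with `gene_id`, `contig_id`, `gene_log2fc`,
#'   `contig_log2fc`, `pairing_status` in {matched, gene_only, contig_only}.
#' @export
pair_fold_changes <- function(gene_records, contig_records, assignments) {
  contig_fc <- contig_records %>%
    select(contig_id = "feature_id", contig_log2fc = "log2fc") %>%
    left_join(assignments %>% select("contig_id", "gene_id"), by = "contig_id")
  gene_fc <- gene_records %>%
    select(gene_id = "feature_id", gene_log2fc = "log2fc")
  matched <- contig_fc %>%
    filter(!is.na(.data$gene_id)) %>%
    left_join(gene_fc, by = "gene_id") %>%
    mutate(
      gene_log2fc = dplyr::coalesce(.data$gene_log2fc, 0),
      pairing_status = "matched"
    )
  gene_only <- gene_fc %>%
    anti_join(matched, by = "gene_id") %>%
    mutate(
      contig_id = NA_character_, contig_log2fc = 0,
      pairing_status = "gene_only"
    )
  contig_only <- contig_fc %>%
    filter(is.na(.data$gene_id)) %>%
    mutate(gene_log2fc = 0, pairing_status = "contig_only")
  bind_rows(matched, gene_only, contig_only) %>%
    select(
      "gene_id", "contig_id", "gene_log2fc", "contig_log2fc", "pairing_status"
    )
}

#' Pearson correlation of paired fold changes
#'
#' The product-moment correlation between gene-axis and contig-axis log2 fold
#' changes.  By default all rows enter the computation, including the
#' axis-aligned `gene_only` and `contig_only` rows — those points are exactly
#' what depresses the correlation of a redundant or erroneous contig set, and
#' their removal is the mechanism by which deduplication improves it.  Set
#' `which = "matched"` for the matched-rows-only variant.
#'
#' @param pairs Output of [pair_fold_changes()] (or any tibble with
#'   `gene_log2fc` and `contig_log2fc`).
#' @param which `"all"` (default) or `"matched"`.
#' @return Pearson correlation in \[-1, 1\], or `NA` when fewer than two rows
#'   or zero variance on either axis.
#' @export
fold_change_correlation <- function(pairs, which = c("all", "matched")) {
  which <- match.arg(which)
  if (which == "matched" && "pairing_status" %in% names(pairs)) {
    pairs <- pairs %>% filter(.data$pairing_status == "matched")
  }
  x <- pairs$gene_log2fc
  y <- pairs$contig_log2fc
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  cor(x, y, method = "pearson")
}
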