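new_dedup_result <- function(method, contigs, kept_ids, gene_to_contig = NULL,
                             n_passthrough = 0L) {
  kept_ids <- sort(unique(kept_ids))
  stopifnot(all(kept_ids %in% contigs$contig_id))
  structure(
    list(
      method = method,
      kept_ids = kept_ids,
      removed_ids = sort(setdiff(contigs$contig_id, kept_ids)),
      gene_to_contig = gene_to_contig,
      n_passthrough = as.integer(n_passthrough),
      n_input = nrow(contigs)
    ),
    class = "dedup_result"
  )
}

#' @export
print.dedup_result <- function(x, ...) {
  cat(
    "<dedup_result> method = ", x$method, ": kept ", length(x$kept_ids),
    " of ", x$n_input, " contigs\n",
    sep = ""
  )
  invisible(x)
}

#' Tidiers for deduplication results
#'
#' `tidy()` returns one row per input contig with its `kept` status (and, for
#' the annotated method, the gene the kept contig represents); `glance()`
#' returns one-row counts.
#'
#' @param x A `dedup_result`.
#' @param ... Unused.
#' @export
tidy.dedup_result <- function(x, ...) {
  out <- tibble(
    contig_id = c(x$kept_ids, x$removed_ids),
    kept = rep(c(TRUE, FALSE), c(length(x$kept_ids), length(x$removed_ids)))
  ) %>% arrange(.data$contig_id)
  if (!is.null(x$gene_to_contig)) {
    out <- out %>%
      left_join(
        x$gene_to_contig %>% select(.data$contig_id, .data$gene_id),
        by = "contig_id"
      )
  }
  out
}

#' @rdname tidy.dedup_result
#' @export
glance.dedup_result <- function(x, ...) {
  tibble(
    method = x$method,
    n_input = x$n_input,
    n_kept = length(x$kept_ids),
    n_removed = length(x$removed_ids),
    n_passthrough = x$n_passthrough
  )
}

#' Subset a contig table to the kept contigs of a deduplication
#'
#' @param contigs The contig tibble the result was computed from.
#' @param result A `dedup_result`.
#' @return The rows of `contigs` whose `contig_id` was kept.
#' @export
kept_contigs <- function(contigs, result) {
  contigs %>% filter(.data$contig_id %in% result$kept_ids)
}

# shared deterministic tie-break: primary criterion desc, then length desc,
# then contig_id asc
pick_first <- function(tbl, ...) {
  tbl %>%
    arrange(..., .by_group = TRUE) %>%
    slice(1)
}

#' Keep the longest contig of each assembler subcomponent
#'
#' The isoform-collapsing strategy: Trinity emits putative splice variants of
#' one locus under a shared subcomponent identifier, and only the longest
#' member of each subcomponent is retained.  Contigs whose identifiers match
#' no known assembler scheme form singleton subcomponents and are always kept.
#' Length ties are broken by lexicographically smaller contig identifier.
#' Note the documented failure mode of this strategy: when the assembler
#' splits one gene across several subcomponents, one contig per subcomponent
#' survives and the gene stays redundantly represented.
#'
#' @param contigs Contig tibble ([read_contig_fasta()]); `subcomponent_key` is
#'   recomputed from `contig_id` when absent.
#' @return A `dedup_result` with method `"longest_subcomponent"`.
#' @export
select_longest_per_subcomponent <- function(contigs) {
  stopifnot(nrow(contigs) == 0 || all(c("contig_id", "length") %in% names(contigs)))
  if (!"subcomponent_key" %in% names(contigs)) {
    contigs <- contigs %>% mutate(subcomponent_key = parse_trinity_id(.data$contig_id))
  }
  kept <- contigs %>%
    group_by(.data$subcomponent_key) %>%
    pick_first(dplyr::desc(.data$length), .data$contig_id) %>%
    ungroup() %>%
    pull("contig_id")
  new_dedup_result("longest_subcomponent", contigs, kept)
}

#' Keep one representative contig per cluster
#'
#' The clustering strategy: given externally computed cluster membership (e.g.
#' CD-HIT at 0.9 identity), each cluster contributes its marked representative
#' or, when no member is marked, its longest member (ties: smaller
#' identifier).  Contigs that belong to no cluster pass through unchanged and
#' are tallied in `n_passthrough`.
#'
#' @param contigs Contig tibble.
#' @param clusters Cluster tibble from [read_clstr()] or [greedy_cluster()].
#' @return A `dedup_result` with method `"cluster_representative"`.
#' @export
select_cluster_representatives <- function(contigs, clusters) {
  unknown <- setdiff(clusters$member_id, contigs$contig_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "cluster member(s) absent from contig set: ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  memb <- clusters %>%
    left_join(contigs %>% select("contig_id", "length"),
      by = c(member_id = "contig_id")
    )
  reps <- memb %>%
    group_by(.data$cluster) %>%
    pick_first(
      dplyr::desc(.data$is_representative), dplyr::desc(.data$length),
      .data$member_id
    ) %>%
    ungroup() %>%
    pull("member_id")
  outside <- setdiff(contigs$contig_id, clusters$member_id)
  new_dedup_result(
    "cluster_representative", contigs, c(reps, outside),
    n_passthrough = length(outside)
  )
}

#' Keep the highest-bit-score contig for each reference gene
#'
#' The homology-search strategy.  Every contig is first assigned its best-hit
#' gene ([best_hit_per_contig()]); then, for each gene, the assigned contig
#' with the highest bit score is kept as that gene's annotated contig (ties:
#' longer contig, then smaller identifier).  Contigs with no homology to any
#' gene are removed entirely, so the output contains neither redundant nor
#' erroneous contigs: re-classification of the kept set yields 100%
#' unique-hit contigs by construction.
#'
#' @param contigs Contig tibble.
#' @param hits HSP-level hit tibble ([read_blast_tab()]).
#' @return A `dedup_result` with method `"annotated_best_hit"` whose
#'   `gene_to_contig` element maps each covered gene to its single kept contig
#'   (columns `gene_id`, `contig_id`, `best_bitscore`).
#' @export
select_annotated <- function(contigs, hits) {
  assignments <- best_hit_per_contig(hits) %>%
    filter(.data$contig_id %in% contigs$contig_id) %>%
    left_join(contigs %>% select("contig_id", "length"), by = "contig_id")
  gene_to_contig <- assignments %>%
    group_by(.data$gene_id) %>%
    pick_first(
      dplyr::desc(.data$best_bitscore), dplyr::desc(.data$length),
      .data$contig_id
    ) %>%
    ungroup() %>%
    select("gene_id", "contig_id", "best_bitscore")
  new_dedup_result(
    "annotated_best_hit", contigs, gene_to_contig$contig_id,
    gene_to_contig = gene_to_contig
  )
}

#' Greedy length-ranked clustering by k-mer containment
#'
#' A desk-scale incremental clustering of contigs, mirroring the greedy scheme
#' of the standard external tool: contigs are visited in order of decreasing
#' length (ties: smaller identifier); each contig joins the first existing
#' cluster whose representative contains at least `identity_threshold` of the
#' shorter sequence's distinct k-mers, otherwise it founds a new cluster and
#' becomes its representative.  Identity is an exact k-mer containment
#' fraction (k = 16 by default), not a banded alignment, so results are not
#' claimed to equal any external tool's output.
#'
#' @param contigs Contig tibble with `sequence` present.
#' @param identity_threshold Containment fraction in (0, 1] required to join a
#'   cluster (default 0.9, the conventional nucleotide-level setting).
#' @param k K-mer size used for the containment computation.
#' @return A cluster tibble (`cluster`, `member_id`, `is_representative`)
#'   compatible with [select_cluster_representatives()] and [write_clstr()].
#' @export
greedy_cluster <- function(contigs, identity_threshold = 0.9, k = 16L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1, k >= 1)
  stopifnot(all(c("contig_id", "sequence", "length") %in% names(contigs)))
  ord <- contigs %>% arrange(dplyr::desc(.data$length), .data$contig_id)
  kmers <- lapply(ord$sequence, seq_kmers, k = k)
  rep_idx <- integer(0) # index into ord of each cluster representative
  assignment <- integer(nrow(ord))
  for (i in seq_len(nrow(ord))) {
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      frac <- kmer_containment(kmers[[i]], kmers[[rep_idx[ci]]])
      if (!is.na(frac) && frac >= identity_threshold) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assignment[i] <- length(rep_idx)
    }
  }
  tibble(
    cluster = assignment,
    member_id = ord$contig_id,
    is_representative = seq_len(nrow(ord)) %in% rep_idx
  ) %>% arrange(.data$cluster, dplyr::desc(.data$is_representative), .data$member_id)
}

seq_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) {
    return(character(0))
  }
  unique(substring(sequence, 1:(n - k + 1), k:n))
}

# fraction of the smaller k-mer set contained in the larger one; NA when the
# smaller sequence is shorter than k
kmer_containment <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    return(NA_real_)
  }
  if (length(a) <= length(b)) {
    mean(a %in% b)
  } else {
    mean(b %in% a)
  }
}
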