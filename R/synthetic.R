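#' @name synthetic
#' @title Synthetic redundant-assembly simulator
#' @description
#' The simulator emulates the generative process behind redundancy in de novo
#' transcriptome assemblies: each reference gene is reconstructed as one
#' near-full-length contig plus a variable number of partial fragments
#' (incomplete-read assembly), occasionally split across two assembler
#' subcomponents (the documented failure mode of longest-per-subcomponent
#' selection); a handful of erroneous contigs with no gene of origin emulates
#' mis-assembled sequence.  Homology hits, cluster files and two-condition
#' count data with planted fold changes are derived from the same truth so
#' every downstream module can be exercised with known answers.  All
#' randomness flows from one top-level seed through named substreams, so
#' every artefact is reproducible file-for-file.
NULL

# Deterministic substream: every stochastic operation draws from a seed derived
# from the top-level seed and the operation's name, so regenerating one
# artefact never perturbs another.
substream_seed <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 1000003
  as.integer((abs(seed) * 1009 + h) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

#' Generate a gold-standard reference gene set
#'
#' Random nucleotide sequences with lengths uniform on
#' `[min_len, max_len]`, playing the role of a curated transcript database.
#' Deterministic for a fixed seed.
#'
#' @param n_genes Number of genes (>= 1).
#' @param min_len,max_len Length bounds in bases.
#' @param seed Top-level simulation seed.
#' @return A tibble (`gene_id`, `sequence`, `length`) usable wherever a
#'   feature-length table is expected.
#' @export
generate_reference_genes <- function(n_genes = 100, min_len = 500,
                                     max_len = 3000, seed = 1) {
  stopifnot(n_genes >= 1, min_len >= 1, min_len <= max_len)
  with_substream(seed, "reference_genes", {
    lens <- as.integer(round(runif(n_genes, min_len, max_len)))
    tibble(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      sequence = vapply(lens, random_dna, character(1)),
      length = lens
    )
  })
}

mutate_sequence <- function(sequence, subst_rate) {
  if (subst_rate <= 0) {
    return(list(sequence = sequence, n_subst = 0L))
  }
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < subst_rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  list(sequence = paste(bases, collapse = ""), n_subst = length(hit))
}

#' Fragment reference genes into a redundant contig assembly
#'
#' Each gene yields `K >= 1` contigs (`K` shifted-Poisson with the given
#' mean): one designated near-full-length contig — the one a best-bit-score
#' selection should keep — plus partial fragments, all contiguous substrings
#' with point substitutions at `subst_rate`.  Contig identifiers follow the
#' assembler `comp<i>_c<j>_seq<k>` scheme with one component per gene; with
#' probability `split_prob` a gene's fragments are split across two
#' subcomponents, so that longest-per-subcomponent selection keeps more than
#' one contig for that gene.  `n_error_contigs` random sequences with no gene
#' of origin are appended.
#'
#' @param genes Reference gene tibble ([generate_reference_genes()]).
#' @param mean_frags_per_gene Mean contigs per gene (>= 1).
#' @param n_error_contigs Number of erroneous no-origin contigs.
#' @param subst_rate Per-base substitution probability in \[0, 0.2\].
#' @param split_prob Probability that a multi-contig gene is split across two
#'   subcomponents.
#' @param min_frag_len Minimum fragment length in bases (assembler
#'   minimum-contig-length; default 120).
#' @param seed Top-level simulation seed.
#' @return A list with `contigs` (contig tibble as from [read_contig_fasta()])
#'   and `truth` (tibble `contig_id`, `gene_id` — `NA` for error contigs —,
#'   `is_best`, `n_subst`).
#' @export
fragment_into_contigs <- function(genes, mean_frags_per_gene = 3,
                                  n_error_contigs = 10, subst_rate = 0.005,
                                  split_prob = 0.15, min_frag_len = 120,
                                  seed = 1) {
  stopifnot(
    mean_frags_per_gene >= 1, subst_rate >= 0, subst_rate <= 0.2,
    n_error_contigs >= 0, split_prob >= 0, split_prob <= 1
  )
  with_substream(seed, "fragment_contigs", {
    rows <- vector("list", nrow(genes) + 1L)
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      k <- 1L + rpois(1, mean_frags_per_gene - 1)
      # fragment lengths: index 1 is the designated near-full-length contig
      fracs <- c(runif(1, 0.9, 1.0), if (k > 1) runif(k - 1, 0.2, 0.7))
      lens <- pmin(g$length, pmax(min_frag_len, as.integer(round(fracs * g$length))))
      starts <- vapply(lens, function(l) sample.int(g$length - l + 1L, 1), integer(1))
      split <- k > 1 && runif(1) < split_prob
      sub_idx <- if (split) {
        c(0L, sample(0:1, k - 1, replace = TRUE))
      } else {
        rep(0L, k)
      }
      seq_no <- stats::ave(sub_idx, sub_idx, FUN = seq_along)
      frag <- lapply(seq_len(k), function(j) {
        raw <- substr(g$sequence, starts[j], starts[j] + lens[j] - 1L)
        mutate_sequence(raw, subst_rate)
      })
      rows[[gi]] <- tibble(
        contig_id = sprintf("comp%d_c%d_seq%d", gi - 1L, sub_idx, seq_no),
        sequence = vapply(frag, `[[`, character(1), "sequence"),
        length = lens,
        gene_id = g$gene_id,
        is_best = seq_len(k) == 1L,
        n_subst = vapply(frag, `[[`, integer(1), "n_subst")
      )
    }
    if (n_error_contigs > 0) {
      elens <- as.integer(round(runif(n_error_contigs, min_frag_len, 1000)))
      rows[[nrow(genes) + 1L]] <- tibble(
        contig_id = sprintf("comp%d_c0_seq1", nrow(genes) + seq_len(n_error_contigs) - 1L),
        sequence = vapply(elens, random_dna, character(1)),
        length = elens,
        gene_id = NA_character_,
        is_best = FALSE,
        n_subst = 0L
      )
    }
    all <- bind_rows(rows)
    contigs <- all %>%
      select("contig_id", "sequence", "length") %>%
      mutate(subcomponent_key = parse_trinity_id(.data$contig_id))
    list(
      contigs = contigs,
      truth = all %>% select("contig_id", "gene_id", "is_best", "n_subst")
    )
  })
}

#' Simulate homology hits for a synthetic assembly
#'
#' Every contig with a gene of origin receives one HSP row against that gene
#' with bit score `2 * matched bases` — a surrogate that preserves the only
#' property downstream selection uses, monotonicity in alignment quality, so
#' the near-full-length contig scores highest for its gene.  Error contigs
#' receive no rows.  With probability `cross_hit_prob` a contig also gets a
#' weaker secondary hit to a random other gene, exercising best-hit
#' tie-breaking.
#'
#' @param contigs,genes,truth Simulation pieces from
#'   [fragment_into_contigs()] / [generate_reference_genes()].
#' @param cross_hit_prob Probability of a spurious secondary hit per contig.
#' @param seed Top-level simulation seed.
#' @return A hit tibble in the 12-column layout of [read_blast_tab()].
#' @export
simulate_blast_hits <- function(contigs, genes, truth, cross_hit_prob = 0.05,
                                seed = 1) {
  stopifnot(all(truth$contig_id %in% contigs$contig_id))
  with_substream(seed, "blast_hits", {
    origin <- truth %>%
      filter(!is.na(.data$gene_id)) %>%
      left_join(contigs %>% select("contig_id", "length"), by = "contig_id")
    primary <- origin %>%
      mutate(
        aln_length = .data$length,
        mismatches = .data$n_subst,
        bitscore = 2 * (.data$aln_length - .data$mismatches),
        pct_identity = round(100 * (1 - .data$mismatches / .data$aln_length), 2),
        evalue = pmax(1e-300, 10^(-.data$bitscore / 4))
      )
    cross <- primary %>%
      filter(runif(n()) < cross_hit_prob) %>%
      mutate(
        gene_id = purrr::map_chr(
          .data$gene_id,
          function(g) sample(setdiff(genes$gene_id, g), 1)
        ),
        aln_length = pmax(32L, as.integer(round(.data$aln_length * 0.3))),
        mismatches = 0L,
        bitscore = round(.data$bitscore * 0.3),
        pct_identity = 90,
        evalue = pmax(1e-300, 10^(-.data$bitscore / 4))
      )
    bind_rows(primary, cross) %>%
      mutate(
        query_id = .data$contig_id,
        subject_id = .data$gene_id,
        gap_opens = 0L,
        q_start = 1L,
        q_end = .data$aln_length,
        s_start = 1L,
        s_end = .data$aln_length
      ) %>%
      select(dplyr::all_of(blast_outfmt6_cols)) %>%
      arrange(.data$query_id, dplyr::desc(.data$bitscore))
  })
}

#' Simulate two-condition count data with planted fold changes
#'
#' Per-gene base expression is drawn log-uniform; condition B multiplies the
#' expression of `n_deg` planted differential genes by `fc` (half up, half
#' down).  Counts are Poisson around `expression x length(kb) x depth`, for
#' genes and for contigs (a contig inherits its gene's expression, scaled by
#' its own length, so fragments receive proportionally fewer reads).  Error
#' contigs carry their own background expression, and half of them are
#' planted with the same fold change — false-positive differential contigs
#' that no gold-standard gene can explain, emulating erroneous contigs being
#' mistaken for differentially expressed genes.
#'
#' @param genes Reference gene tibble.
#' @param contigs,truth Assembly pieces from [fragment_into_contigs()].
#' @param n_deg Number of planted differential genes.
#' @param fc True fold change applied to planted genes (> 1).
#' @param depth Sequencing depth scale (expected reads per kilobase per unit
#'   expression).
#' @param seed Top-level simulation seed.
#' @return A list with `count_table` objects `gene_counts_a/b` and
#'   `contig_counts_a/b`, the planted `deg_ids`, and `expr_truth` (tibble
#'   `gene_id`, `base_expression`, `direction` in {up, down, none}).
#' @export
simulate_counts <- function(genes, contigs, truth, n_deg = 20, fc = 4,
                            depth = 3, seed = 1) {
  stopifnot(n_deg <= nrow(genes), fc >= 1, depth > 0)
  with_substream(seed, "counts", {
    n <- nrow(genes)
    base <- 10^runif(n, log10(3), log10(300))
    deg_ids <- sort(sample(genes$gene_id, n_deg))
    direction <- rep("none", n)
    names(direction) <- genes$gene_id
    up <- deg_ids[seq_len(ceiling(n_deg / 2))]
    down <- setdiff(deg_ids, up)
    direction[up] <- "up"
    direction[down] <- "down"
    mult_b <- unname(c(none = 1, up = fc, down = 1 / fc)[direction])
    gene_expr_a <- setNames(base, genes$gene_id)
    gene_expr_b <- gene_expr_a * mult_b

    draw <- function(expr, lengths) {
      as.integer(rpois(length(expr), expr * (lengths / 1000) * depth))
    }
    gene_a <- tibble(
      feature_id = genes$gene_id,
      count = draw(gene_expr_a, genes$length)
    )
    gene_b <- tibble(
      feature_id = genes$gene_id,
      count = draw(gene_expr_b, genes$length)
    )

    # error contigs: own background expression; alternate ones are planted
    # false-positive differential contigs (fold change with no DEG behind it)
    err <- truth %>% filter(is.na(.data$gene_id))
    err_base <- 10^runif(nrow(err), log10(3), log10(100))
    err_mult <- rep_len(c(fc, 1), nrow(err))
    contig_tbl <- contigs %>%
      left_join(truth, by = "contig_id") %>%
      mutate(
        expr_a = ifelse(
          is.na(.data$gene_id),
          err_base[match(.data$contig_id, err$contig_id)],
          gene_expr_a[.data$gene_id]
        ),
        expr_b = ifelse(
          is.na(.data$gene_id),
          (err_base * err_mult)[match(.data$contig_id, err$contig_id)],
          gene_expr_b[.data$gene_id]
        )
      )
    contig_a <- tibble(
      feature_id = contig_tbl$contig_id,
      count = draw(contig_tbl$expr_a, contig_tbl$length)
    )
    contig_b <- tibble(
      feature_id = contig_tbl$contig_id,
      count = draw(contig_tbl$expr_b, contig_tbl$length)
    )
    # The simulated features are modelled as a measured subset of a larger
    # sequencing library whose remainder is non-differential, so both
    # conditions share one fixed library size (10x the expected condition-A
    # feature mass).  Without this, planting strong fold changes into a
    # 100-gene transcriptome shifts the per-library total itself and the
    # RPKM normalisation mis-scales every null feature - a composition
    # artefact of desk scale, not of the method.
    lib_gene <- round(10 * sum(gene_expr_a * genes$length / 1000 * depth))
    lib_contig <- round(10 * sum(contig_tbl$expr_a * contig_tbl$length / 1000 * depth))
    list(
      gene_counts_a = count_table(gene_a, total_mapped = lib_gene),
      gene_counts_b = count_table(gene_b, total_mapped = lib_gene),
      contig_counts_a = count_table(contig_a, total_mapped = lib_contig),
      contig_counts_b = count_table(contig_b, total_mapped = lib_contig),
      deg_ids = deg_ids,
      expr_truth = tibble(
        gene_id = genes$gene_id,
        base_expression = base,
        direction = unname(direction)
      )
    )
  })
}

#' Simulate a random gene-to-GO-slim annotation map
#'
#' Assigns each gene a small random set of terms from a fixed-size term
#' universe (set size 1 + Poisson).  Slim-style universes are small by
#' design, which keeps per-term counts large enough for distribution-level
#' comparison.
#'
#' @param gene_ids Genes to annotate.
#' @param n_terms Size of the term universe.
#' @param mean_terms_per_gene Mean number of terms per gene (>= 1).
#' @param seed Top-level simulation seed.
#' @return Annotation tibble (`gene_id`, `term`).
#' @export
simulate_go_annotations <- function(gene_ids, n_terms = 20,
                                    mean_terms_per_gene = 2, seed = 1) {
  stopifnot(n_terms >= 1, mean_terms_per_gene >= 1)
  with_substream(seed, "go_annotations", {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    purrr::map(gene_ids, function(g) {
      k <- min(n_terms, 1 + rpois(1, mean_terms_per_gene - 1))
      tibble(gene_id = g, term = sample(terms, k))
    }) %>%
      bind_rows() %>%
      arrange(.data$gene_id, .data$term)
  })
}

#' Simulate a complete synthetic study
#'
#' One call producing every input the evaluation workflow needs: reference
#' genes, a redundant contig assembly with truth, homology hits, a greedy
#' clustering of the contigs, two-condition counts for genes and contigs, and
#' a GO annotation map.  The defaults are the package's standard study
#' conditions: 100 genes of 0.5-3 kb, 3 contigs per gene on average, 10
#' erroneous contigs, 0.5% substitution noise, 20 planted differential genes
#' at 4-fold change, and moderate (depth 3) coverage under which partial
#' fragments are noisy enough to produce false differential calls — the
#' regime redundancy removal is meant to fix.
#'
#' @param seed Top-level seed; every artefact is a deterministic function of
#'   it.
#' @param n_genes,min_gene_len,max_gene_len Reference gene set shape.
#' @param mean_frags_per_gene,n_error_contigs,subst_rate,split_prob Assembly
#'   redundancy model (see [fragment_into_contigs()]).
#' @param cross_hit_prob Spurious secondary homology hit probability.
#' @param n_deg,fc,depth Expression model (see [simulate_counts()]).
#' @param n_go_terms GO slim term universe size.
#' @param cluster_identity Identity threshold for the greedy clustering.
#' @param cluster Set `FALSE` to skip the (comparatively slow) clustering
#'   step when only homology-based paths are needed.
#' @return A list: `genes`, `contigs`, `truth`, `hits`, `clusters` (or
#'   `NULL`), `counts` (list from [simulate_counts()]), `go_map`, `deg_ids`,
#'   `seed`.
#' @export
simulate_assembly <- function(seed = 1, n_genes = 100, min_gene_len = 500,
                              max_gene_len = 3000, mean_frags_per_gene = 3,
                              n_error_contigs = 10, subst_rate = 0.005,
                              split_prob = 0.15, cross_hit_prob = 0.05,
                              n_deg = 20, fc = 4, depth = 3, n_go_terms = 50,
                              cluster_identity = 0.9, cluster = TRUE) {
  genes <- generate_reference_genes(n_genes, min_gene_len, max_gene_len, seed)
  frag <- fragment_into_contigs(
    genes, mean_frags_per_gene, n_error_contigs, subst_rate, split_prob,
    seed = seed
  )
  hits <- simulate_blast_hits(frag$contigs, genes, frag$truth, cross_hit_prob, seed)
  counts <- simulate_counts(genes, frag$contigs, frag$truth, n_deg, fc, depth, seed)
  go_map <- simulate_go_annotations(genes$gene_id, n_go_terms, seed = seed)
  clusters <- if (cluster) greedy_cluster(frag$contigs, cluster_identity) else NULL
  list(
    genes = genes,
    contigs = frag$contigs,
    truth = frag$truth,
    hits = hits,
    clusters = clusters,
    counts = counts,
    go_map = go_map,
    deg_ids = counts$deg_ids,
    seed = seed
  )
}

#' Write every artefact of a simulated study to a directory
#'
#' Emits `genes.fasta`, `contigs.fasta`, `hits.outfmt6`, `clusters.clstr`
#' (when present), four count TSVs, `go_annotations.tsv` and `truth.tsv`, all
#' plain text, reproducible file-for-file for a fixed seed.
#'
#' @param sim Output of [simulate_assembly()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_contig_fasta(
    sim$genes %>% rename(contig_id = "gene_id"), p("genes.fasta")
  )
  write_contig_fasta(sim$contigs, p("contigs.fasta"))
  write_blast_tab(sim$hits, p("hits.outfmt6"))
  if (!is.null(sim$clusters)) {
    write_clstr(sim$clusters, p("clusters.clstr"), sim$contigs)
  }
  wc <- function(ct, f) {
    readr::write_tsv(ct$counts, p(f), col_names = FALSE)
  }
  wc(sim$counts$gene_counts_a, "gene_counts_a.tsv")
  wc(sim$counts$gene_counts_b, "gene_counts_b.tsv")
  wc(sim$counts$contig_counts_a, "contig_counts_a.tsv")
  wc(sim$counts$contig_counts_b, "contig_counts_b.tsv")
  readr::write_tsv(sim$go_map, p("go_annotations.tsv"), col_names = FALSE)
  readr::write_tsv(sim$truth, p("truth.tsv"))
  readr::write_lines(sim$deg_ids, p("planted_deg_ids.txt"))
  invisible(outdir)
}
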