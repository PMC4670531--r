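test_that("longest-per-subcomponent keeps the longest isoform of each group", {
  contigs <- make_contigs(
    c("comp0_c0_seq1", "comp0_c0_seq2", "comp1_c0_seq1"),
    c(300, 500, 200)
  )
  res <- select_longest_per_subcomponent(contigs)
  expect_setequal(res$kept_ids, c("comp0_c0_seq2", "comp1_c0_seq1"))
  expect_setequal(res$removed_ids, "comp0_c0_seq1")
})

test_that("longest-per-subcomponent length ties keep the smaller identifier", {
  # both orderings of the tied pair give the same answer
  for (ids in list(
    c("comp0_c0_seq1", "comp0_c0_seq2"),
    c("comp0_c0_seq2", "comp0_c0_seq1")
  )) {
    contigs <- make_contigs(ids, c(400, 400))
    res <- select_longest_per_subcomponent(contigs)
    expect_equal(res$kept_ids, "comp0_c0_seq1")
  }
})

test_that("cluster-representative selection honours the starred member", {
  contigs <- make_contigs(c("a", "b"), c(800, 200))
  clusters <- tibble::tibble(
    cluster = c(1L, 1L), member_id = c("a", "b"),
    is_representative = c(TRUE, FALSE)
  )
  res <- select_cluster_representatives(contigs, clusters)
  expect_equal(res$kept_ids, "a")
})

test_that("cluster selection keeps one contig per cluster plus pass-throughs", {
  contigs <- make_contigs(letters[1:8], c(100, 90, 80, 70, 60, 50, 40, 999))
  clusters <- tibble::tibble(
    cluster = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
    member_id = letters[1:7],
    is_representative = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  res <- select_cluster_representatives(contigs, clusters)
  expect_setequal(res$kept_ids, c("a", "d", "f", "h")) # 3 reps + pass-through h
  expect_equal(res$n_passthrough, 1L)
  expect_equal(glance(res)$n_kept, 4)
})

test_that("clusters without a starred member fall back to the longest contig", {
  contigs <- make_contigs(c("x", "y", "z"), c(100, 300, 300))
  clusters <- tibble::tibble(
    cluster = c(1L, 1L, 1L), member_id = c("x", "y", "z"),
    is_representative = FALSE
  )
  # longest wins; the y/z length tie resolves to the smaller identifier
  expect_equal(select_cluster_representatives(contigs, clusters)$kept_ids, "y")
})

test_that("unknown cluster members are a hard error", {
  contigs <- make_contigs("a", 100)
  clusters <- tibble::tibble(
    cluster = 1L, member_id = "ghost", is_representative = TRUE
  )
  expect_error(select_cluster_representatives(contigs, clusters), "ghost")
})

test_that("annotated selection keeps the top-scoring contig per gene and drops no-hits", {
  contigs <- make_contigs(c("c1", "c2", "c3", "c4"), c(500, 400, 300, 200))
  hits <- make_hits(
    c("c1", "c2", "c3"), c("g1", "g1", "g2"), c(900, 400, 500)
  )
  res <- select_annotated(contigs, hits)
  expect_setequal(res$kept_ids, c("c1", "c3"))
  expect_setequal(res$removed_ids, c("c2", "c4"))
  # gene map is a bijection between kept contigs and covered genes
  expect_equal(sort(res$gene_to_contig$gene_id), c("g1", "g2"))
  expect_setequal(res$gene_to_contig$contig_id, res$kept_ids)
})

test_that("annotated selection with all-distinct genes removes only no-hit contigs", {
  contigs <- make_contigs(c("c1", "c2", "c3"), c(100, 100, 100))
  hits <- make_hits(c("c1", "c2"), c("g1", "g2"), c(100, 200))
  res <- select_annotated(contigs, hits)
  expect_setequal(res$kept_ids, c("c1", "c2"))
})

test_that("re-classifying the annotated set yields only unique hits", {
  withr::with_seed(5, {
    sim <- simulate_assembly(seed = 5, cluster = FALSE)
  })
  res <- select_annotated(sim$contigs, sim$hits)
  kept <- kept_contigs(sim$contigs, res)
  asg <- best_hit_per_contig(
    dplyr::filter(sim$hits, query_id %in% kept$contig_id)
  )
  g <- glance(classify_contigs(kept, asg))
  expect_equal(g$n_multiple_hit, 0)
  expect_equal(g$n_no_hit, 0)
  expect_equal(g$n_unique_hit, nrow(kept))
  # one kept contig per gene with at least one assigned contig
  all_asg <- best_hit_per_contig(sim$hits)
  expect_equal(length(res$kept_ids), dplyr::n_distinct(all_asg$gene_id))
})

test_that("greedy clustering merges identical sequences and separates disjoint ones", {
  s <- paste(rep("ACGT", 30), collapse = "")
  same <- make_contigs(c("a", "b"), seqs = c(s, s))
  cl <- greedy_cluster(same, 0.9)
  expect_equal(dplyr::n_distinct(cl$cluster), 1)

  withr::with_seed(1, {
    disjoint <- make_contigs(c("a", "b"), c(200, 200))
  })
  cl2 <- greedy_cluster(disjoint, 0.9)
  expect_equal(dplyr::n_distinct(cl2$cluster), 2)
  expect_true(all(cl2$is_representative))
})

test_that("an exact substring joins its source cluster at high identity", {
  withr::with_seed(3, {
    rep400 <- make_contigs("rep", 400)
  })
  sub200 <- tibble::tibble(
    contig_id = "sub",
    sequence = substr(rep400$sequence, 101, 300),
    length = 200L,
    subcomponent_key = "sub"
  )
  contigs <- dplyr::bind_rows(rep400, sub200)
  cl <- greedy_cluster(contigs, 0.9)
  expect_equal(dplyr::n_distinct(cl$cluster), 1)
  expect_true(cl$is_representative[cl$member_id == "rep"])

  # brute-force containment oracle: fraction of the shorter sequence's
  # distinct 16-mers present in the representative
  kmers <- function(s) {
    unique(vapply(1:(nchar(s) - 15), function(i) substr(s, i, i + 15), character(1)))
  }
  frac <- mean(kmers(sub200$sequence) %in% kmers(rep400$sequence))
  expect_equal(frac, 1)
  expect_gte(frac, 0.9)
})

test_that("every dedup method is idempotent and never grows the set", {
  withr::with_seed(2, {
    sim <- simulate_assembly(seed = 2, n_genes = 30, cluster = TRUE)
  })
  apply_method <- function(contigs, method) {
    switch(method,
      longest = select_longest_per_subcomponent(contigs),
      clustered = select_cluster_representatives(
        contigs, greedy_cluster(contigs, 0.9)
      ),
      annotated = select_annotated(
        contigs, dplyr::filter(sim$hits, query_id %in% contigs$contig_id)
      )
    )
  }
  for (method in c("longest", "clustered", "annotated")) {
    first <- apply_method(sim$contigs, method)
    expect_lte(length(first$kept_ids), nrow(sim$contigs))
    kept1 <- kept_contigs(sim$contigs, first)
    second <- apply_method(kept1, method)
    expect_identical(sort(second$kept_ids), sort(first$kept_ids))
    expect_equal(length(second$removed_ids), 0)
  }
})

test_that("kept and removed sets partition the input for every method", {
  withr::with_seed(9, {
    sim <- simulate_assembly(seed = 9, n_genes = 20, cluster = FALSE)
  })
  for (res in list(
    select_longest_per_subcomponent(sim$contigs),
    select_annotated(sim$contigs, sim$hits)
  )) {
    expect_setequal(c(res$kept_ids, res$removed_ids), sim$contigs$contig_id)
    expect_length(intersect(res$kept_ids, res$removed_ids), 0)
  }
})
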