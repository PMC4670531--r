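test_that("FASTA reading takes the first header token as the identifier", {
  fa <- write_tmp_lines(c(">c1 desc words", "AC"), ".fasta")
  tbl <- read_contig_fasta(fa)
  expect_equal(tbl$contig_id, "c1")
  expect_equal(tbl$sequence, "AC")
  expect_equal(tbl$length, 2L)
})

test_that("FASTA reading preserves record order and exact lengths", {
  seqs <- c(
    paste(rep("A", 120), collapse = ""),
    paste(rep("ACGT", 750), collapse = "")
  )
  fa <- write_tmp_lines(c(">short", seqs[1], ">long", seqs[2]), ".fasta")
  tbl <- read_contig_fasta(fa)
  expect_equal(tbl$contig_id, c("short", "long"))
  expect_equal(tbl$length, c(120L, 3000L))
})

test_that("FASTA reading rejects duplicate identifiers and empty sequences", {
  dup <- write_tmp_lines(c(">c1", "ACGT", ">c1 other", "GG"), ".fasta")
  expect_error(read_contig_fasta(dup), "c1")
  empty <- write_tmp_lines(c(">c1", "ACGT", ">c2", ""), ".fasta")
  expect_error(read_contig_fasta(empty), "empty sequence")
})

test_that("FASTA writing round-trips identifiers and sequence content", {
  withr::with_seed(7, {
    contigs <- make_contigs(c("comp0_c0_seq1", "x", "TRINITY_DN3_c0_g1_i2"), c(150, 40, 90))
  })
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_contig_fasta(contigs, fa)
  back <- read_contig_fasta(fa)
  expect_equal(back$contig_id, contigs$contig_id)
  expect_equal(back$sequence, contigs$sequence)
})

test_that("assembler identifiers map to subcomponent keys in both dialects", {
  expect_equal(parse_trinity_id("comp0_c0_seq1"), "comp0_c0")
  expect_equal(parse_trinity_id("comp0_c0_seq2"), "comp0_c0")
  expect_equal(parse_trinity_id("TRINITY_DN5_c1_g2_i3"), "TRINITY_DN5_c1_g2")
  expect_equal(parse_trinity_id("weird_id"), "weird_id")
  # isoforms of a subcomponent share one key
  expect_length(unique(parse_trinity_id(c("comp9_c2_seq1", "comp9_c2_seq7"))), 1)
})

test_that("BLAST tabular parsing maps the 12 outfmt6 columns faithfully", {
  f <- write_tmp_lines("c1\tg1\t98.0\t500\t10\t0\t1\t500\t1\t500\t1e-100\t900")
  hits <- read_blast_tab(f)
  expect_equal(hits$query_id, "c1")
  expect_equal(hits$subject_id, "g1")
  expect_equal(hits$pct_identity, 98)
  expect_equal(hits$aln_length, 500L)
  expect_equal(hits$q_start, 1L)
  expect_equal(hits$evalue, 1e-100)
  expect_equal(hits$bitscore, 900)
})

test_that("BLAST parsing keeps every HSP row and handles empty input", {
  f <- write_tmp_lines(c(
    "c1\tg1\t98.0\t500\t10\t0\t1\t500\t1\t500\t1e-100\t900",
    "c1\tg1\t90.0\t200\t20\t0\t1\t200\t1\t200\t1e-10\t300"
  ))
  expect_equal(nrow(read_blast_tab(f)), 2) # HSP aggregation is deferred
  empty <- write_tmp_lines(character(0))
  expect_equal(nrow(read_blast_tab(empty)), 0)
})

test_that("BLAST parsing reports malformed lines with their line number", {
  f <- write_tmp_lines(c(
    "c1\tg1\t98.0\t500\t10\t0\t1\t500\t1\t500\t1e-100\t900",
    "c2\tg1\tbroken"
  ))
  expect_error(read_blast_tab(f), "line 2")
  g <- write_tmp_lines("c1\tg1\t98.0\t500\t10\t0\t1\t500\t1\t500\t1e-100\tNOTANUMBER")
  expect_error(read_blast_tab(g), "bit score")
})

test_that("BLAST parsing preserves line count on well-formed files", {
  withr::with_seed(11, {
    n <- 57
    hits <- make_hits(
      sprintf("c%d", sample(20, n, TRUE)),
      sprintf("g%d", sample(10, n, TRUE)),
      runif(n, 50, 900)
    )
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(hits, f)
  expect_equal(nrow(read_blast_tab(f)), n)
})

test_that(".clstr parsing identifies members and starred representatives", {
  f <- write_tmp_lines(c(
    ">Cluster 0",
    "0\t800nt, >a... *",
    "1\t200nt, >b... at +/98.5%"
  ), ".clstr")
  cl <- read_clstr(f)
  expect_equal(cl$member_id, c("a", "b"))
  expect_equal(cl$is_representative, c(TRUE, FALSE))
  expect_equal(cl$cluster, c(1L, 1L))
})

test_that(".clstr parsing handles singletons, missing stars and bad layout", {
  f <- write_tmp_lines(c(
    ">Cluster 0", "0\t100nt, >a... *",
    ">Cluster 1", "0\t90nt, >b... *"
  ), ".clstr")
  cl <- read_clstr(f)
  expect_equal(dplyr::n_distinct(cl$cluster), 2)
  expect_true(all(cl$is_representative))

  nostar <- write_tmp_lines(c(
    ">Cluster 0", "0\t100nt, >a... at +/99%", "1\t90nt, >b... at +/98%"
  ), ".clstr")
  expect_false(any(read_clstr(nostar)$is_representative))

  bad <- write_tmp_lines(c("0\t100nt, >a... *", ">Cluster 0"), ".clstr")
  expect_error(read_clstr(bad), "line 1")
})

test_that("TSV count tables read counts and default the library size to their sum", {
  f <- write_tmp_lines(c("g1\t10", "g2\t0"))
  ct <- read_counts(f)
  expect_equal(tidy(ct)$count, c(10L, 0L))
  expect_equal(ct$total_mapped, 10)
  # explicit override for a library larger than the listed features
  ct2 <- read_counts(f, total_mapped = 500)
  expect_equal(ct2$total_mapped, 500)
  # requested features absent from the table get zero
  ct3 <- read_counts(f, feature_ids = c("g1", "g2", "g3"))
  expect_equal(tidy(ct3)$count, c(10L, 0L, 0L))
})

test_that("SAM counting keeps mapped primary records and excludes the rest", {
  sam <- write_tmp_lines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:g1\tLN:1000",
    "@SQ\tSN:g2\tLN:500",
    "r1\t0\tg1\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r2\t0\tg1\t100\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r3\t16\tg1\t200\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*"
  ), ".sam")
  ct <- read_counts(sam, feature_ids = c("g1", "g2"))
  expect_equal(tidy(ct)$count[tidy(ct)$feature_id == "g1"], 3L)
  expect_equal(ct$total_mapped, 3)
})

test_that("SAM counting excludes secondary and supplementary alignments", {
  sam <- write_tmp_lines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:g1\tLN:1000",
    "r1\t0\tg1\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r1\t256\tg1\t500\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r2\t2048\tg1\t700\t60\t10M\t*\t0\t0\tACGTACGTAC\t*"
  ), ".sam")
  ct <- read_counts(sam, feature_ids = "g1")
  expect_equal(tidy(ct)$count, 1L)
  expect_equal(ct$total_mapped, 1)
})

test_that("SAM records on unknown references count toward the library size only", {
  sam <- write_tmp_lines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:g1\tLN:1000",
    "@SQ\tSN:gX\tLN:1000",
    "r1\t0\tg1\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r2\t0\tgX\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*"
  ), ".sam")
  expect_warning(ct <- read_counts(sam, feature_ids = "g1"), "outside")
  expect_equal(sum(tidy(ct)$count), 1L)
  expect_equal(ct$total_mapped, 2)
  expect_equal(ct$n_unknown_reference, 1L)
  # per-feature counts never exceed the library size
  expect_lte(sum(tidy(ct)$count), ct$total_mapped)
})

test_that("GO annotation reading de-duplicates pairs and validates lines", {
  f <- write_tmp_lines(c("g1\tGO:0008150", "g1\tGO:0008150"))
  expect_equal(nrow(read_go_annotations(f)), 1)

  f2 <- write_tmp_lines(c("g1\tT1", "g2\tT1", "g2\tT2"))
  tbl <- read_go_annotations(f2)
  expect_equal(nrow(tbl), 3)
  expect_setequal(tbl$term[tbl$gene_id == "g2"], c("T1", "T2"))

  empty <- write_tmp_lines(character(0))
  expect_equal(nrow(read_go_annotations(empty)), 0)

  bad <- write_tmp_lines(c("g1\tT1", "justonefield"))
  expect_error(read_go_annotations(bad), "line 2")
})
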