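# In-code fixtures shared across test files.

make_contigs <- function(ids, lengths, seqs = NULL) {
  if (is.null(seqs)) {
    seqs <- vapply(
      lengths,
      function(l) paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1)
    )
  }
  tibble::tibble(
    contig_id = ids,
    sequence = seqs,
    length = as.integer(nchar(seqs)),
    subcomponent_key = parse_trinity_id(ids)
  )
}

make_hits <- function(query, subject, bitscore, evalue = NULL) {
  n <- length(query)
  tibble::tibble(
    query_id = query,
    subject_id = subject,
    pct_identity = rep(98, n),
    aln_length = rep(100L, n),
    mismatches = rep(2L, n),
    gap_opens = rep(0L, n),
    q_start = rep(1L, n),
    q_end = rep(100L, n),
    s_start = rep(1L, n),
    s_end = rep(100L, n),
    evalue = evalue %||% rep(1e-50, n),
    bitscore = as.double(bitscore)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

subset_count_table <- function(ct, ids) {
  count_table(
    ct$counts[ct$counts$feature_id %in% ids, ],
    total_mapped = ct$total_mapped
  )
}

# Independent brute-force two-sided Fisher p for a 2x2 table, by enumerating
# the hypergeometric support with explicit binomial coefficients.
fisher_p_bruteforce <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  cs <- a + c
  n <- r1 + r2
  ks <- max(0, cs - r2):min(r1, cs)
  probs <- choose(r1, ks) * choose(r2, cs - ks) / choose(n, cs)
  p_obs <- choose(r1, a) * choose(r2, c) / choose(n, cs)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
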