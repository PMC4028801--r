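test_that("six-frame translation uses the bacterial code and drops partial codons", {
  fr <- six_frame_translate("ATGGCT")
  expect_equal(fr$protein[fr$strand == "+" & fr$frame == 0], "MA")
  # reverse frames equal forward frames of the reverse complement
  set.seed(21)
  for (i in 1:10) {
    d <- random_dna_str(sample(30:300, 1))
    a <- six_frame_translate(d)
    b <- six_frame_translate(revcomp(d))
    expect_equal(a$protein[a$strand == "-"], b$protein[b$strand == "+"])
  }
})

test_that("six frames jointly cover the sequence except short frame ends", {
  set.seed(22)
  d <- random_dna_str(300)
  fr <- six_frame_translate(d)
  # counting oracle: a frame f covers nucleotides f .. f + 3*len - 1
  for (i in 1:6) {
    len <- nchar(fr$protein[i])
    uncovered <- 300 - fr$frame[i] - 3 * len
    expect_lte(uncovered, 2)
  }
})

test_that("local alignment matches the explicit 3-matrix DP oracle", {
  s <- test_scheme()
  set.seed(23)
  # identical sequences: score is the diagonal sum, no gaps
  p <- random_aa(30)
  al <- local_align(p, p, s)
  expect_equal(al$score,
               sum(diag(s$submat[strsplit(p, "")[[1]], strsplit(p, "")[[1]]])))
  expect_false(any(al$pairs == 0))
  for (i in 1:100) {
    q <- random_aa(sample(5:30, 1))
    sub <- random_aa(sample(5:30, 1))
    expect_equal(local_align(q, sub, s)$score,
                 oracle_sw_score(q, sub, s$submat),
                 info = paste("case", i))
  }
})

test_that("alignment score is symmetric for a symmetric matrix", {
  s <- test_scheme()
  set.seed(24)
  for (i in 1:20) {
    q <- random_aa(sample(5:40, 1)); sub <- random_aa(sample(5:40, 1))
    expect_equal(local_align(q, sub, s)$score, local_align(sub, q, s)$score)
  }
})

test_that("translated search finds a planted ORF with a tiny E-value", {
  s <- test_scheme()
  set.seed(25)
  prot <- paste0("M", random_aa(299))
  dna <- encode_orf_dna(prot, lflank = 400, rflank = 400)
  hs <- translated_search(prot, dna, s)
  expect_gte(nrow(hs), 1)
  expect_lte(hs$evalue[1], 1e-20)
  expect_equal(hs$strand[1], "+")
  # reported interval covers the ORF (0-based: starts at 400)
  expect_lte(hs$s_start[1], 403)
  expect_gte(hs$s_end[1], 400 + 3 * 297)
  # same protein planted on the minus strand
  hs2 <- translated_search(prot, revcomp(dna), s)
  expect_equal(hs2$strand[1], "-")
  L <- nchar(dna)
  expect_equal(L - hs2$s_end[1], hs$s_start[1])
  expect_equal(L - hs2$s_start[1], hs$s_end[1])
})

test_that("shuffled queries almost never reach the search cutoff", {
  s <- test_scheme()
  set.seed(26)
  prot <- paste0("M", random_aa(249))
  dna <- encode_orf_dna(prot, lflank = 200, rflank = 200)
  hits <- 0L
  for (i in 1:100) {
    shuf <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
    if (nrow(translated_search(shuf, dna, s)) > 0) hits <- hits + 1L
  }
  expect_lte(hits, 5)
})

test_that("E-value is strictly decreasing in the raw score", {
  s <- test_scheme()
  ev <- hsp_evalue(seq(20, 200, by = 5), 100, 1000, s)
  expect_true(all(diff(ev) < 0))
  expect_true(all(ev >= 0))
})

test_that("Karlin-Altschul calibration roughly matches shuffled background", {
  s <- test_scheme()
  set.seed(27)
  # natural residue composition (the stated lambda/K are defined for it)
  bf <- get(".JTT", envir = getNamespace("phangorn"))$bf
  bf <- bf / sum(bf)
  natural_aa <- function(n) paste(sample(toupper(names(bf)), n,
                                         replace = TRUE, prob = bf),
                                  collapse = "")
  q <- natural_aa(100)
  subject <- natural_aa(300)
  n <- 200
  raws <- numeric(n)
  qe <- intronminer:::aa_encode(q, s)
  for (i in 1:n) {
    shuf <- paste(sample(strsplit(subject, "")[[1]]), collapse = "")
    raws[i] <- sw_score_multi_c(list(qe), intronminer:::aa_encode(shuf, s),
                                s$submat, s$gap_open, s$gap_extend)
  }
  # P(raw >= s0) should match 1 - exp(-E) with E = K*m*n*exp(-lambda*s0)
  # within a factor of 3 over the observed score range
  for (q0 in c(0.25, 0.5, 0.75)) {
    s0 <- quantile(raws, q0)
    emp <- mean(raws >= s0)
    E <- hsp_evalue(s0, 100, 300, s)
    theo <- 1 - exp(-E)
    expect_gt(emp / theo, 1 / 3)
    expect_lt(emp / theo, 3)
  }
})

test_that("hit pooling merges overlapping intervals per accession and strand", {
  base <- data.frame(query_id = c("q1", "q2"), subject_id = "ACC1",
                     s_start = c(100L, 150L), s_end = c(1300L, 1350L),
                     strand = "+", frame = 0L, q_start = 1L, q_end = 10L,
                     raw_score = c(50, 60), bit_score = c(20, 24),
                     evalue = c(1e-30, 1e-34), has_internal_stop = FALSE,
                     stringsAsFactors = FALSE)
  loci <- pool_hits(base)
  expect_equal(nrow(loci), 1)
  expect_equal(c(loci$start, loci$end), c(100L, 1350L))
  expect_equal(loci$supporting_queries, "q1,q2")
  expect_equal(loci$best_evalue, 1e-34)

  # same interval on opposite strands stays two loci
  opp <- base; opp$strand <- c("+", "-"); opp$s_start <- 100L; opp$s_end <- 1300L
  expect_equal(nrow(pool_hits(opp)), 2)

  # bookended intervals are not merged
  book <- base; book$s_start <- c(100L, 1300L); book$s_end <- c(1300L, 1500L)
  expect_equal(nrow(pool_hits(book)), 2)
})

test_that("pooling equals the sweep-line union oracle and refines a partition", {
  set.seed(28)
  for (rep in 1:20) {
    k <- sample(3:12, 1)
    st <- sample(0:5000, k); en <- st + sample(50:800, k, replace = TRUE)
    hs <- data.frame(query_id = paste0("q", seq_len(k)), subject_id = "A",
                     s_start = st, s_end = en, strand = "+", frame = 0L,
                     q_start = 1L, q_end = 10L, raw_score = 50,
                     bit_score = 20, evalue = 1e-30,
                     has_internal_stop = FALSE, stringsAsFactors = FALSE)
    loci <- pool_hits(hs)
    ora <- oracle_interval_union(st, en)
    expect_equal(nrow(loci), length(ora))
    expect_equal(loci$start, vapply(ora, `[`, numeric(1), 1))
    expect_equal(loci$end, vapply(ora, `[`, numeric(1), 2))
    # every HSP interval is contained in exactly one locus
    for (i in seq_len(k)) {
      inside <- loci$start <= st[i] & loci$end >= en[i]
      expect_equal(sum(inside), 1)
    }
  }
})
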