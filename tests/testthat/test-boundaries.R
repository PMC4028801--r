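# A small shared profile pair built from a fixed consensus, reused across
# blocks (calibration makes build_profile moderately expensive).
bp_env <- new.env()
boundary_profiles <- function() {
  if (!is.null(bp_env$p)) return(bp_env$p)
  set.seed(51)
  cons5 <- paste0("GTGCG", random_dna_str(25))
  cons3 <- paste0(random_dna_str(23), "AT")
  tr5 <- replicate(20, intronminer:::sample_motif(cons5, 0.02))
  tr3 <- replicate(20, intronminer:::sample_motif(cons3, 0.02))
  p5 <- build_profile(tr5, "T", "five_prime", bg_n = 300)
  p3 <- build_profile(tr3, "T", "three_prime", bg_n = 300)
  bp_env$p <- list(cons5 = cons5, cons3 = cons3, p5 = p5, p3 = p3)
  bp_env$p
}

test_that("profile columns follow the training alignment", {
  # identical training sequences: argmax is the observed base everywhere
  p <- build_profile(rep("ACGTACGT", 3), "T", "five_prime", bg_n = 50,
                     bg_len = 60)
  expect_equal(profile_consensus(p), "ACGTACGT")
  expect_true(all(abs(colSums(p$probs) - 1) < 1e-12))
  expect_error(build_profile(c("ACGT", "ACG"), "T", "five_prime"), "ragged")
})

test_that("class C training yields the published consensus as the argmax", {
  corpus <- test_corpus()
  b <- corpus$bundle$boundary[["C"]]
  p5 <- build_profile(b$training5, "C", "five_prime", bg_n = 50)
  got <- strsplit(profile_consensus(p5), "")[[1]]
  want <- strsplit("GTNYGCCNRGCATGG", "")[[1]]
  for (j in seq_along(want)) {
    allowed <- intronminer:::iupac_set(want[j])
    if (length(allowed) == 1) expect_equal(got[j], allowed)
    else expect_true(got[j] %in% allowed)
  }
  p3 <- build_profile(b$training3, "C", "three_prime", bg_n = 50)
  got3 <- strsplit(profile_consensus(p3), "")[[1]]
  want3 <- strsplit("CCTACYCGAT", "")[[1]]
  off <- p3$length - 10
  for (j in seq_along(want3)) {
    allowed <- intronminer:::iupac_set(want3[j])
    if (length(allowed) == 1) expect_equal(got3[off + j], allowed)
    else expect_true(got3[off + j] %in% allowed)
  }
})

test_that("column entropy decreases as training conservation increases", {
  set.seed(52)
  cons <- random_dna_str(20)
  entropy <- function(mut) {
    tr <- replicate(30, intronminer:::sample_motif(cons, mut))
    p <- build_profile(tr, "T", "five_prime", bg_n = 50, bg_len = 60)
    mean(-colSums(p$probs * log(p$probs)))
  }
  expect_lt(entropy(0.02), entropy(0.15))
  expect_lt(entropy(0.15), entropy(0.35))
})

test_that("the forward scorer dominates the best-path scorer at every offset", {
  p <- boundary_profiles()
  set.seed(53)
  for (i in 1:5) {
    w <- random_dna_str(400)
    sc <- intronminer:::profile_scan_c(p$p5$logodds,
                                       intronminer:::encode_dna(w),
                                       p$p5$del_pen, p$p5$ins_pen, p$p5$band)
    valid <- is.finite(sc[1, ]) & is.finite(sc[2, ])
    expect_true(all(sc[2, valid] >= sc[1, valid] - 1e-9))
  }
})

test_that("scanning finds a planted motif at its exact offset", {
  p <- boundary_profiles()
  set.seed(54)
  inst5 <- intronminer:::sample_motif(p$cons5, 0)
  inst3 <- intronminer:::sample_motif(p$cons3, 0)
  w <- paste0(random_dna_str(1500), inst5, random_dna_str(2000), inst3,
              random_dna_str(1200))
  call <- scan_boundaries(w, p$p5, p$p3)
  expect_equal(call$bin, "both")
  expect_equal(call$candidates_5$window_position[1], 1500)
  expect_equal(call$candidates_3$window_position[1],
               1500 + 30 + 2000 + 25 - 1)
  # translation equivariance: shifting the motif shifts the call by 7
  w2 <- paste0(random_dna_str(7), w)
  call2 <- scan_boundaries(w2, p$p5, p$p3)
  expect_equal(call2$candidates_5$window_position[1], 1507)
})

test_that("random windows almost always bin as none", {
  p <- boundary_profiles()
  set.seed(55)
  none <- 0L
  for (i in 1:100) {
    call <- scan_boundaries(random_dna_str(2000), p$p5, p$p3)
    if (call$bin == "none") none <- none + 1L
  }
  expect_gte(none, 95L)
})

test_that("tier is monotone in the best score", {
  th <- c(high = 6, medium = 4, low = 2.5)
  z <- seq(0, 10, by = 0.25)
  tiers <- intronminer:::tier_rank(intronminer:::tier_of(z, th))
  tiers[is.na(tiers)] <- 0L
  expect_true(all(diff(tiers) >= 0))
})

test_that("boundary resolution demands a unique, ordered, plausible pair", {
  cand <- function(side, pos, tier, z = c(low = 3, medium = 5, high = 8)[[tier]])
    data.frame(side = side, window_position = pos, offset = pos,
               score_a = z, score_b = z, best_score = z, tier = tier,
               stringsAsFactors = FALSE)
  call <- structure(list(bin = "both", tier = "high",
                         candidates_5 = cand("five_prime", 2100L, "high"),
                         candidates_3 = cand("three_prime", 4600L, "high"),
                         class_label = "T"),
                    class = "boundary_call")
  ic <- resolve_boundaries(call, orf_span = c(2400L, 4300L))
  expect_equal(ic$status, "have_boundaries")
  expect_equal(ic$length, 4600 - 2100 + 1)

  # two high-tier 5' candidates flanking the ORF start -> ambiguous
  call2 <- call
  call2$candidates_5 <- rbind(cand("five_prime", 2100L, "high"),
                              cand("five_prime", 1800L, "high"))
  amb <- resolve_boundaries(call2, orf_span = c(2400L, 4300L))
  expect_equal(amb$status, "ambiguous")
  expect_true(any(grepl("multiple_5prime", amb$reasons)))

  # 3' upstream of 5' -> ambiguous (order violated via position gates)
  call3 <- call
  call3$candidates_3 <- cand("three_prime", 1500L, "high")
  expect_equal(resolve_boundaries(call3, orf_span = c(2400L, 4300L))$status,
               "ambiguous")

  # medium-tier side fails at the default floor but passes with the
  # best-single fallback
  call4 <- call
  call4$candidates_3$tier <- "medium"
  expect_equal(resolve_boundaries(call4, orf_span = c(2400L, 4300L))$status,
               "ambiguous")
  ok <- resolve_boundaries(call4, orf_span = c(2400L, 4300L),
                           admit_best_single = TRUE)
  expect_equal(ok$status, "have_boundaries")
  expect_equal(ok$tier, "medium")

  # length bounds are enforced
  short <- resolve_boundaries(call, orf_span = c(2400L, 4300L),
                              length_bounds = c(400L, 2000L))
  expect_equal(short$status, "ambiguous")
})

test_that("the emitted intron is the exact window substring with context", {
  p <- boundary_profiles()
  set.seed(56)
  inst5 <- intronminer:::sample_motif(p$cons5, 0)
  inst3 <- intronminer:::sample_motif(p$cons3, 0)
  wseq <- paste0(random_dna_str(900), inst5, random_dna_str(1500), inst3,
                 random_dna_str(700))
  rec <- genomic_record("GEN1", sequence = wseq)
  win <- extract_window(rec, c(0, nchar(wseq)), "+", flank_nt = 0)
  call <- scan_boundaries(win, p$p5, p$p3)
  ic <- resolve_boundaries(call, orf_span = c(1200L, 2200L))
  expect_equal(ic$status, "have_boundaries")
  out <- generate_intron(win, ic)
  expect_equal(out$intron_seq,
               substr(wseq, out$start_5 + 1, out$end_3 + 1))
  expect_true(startsWith(out$intron_seq, substr(inst5, 1, 5)))
  expect_true(endsWith(out$intron_seq, substr(inst3, 24, 25)))
  expect_equal(nchar(out$exon_5), 20)
  expect_equal(as_rna("GATTACA"), "GAUUACA")
  # generic terminus consensus: starts GT..., ends ...AY
  expect_equal(substr(out$intron_seq, 1, 2), "GT")
  expect_equal(substr(out$intron_seq, nchar(out$intron_seq) - 1,
                      nchar(out$intron_seq) - 1), "A")
})

test_that("class C fixture introns start GT and end AT", {
  corpus <- test_corpus()
  tr <- corpus$truth
  rows <- tr[tr$kind == "full" & tr$class == "C", ]
  for (i in seq_len(nrow(rows))) {
    t <- rows[i, ]
    rec <- corpus$records[[t$accession]]
    intron <- substr(rec$sequence, t$intron_start + 1, t$intron_end)
    if (t$strand == "-") intron <- revcomp(intron)
    expect_equal(substr(intron, 1, 2), "GT")
    expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AT")
  }
})
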