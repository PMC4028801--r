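make_ref_iep <- function(prot, with_en = TRUE) {
  doms <- c("0", "1", "2", "3", "4", "5", "6", "7", "X")
  if (with_en) doms <- c(doms, "En")
  pos <- round(seq_along(doms) / (length(doms) + 1) * (nchar(prot) - 1))
  reference_iep("T1", prot, setNames(as.integer(pos), doms))
}

window_of_dna <- function(dna, id = "ORF1") {
  rec <- genomic_record(id, sequence = dna)
  extract_window(rec, c(10, nchar(dna) - 10), "+", flank_nt = 10)
}

test_that("domain category mapping is total and mutually exclusive", {
  # exhaustive truth table over count patterns for three domains
  pats <- expand.grid(a = 0:2, b = 0:2, c = 0:2)
  for (i in seq_len(nrow(pats))) {
    counts <- unlist(pats[i, ])
    missing <- any(counts == 0); extra <- any(counts > 1)
    want <- if (!missing && !extra) "normal"
            else if (missing && !extra) "missing"
            else if (!missing && extra) "extra"
            else "missing_and_extra"
    got <- intronminer:::domain_category_of(counts)
    expect_equal(got, want)
  }
})

test_that("a reference aligned to its own coding window shows all domains once", {
  set.seed(41)
  prot <- paste0("M", random_aa(449))
  ref <- make_ref_iep(prot)
  win <- window_of_dna(encode_orf_dna(prot))
  inv <- domain_inventory(win, ref, test_scheme())
  expect_true(all(inv$counts == 1L))
  expect_equal(inv$category, "normal")
})

test_that("truncation removes downstream domains; a second ORF copy doubles counts", {
  set.seed(42)
  prot <- paste0("M", random_aa(449))
  ref <- make_ref_iep(prot)
  s <- test_scheme()
  # keep only the first 55% of the ORF
  part <- substr(prot, 1, round(0.55 * nchar(prot)))
  invt <- domain_inventory(window_of_dna(encode_orf_dna(part)), ref, s)
  expect_equal(invt$category, "missing")
  expect_true(all(invt$counts[c("7", "X", "En")] == 0L))
  expect_true(invt$counts[["0"]] >= 1L)
  # twintron-like window: two full ORF copies
  two <- paste0(encode_orf_dna(prot, 60, 40), encode_orf_dna(prot, 40, 60))
  inv2 <- domain_inventory(window_of_dna(two), ref, s)
  expect_equal(inv2$category, "extra")
  expect_true(all(inv2$counts >= 2L))
})

test_that("removing a proxy-covering segment never increases its count", {
  set.seed(43)
  prot <- paste0("M", random_aa(449))
  ref <- make_ref_iep(prot)
  s <- test_scheme()
  full_dna <- encode_orf_dna(prot)
  base <- domain_inventory(window_of_dna(full_dna), ref, s)
  # delete the codons around the domain-5 proxy
  p5 <- ref$proxy_positions[["5"]]
  cut_from <- 90 + 3 * (p5 - 8)
  cut_to <- 90 + 3 * (p5 + 8)
  cut_dna <- paste0(substr(full_dna, 1, cut_from),
                    substr(full_dna, cut_to + 1, nchar(full_dna)))
  cut <- domain_inventory(window_of_dna(cut_dna), ref, s)
  expect_lte(cut$counts[["5"]], base$counts[["5"]])
  expect_equal(cut$counts[["5"]], 0L)
})

test_that("ORF intactness flags frameshifts, premature stops and gaps", {
  set.seed(44)
  prot <- paste0("M", random_aa(449))
  rel <- mutate_k(prot, 45)  # a 90%-identical curated relative
  s <- test_scheme()
  dna <- encode_orf_dna(prot)
  ok <- orf_intactness(window_of_dna(dna), rel, s)
  expect_true(ok$intact)
  expect_equal(ok$hsp_count, 1L)

  # +1 frameshift mid-ORF: two HSPs in different frames
  at <- 90 + 3 * 225
  fs <- paste0(substr(dna, 1, at), "G", substr(dna, at + 1, nchar(dna)))
  st_fs <- orf_intactness(window_of_dna(fs), rel, s)
  expect_false(st_fs$intact)
  expect_true("multiple_hsps" %in% st_fs$issues)
  expect_gte(st_fs$hsp_count, 2L)

  # TAA at 60% of the ORF
  at60 <- 90 + 3 * round(0.6 * nchar(prot))
  ps <- paste0(substr(dna, 1, at60), "TAA", substr(dna, at60 + 4, nchar(dna)))
  st_ps <- orf_intactness(window_of_dna(ps), rel, s)
  expect_false(st_ps$intact)
  expect_true("premature_stop" %in% st_ps$issues)

  # 5-codon insertion: gap run beyond the 2-codon allowance
  ins <- paste0(substr(dna, 1, at), random_dna_str(15),
                substr(dna, at + 1, nchar(dna)))
  st_in <- orf_intactness(window_of_dna(ins), rel, s)
  expect_false(st_in$intact)
  expect_true(any(c("gap_insertion", "multiple_hsps") %in% st_in$issues))
})

test_that("a duplicated ORF elsewhere in the window is a multiple-locations case", {
  set.seed(45)
  prot <- paste0("M", random_aa(399))
  rel <- mutate_k(prot, 40)
  two <- paste0(encode_orf_dna(prot, 60, 40), encode_orf_dna(prot, 40, 60))
  st2 <- orf_intactness(window_of_dna(two), rel, test_scheme())
  expect_true("multiple_locations" %in% st2$issues)
})

test_that("start-codon selection recovers the exact planted protein", {
  set.seed(46)
  prot <- paste0("M", random_aa(420))
  rel <- mutate_k(prot, 42)
  s <- test_scheme()
  # plant an SD motif 8 nt upstream of the true ATG
  orf <- paste(vapply(strsplit(prot, "")[[1]][-1],
                      function(a) aa_codon(a), character(1)), collapse = "")
  dna <- paste0(random_dna_str(200), "AGGAGG", random_dna_str(8),
                "ATG", orf, "TAA", random_dna_str(200))
  win <- window_of_dna(dna)
  st <- orf_intactness(win, rel, s)
  expect_true(st$intact)
  iep <- assign_iep(win, st, s)
  expect_equal(iep$start_codon, "ATG")
  expect_equal(iep$start_pos_window, 200 + 6 + 8)
  expect_equal(iep$protein, prot)
})

test_that("SD scoring prefers a motif-backed ATG over a bare GTG", {
  # hand-computed with the packaged PWM: a perfect AGGAGG 8 nt upstream of an
  # ATG scores 6*log2(0.7/0.25) = 8.91 bits; a start with no SD support is
  # floored at 0 and cannot win on codon bonus alone
  pwm <- sd_pwm()
  perfect <- sum(pwm[cbind(match(strsplit("AGGAGG", "")[[1]], rownames(pwm)),
                           1:6)])
  expect_equal(perfect, 6 * log2(0.7 / 0.25), tolerance = 1e-12)
  set.seed(47)
  prot <- paste0("M", random_aa(300))
  rel <- mutate_k(prot, 30)
  s <- test_scheme()
  body <- paste(vapply(strsplit(prot, "")[[1]][-1], aa_codon, character(1)),
                collapse = "")
  # in-frame GTG 27 nt upstream of an SD-backed ATG (proline codons between)
  dna <- paste0(random_dna_str(180), "GTG", "CCCCCCCCC",
                "AGGAGG", random_dna_str(9),
                "ATG", body, "TAA", random_dna_str(180))
  win <- window_of_dna(dna)
  st <- orf_intactness(win, rel, s)
  iep <- assign_iep(win, st, s)
  expect_equal(iep$start_codon, "ATG")
  expect_gte(iep$sd_score, perfect - 1e-9)
})

test_that("a relative start aligning into a truncated flank is flagged", {
  set.seed(48)
  prot <- paste0("M", random_aa(400))
  rel <- mutate_k(prot, 40)
  s <- test_scheme()
  # cut the window so it starts 150 nt into the ORF: the position aligning to
  # the relative's start falls outside the window, no start codon in range
  dna <- encode_orf_dna(prot, lflank = 0, rflank = 60)
  dna <- substr(dna, 151, nchar(dna))
  rec <- genomic_record("TR1", sequence = dna)
  win <- extract_window(rec, c(0, nchar(dna)), "+", flank_nt = 0)
  st <- orf_intactness(win, rel, s, coverage_frac = 0.5)
  iep <- assign_iep(win, st, s, scan_halfwidth = 30)
  expect_true(is.na(iep$start_pos_window))
  expect_equal(iep$flag, "no_start_in_range")
})
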