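# Small shared fixture corpus, built once per test run.

small_spec <- function(seed = 7) {
  fixture_spec(seed = seed, classes = c("ML", "C"), introns_per_class = 2,
               decoys = c(truncated = 1, frameshifted = 1, premature_stop = 1,
                          non_gii_rt = 1, twintron = 1),
               identity_clusters = list(), training_n = 10)
}

test_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture_corpus(small_spec())
    cache
  }
})

test_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- scoring_scheme()
    cache
  }
})

# oriented window around a truth row's ORF, as the pipeline would cut it
truth_window <- function(corpus, truth_row, flank = 3000) {
  rec <- corpus$records[[truth_row$accession]]
  extract_window(rec, c(truth_row$orf_start, truth_row$orf_end),
                 truth_row$strand, flank_nt = flank)
}

# planted intron boundaries of a truth row in window coordinates
truth_boundaries <- function(win, truth_row) {
  if (truth_row$strand == "+") {
    c(five = source_to_window(win, truth_row$intron_start),
      three = source_to_window(win, truth_row$intron_end - 1L))
  } else {
    c(five = source_to_window(win, truth_row$intron_end - 1L),
      three = source_to_window(win, truth_row$intron_start))
  }
}

# DNA that encodes a protein (assumed to start with M) with untranslated
# flanks; the ORF begins at 0-based position lflank
encode_orf_dna <- function(protein, lflank = 90, rflank = 90) {
  orf <- paste(vapply(strsplit(protein, "")[[1]][-1], aa_codon, character(1)),
               collapse = "")
  paste0(random_dna_str(lflank), "ATG", orf, "TAA", random_dna_str(rflank))
}

aa_codon <- function(a) {
  code <- Biostrings::getGeneticCode("11")
  names(code)[match(a, code)]
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")
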