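#' Six-frame translation
#'
#' Translates a DNA string in all six reading frames under the bacterial
#' genetic code (table 11). Stop codons are rendered `*`; partial terminal
#' codons are dropped; codons containing ambiguity that does not resolve are
#' rendered `X`.
#'
#' @param dna DNA string (length >= 3).
#' @return A data.frame with columns `strand` (`"+"`/`"-"`), `frame`
#'   (0, 1, 2) and `protein`.
#' @export
six_frame_translate <- function(dna) {
  stopifnot(nchar(dna) >= 3)
  prots <- translate_frames_c(dna, genetic_code_64())
  data.frame(strand = rep(c("+", "-"), each = 3), frame = rep(0:2, 2),
             protein = as.character(prots), stringsAsFactors = FALSE)
}

# bacterial genetic code (table 11) as a 64-char lookup string indexed by
# codon 16*b1 + 4*b2 + b3 (A=0, C=1, G=2, T=3), built from Biostrings once
genetic_code_64 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- Biostrings::getGeneticCode("11")
    bases <- c("A", "C", "G", "T")
    out <- character(64)
    for (a in 0:3) for (b in 0:3) for (cc in 0:3) {
      codon <- paste0(bases[a + 1], bases[b + 1], bases[cc + 1])
      out[16 * a + 4 * b + cc + 1] <- unname(code[codon])
    }
    cache <<- paste(out, collapse = "")
    cache
  }
})

# translate a plus-strand frame-0 DNA string (fast path)
translate_f0 <- function(dna) {
  as.character(translate_frames_c(dna, genetic_code_64())[1])
}

#' Optimal local alignment of two proteins
#'
#' Affine-gap Smith-Waterman with the scheme's substitution matrix. The
#' tie-break is deterministic (earliest best-scoring end cell; match state
#' preferred over gap states within a cell).
#'
#' @param query,subject Protein strings.
#' @param scheme A [scoring_scheme()].
#' @return List with `score`, 1-based `q_start`, `q_end`, `s_start`, `s_end`,
#'   and `pairs`, a 2 x L integer matrix of aligned (query, subject) positions
#'   with 0 marking a gap. `score` is 0 and coordinates are `NA` when no
#'   positive-scoring alignment exists.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  stopifnot(nzchar(query), nzchar(subject))
  sw_align_c(aa_encode(query, scheme), aa_encode(subject, scheme),
             scheme$submat, scheme$gap_open, scheme$gap_extend)
}

subject_dna <- function(subject) {
  if (inherits(subject, "genomic_record")) list(seq = subject$sequence, id = subject$accession)
  else if (inherits(subject, "sequence_window")) list(seq = subject$window_seq, id = subject$candidate_id)
  else list(seq = as.character(subject), id = "subject")
}

#' Translated local-alignment search (protein query vs six-frame DNA)
#'
#' Scores a protein query against all six reading frames of a DNA subject and
#' reports high-scoring pairs (HSPs) with Karlin-Altschul E-values
#' `E = K * m * n * exp(-lambda * S)`, where `m` is the query length and `n`
#' the subject frame length in residues. HSPs with `E <= evalue_cutoff` are
#' returned sorted by E-value.
#'
#' With `max_hits_per_frame > 1`, additional non-overlapping HSPs per frame
#' are recovered by masking each accepted subject segment and realigning
#' (needed e.g. for twintrons carrying two ORF copies).
#'
#' @param query Protein string.
#' @param subject A `genomic_record`, `sequence_window`, or DNA string.
#' @param scheme A [scoring_scheme()].
#' @param evalue_cutoff Retain HSPs with E-value at or below this (default
#'   1e-20, the pipeline's search cutoff).
#' @param query_id,subject_id Identifiers carried into the result.
#' @param max_hits_per_frame Maximum HSPs recovered per frame (default 1).
#' @param with_alignment Keep the aligned-pairs matrices (list column `pairs`,
#'   plus `s_aa_start`/`s_aa_end` frame-protein coordinates).
#' @param region Optional `c(start, end)` 0-based half-open interval
#'   restricting the subject DNA searched; reported nucleotide coordinates
#'   remain on the full subject.
#' @param frames Optional precomputed [six_frame_translate()] result for the
#'   (region-restricted) subject, with an optional `enc` list column of
#'   residue encodings - lets callers searching many queries against one
#'   subject translate and encode it once.
#' @return A data.frame of HSPs: `query_id`, `subject_id`, `s_start`, `s_end`
#'   (0-based half-open nucleotide interval on the subject forward strand),
#'   `strand`, `frame`, `q_start`, `q_end` (1-based query residues),
#'   `raw_score`, `bit_score`, `evalue`, `has_internal_stop`.
#' @export
translated_search <- function(query, subject, scheme = scoring_scheme(),
                              evalue_cutoff = 1e-20, query_id = "query",
                              subject_id = NULL, max_hits_per_frame = 1L,
                              with_alignment = FALSE, region = NULL,
                              frames = NULL) {
  sd <- subject_dna(subject)
  if (is.null(subject_id)) subject_id <- sd$id
  dna <- sd$seq
  off <- 0L
  if (!is.null(region)) {
    stopifnot(region[1] >= 0, region[2] <= nchar(dna), region[2] > region[1])
    off <- as.integer(region[1])
    dna <- substr(dna, region[1] + 1L, region[2])
  }
  Lloc <- nchar(dna)
  if (is.null(frames)) frames <- six_frame_translate(dna)
  if (is.null(frames$enc))
    frames$enc <- I(lapply(frames$protein, aa_encode, scheme = scheme))
  m <- nchar(query)
  qenc <- aa_encode(query, scheme)
  star <- match("*", scheme$alphabet) - 1L
  rows <- list()
  for (i in seq_len(6)) {
    prot <- frames$protein[i]
    if (nchar(prot) < 1) next
    n <- nchar(prot)
    senc <- frames$enc[[i]]
    # score-only prescreen: skip frames that cannot pass the cutoff
    pre <- sw_score_multi_c(list(qenc), senc, scheme$submat,
                            scheme$gap_open, scheme$gap_extend)
    if (hsp_evalue(pre, m, n, scheme) > evalue_cutoff) next
    for (h in seq_len(max_hits_per_frame)) {
      al <- sw_align_c(qenc, senc, scheme$submat, scheme$gap_open, scheme$gap_extend)
      if (al$score <= 0) break
      ev <- hsp_evalue(al$score, m, n, scheme)
      if (ev > evalue_cutoff) break
      a1 <- al$s_start; a2 <- al$s_end
      f <- frames$frame[i]
      if (frames$strand[i] == "+") {
        nt <- c(f + 3L * (a1 - 1L), f + 3L * a2)
      } else {
        nt <- c(Lloc - (f + 3L * a2), Lloc - (f + 3L * (a1 - 1L)))
      }
      seg <- substr(prot, a1, a2)
      row <- data.frame(query_id = query_id, subject_id = subject_id,
                        s_start = nt[1] + off, s_end = nt[2] + off,
                        strand = frames$strand[i], frame = f,
                        q_start = al$q_start, q_end = al$q_end,
                        raw_score = al$score,
                        bit_score = bit_score(al$score, scheme),
                        evalue = ev,
                        has_internal_stop = grepl("*", seg, fixed = TRUE),
                        stringsAsFactors = FALSE)
      if (with_alignment) {
        row$pairs <- I(list(al$pairs))
        row$s_aa_start <- a1; row$s_aa_end <- a2
      }
      rows[[length(rows) + 1L]] <- row
      if (h < max_hits_per_frame) senc[a1:a2] <- star  # mask and rescan
    }
  }
  if (!length(rows)) {
    out <- data.frame(query_id = character(), subject_id = character(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), frame = integer(),
                      q_start = integer(), q_end = integer(),
                      raw_score = numeric(), bit_score = numeric(),
                      evalue = numeric(), has_internal_stop = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out[order(out$evalue, -out$raw_score), , drop = FALSE]
}

#' Pool HSPs from all queries into unique, non-overlapping candidate loci
#'
#' HSP intervals on the same subject and strand that overlap by at least one
#' nucleotide are merged into a single locus (interval union); bookended
#' (adjacent) intervals are not merged. Supporting queries and the best
#' E-value are recorded.
#'
#' @param hsps A data.frame as returned by [translated_search()] (rows from
#'   several queries/subjects may be concatenated).
#' @return A data.frame of loci: `accession`, `start`, `end` (0-based
#'   half-open), `strand`, `best_evalue`, `supporting_queries` (comma
#'   separated, sorted unique), `n_hsps`; sorted by accession then start.
#' @export
pool_hits <- function(hsps) {
  if (!nrow(hsps)) {
    return(data.frame(accession = character(), start = integer(),
                      end = integer(), strand = character(),
                      best_evalue = numeric(), supporting_queries = character(),
                      n_hsps = integer(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (key in unique(paste(hsps$subject_id, hsps$strand, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- hsps[hsps$subject_id == parts[1] & hsps$strand == parts[2], , drop = FALSE]
    sub <- sub[order(sub$s_start, sub$s_end), , drop = FALSE]
    cs <- sub$s_start[1]; ce <- sub$s_end[1]
    idx <- 1L; grp <- integer(nrow(sub)); grp[1] <- 1L
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      if (sub$s_start[i] < ce) { ce <- max(ce, sub$s_end[i]); grp[i] <- idx }
      else { idx <- idx + 1L; grp[i] <- idx; ce <- sub$s_end[i] }
    }
    for (g in seq_len(max(grp))) {
      rows <- sub[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        accession = parts[1], start = min(rows$s_start), end = max(rows$s_end),
        strand = parts[2], best_evalue = min(rows$evalue),
        supporting_queries = paste(sort(unique(rows$query_id)), collapse = ","),
        n_hsps = nrow(rows), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$accession, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
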