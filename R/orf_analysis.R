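#' Reference IEP with domain proxy positions
#'
#' A reference intron-encoded protein for one class (ML, CL1, CL2, A-F) in
#' which one conserved residue per domain (labels among 0-7, X, En) serves as
#' a proxy for that domain's presence: a candidate is judged to contain a
#' domain when the proxy residue falls inside an aligned (non-gap) column of
#' the candidate/reference alignment. Which domains are expected is
#' per-reference metadata (e.g. En is absent from some classes).
#'
#' @param class_label Class of the reference (ML, CL1, CL2, A, B, C, D, E, F).
#' @param seq Protein sequence.
#' @param proxy_positions Named integer vector, 0-based position per domain
#'   label; positions must be strictly increasing in domain order.
#' @param start_codon Annotated start codon of the reference ORF.
#' @return A `reference_iep`.
#' @export
reference_iep <- function(class_label, seq, proxy_positions, start_codon = "ATG") {
  stopifnot(!is.null(names(proxy_positions)),
            all(proxy_positions >= 0 & proxy_positions < nchar(seq)),
            !is.unsorted(proxy_positions, strictly = TRUE))
  structure(list(class_label = class_label, seq = seq,
                 proxy_positions = proxy_positions,
                 expected_domains = names(proxy_positions),
                 start_codon = start_codon),
            class = "reference_iep")
}

#' @export
print.reference_iep <- function(x, ...) {
  cat("<reference_iep> class ", x$class_label, ", ", nchar(x$seq), " aa, domains: ",
      paste(x$expected_domains, collapse = " "), "\n", sep = "")
  invisible(x)
}

proxy_to_string <- function(p) paste(sprintf("%s=%d", names(p), p), collapse = ";")

string_to_proxy <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(vapply(kv, function(x) as.integer(x[2]), integer(1)),
           vapply(kv, `[`, character(1), 1))
}

# Greedy selection of HSPs covering distinct parts of the query (reference
# residues) or the subject (window nucleotides): sorted by score, an HSP is
# kept if it contributes at least min_new previously uncovered units.
distinct_hsps <- function(hs, min_new = 20L, by = c("query", "subject")) {
  by <- match.arg(by)
  if (!nrow(hs)) return(hs)
  hs <- hs[order(-hs$raw_score), , drop = FALSE]
  covered <- integer(0)
  keep <- logical(nrow(hs))
  for (i in seq_len(nrow(hs))) {
    span <- if (by == "query") hs$q_start[i]:hs$q_end[i]
            else hs$s_start[i]:hs$s_end[i]
    if (length(setdiff(span, covered)) >= min_new) {
      keep[i] <- TRUE
      covered <- union(covered, span)
    }
  }
  hs[keep, , drop = FALSE]
}

#' Inventory the IEP domains present in a candidate window
#'
#' Aligns the class reference IEP to the candidate window (translated search,
#' up to `max_copies` alignments per frame so repeated ORF copies are seen)
#' and counts, for each expected domain, in how many distinct alignments its
#' proxy residue appears inside an aligned column. The candidate residue need
#' not be identical - presence in the pairwise alignment suffices.
#'
#' Category: `normal` when every expected domain counts exactly once,
#' `missing` when some count 0 and none more than once, `extra` when some
#' count more than once and none are absent, `missing_and_extra` otherwise.
#'
#' @param window A `sequence_window`.
#' @param reference A [reference_iep()] for the candidate's class.
#' @param scheme A [scoring_scheme()].
#' @param evalue_max E-value cutoff for alignments considered.
#' @param max_copies Maximum alignments recovered per frame.
#' @return A `domain_inventory`: list with `counts` (named integer vector)
#'   and `category`.
#' @export
domain_inventory <- function(window, reference, scheme = scoring_scheme(),
                             evalue_max = 1e-5, max_copies = 3L) {
  hs <- translated_search(reference$seq, window, scheme,
                          evalue_cutoff = evalue_max,
                          max_hits_per_frame = max_copies,
                          with_alignment = TRUE)
  # distinct window segments: repeated ORF copies (twintrons) must each count
  hs <- distinct_hsps(hs, min_new = 60L, by = "subject")
  counts <- setNames(integer(length(reference$expected_domains)),
                     reference$expected_domains)
  if (nrow(hs)) {
    for (i in seq_len(nrow(hs))) {
      pairs <- hs$pairs[[i]]
      aligned_q <- pairs[1, pairs[1, ] > 0 & pairs[2, ] > 0]
      for (d in reference$expected_domains) {
        qpos <- reference$proxy_positions[[d]] + 1L  # 1-based
        if (qpos %in% aligned_q) counts[d] <- counts[d] + 1L
      }
    }
  }
  structure(list(counts = counts, category = domain_category_of(counts),
                 n_alignments = nrow(hs)),
            class = "domain_inventory")
}

# total, mutually exclusive mapping from per-domain counts to a category
domain_category_of <- function(counts) {
  missing <- any(counts == 0L)
  extra <- any(counts > 1L)
  if (!missing && !extra) "normal"
  else if (missing && !extra) "missing"
  else if (!missing && extra) "extra"
  else "missing_and_extra"
}

#' @export
print.domain_inventory <- function(x, ...) {
  cat("<domain_inventory> ", x$category, ": ",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Judge ORF intactness against the closest curated relative
#'
#' A putatively intact ORF shows a single uninterrupted alignment between the
#' candidate window and its closest curated IEP relative: exactly one HSP
#' (frame shifts or large indels split the alignment into several), no stop
#' codon inside the aligned candidate frame, no insertion gaps longer than
#' `max_gap_codons`, and coverage of at least `coverage_frac` of the
#' relative's domain 0-to-X span.
#'
#' @param window A `sequence_window`.
#' @param relative_seq Protein sequence of the closest curated relative.
#' @param scheme A [scoring_scheme()].
#' @param domain_span 1-based `c(from, to)` residue interval of the relative
#'   spanning domains 0 to X (defaults to the whole protein).
#' @param coverage_frac Minimum fraction of `domain_span` covered.
#' @param max_gap_codons Tolerated gap run length in codons; natural 1-2
#'   codon indels should not disqualify an intron.
#' @param evalue_max E-value cutoff for HSPs considered.
#' @return An `orf_status`: `intact`, `issues` (subset of `premature_stop`,
#'   `gap_insertion`, `multiple_hsps`, `multiple_locations`, `low_coverage`),
#'   `hsp_count`, and the top HSP (`top`) for downstream start-codon
#'   selection. `multiple_locations` marks windows in which a second ORF
#'   copy re-covers the same relative residues elsewhere in the window
#'   (twintrons and other multi-copy arrangements).
#' @export
orf_intactness <- function(window, relative_seq, scheme = scoring_scheme(),
                           domain_span = NULL, coverage_frac = 0.95,
                           max_gap_codons = 2L, evalue_max = 1e-5) {
  if (is.null(domain_span)) domain_span <- c(1L, nchar(relative_seq))
  raw <- translated_search(relative_seq, window, scheme,
                           evalue_cutoff = evalue_max,
                           max_hits_per_frame = 2L, with_alignment = TRUE)
  hs <- distinct_hsps(raw)
  issues <- character()
  if (!nrow(hs)) {
    return(structure(list(intact = FALSE, issues = "low_coverage",
                          hsp_count = 0L, top = NULL), class = "orf_status"))
  }
  if (nrow(hs) > 1) issues <- c(issues, "multiple_hsps")
  # repeated ORF copies: a second window segment re-covering the same
  # relative residues signals multiple ORF locations in the window
  seg <- distinct_hsps(raw, min_new = 60L, by = "subject")
  if (nrow(seg) > 1) {
    qo <- vapply(seq_len(nrow(seg)), function(i)
      length(intersect(seg$q_start[i]:seg$q_end[i],
                       seg$q_start[1]:seg$q_end[1])), integer(1))
    if (any(qo[-1] > 0.5 * (seg$q_end[1] - seg$q_start[1] + 1L)))
      issues <- c(issues, "multiple_locations")
  }
  top <- hs[1, , drop = FALSE]
  if (top$has_internal_stop) issues <- c(issues, "premature_stop")
  pairs <- top$pairs[[1]]
  gap_runs <- rle(pairs[1, ] == 0 | pairs[2, ] == 0)
  if (any(gap_runs$lengths[gap_runs$values] > max_gap_codons))
    issues <- c(issues, "gap_insertion")
  cov <- length(intersect(top$q_start:top$q_end, domain_span[1]:domain_span[2])) /
    (domain_span[2] - domain_span[1] + 1L)
  if (cov < coverage_frac) issues <- c(issues, "low_coverage")
  structure(list(intact = length(issues) == 0L, issues = issues,
                 hsp_count = nrow(hs), coverage = cov, top = top),
            class = "orf_status")
}

#' @export
print.orf_status <- function(x, ...) {
  cat("<orf_status> ", if (x$intact) "intact" else
    paste("not intact:", paste(x$issues, collapse = ",")),
    " (", x$hsp_count, " HSP)\n", sep = "")
  invisible(x)
}

#' Shine-Dalgarno position weight matrix
#'
#' Log2-odds PWM for the AGGAGG ribosome-binding core against uniform
#' background: consensus base probability 0.7, others 0.1.
#'
#' @return 4 x 6 numeric matrix, rows A, C, G, T.
#' @export
sd_pwm <- function() {
  cons <- c("A", "G", "G", "A", "G", "G")
  bases <- c("A", "C", "G", "T")
  m <- matrix(log2(0.1 / 0.25), 4, 6, dimnames = list(bases, NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- log2(0.7 / 0.25)
  m
}

# Best SD motif score upstream of 0-based start position p: max over spacer
# lengths of the PWM score of the 6-mer ending `spacer` nt before the start.
sd_motif_score <- function(seq, p, pwm = sd_pwm(), spacer = c(5L, 13L)) {
  best <- -Inf
  for (d in spacer[1]:spacer[2]) {
    s <- p - d - 6L
    if (s < 0) next
    hex <- strsplit(substr(seq, s + 1L, s + 6L), "")[[1]]
    idx <- match(hex, rownames(pwm))
    if (anyNA(idx)) next
    best <- max(best, sum(pwm[cbind(idx, 1:6)]))
  }
  best
}

#' Assign the IEP amino-acid sequence with start-codon selection
#'
#' The candidate's start codon is scanned among in-frame ATG/GTG/TTG within
#' `scan_halfwidth` nt of the position aligning to the relative's start.
#' Each candidate start is scored as an alignment-consistency bonus (1 for
#' the exact aligned position, minus 0.3 per codon of offset), a start-codon
#' bonus (ATG 0.5, GTG 0.2, TTG 0), plus the Shine-Dalgarno motif score
#' (floored at 0) in a 5-13 nt upstream spacer. The maximal-scoring start
#' wins; the protein is emitted from that start (rendered M) to the stop.
#'
#' @param window A `sequence_window`.
#' @param orf_status An intact [orf_intactness()] result for this window.
#' @param scheme A [scoring_scheme()].
#' @param scan_halfwidth Scan half-width in nt around the aligned start.
#' @param spacer Allowed SD spacer range in nt.
#' @return An `iep_sequence`: `protein`, `start_codon`, `start_pos_window`
#'   (0-based), `orf_span` (0-based half-open, including the stop codon),
#'   `sd_score`; `start_pos_window` is `NA` (candidate flagged) when no
#'   start codon is found in range.
#' @export
assign_iep <- function(window, orf_status, scheme = scoring_scheme(),
                       scan_halfwidth = 45L, spacer = c(5L, 13L)) {
  stopifnot(inherits(orf_status, "orf_status"), !is.null(orf_status$top))
  top <- orf_status$top
  seq <- window$window_seq
  flagged <- structure(list(protein = NA_character_, start_codon = NA_character_,
                            start_pos_window = NA_integer_, orf_span = NULL,
                            sd_score = NA_real_, flag = "no_start_in_range"),
                       class = "iep_sequence")
  if (top$strand != "+") return(flagged)
  # window position aligning to relative residue 1 (extrapolated through
  # local-alignment clipping at the N terminus)
  pos0 <- top$s_start - 3L * (top$q_start - 1L)
  cand <- seq(pos0 - scan_halfwidth, pos0 + scan_halfwidth, by = 3L)
  cand <- cand[cand >= 0 & cand + 3 <= nchar(seq)]
  starts <- c(ATG = 0.5, GTG = 0.2, TTG = 0)
  best <- NULL; best_score <- -Inf
  for (p in cand) {
    codon <- substr(seq, p + 1L, p + 3L)
    if (!codon %in% names(starts)) next
    orf <- emit_orf(seq, p)
    if (is.null(orf)) next
    # the ORF must run through the aligned region
    if (orf$stop_end < top$s_end - 3L) next
    sd <- sd_motif_score(seq, p, spacer = spacer)
    consistency <- (p == pos0) - 0.3 * abs(p - pos0) / 3
    score <- consistency + starts[[codon]] + max(0, sd)
    if (score > best_score) {
      best_score <- score
      best <- list(p = p, codon = codon, sd = sd, orf = orf)
    }
  }
  if (is.null(best)) return(flagged)
  structure(list(protein = best$orf$protein, start_codon = best$codon,
                 start_pos_window = best$p,
                 orf_span = c(best$p, best$orf$stop_end),
                 sd_score = best$sd, flag = NA_character_),
            class = "iep_sequence")
}

# Translate from 0-based start p to the first in-frame stop. The start codon
# is rendered M regardless of ATG/GTG/TTG. NULL when no stop is reached.
emit_orf <- function(seq, p) {
  L <- nchar(seq)
  n <- L - p
  n <- n - (n %% 3)
  if (n < 6) return(NULL)
  sub <- substr(seq, p + 1L, p + n)
  prot <- translate_f0(sub)
  stop_at <- regexpr("*", prot, fixed = TRUE)
  if (stop_at < 0) return(NULL)
  list(protein = paste0("M", substr(prot, 2, stop_at - 1L)),
       stop_end = p + 3L * stop_at)  # 0-based end, exclusive, incl. stop codon
}

#' @export
print.iep_sequence <- function(x, ...) {
  if (is.na(x$start_pos_window)) cat("<iep_sequence> flagged:", x$flag, "\n")
  else cat("<iep_sequence> ", nchar(x$protein), " aa, start ", x$start_codon,
           " at window pos ", x$start_pos_window, "\n", sep = "")
  invisible(x)
}
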