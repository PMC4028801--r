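#' Build a protein reference set
#'
#' A reference set is a data.frame with one row per reference protein and at
#' least columns `id` and `seq`; screening uses `category` (RT-type sets) or
#' `class` (curated intron IEP sets). Sets round-trip through FASTA plus a TSV
#' sidecar via [read_reference_set()] / [write_reference_set()].
#'
#' @param id,seq Character vectors (equal length).
#' @param ... Further per-reference columns (e.g. `category`, `class`,
#'   `subclass`, `species`).
#' @return A `reference_set` data.frame.
#' @export
reference_set <- function(id, seq, ...) {
  stopifnot(length(id) == length(seq), !anyDuplicated(id))
  out <- data.frame(id = id, seq = seq, ..., stringsAsFactors = FALSE)
  class(out) <- c("reference_set", "data.frame")
  out
}

#' @rdname reference_set
#' @param path Basename; `<path>.fasta` and `<path>.tsv` are used.
#' @param x A `reference_set`.
#' @export
write_reference_set <- function(x, path) {
  write_fasta(setNames(x$seq, x$id), paste0(path, ".fasta"))
  meta <- x[, setdiff(names(x), "seq"), drop = FALSE]
  write.table(meta, paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname reference_set
#' @export
read_reference_set <- function(path) {
  seqs <- read_fasta(paste0(path, ".fasta"))
  meta <- read.delim(paste0(path, ".tsv"), stringsAsFactors = FALSE)
  stopifnot(setequal(meta$id, names(seqs)))
  meta$seq <- unname(seqs[meta$id])
  class(meta) <- c("reference_set", "data.frame")
  meta
}

# Rank reference proteins against a candidate window by translated-search
# E-value. Scores every reference against the six frames of the window's
# hit region (plus margin) with the score-only engine; ties broken by raw
# score then reference id, so ranking is independent of database order.
rank_matches <- function(window, db, scheme = scoring_scheme(),
                         evalue_max = 1e-5, margin = 1000L) {
  sdna <- window$window_seq
  region <- NULL
  if (!is.null(window$hit_rel)) {
    region <- c(max(0L, window$hit_rel[1] - margin),
                min(nchar(sdna), window$hit_rel[2] + margin))
    sdna <- substr(sdna, region[1] + 1L, region[2])
  }
  frames <- six_frame_translate(sdna)
  encs <- lapply(db$seq, aa_encode, scheme = scheme)
  best <- rep(0, nrow(db))
  for (i in seq_len(6)) {
    prot <- frames$protein[i]
    if (nchar(prot) < 1) next
    sc <- sw_score_multi_c(encs, aa_encode(prot, scheme), scheme$submat,
                           scheme$gap_open, scheme$gap_extend)
    best <- pmax(best, sc)
  }
  n <- max(1L, nchar(sdna) %/% 3L)
  ev <- hsp_evalue(best, nchar(db$seq), n, scheme)
  res <- data.frame(id = db$id, raw_score = best, evalue = ev,
                    stringsAsFactors = FALSE)
  extra <- intersect(c("category", "class", "subclass"), names(db))
  for (col in extra) res[[col]] <- db[[col]]
  res <- res[res$evalue <= evalue_max & res$raw_score > 0, , drop = FALSE]
  res <- res[order(res$evalue, -res$raw_score, res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Screen a candidate against a categorized RT reference set
#'
#' Ranks all reference RTs by translated-search E-value against the candidate
#' window and counts how many of the top three are group II introns:
#' all three -> `probable`, one or two -> `possible`, none -> `non_group_II`.
#' By default only probable candidates proceed in the pipeline. With fewer
#' than three scoring references the count rule applies to the available
#' ranks, so `probable` (3 votes) cannot be reached.
#'
#' @param window A `sequence_window`.
#' @param rt_db A [reference_set()] with a `category` column; group II
#'   references carry category `"group_II"`.
#' @param scheme A [scoring_scheme()].
#' @param evalue_max Matches above this E-value are ignored (default 1e-5).
#' @param vote_threshold Number of group-II votes among the top three needed
#'   for `probable` (default 3; exposed so screening stringency can be
#'   relaxed for exploratory sweeps).
#' @return An `rt_verdict`: list with `value` and `top_matches` (<= 3 rows).
#' @export
rt_verdict <- function(window, rt_db, scheme = scoring_scheme(),
                       evalue_max = 1e-5, vote_threshold = 3L) {
  stopifnot(nrow(rt_db) > 0, "category" %in% names(rt_db))
  ranked <- rank_matches(window, rt_db, scheme, evalue_max = evalue_max)
  top <- head(ranked, 3L)
  n_gii <- sum(top$category == "group_II")
  value <- if (nrow(top) == 0) "non_group_II"
           else if (n_gii >= vote_threshold) "probable"
           else if (n_gii >= 1) "possible"
           else "non_group_II"
  structure(list(value = value, n_group_II = n_gii, top_matches = top),
            class = "rt_verdict")
}

#' @export
print.rt_verdict <- function(x, ...) {
  cat("<rt_verdict> ", x$value, " (", x$n_group_II, "/",
      nrow(x$top_matches), " group II in top matches)\n", sep = "")
  invisible(x)
}

#' Assign an intron class from the curated IEP set
#'
#' Ranks curated intron IEPs against the candidate window. If the top three
#' matches share one defined class the candidate gets that class; if all
#' three are curated "unclassified" introns it is `unclassified`; otherwise
#' `undefined`. CL1/CL2 reference subclasses both count as class CL (the
#' subclass of the best match is kept as metadata). The best match is
#' recorded as the candidate's closest curated relative for later stages.
#'
#' @param window A `sequence_window`.
#' @param iep_db A [reference_set()] with a `class` column (values among
#'   ML, CL, CL1, CL2, A, B, C, D, E, F, unclassified).
#' @param scheme A [scoring_scheme()].
#' @param evalue_max Matches above this E-value are ignored.
#' @return A `class_assignment`: list with `intron_class`, `subclass`,
#'   `closest_relative_id`, `top_matches`.
#' @export
assign_class <- function(window, iep_db, scheme = scoring_scheme(),
                         evalue_max = 1e-5) {
  stopifnot(nrow(iep_db) > 0, "class" %in% names(iep_db))
  ranked <- rank_matches(window, iep_db, scheme, evalue_max = evalue_max)
  top <- head(ranked, 3L)
  if (nrow(top) == 0) {
    return(structure(list(intron_class = "undefined", subclass = NA_character_,
                          closest_relative_id = NA_character_,
                          top_matches = top),
                     class = "class_assignment"))
  }
  norm <- sub("^CL[12]$", "CL", top$class)
  cls <- if (all(norm == "unclassified")) "unclassified"
         else if (length(unique(norm)) == 1 && nrow(top) == 3) norm[1]
         else if (nrow(top) < 3 && length(unique(norm)) == 1 &&
                  norm[1] != "unclassified") norm[1]
         else "undefined"
  subclass <- if (cls == "CL" && grepl("^CL[12]$", top$class[1])) top$class[1] else NA_character_
  structure(list(intron_class = cls, subclass = subclass,
                 closest_relative_id = top$id[1], top_matches = top),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat("<class_assignment> ", x$intron_class,
      if (!is.na(x$subclass)) paste0(" (", x$subclass, ")"),
      ", closest relative: ", x$closest_relative_id, "\n", sep = "")
  invisible(x)
}
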