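#' Read GenBank flat-file text into genomic records
#'
#' Minimal, offline GenBank flat-file parser. Only the fields the pipeline
#' needs are interpreted: LOCUS (name, stated length), ACCESSION, VERSION,
#' ORGANISM (species plus taxonomy lineage), the source feature's
#' `/organelle` qualifier, and the ORIGIN sequence block. The complete
#' original text of each entry is retained in `raw_entry`.
#'
#' A malformed block (missing ORIGIN, or sequence length disagreeing with the
#' LOCUS line) is skipped with a warning; other records are unaffected.
#'
#' @param x Path to a GenBank flat file, or the file text itself (single
#'   string or character vector of lines).
#' @return A list of `genomic_record` objects, each with fields `accession`,
#'   `version`, `sequence` (uppercase DNA), `taxonomy_lineage` (character
#'   vector), `organelle` (`"none"`, `"mitochondrion"` or `"chloroplast"`),
#'   `organism`, and `raw_entry`. Parse failures are reported in the
#'   `"errors"` attribute.
#' @export
read_genbank <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("no LOCUS record found in GenBank input")
  ends <- grep("^//", lines)
  records <- list()
  errors <- character()
  for (s in starts) {
    e <- ends[ends > s]
    if (!length(e)) { errors <- c(errors, "LOCUS block without // terminator"); next }
    block <- lines[s:e[1]]
    rec <- try(parse_genbank_block(block), silent = TRUE)
    if (inherits(rec, "try-error")) {
      errors <- c(errors, conditionMessage(attr(rec, "condition")))
    } else records[[length(records) + 1L]] <- rec
  }
  if (length(errors)) {
    warning(length(errors), " GenBank record(s) failed to parse")
    attr(records, "errors") <- errors
  }
  records
}

parse_genbank_block <- function(block) {
  locus <- block[1]
  locus_name <- sub("^LOCUS\\s+(\\S+).*$", "\\1", locus)
  stated_len <- suppressWarnings(as.integer(
    sub("^LOCUS\\s+\\S+\\s+(\\d+)\\s+bp.*$", "\\1", locus)))
  acc_line <- grep("^ACCESSION", block, value = TRUE)
  accession <- if (length(acc_line)) sub("^ACCESSION\\s+(\\S+).*$", "\\1", acc_line[1]) else locus_name
  ver_line <- grep("^VERSION", block, value = TRUE)
  version <- if (length(ver_line)) sub("^VERSION\\s+(\\S+).*$", "\\1", ver_line[1]) else accession
  # ORGANISM: species on the keyword line, lineage on indented continuation lines
  org_i <- grep("^\\s{2}ORGANISM", block)
  organism <- ""
  lineage <- character()
  if (length(org_i)) {
    organism <- sub("^\\s{2}ORGANISM\\s+", "", block[org_i[1]])
    j <- org_i[1] + 1L
    lin <- character()
    while (j <= length(block) && grepl("^\\s{4,}\\S", block[j]) &&
           !grepl("^\\s{0,5}[A-Z]+\\s", block[j])) {
      lin <- c(lin, trimws(block[j])); j <- j + 1L
    }
    lineage_str <- sub("\\.$", "", paste(lin, collapse = " "))
    if (nzchar(lineage_str)) lineage <- trimws(strsplit(lineage_str, ";", fixed = TRUE)[[1]])
  }
  organelle <- "none"
  oq <- grep("/organelle=", block, value = TRUE)
  if (length(oq)) {
    val <- sub('.*?/organelle="?([^"]+)"?.*', "\\1", oq[1])
    if (grepl("mitochondri", val, ignore.case = TRUE)) organelle <- "mitochondrion"
    if (grepl("chloroplast|plastid", val, ignore.case = TRUE)) organelle <- "chloroplast"
  }
  ori <- grep("^ORIGIN", block)
  if (!length(ori)) stop("record ", accession, ": no ORIGIN block")
  seq_lines <- block[(ori[1] + 1L):(length(block) - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seq)) stop("record ", accession, ": empty sequence")
  if (!is.na(stated_len) && nchar(seq) != stated_len)
    stop("record ", accession, ": ORIGIN length ", nchar(seq),
         " disagrees with LOCUS length ", stated_len)
  genomic_record(accession = accession, version = version, sequence = seq,
                 taxonomy_lineage = lineage, organelle = organelle,
                 organism = organism, raw_entry = paste(block, collapse = "\n"))
}

#' Construct a genomic record
#'
#' @param accession,version Record identifiers.
#' @param sequence Uppercase DNA string (IUPAC letters allowed).
#' @param taxonomy_lineage Character vector of lineage ranks, root first.
#' @param organelle `"none"`, `"mitochondrion"` or `"chloroplast"`.
#' @param organism Species string.
#' @param raw_entry Original flat-file text (regenerated if empty).
#' @return A `genomic_record`.
#' @export
genomic_record <- function(accession, version = accession, sequence,
                           taxonomy_lineage = character(), organelle = "none",
                           organism = "", raw_entry = "") {
  stopifnot(nzchar(accession), nchar(sequence) > 0,
            organelle %in% c("none", "mitochondrion", "chloroplast"))
  structure(list(accession = accession, version = version,
                 sequence = toupper(sequence),
                 taxonomy_lineage = taxonomy_lineage,
                 organelle = organelle, organism = organism,
                 raw_entry = raw_entry),
            class = "genomic_record")
}

#' @export
print.genomic_record <- function(x, ...) {
  cat("<genomic_record> ", x$accession, " (", nchar(x$sequence), " bp) ",
      x$organism, "\n", sep = "")
  invisible(x)
}

#' Write genomic records as GenBank flat-file text
#'
#' @param records A `genomic_record` or list of them.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return The flat-file text, invisibly when written to `path`.
#' @export
write_genbank <- function(records, path = NULL) {
  if (inherits(records, "genomic_record")) records <- list(records)
  txt <- vapply(records, format_genbank_record, character(1))
  out <- paste(txt, collapse = "\n")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

format_genbank_record <- function(rec) {
  L <- nchar(rec$sequence)
  lines <- c(
    sprintf("LOCUS       %-16s %10d bp    DNA     linear   BCT", rec$accession, L),
    sprintf("DEFINITION  %s synthetic fixture sequence.", rec$organism),
    sprintf("ACCESSION   %s", rec$accession),
    sprintf("VERSION     %s", rec$version),
    sprintf("SOURCE      %s", rec$organism),
    sprintf("  ORGANISM  %s", rec$organism))
  if (length(rec$taxonomy_lineage)) {
    lin <- paste0(paste(rec$taxonomy_lineage, collapse = "; "), ".")
    wrapped <- strwrap(lin, width = 67)
    lines <- c(lines, paste0("            ", wrapped))
  }
  lines <- c(lines,
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    sprintf("                     /organism=\"%s\"", rec$organism))
  if (rec$organelle != "none")
    lines <- c(lines, sprintf("                     /organelle=\"%s\"", rec$organelle))
  lines <- c(lines, "ORIGIN")
  sq <- tolower(rec$sequence)
  pos <- seq(1, L, by = 60)
  for (p in pos) {
    chunk <- substr(sq, p, min(p + 59, L))
    parts <- substring(chunk, seq(1, nchar(chunk), 10),
                       pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(parts, collapse = " ")))
  }
  paste(c(lines, "//"), collapse = "\n")
}

#' Classify a record into one of five taxonomy buckets
#'
#' Organelle qualifiers take precedence; otherwise the lineage root decides:
#' Bacteria or Archaea go to `bacteria_archaea`, Eukaryota to `eukaryotes`,
#' and everything else (including records without taxonomy) to `other`.
#'
#' @param record A `genomic_record`.
#' @return One of `"bacteria_archaea"`, `"eukaryotes"`, `"mitochondria"`,
#'   `"chloroplasts"`, `"other"`.
#' @export
classify_taxon <- function(record) {
  if (record$organelle == "mitochondrion") return("mitochondria")
  if (record$organelle == "chloroplast") return("chloroplasts")
  root <- if (length(record$taxonomy_lineage)) record$taxonomy_lineage[1] else ""
  if (root %in% c("Bacteria", "Archaea")) return("bacteria_archaea")
  if (root == "Eukaryota") return("eukaryotes")
  "other"
}

#' Extract an oriented candidate window with flanking sequence
#'
#' Cuts `flank_nt` of flanking sequence on each side of a hit interval and
#' orients the window so the candidate IEP lies on the forward strand
#' (reverse-complementing minus-strand hits). A coordinate map back to the
#' source record is retained; flanks are truncated silently at record ends.
#'
#' Intervals are 0-based half-open on the source forward strand.
#'
#' @param record A `genomic_record`.
#' @param hit_interval Integer `c(start, end)`, 0-based half-open.
#' @param strand `"+"` or `"-"`: strand encoding the candidate IEP.
#' @param flank_nt Flank length per side (default 3000).
#' @param candidate_id Identifier for the window.
#' @return A `sequence_window` with fields `window_seq`, `source_interval`
#'   (of the whole window), `hit_rel` (hit interval in window coordinates),
#'   `source_strand`, and accessors [window_to_source()] / [source_to_window()].
#' @export
extract_window <- function(record, hit_interval, strand, flank_nt = 3000,
                           candidate_id = NULL) {
  start <- hit_interval[1]; end <- hit_interval[2]
  L <- nchar(record$sequence)
  stopifnot(strand %in% c("+", "-"), start >= 0, end <= L)
  if (end <= start) stop("empty hit interval")
  ws <- max(0L, as.integer(start - flank_nt))
  we <- min(L, as.integer(end + flank_nt))
  seq <- substr(record$sequence, ws + 1L, we)
  if (strand == "-") seq <- revcomp(seq)
  if (is.null(candidate_id))
    candidate_id <- sprintf("%s:%d-%d(%s)", record$accession, start, end, strand)
  # hit interval in window coordinates (0-based half-open, forward orientation)
  hit_rel <- if (strand == "+") c(start - ws, end - ws) else c(we - end, we - start)
  structure(list(candidate_id = candidate_id,
                 source_accession = record$accession,
                 window_seq = seq,
                 source_interval = c(ws, we),
                 hit_interval = c(start, end),
                 hit_rel = as.integer(hit_rel),
                 source_strand = strand),
            class = "sequence_window")
}

#' @export
print.sequence_window <- function(x, ...) {
  cat("<sequence_window> ", x$candidate_id, " ", nchar(x$window_seq), " nt, ",
      "source [", x$source_interval[1], ",", x$source_interval[2], ") strand ",
      x$source_strand, "\n", sep = "")
  invisible(x)
}

#' Map window positions to source positions (and back)
#'
#' Positions are 0-based. For minus-strand windows, window index 0 corresponds
#' to the last base of the source interval.
#'
#' @param window A `sequence_window`.
#' @param pos Integer vector of 0-based positions.
#' @return Integer vector of mapped 0-based positions.
#' @export
window_to_source <- function(window, pos) {
  W <- nchar(window$window_seq)
  stopifnot(all(pos >= 0 & pos < W))
  if (window$source_strand == "+") window$source_interval[1] + pos
  else window$source_interval[2] - 1L - pos
}

#' @rdname window_to_source
#' @export
source_to_window <- function(window, pos) {
  stopifnot(all(pos >= window$source_interval[1] & pos < window$source_interval[2]))
  if (window$source_strand == "+") pos - window$source_interval[1]
  else window$source_interval[2] - 1L - pos
}

#' Reverse-complement a DNA string
#'
#' IUPAC ambiguity codes are complemented correctly (via Biostrings).
#'
#' @param dna DNA string.
#' @return The reverse complement.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Read / write FASTA (thin wrappers over Biostrings)
#'
#' @param path FASTA file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
  invisible(path)
}
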