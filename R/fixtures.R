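AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Specification for the synthetic fixture suite
#'
#' The generator plants ground-truth group II introns and decoys into
#' GenBank-format records so every pipeline stage can be exercised offline.
#' Defaults define the standard study conditions: 8 intron classes with 5
#' full-length introns each, plus a 3-member 95%-identity cluster spanning
#' two species, and 25 decoys (truncations, frameshifts, premature stops,
#' non-group-II RTs, twintrons).
#'
#' @param seed Integer seed; the whole suite is a deterministic function of
#'   the spec.
#' @param classes Intron classes to generate.
#' @param introns_per_class Full-length planted introns per class.
#' @param decoys Named counts of decoy kinds.
#' @param identity_clusters List of clusters, each
#'   `list(class=, size=, identity=, n_species=)`.
#' @param record_length Length of each genomic record (nt).
#' @param flank Flank the pipeline is expected to cut (nt).
#' @param motif_mut Per-column mutation rate of planted/training boundary
#'   motifs.
#' @param training_n Training sequences per boundary profile.
#' @param curated_per_class Curated relatives per class in the reference sets.
#' @param curated_identity Identity of curated relatives to the class
#'   ancestor.
#' @param planted_identity Identity of planted intron IEPs to the class
#'   ancestor.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 101L,
                         classes = c("ML", "CL", "A", "B", "C", "D", "E", "F"),
                         introns_per_class = 5L,
                         decoys = c(truncated = 6L, frameshifted = 6L,
                                    premature_stop = 5L, non_gii_rt = 5L,
                                    twintron = 3L),
                         identity_clusters = list(list(class = "ML", size = 3L,
                                                       identity = 0.95,
                                                       n_species = 2L)),
                         record_length = 12000L, flank = 3000L,
                         motif_mut = 0, training_n = 25L,
                         curated_per_class = 4L, curated_identity = 0.90,
                         planted_identity = 0.97) {
  stopifnot(length(classes) >= 1, introns_per_class >= 0, all(decoys >= 0),
            curated_identity > 0.5, curated_identity <= 1,
            planted_identity > 0.5, planted_identity <= 1,
            motif_mut >= 0, motif_mut < 0.5)
  for (cl in identity_clusters)
    stopifnot(cl$identity > 0.5, cl$identity <= 1, cl$size >= 2)
  structure(list(seed = as.integer(seed), classes = classes,
                 introns_per_class = as.integer(introns_per_class),
                 decoys = decoys, identity_clusters = identity_clusters,
                 record_length = as.integer(record_length),
                 flank = as.integer(flank), motif_mut = motif_mut,
                 training_n = as.integer(training_n),
                 curated_per_class = as.integer(curated_per_class),
                 curated_identity = curated_identity,
                 planted_identity = planted_identity),
            class = "fixture_spec")
}

random_protein <- function(len) paste(c("M", sample(AA20, len - 1, TRUE)), collapse = "")

# substitution-only divergence: exactly round(rate * (L-1)) positions (never
# the initial M) changed to a different uniformly chosen residue, so identity
# targets are exact and oracles trivial
mutate_protein <- function(protein, rate, positions = NULL) {
  ch <- strsplit(protein, "")[[1]]
  L <- length(ch)
  k <- round(rate * (L - 1))
  if (is.null(positions)) positions <- sample(2:L, k)
  for (i in positions) ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  paste(ch, collapse = "")
}

iupac_set <- function(code) {
  switch(code, A = "A", C = "C", G = "G", T = "T",
         N = c("A", "C", "G", "T"), Y = c("C", "T"), R = c("A", "G"),
         W = c("A", "T"), S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
         stop("unsupported IUPAC code ", code))
}

# sample a boundary motif instance from a consensus: ambiguity codes draw
# uniformly from their set; fixed letters mutate at rate `mut`
sample_motif <- function(consensus, mut) {
  ch <- strsplit(consensus, "")[[1]]
  out <- vapply(ch, function(c0) {
    s <- iupac_set(c0)
    if (length(s) > 1) sample(s, 1)
    else if (stats::runif(1) < mut) sample(setdiff(c("A", "C", "G", "T"), s), 1)
    else s
  }, character(1))
  paste(out, collapse = "")
}

codon_table_11 <- function() {
  code <- Biostrings::getGeneticCode("11")
  code <- code[code != "*"]
  split(names(code), unname(code))
}

reverse_translate <- function(protein, codons = codon_table_11()) {
  ch <- strsplit(protein, "")[[1]]
  paste(vapply(ch, function(a) {
    opts <- codons[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue ", a)
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")

#' Generate the reference bundle
#'
#' Deterministically builds, per class: an ancestral IEP, curated relatives
#' (the stand-ins for the curated intron IEP set), a reference IEP with
#' evenly spaced domain proxy positions (class CL gets CL1 and CL2
#' subclass references; class C lacks En), boundary consensus strings with
#' training alignments (class C uses the canonical IIC terminus consensus; other
#' classes get generated consensuses of comparable information content), a
#' categorized RT reference set with decoy RT families kept well diverged
#' from all intron IEPs, query ORFs (one representative per class plus an
#' unclassified one), and curated intron DNA sequences.
#'
#' @param spec A [fixture_spec()].
#' @param validate Run the generation-time self-consistency check that every
#'   curated IEP's best hit among curated IEPs is of its own class.
#' @return A `reference_bundle`.
#' @export
make_reference_bundle <- function(spec, validate = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  classes <- spec$classes
  fams <- c(classes, "unclassified")
  ancestors <- list()
  boundary <- list()
  iep_rows <- list()
  reference_ieps <- list()
  for (fam in fams) {
    anc <- random_protein(sample(420:600, 1))
    ancestors[[fam]] <- anc
    for (i in seq_len(spec$curated_per_class)) {
      lab <- if (fam == "CL") c("CL1", "CL2")[1 + (i %% 2)] else fam
      iep_rows[[length(iep_rows) + 1L]] <- data.frame(
        id = sprintf("%s_cur%d", fam, i),
        seq = mutate_protein(anc, 1 - spec$curated_identity),
        class = lab, stringsAsFactors = FALSE)
    }
    if (fam == "unclassified") next
    # reference IEP(s) with proxies
    make_ref <- function(label, seq) {
      doms <- c("0", "1", "2", "3", "4", "5", "6", "7", "X")
      if (fam != "C") doms <- c(doms, "En")
      pos <- round(seq_len(length(doms)) / (length(doms) + 1) * (nchar(seq) - 1))
      reference_iep(label, seq, setNames(as.integer(pos), doms))
    }
    if (fam == "CL") {
      reference_ieps[["CL1"]] <- make_ref("CL1", anc)
      reference_ieps[["CL2"]] <- make_ref("CL2", mutate_protein(anc, 0.30))
    } else {
      reference_ieps[[fam]] <- make_ref(fam, anc)
    }
    # boundary consensus + training
    # boundary consensus blocks: the terminal core follows the generic
    # GTGYG.../...AY pattern (class C uses the canonical IIC consensus
    # verbatim), extended inward by class-conserved columns so profiles carry
    # enough information to separate termini from multi-kb background
    if (fam == "C") {
      cons5 <- paste0("GTNYGCCNRGCATGG", random_dna(15))
      cons3 <- paste0(random_dna(15), "CCTACYCGAT")
    } else {
      cons5 <- paste0("GTG", sample(c("C", "T"), 1), "G", random_dna(25))
      cons3 <- paste0(random_dna(23), "A", sample(c("C", "T"), 1))
    }
    boundary[[fam]] <- list(
      consensus5 = cons5, consensus3 = cons3,
      training5 = replicate(spec$training_n, sample_motif(cons5, spec$motif_mut)),
      training3 = replicate(spec$training_n, sample_motif(cons3, spec$motif_mut)))
  }
  iep_db <- do.call(rbind, iep_rows)
  class(iep_db) <- c("reference_set", "data.frame")
  # decoy RT families, each seeded from a (moderately distant) intron IEP so
  # initial searches still detect them, but >= 35% diverged from every
  # intron IEP so the verdict vote separates them
  decoy_cats <- c("retron", "CRISPR_RT", "DGR", "other_RT")
  rt_rows <- list()
  decoy_ancestors <- list()
  for (cat in decoy_cats) {
    src <- ancestors[[sample(classes, 1)]]
    fam_anc <- mutate_protein(src, 0.45)
    decoy_ancestors[[cat]] <- fam_anc
    for (i in 1:3) {
      rt_rows[[length(rt_rows) + 1L]] <- data.frame(
        id = sprintf("%s_ref%d", cat, i),
        seq = mutate_protein(fam_anc, 0.10), category = cat,
        stringsAsFactors = FALSE)
    }
  }
  rt_db <- rbind(
    data.frame(id = iep_db$id, seq = iep_db$seq, category = "group_II",
               stringsAsFactors = FALSE),
    do.call(rbind, rt_rows))
  class(rt_db) <- c("reference_set", "data.frame")
  queries <- setNames(
    iep_db$seq[match(sprintf("%s_cur1", fams), iep_db$id)],
    sprintf("query_%s", fams))
  # curated intron DNA sequences (reporting/reference artifact)
  curated_dna <- setNames(vapply(seq_len(nrow(iep_db)), function(i) {
    fam <- sub("_cur\\d+$", "", iep_db$id[i])
    b <- boundary[[if (fam %in% names(boundary)) fam else classes[1]]]
    paste0(sample_motif(b$consensus5, spec$motif_mut), random_dna(250),
           "AGGAGG", random_dna(7),
           reverse_translate(iep_db$seq[i]), "TAA", random_dna(180),
           sample_motif(b$consensus3, spec$motif_mut))
  }, character(1)), iep_db$id)
  bundle <- structure(list(spec = spec, classes = classes,
                           ancestors = ancestors,
                           decoy_ancestors = decoy_ancestors,
                           iep_db = iep_db, rt_db = rt_db,
                           reference_ieps = reference_ieps,
                           boundary = boundary, queries = queries,
                           curated_dna = curated_dna),
                      class = "reference_bundle")
  if (validate) validate_bundle(bundle)
  bundle
}

# generation-time self-consistency: every curated IEP's top-scoring hit among
# the other curated IEPs is of its own class family
validate_bundle <- function(bundle, scheme = scoring_scheme()) {
  db <- bundle$iep_db
  fam_of <- sub("_cur\\d+$", "", db$id)
  encs <- lapply(db$seq, aa_encode, scheme = scheme)
  for (i in seq_len(nrow(db))) {
    others <- setdiff(seq_len(nrow(db)), i)
    sc <- sw_score_multi_c(encs[others], encs[[i]], scheme$submat,
                           scheme$gap_open, scheme$gap_extend)
    top <- others[which.max(sc)]
    if (fam_of[top] != fam_of[i])
      stop("bundle self-consistency failed: top hit of ", db$id[i],
           " is ", db$id[top])
  }
  invisible(TRUE)
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("<reference_bundle> ", length(x$classes), " classes, ",
      nrow(x$iep_db), " curated IEPs, ", nrow(x$rt_db), " RT references, ",
      length(x$queries), " queries\n", sep = "")
  invisible(x)
}

# assemble a full intron DNA from parts; returns the sequence and the ORF
# interval (0-based half-open, including the stop codon) within the intron
assemble_intron <- function(protein, bclass, spec, bundle) {
  b <- bundle$boundary[[bclass]]
  five <- sample_motif(b$consensus5, spec$motif_mut)
  fill1 <- random_dna(sample(220:300, 1))
  spacer <- random_dna(sample(6:9, 1))
  orf <- paste0(reverse_translate(protein), "TAA")
  fill2 <- random_dna(sample(150:220, 1))
  three <- sample_motif(b$consensus3, spec$motif_mut)
  pre <- paste0(five, fill1, "AGGAGG", spacer)
  seq <- paste0(pre, orf, fill2, three)
  list(seq = seq, orf = c(nchar(pre), nchar(pre) + nchar(orf)))
}

#' Plant a synthetic genome corpus with ground truth
#'
#' Builds one genomic record per planted element: full-length introns for
#' every class (including the requested 95%-identity clusters, whose members
#' are mutated on disjoint position sets so every pairwise identity hits the
#' target exactly), plus decoys - 3'-truncated introns, single-nucleotide
#' frameshifts, premature stops, non-group-II RT ORFs, and twintrons (an
#' intron nested inside another). Elements are inserted at random positions
#' on a random strand; each record carries bacterial taxonomy.
#'
#' @param spec A [fixture_spec()].
#' @param bundle The matching [make_reference_bundle()].
#' @return List with `records` (list of `genomic_record`) and `truth`
#'   (data.frame: one row per planted element with coordinates on the source
#'   forward strand, 0-based half-open, the planted protein, and the
#'   expected final disposition).
#' @export
plant_genome <- function(spec, bundle) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(bundle, "reference_bundle"))
  set.seed(spec$seed + 1L)
  plan <- list()
  add <- function(kind, class, protein, cluster = NA_character_,
                  species = NULL) {
    i <- length(plan) + 1L
    plan[[i]] <<- list(kind = kind, class = class, protein = protein,
                       cluster = cluster, species = species)
  }
  for (cl in spec$classes) {
    for (i in seq_len(spec$introns_per_class))
      add("full", cl, mutate_protein(bundle$ancestors[[cl]],
                                     1 - spec$planted_identity))
  }
  for (ci in seq_along(spec$identity_clusters)) {
    cc <- spec$identity_clusters[[ci]]
    center <- mutate_protein(bundle$ancestors[[cc$class]],
                             1 - spec$planted_identity)
    L <- nchar(center)
    k <- round((1 - cc$identity) / 2 * (L - 1))
    pos_pool <- sample(2:L)
    species <- sprintf("Synthbacter cluster%d sp%d", ci,
                       rep_len(seq_len(cc$n_species), cc$size))
    for (j in seq_len(cc$size)) {
      positions <- pos_pool[((j - 1) * k + 1):(j * k)]
      add("full", cc$class, mutate_protein(center, 0, positions = positions),
          cluster = sprintf("cluster%d", ci), species = species[j])
    }
  }
  dk <- spec$decoys
  for (kind in names(dk)) {
    for (i in seq_len(dk[[kind]])) {
      if (kind == "non_gii_rt") {
        cat <- names(bundle$decoy_ancestors)[1 + (i - 1) %% length(bundle$decoy_ancestors)]
        add(kind, cat, mutate_protein(bundle$decoy_ancestors[[cat]], 0.10))
      } else {
        cl <- spec$classes[1 + (i - 1) %% length(spec$classes)]
        add(kind, cl, mutate_protein(bundle$ancestors[[cl]],
                                     1 - spec$planted_identity))
      }
    }
  }
  records <- vector("list", length(plan))
  truth <- vector("list", length(plan))
  genera <- c("Synthbacter", "Fixibacillus", "Mockococcus", "Planticola")
  for (i in seq_along(plan)) {
    el <- plan[[i]]
    acc <- sprintf("FIX%04d", i)
    species <- if (!is.null(el$species)) el$species
               else sprintf("%s intronicus str. %d", sample(genera, 1), i)
    disposition <- switch(el$kind,
      full = "folder_A", truncated = "missing_domains",
      frameshifted = "orf_not_intact", premature_stop = "orf_not_intact",
      non_gii_rt = "non_group_II_rt", twintron = "extra_domains")
    if (el$kind == "full") {
      asm <- assemble_intron(el$protein, el$class, spec, bundle)
    } else if (el$kind == "truncated") {
      asm <- assemble_intron(el$protein, el$class, spec, bundle)
      cut <- asm$orf[1] + 3L * round(0.55 * nchar(el$protein))
      asm$seq <- substr(asm$seq, 1, cut)
      asm$orf[2] <- cut
    } else if (el$kind == "frameshifted") {
      asm <- assemble_intron(el$protein, el$class, spec, bundle)
      at <- asm$orf[1] + 3L * round(0.5 * nchar(el$protein))
      asm$seq <- paste0(substr(asm$seq, 1, at), sample(c("A", "C", "G", "T"), 1),
                        substr(asm$seq, at + 1L, nchar(asm$seq)))
      asm$orf[2] <- asm$orf[2] + 1L
    } else if (el$kind == "premature_stop") {
      asm <- assemble_intron(el$protein, el$class, spec, bundle)
      at <- asm$orf[1] + 3L * round(0.6 * nchar(el$protein))
      asm$seq <- paste0(substr(asm$seq, 1, at), "TAA",
                        substr(asm$seq, at + 4L, nchar(asm$seq)))
    } else if (el$kind == "non_gii_rt") {
      orf <- paste0(reverse_translate(el$protein), "TAA")
      pre <- paste0(random_dna(40), "AGGAGG", random_dna(7))
      asm <- list(seq = paste0(pre, orf, random_dna(40)),
                  orf = c(nchar(pre), nchar(pre) + nchar(orf)))
    } else if (el$kind == "twintron") {
      outer <- assemble_intron(el$protein, el$class, spec, bundle)
      inner <- assemble_intron(mutate_protein(bundle$ancestors[[el$class]],
                                              1 - spec$planted_identity),
                               el$class, spec, bundle)
      at <- 100L  # inside the outer 5' ribozyme filler
      asm <- list(seq = paste0(substr(outer$seq, 1, at), inner$seq,
                               substr(outer$seq, at + 1L, nchar(outer$seq))),
                  orf = outer$orf + c(0L, nchar(inner$seq)))
      asm$orf[1] <- outer$orf[1] + nchar(inner$seq)
    }
    elen <- nchar(asm$seq)
    lo <- spec$flank + 100L
    hi <- spec$record_length - spec$flank - elen - 100L
    if (hi < lo) stop("record too short to host element of length ", elen)
    at <- sample(lo:hi, 1)
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "+") asm$seq else revcomp(asm$seq)
    dna <- paste0(random_dna(at), ins,
                  random_dna(spec$record_length - at - elen))
    records[[i]] <- genomic_record(
      accession = acc, version = paste0(acc, ".1"), sequence = dna,
      taxonomy_lineage = c("Bacteria", "Synthbacteria", "Fixturales"),
      organism = species)
    orf_src <- if (strand == "+") at + asm$orf
               else c(at + elen - asm$orf[2], at + elen - asm$orf[1])
    truth[[i]] <- data.frame(
      element_id = sprintf("el%03d", i), accession = acc, kind = el$kind,
      class = el$class, species = species, strand = strand,
      intron_start = at, intron_end = at + elen,
      orf_start = orf_src[1], orf_end = orf_src[2],
      protein = el$protein, cluster = el$cluster,
      disposition = disposition, stringsAsFactors = FALSE)
  }
  names(records) <- vapply(records, `[[`, character(1), "accession")
  list(records = records, truth = do.call(rbind, truth))
}

#' Generate the complete fixture corpus
#'
#' @param spec A [fixture_spec()].
#' @param validate Passed to [make_reference_bundle()].
#' @return List with `bundle`, `records`, `truth`.
#' @export
make_fixture_corpus <- function(spec = fixture_spec(), validate = TRUE) {
  bundle <- make_reference_bundle(spec, validate = validate)
  planted <- plant_genome(spec, bundle)
  list(bundle = bundle, records = planted$records, truth = planted$truth)
}

#' Write a fixture corpus to disk
#'
#' GenBank records are concatenated per taxonomy bucket; the truth table is
#' written as TSV and BED; reference sets as FASTA + TSV sidecars.
#'
#' @param corpus From [make_fixture_corpus()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  buckets <- vapply(corpus$records, classify_taxon, character(1))
  for (b in unique(buckets)) {
    write_genbank(corpus$records[buckets == b],
                  file.path(dir, paste0(b, ".gb")))
  }
  write.table(corpus$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bed <- corpus$truth[, c("accession", "intron_start", "intron_end",
                          "element_id", "kind", "strand")]
  write.table(bed, file.path(dir, "truth.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_reference_set(corpus$bundle$rt_db, file.path(dir, "rt_db"))
  write_reference_set(corpus$bundle$iep_db, file.path(dir, "iep_db"))
  write_fasta(corpus$bundle$queries, file.path(dir, "queries.fasta"))
  invisible(dir)
}
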