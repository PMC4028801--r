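#' Pipeline configuration
#'
#' All tunable thresholds of the discovery pipeline with their defaults: the
#' translated-search E-value cutoff (1e-20), flank length (3 kb per side),
#' the RT vote threshold (all top three matches must be group II), the
#' boundary tier floor (high), the intron length bounds, and the redundancy
#' grouping distance (0.061 substitutions/site, the empirical 95%-identity
#' cutoff).
#'
#' @param evalue_cutoff E-value cutoff of the initial translated search.
#' @param flank_nt Flanking sequence per side when windows are cut.
#' @param rt_vote_threshold Group-II votes among top 3 needed to proceed.
#' @param include_possible_rts Also keep `possible` RT verdicts.
#' @param screen_evalue E-value ceiling for screening/alignment stages.
#' @param tier_minimum Minimum boundary tier for resolution.
#' @param admit_best_single Admit the single best medium/low boundary on a
#'   side lacking a high-tier one.
#' @param tier_thresholds Named z-score tier cutoffs.
#' @param length_bounds Allowed intron length (nt).
#' @param distance_threshold Single-linkage grouping distance.
#' @param coverage_frac,max_gap_codons ORF intactness settings.
#' @param buckets Taxonomy buckets retained after download/classification.
#' @param cal_seed Seed for boundary-profile background calibration.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(evalue_cutoff = 1e-20, flank_nt = 3000L,
                            rt_vote_threshold = 3L,
                            include_possible_rts = FALSE,
                            screen_evalue = 1e-5,
                            tier_minimum = "high",
                            admit_best_single = FALSE,
                            tier_thresholds = c(high = 6, medium = 4, low = 2.5),
                            length_bounds = c(400L, 8000L),
                            distance_threshold = 0.061,
                            coverage_frac = 0.95, max_gap_codons = 2L,
                            buckets = "bacteria_archaea",
                            cal_seed = 1003L) {
  stopifnot(evalue_cutoff > 0, flank_nt > 0, rt_vote_threshold >= 1,
            distance_threshold > 0, length_bounds[1] > 0,
            length_bounds[2] > length_bounds[1])
  structure(as.list(environment()), class = "pipeline_config")
}

#' Initialize pipeline state
#'
#' @param records List of `genomic_record` (the corpus).
#' @param bundle A `reference_bundle` (or equivalent list carrying `queries`,
#'   `rt_db`, `iep_db`, `reference_ieps`, `boundary`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for the storage tree; when set, every
#'   stage serializes its outputs under `out_dir/storage/<n>`.
#' @param scheme A [scoring_scheme()].
#' @return A `pipeline_state` at stage -1 (nothing run).
#' @export
pipeline_state <- function(records, bundle, config = pipeline_config(),
                           out_dir = NULL, scheme = scoring_scheme()) {
  names(records) <- vapply(records, `[[`, character(1), "accession")
  structure(list(records = records, bundle = bundle, config = config,
                 scheme = scheme, out_dir = out_dir, stage = -1L,
                 candidates = list(), profiles = NULL,
                 set_aside = list(), folder_a = NULL, folder_b = NULL),
            class = "pipeline_state")
}

#' @export
print.pipeline_state <- function(x, ...) {
  cat("<pipeline_state> stage ", x$stage, ", ",
      sum(vapply(x$candidates, function(cc) is.na(cc$set_aside_reason), logical(1))),
      " retained / ", length(x$candidates), " candidates\n", sep = "")
  invisible(x)
}

retained <- function(state) {
  Filter(function(cc) is.na(cc$set_aside_reason), state$candidates)
}

set_aside <- function(state, id, stage, reason) {
  state$candidates[[id]]$set_aside_reason <- reason
  state$candidates[[id]]$set_aside_stage <- stage
  state
}

stage_names <- c("collect", "filter_rts", "find_class", "find_orf_domains",
                 "find_orf", "find_boundaries", "generate_rna", "group")

#' Run one pipeline stage
#'
#' Stages follow the storage-folder state machine: 0 collect (translated
#' search, pooling, download/bucketing, window extraction), 1 RT filtering,
#' 2 class assignment, 3 ORF domain inventory, 4 ORF intactness and IEP
#' assignment, 5 boundary scanning, 6 boundary resolution and intron
#' generation, 7 redundancy grouping and prototype selection. Each stage
#' only ever shrinks the retained set; candidates leaving the main track are
#' kept with a set-aside reason. With an `out_dir`, outputs are serialized
#' under `storage/<n>`.
#'
#' @param state A `pipeline_state` with stage `n - 1` complete.
#' @param n Stage number, 0-7.
#' @return The updated state.
#' @export
run_stage <- function(state, n) {
  stopifnot(inherits(state, "pipeline_state"), n %in% 0:7)
  if (state$stage < n - 1)
    stop("cannot run stage ", n, ": stage ", n - 1, " not complete (at stage ",
         state$stage, ")")
  if (!is.null(state$out_dir) && n > 0) {
    prev <- file.path(state$out_dir, "storage", n - 1)
    if (!dir.exists(prev)) stop("missing prior stage output: ", prev)
  }
  state <- switch(as.character(n),
                  "0" = stage_collect(state), "1" = stage_filter_rts(state),
                  "2" = stage_find_class(state), "3" = stage_domains(state),
                  "4" = stage_orf(state), "5" = stage_boundaries(state),
                  "6" = stage_rna(state), "7" = stage_group(state))
  state$stage <- max(state$stage, as.integer(n))
  if (!is.null(state$out_dir)) write_stage(state, n)
  state
}

#' Run the whole pipeline
#'
#' @param records,bundle,config,out_dir,scheme See [pipeline_state()].
#' @return The final `pipeline_state`; `folder_a` holds all full-length
#'   putatively functional introns, `folder_b` the non-redundant prototype
#'   set (including per-species prototypes within a group).
#' @export
run_all <- function(records, bundle, config = pipeline_config(),
                    out_dir = NULL, scheme = scoring_scheme()) {
  state <- pipeline_state(records, bundle, config, out_dir, scheme)
  if (!length(records)) {
    warning("empty corpus; empty outputs")
    state$stage <- 7L
    state$folder_a <- candidate_table(state, character(0))
    state$folder_b <- state$folder_a
    return(state)
  }
  for (n in 0:7) state <- run_stage(state, n)
  state
}

# --- stage implementations -------------------------------------------------

stage_collect <- function(state) {
  cfg <- state$config
  keep <- vapply(state$records, function(r)
    classify_taxon(r) %in% cfg$buckets, logical(1))
  hsps <- list()
  for (r in state$records[keep]) {
    # translate and encode each record once for all queries
    frames <- six_frame_translate(r$sequence)
    frames$enc <- I(lapply(frames$protein, aa_encode, scheme = state$scheme))
    for (qi in seq_along(state$bundle$queries)) {
      h <- translated_search(state$bundle$queries[[qi]], r, state$scheme,
                             evalue_cutoff = cfg$evalue_cutoff,
                             query_id = names(state$bundle$queries)[qi],
                             frames = frames)
      if (nrow(h)) hsps[[length(hsps) + 1L]] <- h
    }
  }
  loci <- pool_hits(if (length(hsps)) do.call(rbind, hsps) else
    data.frame(query_id = character(), subject_id = character(),
               s_start = integer(), s_end = integer(), strand = character(),
               frame = integer(), q_start = integer(), q_end = integer(),
               raw_score = numeric(), bit_score = numeric(),
               evalue = numeric(), has_internal_stop = logical()))
  state$loci <- loci
  cands <- list()
  if (nrow(loci)) for (i in seq_len(nrow(loci))) {
    rec <- state$records[[loci$accession[i]]]
    win <- extract_window(rec, c(loci$start[i], loci$end[i]), loci$strand[i],
                          flank_nt = cfg$flank_nt)
    cands[[win$candidate_id]] <- list(
      candidate_id = win$candidate_id, accession = rec$accession,
      species = rec$organism, taxon_bucket = classify_taxon(rec),
      locus = c(loci$start[i], loci$end[i]), strand = loci$strand[i],
      best_evalue = loci$best_evalue[i],
      supporting_queries = loci$supporting_queries[i],
      window = win, set_aside_reason = NA_character_,
      set_aside_stage = NA_integer_)
  }
  state$candidates <- cands
  state
}

stage_filter_rts <- function(state) {
  cfg <- state$config
  for (cc in retained(state)) {
    v <- rt_verdict(cc$window, state$bundle$rt_db, state$scheme,
                    evalue_max = cfg$screen_evalue,
                    vote_threshold = cfg$rt_vote_threshold)
    state$candidates[[cc$candidate_id]]$rt <- v
    ok <- v$value == "probable" ||
      (cfg$include_possible_rts && v$value == "possible")
    if (!ok) state <- set_aside(state, cc$candidate_id, 1L, "non_group_II_rt")
  }
  state
}

stage_find_class <- function(state) {
  cfg <- state$config
  for (cc in retained(state)) {
    a <- assign_class(cc$window, state$bundle$iep_db, state$scheme,
                      evalue_max = cfg$screen_evalue)
    state$candidates[[cc$candidate_id]]$class <- a
    if (is.na(a$closest_relative_id))
      state <- set_aside(state, cc$candidate_id, 2L, "no_curated_match")
  }
  state
}

# choose the reference IEP for a candidate: its class (CL decided between
# CL1/CL2 by better score against the window); undefined/unclassified get
# the best-scoring reference overall
pick_reference <- function(state, cc) {
  refs <- state$bundle$reference_ieps
  cls <- cc$class$intron_class
  pool <- if (cls == "CL") refs[intersect(c("CL1", "CL2"), names(refs))]
          else if (cls %in% names(refs)) refs[cls]
          else refs
  if (length(pool) == 1) return(pool[[1]])
  db <- reference_set(id = names(pool),
                      seq = vapply(pool, `[[`, character(1), "seq"))
  ranked <- rank_matches(cc$window, db, state$scheme, evalue_max = Inf)
  if (!nrow(ranked)) return(pool[[1]])
  pool[[ranked$id[1]]]
}

stage_domains <- function(state) {
  cfg <- state$config
  for (cc in retained(state)) {
    ref <- pick_reference(state, cc)
    inv <- domain_inventory(cc$window, ref, state$scheme,
                            evalue_max = cfg$screen_evalue)
    state$candidates[[cc$candidate_id]]$reference_label <- ref$class_label
    state$candidates[[cc$candidate_id]]$inventory <- inv
    if (inv$category != "normal")
      state <- set_aside(state, cc$candidate_id, 3L,
                         paste0(inv$category, "_domains"))
  }
  state
}

# interval of the relative spanning domains 0 to X, mapped from the class
# reference's proxy positions through a pairwise alignment
relative_domain_span <- function(relative_seq, reference, scheme) {
  sp <- try(suppressWarnings({
    seg <- excise_orf_region(relative_seq, reference, scheme)
    from <- regexpr(seg, relative_seq, fixed = TRUE)
    c(from, from + nchar(seg) - 1L)
  }), silent = TRUE)
  if (inherits(sp, "try-error") || sp[1] < 1) c(1L, nchar(relative_seq)) else sp
}

stage_orf <- function(state) {
  cfg <- state$config
  for (cc in retained(state)) {
    rel_id <- cc$class$closest_relative_id
    rel_seq <- state$bundle$iep_db$seq[state$bundle$iep_db$id == rel_id]
    ref <- state$bundle$reference_ieps[[cc$reference_label]]
    span <- relative_domain_span(rel_seq, ref, state$scheme)
    st <- orf_intactness(cc$window, rel_seq, state$scheme, domain_span = span,
                         coverage_frac = cfg$coverage_frac,
                         max_gap_codons = cfg$max_gap_codons,
                         evalue_max = cfg$screen_evalue)
    state$candidates[[cc$candidate_id]]$orf_status <- st
    if (!st$intact) {
      reason <- if ("multiple_locations" %in% st$issues) "multiple_orf_locations"
                else "orf_not_intact"
      state <- set_aside(state, cc$candidate_id, 4L, reason)
      next
    }
    iep <- assign_iep(cc$window, st, state$scheme)
    state$candidates[[cc$candidate_id]]$iep <- iep
    if (is.na(iep$start_pos_window))
      state <- set_aside(state, cc$candidate_id, 4L, "no_start_codon")
  }
  state
}

build_profiles <- function(state) {
  cfg <- state$config
  lapply(state$bundle$boundary, function(b) list(
    five = build_profile(b$training5, class_label = "", side = "five_prime",
                         cal_seed = cfg$cal_seed),
    three = build_profile(b$training3, class_label = "", side = "three_prime",
                          cal_seed = cfg$cal_seed)))
}

stage_boundaries <- function(state) {
  cfg <- state$config
  if (is.null(state$profiles)) state$profiles <- build_profiles(state)
  for (cc in retained(state)) {
    cls <- cc$class$intron_class
    call <- if (cls %in% names(state$profiles)) {
      p <- state$profiles[[cls]]
      scan_boundaries(cc$window, p$five, p$three, cfg$tier_thresholds)
    } else {
      scan_boundaries_all(cc$window, state$profiles, cfg$tier_thresholds)
    }
    state$candidates[[cc$candidate_id]]$boundary_call <- call
  }
  state
}

stage_rna <- function(state) {
  cfg <- state$config
  for (cc in retained(state)) {
    ic <- resolve_boundaries(cc$boundary_call, cc$iep$orf_span,
                             length_bounds = cfg$length_bounds,
                             tier_minimum = cfg$tier_minimum,
                             admit_best_single = cfg$admit_best_single)
    if (ic$status == "have_boundaries")
      ic <- generate_intron(cc$window, ic)
    state$candidates[[cc$candidate_id]]$intron_call <- ic
    if (ic$status != "have_boundaries")
      state <- set_aside(state, cc$candidate_id, 6L, "ambiguous_boundaries")
  }
  state
}

stage_group <- function(state) {
  cfg <- state$config
  keep <- retained(state)
  md <- data.frame(id = vapply(keep, `[[`, character(1), "candidate_id"),
                   species = vapply(keep, `[[`, character(1), "species"),
                   intron_length = vapply(keep, function(cc)
                     cc$intron_call$length, numeric(1)),
                   class = vapply(keep, function(cc)
                     cc$class$intron_class, character(1)),
                   stringsAsFactors = FALSE)
  gi <- 0L
  for (cls in sort(unique(md$class))) {
    ids <- md$id[md$class == cls]
    regions <- vapply(ids, function(id) {
      cc <- state$candidates[[id]]
      ref <- state$bundle$reference_ieps[[cc$reference_label]]
      excise_orf_region(cc$iep$protein, ref, state$scheme)
    }, character(1))
    aligned <- align_orf_region(regions)
    d <- distance_matrix(aligned)
    groups <- group_by_threshold(d, cfg$distance_threshold)
    for (g in groups) {
      gi <- gi + 1L
      gid <- sprintf("%s_G%03d", cls, gi)
      proto <- select_prototypes(g$member_ids, md)
      for (j in seq_len(nrow(proto))) {
        id <- proto$id[j]
        state$candidates[[id]]$group_id <- gid
        state$candidates[[id]]$is_prototype <- proto$prototype[j]
        state$candidates[[id]]$is_primary <- proto$primary[j]
      }
    }
  }
  ids <- md$id
  state$folder_a <- candidate_table(state, ids)
  proto_ids <- ids[vapply(ids, function(id)
    isTRUE(state$candidates[[id]]$is_prototype), logical(1))]
  state$folder_b <- candidate_table(state, proto_ids)
  state
}

# flat summary table for a set of candidate ids
candidate_table <- function(state, ids) {
  cols <- c("candidate_id", "accession", "species", "strand")
  if (!length(ids)) {
    out <- data.frame(candidate_id = character(), accession = character(),
                      species = character(), strand = character(),
                      class = character(), group_id = character(),
                      prototype = logical(), intron_start_w = integer(),
                      intron_end_w = integer(), intron_length = integer(),
                      tier = character(), intron_seq = character(),
                      iep = character(), stringsAsFactors = FALSE)
    return(out)
  }
  do.call(rbind, lapply(ids, function(id) {
    cc <- state$candidates[[id]]
    data.frame(candidate_id = cc$candidate_id, accession = cc$accession,
               species = cc$species, strand = cc$strand,
               class = cc$class$intron_class,
               group_id = if (is.null(cc$group_id)) NA_character_ else cc$group_id,
               prototype = isTRUE(cc$is_prototype),
               intron_start_w = cc$intron_call$start_5,
               intron_end_w = cc$intron_call$end_3,
               intron_length = cc$intron_call$length,
               tier = cc$intron_call$tier,
               intron_seq = cc$intron_call$intron_seq,
               iep = cc$iep$protein, stringsAsFactors = FALSE)
  }))
}

# --- storage serialization -------------------------------------------------

stage_snapshot <- function(state, n) {
  cands <- state$candidates
  if (!length(cands)) {
    return(data.frame(candidate_id = character(), stage = integer(),
                      retained = logical(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(cands, function(cc) data.frame(
    candidate_id = cc$candidate_id, accession = cc$accession,
    species = cc$species, start = cc$locus[1], end = cc$locus[2],
    strand = cc$strand,
    retained = is.na(cc$set_aside_reason),
    set_aside_reason = ifelse(is.na(cc$set_aside_reason), "",
                              cc$set_aside_reason),
    rt_verdict = if (!is.null(cc$rt)) cc$rt$value else "",
    class = if (!is.null(cc$class)) cc$class$intron_class else "",
    closest_relative = if (!is.null(cc$class) &&
                           !is.na(cc$class$closest_relative_id))
      cc$class$closest_relative_id else "",
    domain_category = if (!is.null(cc$inventory)) cc$inventory$category else "",
    orf_intact = if (!is.null(cc$orf_status)) cc$orf_status$intact else NA,
    boundary_bin = if (!is.null(cc$boundary_call)) cc$boundary_call$bin else "",
    boundary_tier = if (!is.null(cc$boundary_call) &&
                        !is.na(cc$boundary_call$tier))
      cc$boundary_call$tier else "",
    intron_status = if (!is.null(cc$intron_call)) cc$intron_call$status else "",
    intron_start_w = if (!is.null(cc$intron_call) &&
                         !is.na(cc$intron_call$start_5))
      cc$intron_call$start_5 else NA_integer_,
    intron_end_w = if (!is.null(cc$intron_call) &&
                       !is.na(cc$intron_call$end_3))
      cc$intron_call$end_3 else NA_integer_,
    group_id = if (!is.null(cc$group_id)) cc$group_id else "",
    prototype = isTRUE(cc$is_prototype),
    stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df[order(df$candidate_id), , drop = FALSE]
}

write_stage <- function(state, n) {
  dir <- file.path(state$out_dir, "storage", n)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snap <- stage_snapshot(state, n)
  write.table(snap, file.path(dir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (n == 0 && length(state$candidates)) {
    write_genbank(state$records, file.path(dir, "records.gb"))
    wins <- lapply(state$candidates, function(cc) cc$window$window_seq)
    write_fasta(setNames(unlist(wins), names(wins)),
                file.path(dir, "windows.fasta"))
  }
  if (n == 4) {
    keep <- retained(state)
    ieps <- vapply(keep, function(cc) cc$iep$protein, character(1))
    if (length(ieps)) write_fasta(ieps, file.path(dir, "ieps.fasta"))
  }
  if (n == 6) {
    keep <- retained(state)
    if (length(keep)) {
      introns <- vapply(keep, function(cc) cc$intron_call$intron_seq,
                        character(1))
      write_fasta(introns, file.path(dir, "introns.fasta"))
      write_intron_annotations(state, keep, dir)
    }
  }
  if (n == 7) {
    write_final_folders(state)
  }
  invisible(dir)
}

# intron coordinates on the source records, as GFF3 and BED
write_intron_annotations <- function(state, keep, dir) {
  rows <- lapply(keep, function(cc) {
    w <- cc$window
    src <- sort(window_to_source(w, c(cc$intron_call$start_5,
                                      cc$intron_call$end_3)))
    data.frame(acc = cc$accession, start0 = src[1], end1 = src[2] + 1L,
               id = cc$candidate_id, strand = cc$strand,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  bed <- ann[, c("acc", "start0", "end1", "id", "strand")]
  write.table(cbind(bed[, 1:4], score = 0, strand = bed$strand),
              file.path(dir, "introns.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  gff <- sprintf("%s\tintronminer\tgroup_II_intron\t%d\t%d\t.\t%s\t.\tID=%s",
                 ann$acc, ann$start0 + 1L, ann$end1, ann$strand, ann$id)
  writeLines(c("##gff-version 3", gff), file.path(dir, "introns.gff3"))
}

write_final_folders <- function(state) {
  for (fold in c("full_length_introns", "prototypes")) {
    dir <- file.path(state$out_dir, fold)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tab <- if (fold == "full_length_introns") state$folder_a else state$folder_b
    write.table(tab[, setdiff(names(tab), c("intron_seq", "iep"))],
                file.path(dir, "introns.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (nrow(tab)) {
      write_fasta(setNames(tab$intron_seq, tab$candidate_id),
                  file.path(dir, "introns.fasta"))
      write_fasta(setNames(tab$iep, tab$candidate_id),
                  file.path(dir, "ieps.fasta"))
    }
  }
}

#' Per-stage summary report
#'
#' @param state A `pipeline_state`.
#' @param path Optional basename; `<path>.tsv` and `<path>.json` are written.
#' @return Data.frame with per-stage retained counts and set-aside reasons.
#' @export
report <- function(state, path = NULL) {
  cands <- state$candidates
  total <- length(cands)
  rows <- lapply(0:state$stage, function(n) {
    out_n <- vapply(cands, function(cc)
      !is.na(cc$set_aside_reason) && cc$set_aside_stage <= n, logical(1))
    reasons <- vapply(cands[out_n], `[[`, character(1), "set_aside_reason")
    data.frame(stage = n, name = stage_names[n + 1],
               retained = total - sum(out_n),
               set_aside = if (length(reasons))
                 paste(sprintf("%s:%d", names(table(reasons)), table(reasons)),
                       collapse = ",") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(out, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(out, paste0(path, ".json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
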