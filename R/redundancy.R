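#' Excise the domain 0-to-X region of an IEP
#'
#' Aligns the class reference to the candidate IEP and cuts the candidate
#' segment matching the reference interval from the domain-0 proxy to the
#' domain-X proxy (extrapolating through local-alignment clipping at the
#' ends). Redundancy grouping operates on this region only.
#'
#' @param protein Candidate IEP sequence.
#' @param reference A [reference_iep()] with `0` and `X` proxies.
#' @param scheme A [scoring_scheme()].
#' @return The excised protein segment.
#' @export
excise_orf_region <- function(protein, reference, scheme = scoring_scheme()) {
  stopifnot(all(c("0", "X") %in% names(reference$proxy_positions)))
  al <- local_align(reference$seq, protein, scheme)
  if (al$score <= 0) stop("reference does not align to candidate IEP")
  pairs <- al$pairs
  q2s <- function(qpos) {
    hit <- which(pairs[1, ] == qpos & pairs[2, ] > 0)
    if (length(hit)) return(pairs[2, hit[1]])
    # extrapolate past clipped termini assuming no terminal gaps
    if (qpos < al$q_start) return(al$s_start - (al$q_start - qpos))
    if (qpos > al$q_end) return(al$s_end + (qpos - al$q_end))
    NA_integer_
  }
  from <- q2s(reference$proxy_positions[["0"]] + 1L)
  to <- q2s(reference$proxy_positions[["X"]] + 1L)
  if (is.na(from) || is.na(to)) stop("proxy positions fall in alignment gaps")
  substr(protein, max(1L, from), min(nchar(protein), to))
}

#' Progressive multiple alignment of IEP region sequences
#'
#' Delegates to the mafft command-line aligner (progressive alignment over a
#' guide tree). A single sequence short-circuits.
#'
#' @param seqs Named character vector of protein sequences.
#' @return Named character vector of aligned (gapped) sequences.
#' @export
align_orf_region <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  if (length(seqs) < 2) return(seqs)
  if (length(unique(nchar(seqs))) == 1 && !nzchar(Sys.which("mafft"))) {
    return(seqs)  # equal-length, substitution-only inputs are already columnar
  }
  if (!nzchar(Sys.which("mafft"))) stop("mafft not found on PATH")
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)))
  write_fasta(seqs, fin)
  status <- system2("mafft", c("--auto", "--quiet", "--amino", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed with status ", status)
  out <- toupper(read_fasta(fout))
  out[names(seqs)]
}

jtt_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    jtt <- get(".JTT", envir = getNamespace("phangorn"))
    bf <- jtt$bf / sum(jtt$bf)
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- jtt$Q
    S <- S + t(S)
    Q <- S %*% diag(bf)
    diag(Q) <- -rowSums(Q)
    Q <- Q / sum(-diag(Q) * bf)           # mean substitution rate 1
    B <- diag(sqrt(bf)) %*% Q %*% diag(1 / sqrt(bf))
    ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
    cache <<- list(bf = bf, ord = toupper(names(jtt$bf)),
                   vec = diag(1 / sqrt(bf)) %*% ev$vectors,
                   inv = t(ev$vectors) %*% diag(sqrt(bf)),
                   val = ev$values)
    cache
  }
})

jtt_pmatrix <- function(t) {
  m <- jtt_model()
  P <- m$vec %*% diag(exp(m$val * t)) %*% m$inv
  pmax(P, 1e-12)
}

#' Maximum-likelihood protein distance under the JTT model
#'
#' Distance in expected substitutions per site between two aligned protein
#' sequences, maximizing the likelihood of the JTT substitution model over
#' the branch length (1-D optimization). Columns with a gap or non-standard
#' residue in either sequence are excluded pairwise. This is the
#' PROTDIST-style distance the redundancy grouping operates on.
#'
#' @param a,b Aligned protein strings of equal length.
#' @param upper Upper bound of the optimization interval.
#' @return Non-negative distance (substitutions/site).
#' @export
ml_distance <- function(a, b, upper = 10) {
  stopifnot(nchar(a) == nchar(b))
  m <- jtt_model()
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ia <- match(ca, m$ord); ib <- match(cb, m$ord)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stop("no comparable columns between sequences")
  ia <- ia[ok]; ib <- ib[ok]
  if (all(ia == ib)) return(0)
  nll <- function(t) {
    P <- jtt_pmatrix(t)
    -sum(log(m$bf[ia] * P[cbind(ia, ib)]))
  }
  opt <- stats::optimize(nll, c(1e-6, upper))
  if (nll(1e-8) <= opt$objective) return(0)
  opt$minimum
}

#' Pairwise ML distance matrix
#'
#' @param seqs Named character vector of aligned protein sequences (equal
#'   length, e.g. from [align_orf_region()]).
#' @return A symmetric matrix of JTT ML distances with zero diagonal.
#' @export
distance_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- ml_distance(seqs[[i]], seqs[[j]])
  }
  d
}

#' Group candidates by distance threshold (single linkage)
#'
#' Two candidates belong to the same ~95%-identity group when they are
#' connected by a chain of pairwise distances below the threshold. The
#' default 0.061 substitutions/site is the pipeline's empirical cutoff
#' corresponding to 95% protein identity under the JTT distance (a 95%
#' identical pair sits near 0.052).
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param threshold Linking distance (default 0.061).
#' @return List of `identity_group` objects (fields `group_id`,
#'   `member_ids`), ordered by smallest member id; groups partition the ids.
#' @export
group_by_threshold <- function(d, threshold = 0.061) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  adj <- d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  ids <- rownames(d)
  groups <- split(ids, comp$membership)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  lapply(seq_along(groups), function(i)
    structure(list(group_id = sprintf("G%03d", i), member_ids = groups[[i]]),
              class = "identity_group"))
}

#' @export
print.identity_group <- function(x, ...) {
  cat("<identity_group> ", x$group_id, ": ",
      paste(x$member_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select group prototypes
#'
#' One primary prototype per group - the longest intact intron, ties broken
#' by lexicographic candidate id - plus one prototype per distinct species
#' in the group, so cross-species redundancy is kept visible in the final
#' set.
#'
#' @param group An `identity_group` (or character vector of member ids).
#' @param metadata Data.frame with columns `id`, `species` and
#'   `intron_length` covering the members.
#' @return Data.frame of members with logical columns `prototype` and
#'   `primary`.
#' @export
select_prototypes <- function(group, metadata) {
  ids <- if (inherits(group, "identity_group")) group$member_ids else group
  stopifnot(all(ids %in% metadata$id))
  md <- metadata[match(ids, metadata$id), , drop = FALSE]
  best_of <- function(rows) rows$id[order(-rows$intron_length, rows$id)][1]
  primary <- best_of(md)
  per_species <- vapply(split(md, md$species), best_of, character(1))
  md$primary <- md$id == primary
  md$prototype <- md$id %in% union(primary, per_species)
  rownames(md) <- NULL
  md
}
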