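#' Protein scoring scheme for the translated search engine
#'
#' Bundles a substitution matrix, affine gap penalties and Karlin-Altschul
#' statistical parameters. The defaults (BLOSUM62, gap open 11, gap extend 1,
#' lambda 0.267, K 0.041) are the standard gapped protein-search parameters,
#' so E-values are on the familiar scale.
#'
#' @param matrix Substitution matrix name (looked up in Biostrings data) or a
#'   square numeric matrix with residue letters as dimnames.
#' @param gap_open,gap_extend Non-negative gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters for the chosen matrix/penalties.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0)
  alphabet <- rownames(matrix)
  structure(list(submat = matrix, alphabet = alphabet,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", nrow(x$submat), "x", ncol(x$submat),
      " matrix, gap ", x$gap_open, "/", x$gap_extend,
      ", lambda=", x$lambda, ", K=", x$K, "\n", sep = "")
  invisible(x)
}

# Encode a protein string as 0-based codes into the scheme alphabet.
# Unknown letters map to 'X' (near-neutral) so ambiguity never fabricates
# similarity.
aa_encode <- function(protein, scheme) {
  ch <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  idx <- match(ch, scheme$alphabet)
  xi <- match("X", scheme$alphabet)
  idx[is.na(idx)] <- xi
  as.integer(idx - 1L)
}

#' Bit score and E-value under Karlin-Altschul statistics
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' subject length, both in residues.
#'
#' @param raw_score Raw alignment score.
#' @param m,n Query and subject lengths (residues).
#' @param scheme A [scoring_scheme()].
#' @return Numeric E-value (or bit score).
#' @export
hsp_evalue <- function(raw_score, m, n, scheme) {
  scheme$K * m * n * exp(-scheme$lambda * raw_score)
}

#' @rdname hsp_evalue
#' @export
bit_score <- function(raw_score, scheme) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}
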