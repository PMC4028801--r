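# Independent oracles, coded from first principles and kept separate from the
# package's implementations.

AAS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_aa <- function(n) paste(sample(AAS, n, replace = TRUE), collapse = "")

# substitute exactly k positions (never the first) with different residues
mutate_k <- function(protein, k) {
  ch <- strsplit(protein, "")[[1]]
  at <- sample(2:length(ch), k)
  for (i in at) ch[i] <- sample(setdiff(AAS, ch[i]), 1)
  paste(ch, collapse = "")
}

# Exhaustive affine-gap local alignment score by the explicit 3-matrix
# recursion (gap of length L costs go + L * ge).
oracle_sw_score <- function(q, s, submat, go = 11, ge = 1) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 1:m) for (j in 1:n) {
    M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + submat[qc[i], sc[j]]
    if (M[i + 1, j + 1] < 0) M[i + 1, j + 1] <- 0
    X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# JTT rate machinery built directly from phangorn's published rates; the
# distance estimate below uses plain grid search, independent of the
# package's 1-D optimizer.
oracle_jtt <- local({
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
    Q <- Q / sum(-diag(Q) * bf)
    cache <<- list(Q = Q, bf = bf, ord = toupper(names(jtt$bf)))
    cache
  }
})

# matrix exponential by scaling-and-squaring on a truncated series
oracle_expm <- function(A, k = 8L, terms = 12L) {
  B <- A / 2^k
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (i in 1:terms) { term <- term %*% B / i; P <- P + term }
  for (i in seq_len(k)) P <- P %*% P
  P
}

oracle_ml_distance <- function(a, b, grid = seq(0.0005, 2, by = 0.0005)) {
  m <- oracle_jtt()
  ia <- match(strsplit(a, "")[[1]], m$ord)
  ib <- match(strsplit(b, "")[[1]], m$ord)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  tab <- table(ia, ib)
  idx <- cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])
  ll <- vapply(grid, function(t) {
    P <- oracle_expm(m$Q * t)
    sum(tab * log(pmax(m$bf[idx[, 1]] * P[idx], 1e-300)))
  }, numeric(1))
  grid[which.max(ll)]
}

# brute-force connected components under a distance threshold
oracle_components <- function(d, threshold) {
  n <- nrow(d)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in 1:n) for (j in 1:n) {
      if (i != j && d[i, j] < threshold && comp[j] != comp[i]) {
        old <- comp[j]
        comp[comp == old] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(rownames(d), comp)
}

# sweep-line interval union
oracle_interval_union <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out <- list(c(starts[1], ends[1]))
  for (i in seq_along(starts)[-1]) {
    last <- out[[length(out)]]
    if (starts[i] < last[2]) out[[length(out)]] <- c(last[1], max(last[2], ends[i]))
    else out[[length(out) + 1L]] <- c(starts[i], ends[i])
  }
  out
}

protein_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}
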