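#' Build a class-specific boundary profile
#'
#' Per-column emission distributions over A/C/G/T are estimated from an
#' aligned, equal-length block of training boundary sequences with a Laplace
#' pseudocount, giving log-odds emissions against uniform background. The
#' profile is calibrated against seeded random windows: the distribution of
#' the per-window maximum score of each scorer is summarized (mean, sd) and
#' a Gumbel scale parameter is derived so the calibration transfers to
#' windows of other lengths (the maximum over n offsets shifts by
#' `beta * log(n / n0)`).
#'
#' @param training Character vector (>= 2) of equal-length DNA strings, one
#'   aligned block per boundary instance; 5' blocks start at the intron's
#'   first nucleotide, 3' blocks end at its last.
#' @param class_label Intron class the profile belongs to.
#' @param side `"five_prime"` or `"three_prime"`.
#' @param pseudocount Laplace pseudocount per base (default 1).
#' @param bg_n,bg_len Number and length of random calibration windows.
#' @param cal_seed RNG seed for calibration (fixed so identical inputs give
#'   identical profiles).
#' @param del_pen,ins_pen,band Scanner gap penalties (nats) and band width.
#' @return A `boundary_profile`.
#' @export
build_profile <- function(training, class_label, side,
                          pseudocount = 1, bg_n = 1000L, bg_len = 300L,
                          cal_seed = 1003L, del_pen = 3, ins_pen = 3,
                          band = 2L) {
  stopifnot(length(training) >= 2, side %in% c("five_prime", "three_prime"))
  lens <- nchar(training)
  if (length(unique(lens)) != 1) stop("ragged training alignment")
  P <- lens[1]
  bases <- c("A", "C", "G", "T")
  counts <- matrix(pseudocount, 4, P, dimnames = list(bases, NULL))
  for (s in training) {
    ch <- strsplit(toupper(s), "")[[1]]
    idx <- match(ch, bases)
    ok <- !is.na(idx)
    counts[cbind(idx[ok], which(ok))] <- counts[cbind(idx[ok], which(ok))] + 1
  }
  probs <- sweep(counts, 2, colSums(counts), "/")
  logodds <- log(probs / 0.25)
  prof <- structure(list(class_label = class_label, side = side,
                         probs = probs, logodds = logodds,
                         trained_n = length(training), length = P,
                         del_pen = del_pen, ins_pen = ins_pen, band = band,
                         calibration = NULL),
                    class = "boundary_profile")
  # background calibration
  calib <- with_local_seed(cal_seed, {
    vit <- numeric(bg_n); fwd <- numeric(bg_n)
    for (i in seq_len(bg_n)) {
      w <- paste(sample(bases, bg_len, replace = TRUE), collapse = "")
      sc <- profile_scan_c(logodds, encode_dna(w), del_pen, ins_pen, band)
      valid <- is.finite(sc[1, ])
      vit[i] <- max(sc[1, valid]); fwd[i] <- max(sc[2, valid])
    }
    list(vit = vit, fwd = fwd)
  })
  n0 <- max(1L, bg_len - P + 1L)
  prof$calibration <- list(
    mean = c(a = mean(calib$vit), b = mean(calib$fwd)),
    sd = c(a = stats::sd(calib$vit), b = stats::sd(calib$fwd)),
    beta = c(a = stats::sd(calib$vit) * sqrt(6) / pi,
             b = stats::sd(calib$fwd) * sqrt(6) / pi),
    n0 = n0)
  prof
}

#' @export
print.boundary_profile <- function(x, ...) {
  cat("<boundary_profile> class ", x$class_label, " ", x$side, ", ",
      x$length, " columns, trained on ", x$trained_n, " sequences\n", sep = "")
  invisible(x)
}

#' Per-column consensus of a boundary profile
#' @param profile A `boundary_profile`.
#' @return Character string of per-column argmax bases.
#' @export
profile_consensus <- function(profile) {
  paste(rownames(profile$probs)[apply(profile$probs, 2, which.max)], collapse = "")
}

encode_dna <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  idx[is.na(idx)] <- 0L
  as.integer(idx - 1L)
}

# run RNG-dependent code under a local seed without disturbing the caller's
# RNG stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# scan one profile over a window; returns per-offset calibrated z-scores for
# both scorers plus the best-path length drift
scan_profile <- function(profile, seq) {
  sc <- profile_scan_c(profile$logodds, encode_dna(seq),
                       profile$del_pen, profile$ins_pen, profile$band)
  W <- nchar(seq)
  neff <- max(1L, W - profile$length + 1L)
  cal <- profile$calibration
  adj <- log(neff / cal$n0)
  za <- (sc[1, ] - (cal$mean["a"] + cal$beta["a"] * adj)) / cal$sd["a"]
  zb <- (sc[2, ] - (cal$mean["b"] + cal$beta["b"] * adj)) / cal$sd["b"]
  list(za = za, zb = zb, kbest = sc[3, ])
}

tier_of <- function(z, thresholds) {
  ifelse(z >= thresholds["high"], "high",
         ifelse(z >= thresholds["medium"], "medium",
                ifelse(z >= thresholds["low"], "low", NA_character_)))
}

tier_rank <- function(tier) match(tier, c("low", "medium", "high"))

# candidate extraction for one side: local maxima of the combined z track
# above the low threshold, with non-maximum suppression within one profile
# length
side_candidates <- function(profile, seq, side, thresholds) {
  sc <- scan_profile(profile, seq)
  z <- pmax(sc$za, sc$zb)
  ord <- order(-z)
  taken <- integer(0)
  rows <- list()
  for (j in ord) {
    if (!is.finite(z[j]) || z[j] < thresholds["low"]) break
    if (length(taken) && any(abs(taken - j) < profile$length)) next
    taken <- c(taken, j)
    offset <- j - 1L  # 0-based window offset of the profile start
    pos <- if (side == "five_prime") offset
           else offset + profile$length - 1L + sc$kbest[j]
    rows[[length(rows) + 1L]] <- data.frame(
      side = side, window_position = as.integer(pos), offset = offset,
      score_a = sc$za[j], score_b = sc$zb[j], best_score = z[j],
      tier = tier_of(z[j], thresholds), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(side = character(), window_position = integer(),
                      offset = integer(), score_a = numeric(),
                      score_b = numeric(), best_score = numeric(),
                      tier = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(-out$best_score), , drop = FALSE]
}

#' Scan a candidate window for 5' and 3' intron boundaries
#'
#' Every window offset is scored by two algorithms over the class profile -
#' a best-path (Viterbi-style) log-odds score and a sum-over-paths
#' (forward-style) score - and for each offset the better calibrated z-score
#' is kept, so whichever scorer works better for a given sequence wins.
#' Candidate positions are local maxima above the low tier threshold.
#'
#' @param window A `sequence_window` (or DNA string).
#' @param profile_5,profile_3 [build_profile()] objects for the candidate's
#'   class.
#' @param thresholds Named z-score tier thresholds
#'   (default `c(high = 6, medium = 4, low = 2.5)`).
#' @return A `boundary_call`: `bin` (`both`, `five_only`, `three_only`,
#'   `none`), overall `tier`, and ranked candidate tables `candidates_5`,
#'   `candidates_3` with both scores and per-candidate tiers.
#' @export
scan_boundaries <- function(window, profile_5, profile_3,
                            thresholds = c(high = 6, medium = 4, low = 2.5)) {
  seq <- if (inherits(window, "sequence_window")) window$window_seq else as.character(window)
  if (nchar(seq) < max(profile_5$length, profile_3$length)) {
    empty <- data.frame(side = character(), window_position = integer(),
                        offset = integer(), score_a = numeric(),
                        score_b = numeric(), best_score = numeric(),
                        tier = character(), stringsAsFactors = FALSE)
    return(structure(list(bin = "none", tier = NA_character_,
                          candidates_5 = empty, candidates_3 = empty,
                          class_label = profile_5$class_label),
                     class = "boundary_call"))
  }
  c5 <- side_candidates(profile_5, seq, "five_prime", thresholds)
  c3 <- side_candidates(profile_3, seq, "three_prime", thresholds)
  bin <- if (nrow(c5) && nrow(c3)) "both"
         else if (nrow(c5)) "five_only"
         else if (nrow(c3)) "three_only"
         else "none"
  tier <- if (bin == "both") c("low", "medium", "high")[min(tier_rank(c5$tier[1]), tier_rank(c3$tier[1]))]
          else if (bin == "five_only") c5$tier[1]
          else if (bin == "three_only") c3$tier[1]
          else NA_character_
  structure(list(bin = bin, tier = tier, candidates_5 = c5, candidates_3 = c3,
                 class_label = profile_5$class_label),
            class = "boundary_call")
}

#' @export
print.boundary_call <- function(x, ...) {
  cat("<boundary_call> bin=", x$bin,
      if (!is.na(x$tier)) paste0(" tier=", x$tier),
      " (", nrow(x$candidates_5), " x 5', ",
      if (is.null(x$candidates_3)) 0 else nrow(x$candidates_3), " x 3')\n", sep = "")
  invisible(x)
}

#' Scan with the profiles of all classes (unclassified/undefined candidates)
#'
#' @param window A `sequence_window`.
#' @param profiles Named list of per-class `list(five, three)` profile pairs.
#' @inheritParams scan_boundaries
#' @return The best `boundary_call` across classes (highest combined top
#'   candidate score; complete bins beat incomplete ones).
#' @export
scan_boundaries_all <- function(window, profiles,
                                thresholds = c(high = 6, medium = 4, low = 2.5)) {
  calls <- lapply(profiles, function(p)
    scan_boundaries(window, p$five, p$three, thresholds))
  score <- vapply(calls, function(cl) {
    s5 <- if (nrow(cl$candidates_5)) cl$candidates_5$best_score[1] else -Inf
    s3 <- if (!is.null(cl$candidates_3) && nrow(cl$candidates_3)) cl$candidates_3$best_score[1] else -Inf
    completeness <- sum(is.finite(c(s5, s3))) * 1e6
    completeness + sum(pmax(c(s5, s3), -100))
  }, numeric(1))
  calls[[which.max(score)]]
}

#' Resolve a unique boundary pair into an intron call
#'
#' A full-length intron is called when there is exactly one plausible 5' and
#' one plausible 3' boundary: tier at or above `tier_minimum`, the 5' end
#' upstream of the ORF start, the 3' end downstream of the ORF end, and the
#' implied intron length within `length_bounds`. Anything else is
#' `ambiguous`, with reasons. With `admit_best_single = TRUE`, a side with
#' no boundary at `tier_minimum` falls back to its single best lower-tier
#' candidate (the paper-style inclusion of the best medium/low prediction).
#'
#' @param call A [scan_boundaries()] result.
#' @param orf_span 0-based half-open ORF interval in window coordinates.
#' @param length_bounds Allowed intron length range in nt.
#' @param tier_minimum Minimum tier for a plausible boundary.
#' @param admit_best_single Fall back to the best sub-threshold candidate on
#'   a side with none at `tier_minimum`.
#' @return An `intron_call`: `status` (`have_boundaries` / `ambiguous`),
#'   `start_5`, `end_3` (0-based, inclusive), `length`, `tier`, `reasons`.
#' @export
resolve_boundaries <- function(call, orf_span, length_bounds = c(400L, 8000L),
                               tier_minimum = "high", admit_best_single = FALSE) {
  reasons <- character()
  min_rank <- tier_rank(tier_minimum)
  pick_side <- function(cands, ok_pos) {
    if (is.null(cands) || !nrow(cands)) return(list(sel = NULL, why = "none"))
    cands <- cands[ok_pos(cands$window_position), , drop = FALSE]
    if (!nrow(cands)) return(list(sel = NULL, why = "none"))
    at <- cands[tier_rank(cands$tier) >= min_rank, , drop = FALSE]
    if (nrow(at) == 1) return(list(sel = at, why = NA))
    if (nrow(at) > 1) return(list(sel = NULL, why = "multiple"))
    if (admit_best_single) return(list(sel = cands[1, , drop = FALSE], why = NA))
    list(sel = NULL, why = "none")
  }
  p5 <- pick_side(call$candidates_5, function(p) p < orf_span[1])
  p3 <- pick_side(call$candidates_3, function(p) p >= orf_span[2] - 1L)
  if (is.null(p5$sel)) reasons <- c(reasons, paste0(p5$why, "_5prime"))
  if (is.null(p3$sel)) reasons <- c(reasons, paste0(p3$why, "_3prime"))
  if (!length(reasons)) {
    s5 <- p5$sel$window_position; e3 <- p3$sel$window_position
    len <- e3 - s5 + 1L
    if (e3 <= s5) reasons <- c(reasons, "order_violation")
    else if (len < length_bounds[1] || len > length_bounds[2])
      reasons <- c(reasons, "length_out_of_bounds")
  }
  if (length(reasons)) {
    return(structure(list(status = "ambiguous", start_5 = NA_integer_,
                          end_3 = NA_integer_, length = NA_integer_,
                          tier = NA_character_, reasons = reasons),
                     class = "intron_call"))
  }
  tier <- c("low", "medium", "high")[min(tier_rank(p5$sel$tier), tier_rank(p3$sel$tier))]
  structure(list(status = "have_boundaries", start_5 = s5, end_3 = e3,
                 length = len, tier = tier, reasons = character()),
            class = "intron_call")
}

#' @export
print.intron_call <- function(x, ...) {
  if (x$status == "have_boundaries")
    cat("<intron_call> [", x$start_5, ",", x$end_3, "] length ", x$length,
        " tier ", x$tier, "\n", sep = "")
  else cat("<intron_call> ambiguous:", paste(x$reasons, collapse = ","), "\n")
  invisible(x)
}

#' Emit the full intron sequence with exon context
#'
#' @param window A `sequence_window`.
#' @param intron_call A resolved [resolve_boundaries()] call with
#'   `status == "have_boundaries"`.
#' @param exon_nt Exon context captured on each side (default 20 nt).
#' @return The `intron_call` augmented with `intron_seq`, `exon_5`, `exon_3`.
#' @export
generate_intron <- function(window, intron_call, exon_nt = 20L) {
  stopifnot(intron_call$status == "have_boundaries")
  seq <- window$window_seq
  s <- intron_call$start_5; e <- intron_call$end_3
  if (s < 0 || e >= nchar(seq)) stop("boundaries outside window")
  intron_call$intron_seq <- substr(seq, s + 1L, e + 1L)
  intron_call$exon_5 <- substr(seq, max(1L, s + 1L - exon_nt), s)
  intron_call$exon_3 <- substr(seq, e + 2L, min(nchar(seq), e + 1L + exon_nt))
  intron_call
}

#' DNA-to-RNA view
#' @param x DNA string(s).
#' @return The same string(s) with T replaced by U.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)
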