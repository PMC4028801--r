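test_that("ML distances behave like PROTDIST distances", {
  set.seed(62)
  a <- random_aa(400)
  expect_equal(ml_distance(a, a), 0)
  # 20 uniform substitutions in 400 residues sit near 0.052 subst/site
  ch <- strsplit(a, "")[[1]]
  idx <- sample(400, 20)
  for (i in idx) ch[i] <- sample(setdiff(AAS, ch[i]), 1)
  b <- paste(ch, collapse = "")
  d <- ml_distance(a, b)
  expect_equal(d, 0.052, tolerance = 0.2)
  expect_lt(abs(d - oracle_ml_distance(a, b)), 1e-3)
  # monotone under nested difference sets
  i21 <- sample(setdiff(1:400, idx), 1)
  ch[i21] <- sample(setdiff(AAS, ch[i21]), 1)
  expect_gt(ml_distance(a, paste(ch, collapse = "")), d)
})

test_that("ML distance agrees with oracles on random pairs and handles gaps", {
  set.seed(63)
  for (i in 1:10) {
    a <- random_aa(150)
    ch <- strsplit(a, "")[[1]]
    k <- sample(c(3, 10, 25, 60), 1)
    at <- sample(150, k)
    for (j in at) ch[j] <- sample(setdiff(AAS, ch[j]), 1)
    b <- paste(ch, collapse = "")
    d <- ml_distance(a, b)
    expect_lt(abs(d - oracle_ml_distance(a, b)), 1e-3)
    # independent established implementation
    pd <- phangorn::phyDat(rbind(A = strsplit(a, "")[[1]],
                                 B = strsplit(b, "")[[1]]), type = "AA")
    expect_equal(d, as.numeric(phangorn::dist.ml(pd, model = "JTT")),
                 tolerance = 2e-2)
  }
  # gap columns are excluded pairwise
  expect_equal(ml_distance("AC-DE", "AC-DE"), 0)
  ga <- ml_distance("ACDE-F", "ACDEGF")
  expect_equal(ga, ml_distance("ACDEF", "ACDEF"))
  expect_error(ml_distance("---", "AAA"), "comparable")
})

test_that("region excision is bounded by the domain 0-to-X proxies", {
  set.seed(64)
  prot <- paste0("M", random_aa(449))
  doms <- c("0", "1", "2", "3", "4", "5", "6", "7", "X", "En")
  pos <- round(seq_along(doms) / (length(doms) + 1) * (nchar(prot) - 1))
  ref <- reference_iep("R", prot, setNames(as.integer(pos), doms))
  # exact self-excision: the region is precisely proxy0..proxyX (1-based)
  seg <- excise_orf_region(prot, ref, test_scheme())
  expect_equal(seg, substr(prot, pos[1] + 1, pos[9] + 1))
  # a diverged member yields a segment of comparable length
  memb <- mutate_k(prot, 45)
  seg2 <- excise_orf_region(memb, ref, test_scheme())
  expect_lt(abs(nchar(seg2) - nchar(seg)), 10)
})

test_that("progressive alignment of identical and near-identical pairs", {
  set.seed(65)
  a <- random_aa(200)
  al <- align_orf_region(c(x = a, y = a))
  expect_false(any(grepl("-", al, fixed = TRUE)))
  expect_equal(unname(al["x"]), a)
  # 95% pair: alignment identity within 1% of the planted value
  ch <- strsplit(a, "")[[1]]
  at <- sample(200, 10)
  for (j in at) ch[j] <- sample(setdiff(AAS, ch[j]), 1)
  al2 <- align_orf_region(c(x = a, y = paste(ch, collapse = "")))
  expect_equal(protein_identity(al2[["x"]], al2[["y"]]), 0.95,
               tolerance = 0.011)
  # singleton short-circuits
  expect_equal(align_orf_region(c(only = a)), c(only = a))
})

test_that("threshold grouping equals brute-force single linkage", {
  d3 <- matrix(c(0, 0.05, 0.12,
                 0.05, 0, 0.05,
                 0.12, 0.05, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- group_by_threshold(d3, 0.061)
  expect_length(g, 1)
  expect_equal(g[[1]]$member_ids, c("a", "b", "c"))

  dd <- d3; dd[dd > 0] <- 0.1
  expect_length(group_by_threshold(dd, 0.061), 3)

  set.seed(66)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    m <- matrix(runif(n * n, 0, 0.15), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    got <- group_by_threshold(m, 0.061)
    want <- oracle_components(m, 0.061)
    got_sets <- lapply(got, `[[`, "member_ids")
    want_sets <- unname(lapply(want, sort))
    expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                    vapply(want_sets, paste, character(1), collapse = ","))
    # partition: disjoint and covering
    all_ids <- unlist(got_sets)
    expect_setequal(all_ids, rownames(m))
    expect_equal(anyDuplicated(all_ids), 0)
  }
})

test_that("prototype selection is per-group and per-species", {
  md <- data.frame(id = sprintf("c%d", 1:5),
                   species = c("S one", "S one", "S one", "S two", "S two"),
                   intron_length = c(2000, 2400, 2200, 2100, 2100),
                   stringsAsFactors = FALSE)
  # one species: single prototype, the longest
  p1 <- select_prototypes(md$id[1:3], md[1:3, ])
  expect_equal(p1$id[p1$prototype], "c2")
  expect_equal(sum(p1$prototype), 1)
  # two species: one per species; primary is the global best
  p2 <- select_prototypes(md$id, md)
  expect_equal(sort(p2$id[p2$prototype]), c("c2", "c4"))  # c4 beats c5 by id
  expect_equal(p2$id[p2$primary], "c2")
  # singleton group
  p3 <- select_prototypes("c5", md)
  expect_true(p3$prototype)
})

test_that("simulated 95%-identity pairs all fall below the grouping threshold", {
  set.seed(67)
  dmax <- 0
  for (i in 1:10) {
    a <- random_aa(400)
    ch <- strsplit(a, "")[[1]]
    for (j in sample(400, 20)) ch[j] <- sample(setdiff(AAS, ch[j]), 1)
    dmax <- max(dmax, ml_distance(a, paste(ch, collapse = "")))
  }
  expect_lt(dmax, 0.061)
})
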