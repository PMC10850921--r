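make_aln <- function(...) multi_alignment(c(...))

test_that("pairwise usable sites count doubly-unambiguous columns", {
  s <- rand_seq(100)
  aln <- make_aln(a = s, b = s, c = s)
  expect_true(all(pairwise_usable_sites(aln)[upper.tri(diag(3))] == 100))
  gapped <- paste0(strrep("-", 10), substr(s, 11, 100))
  aln2 <- make_aln(a = s, b = gapped, c = s)
  u <- pairwise_usable_sites(aln2)
  expect_equal(u["a", "b"], 90)
  expect_equal(u["a", "c"], 100)
  ## random gapped alignment equals the brute-force column scan
  set.seed(17)
  rows <- vapply(1:4, function(i) {
    ch <- strsplit(rand_seq(200), "")[[1]]
    ch[sample(200, 30)] <- sample(c("-", "N"), 30, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  names(rows) <- letters[1:4]
  aln3 <- multi_alignment(rows)
  expect_equal(unname(pairwise_usable_sites(aln3)),
               unname(bf_usable(aln3$mat)))
})

test_that("identical sequences have zero distance; rows permute cleanly", {
  s <- rand_seq(2000)
  s2 <- rand_seq(2000)
  d <- mcl_distances(make_aln(a = s, b = s, c = s2),
                     fixed_params = list(kappa1 = 2, kappa2 = 2,
                                         freqs = rep(0.25, 4)))
  expect_equal(d$d["a", "b"], 0)
  expect_true(all(diag(d$d) == 0))
  expect_equal(d$d, t(d$d))
  d2 <- mcl_distances(make_aln(b = s, c = s2, a = s),
                      fixed_params = list(kappa1 = 2, kappa2 = 2,
                                          freqs = rep(0.25, 4)))
  expect_equal(d$d[c("a", "b", "c"), c("a", "b", "c")],
               d2$d[c("a", "b", "c"), c("a", "b", "c")], tolerance = 1e-12)
})

test_that("forcing equal rates reduces the MCL distance to Jukes-Cantor", {
  set.seed(19)
  n <- 20000
  s1 <- strsplit(rand_seq(n), "")[[1]]
  s2 <- s1
  idx <- which(runif(n) < 0.06)
  s2[idx] <- vapply(s1[idx], function(b) sample(setdiff(BASES, b), 1), "")
  aln <- make_aln(x = paste(s1, collapse = ""),
                  y = paste(s2, collapse = ""))
  d <- mcl_distances(aln, fixed_params = list(kappa1 = 1, kappa2 = 1,
                                              freqs = rep(0.25, 4)))
  expect_lt(abs(d$d["x", "y"] - jc_closed_form(mean(s1 != s2))), 1e-10)
})

test_that("saturated pairs are flagged rather than silent", {
  set.seed(29)
  aln <- make_aln(x = rand_seq(300), y = rand_seq(300))
  d <- mcl_distances(aln, fixed_params = list(kappa1 = 1, kappa2 = 1,
                                              freqs = rep(0.25, 4)))
  if (is.na(d$d["x", "y"])) {
    expect_false(is.null(d$flags))
    expect_match(d$flags$reason[1], "saturated")
    expect_error(nj_tree(rbind(cbind(d$d, z = c(0.1, 0.1)),
                               z = c(0.1, 0.1, 0))), "NA")
  } else {
    ## two random sequences sit near the p = 0.75 boundary; if finite the
    ## distance must be very large
    expect_gt(d$d["x", "y"], 1)
  }
})

test_that("three-taxon branch lengths solve the analytic system", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.4,
                0.5, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  la <- (0.3 + 0.5 - 0.4) / 2
  lb <- (0.3 + 0.4 - 0.5) / 2
  lc <- (0.5 + 0.4 - 0.3) / 2
  got <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(got[c("a", "b", "c")], c(a = la, b = lb, c = lc))
})

test_that("neighbor joining is exact on additive matrices", {
  ## fixed 4-taxon additive case: ((a:1,b:2):1.5,c:3,d:2.5) unrooted
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- 3
  D["a", "c"] <- 5.5
  D["a", "d"] <- 5
  D["b", "c"] <- 6.5
  D["b", "d"] <- 6
  D["c", "d"] <- 5.5
  D <- D + t(D)
  tr <- nj_tree(D)
  pd <- stats::cophenetic(tr)[letters[1:4], letters[1:4]]
  expect_lt(max(abs(pd - D)), 1e-9)
  ## topology agrees with the best least-squares fit over all 3 topologies
  quartets <- list(c("a", "b", "c", "d"), c("a", "c", "b", "d"),
                   c("a", "d", "b", "c"))
  resid <- vapply(quartets, function(q) {
    ## four-point condition residual for split q12 | q34
    abs((D[q[1], q[3]] + D[q[2], q[4]]) - (D[q[1], q[4]] + D[q[2], q[3]]))
  }, 0)
  best <- quartets[[which.min(resid)]]
  want <- ape::read.tree(text = sprintf("((%s,%s),%s,%s);", best[1],
                                        best[2], best[3], best[4]))
  expect_true(same_topology(tr, want))
  ## random additive matrices from random trees
  for (seed in 1:5) {
    ra <- random_additive_matrix(6, seed)
    tr2 <- nj_tree(ra$D)
    pd2 <- stats::cophenetic(tr2)
    pd2 <- pd2[rownames(ra$D), colnames(ra$D)]
    expect_lt(max(abs(pd2 - ra$D)), 1e-9)
    expect_true(same_topology(tr2, ra$tree))
    ## independent cross-check against the reference implementation
    expect_true(same_topology(tr2, ape::nj(ra$D)))
  }
})

test_that("negative branch estimates are clamped with the deficit moved", {
  ## near-degenerate matrix known to push one NJ branch negative
  D <- matrix(c(0, 5, 9, 9, 8,
                5, 0, 10, 10, 9,
                9, 10, 0, 8, 7,
                9, 10, 8, 0, 3,
                8, 9, 7, 3, 0), 5, 5,
              dimnames = list(letters[1:5], letters[1:5]))
  D["a", "b"] <- D["b", "a"] <- 0.01   # force r_a ~ r_b with tiny d(a,b)
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("outgroup rooting halves the pendant edge and is idempotent", {
  ra <- random_additive_matrix(7, 99)
  tr <- nj_tree(ra$D)
  og <- tr$tip.label[1]
  pend <- tr$edge.length[tr$edge[, 2] == match(og, tr$tip.label)]
  rooted <- root_with_outgroup(tr, og)
  expect_true(ape::is.rooted(rooted))
  root_node <- ape::Ntip(rooted) + 1L
  expect_equal(sum(rooted$edge[, 1] == root_node), 2)
  expect_setequal(rooted$tip.label, tr$tip.label)
  og_edge <- rooted$edge.length[rooted$edge[, 2] ==
                                  match(og, rooted$tip.label)]
  expect_equal(og_edge, pend / 2, tolerance = 1e-9)
  rooted2 <- root_with_outgroup(rooted, og)
  expect_true(same_topology(rooted, rooted2))
  expect_error(root_with_outgroup(tr, "nope"), "not a leaf")
})

test_that("variable and parsimony-informative site counts match brute force", {
  aln <- make_aln(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAT")
  expect_equal(count_variable_sites(aln, "variable"), 1)
  expect_equal(count_variable_sites(aln, "parsimony"), 0)
  expect_equal(count_variable_sites(make_aln(a = "ACGT", b = "ACGT"),
                                    "variable"), 0)
  set.seed(37)
  rows <- vapply(1:5, function(i) {
    ch <- strsplit(rand_seq(300), "")[[1]]
    ch[sample(300, 20)] <- "-"
    paste(ch, collapse = "")
  }, "")
  names(rows) <- letters[1:5]
  aln2 <- multi_alignment(rows)
  expect_equal(count_variable_sites(aln2, "variable"),
               bf_variable_sites(aln2$mat, "variable"))
  expect_equal(count_variable_sites(aln2, "parsimony"),
               bf_variable_sites(aln2$mat, "parsimony"))
})

test_that("the simulated five-taxon history is recovered end to end", {
  ref <- simulate_reference_genome(14, small_regions)
  sim <- simulate_lineages(ref, seed = 43)
  maln <- build_multi_alignment(c(list(reference = ref), sim$genomes),
                                "reference")
  leaves <- multi_alignment(setNames(
    apply(maln$mat[names(sim$genomes), , drop = FALSE], 1, paste,
          collapse = ""), names(sim$genomes)))
  d <- mcl_distances(leaves)
  tr <- nj_tree(d)
  expect_true(same_topology(tr, truth_topology()))
  rooted <- root_with_outgroup(tr, "outgroup")
  ## the domesticated/natans sister pair survives rooting
  bisp <- ape::getMRCA(rooted, c("bispinosa", "natans"))
  expect_equal(length(ape::extract.clade(rooted, bisp)$tip.label), 2)
})
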