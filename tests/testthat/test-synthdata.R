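test_that("reference plastome respects lengths, determinism and IR mirror", {
  g <- simulate_reference_genome(1, small_regions)
  expect_equal(nchar(g$sequence), sum(small_regions))
  expect_identical(region_seq(g, "IRb"), revcomp(region_seq(g, "IRa")))
  g2 <- simulate_reference_genome(1, small_regions)
  expect_identical(g$sequence, g2$sequence)
  g3 <- simulate_reference_genome(2, small_regions)
  expect_false(identical(g$sequence, g3$sequence))
  ## the assembled-contig default sums to the requested lengths exactly
  expect_equal(sum(c(LSC = 88684, IRa = 24452, SSC = 18414, IRb = 24452)),
               156002)
  expect_error(simulate_reference_genome(
    1, c(LSC = 5000L, IRa = 700L, SSC = 900L, IRb = 800L)),
    "equal lengths")
  expect_error(simulate_reference_genome(
    1, c(LSC = 100L, IRa = 100L, SSC = 100L, IRb = 100L)), "1 kb")
})

test_that("lineage simulation plants exactly the root-path variants", {
  ref <- simulate_reference_genome(5, small_regions)
  sim <- simulate_lineages(ref, seed = 9)
  expect_setequal(names(sim$genomes),
                  c("outgroup", "incisa", "japonica", "natans", "bispinosa"))
  for (leaf in names(sim$genomes)) {
    g <- sim$genomes[[leaf]]
    expect_identical(revcomp(region_seq(g, "IRa")), region_seq(g, "IRb"))
    br <- trapatools:::tree_spec_path(sim$truth$tree_spec, leaf)
    s <- sim$truth$snps[sim$truth$snps$branch %in% br, ]
    i <- sim$truth$indels[sim$truth$indels$branch %in% br, ]
    expect_identical(apply_variants(ref$sequence, s, i), g$sequence)
    expect_equal(nchar(g$sequence), nchar(ref$sequence) + sum(i$length))
  }
  ## determinism
  sim2 <- simulate_lineages(ref, seed = 9)
  expect_identical(sim$genomes$bispinosa$sequence,
                   sim2$genomes$bispinosa$sequence)
  expect_identical(sim$truth$indels, sim2$truth$indels)
  ## planted positions unique, INDELs well spaced
  expect_false(anyDuplicated(c(sim$truth$snps$pos,
                               sim$truth$indels$pos)) > 0)
  idp <- sort(sim$truth$indels$pos)
  if (length(idp) > 1L) expect_true(min(diff(idp)) >= 300)
})

test_that("zero mutation counts give leaves identical to the reference", {
  ref <- simulate_reference_genome(2, tiny_regions)
  sim <- simulate_lineages(ref, fig_tree_spec(0, 0), seed = 1)
  for (g in sim$genomes) expect_identical(g$sequence, ref$sequence)
})

test_that("explicit deletion shortens the sequence by its length", {
  ref <- simulate_reference_genome(3, tiny_regions)
  del <- data.frame(pos = 1000L,
                    ref = substr(ref$sequence, 1000, 1005), alt =
                      substr(ref$sequence, 1000, 1000))
  out <- apply_variants(ref$sequence, NULL, del)
  expect_equal(nchar(out), nchar(ref$sequence) - 5L)
})

test_that("pileup candidates carry clean truth at zero noise", {
  ref <- simulate_reference_genome(4, small_regions)
  sim <- simulate_lineages(ref, seed = 11)
  cand <- simulate_pileup_candidates(sim$truth, nchar(ref$sequence),
                                     coverage_mean = 300, frac_noise = 0,
                                     fp_rate = 0, seed = 2)
  expect_true(all(cand$is_true))
  expect_true(all(cand$allele_fraction == 1))
  n_unique <- nrow(unique(rbind(
    data.frame(pos = sim$truth$snps$pos),
    data.frame(pos = sim$truth$indels$pos))))
  expect_equal(nrow(cand), n_unique)
  ## determinism
  cand2 <- simulate_pileup_candidates(sim$truth, nchar(ref$sequence),
                                      coverage_mean = 300, frac_noise = 0,
                                      fp_rate = 0, seed = 2)
  expect_identical(cand, cand2)
  ## the default screen keeps every clean true variant at this depth
  expect_equal(nrow(filter_candidates(cand, filter_spec())), nrow(cand))
})

test_that("false positives appear at the configured rate with low fractions", {
  ref <- simulate_reference_genome(6, small_regions)
  sim <- simulate_lineages(ref, seed = 12)
  L <- nchar(ref$sequence)
  cand <- simulate_pileup_candidates(sim$truth, L, coverage_mean = 300,
                                     frac_noise = 0.02, fp_rate = 0.01,
                                     seed = 3)
  n_fp <- sum(!cand$is_true)
  expect_gt(n_fp, 0.01 * L - 5 * sqrt(0.01 * L))
  expect_lt(n_fp, 0.01 * L + 5 * sqrt(0.01 * L))
  expect_lt(mean(cand$allele_fraction[!cand$is_true]), 0.5)
  expect_gt(mean(cand$allele_fraction[cand$is_true]), 0.9)
})

test_that("flow peaks reproduce the configured ratio exactly at zero noise", {
  pk <- simulate_flow_peaks(c(x = 2 * 373245519), noise_sd = 0,
                            n_reps = 3, seed = 1)
  expect_equal(pk$peak / pk$internal_peak, rep(2, 3))
  pk2 <- simulate_flow_peaks(c(x = 2 * 373245519), noise_sd = 0,
                             n_reps = 3, seed = 1)
  expect_identical(pk, pk2)
})

test_that("morphometry presets honor SD=0, taxon dropout and volume order", {
  p <- default_morph_params()
  p$height_sd <- p$width_sd <- p$total_sd <- 0
  p$endo_frac_sd <- 0
  mm <- simulate_morphometry(p, n_seed = c(incisa = 3, japonica = 3,
                                           natans = 3, bispinosa = 3),
                             n_volume = c(incisa = 2, japonica = 2,
                                          natans = 2, bispinosa = 2),
                             seed = 1)
  sub <- mm$seeds[mm$seeds$taxon == "natans", ]
  expect_true(all(sub$height == p$height_mm[p$taxon == "natans"]))
  expect_true(all(mm$volumes$endosperm_volume <= mm$volumes$total_volume))
  mm2 <- simulate_morphometry(n_seed = c(incisa = 0, japonica = 4,
                                         natans = 4, bispinosa = 4),
                              seed = 2)
  expect_false("incisa" %in% mm2$seeds$taxon)
  ## qualitative size order incisa < japonica <= natans < bispinosa
  means <- tapply(mm$seeds$width, mm$seeds$taxon, mean)
  expect_true(means["incisa"] < means["japonica"])
  expect_true(means["japonica"] <= means["natans"])
  expect_true(means["natans"] < means["bispinosa"])
})

test_that("expand_plastid_table preserves every printed count", {
  tab <- trapa_genotype_table()
  acc <- expand_plastid_table(tab)
  expect_equal(nrow(acc), 79)
  tt <- table(acc$taxon)
  expect_equal(unname(tt[c("incisa", "japonica", "natans", "bispinosa")]),
               c(4L, 16L, 10L, 49L), ignore_attr = TRUE)
  ## the largest single row expands to 25 identical accessions
  nb8 <- acc[acc$plastid_type == "natans-bispinosa 8", ]
  expect_equal(nrow(nb8), 25)
  expect_equal(nrow(unique(nb8[grep("^cpINDEL", names(nb8))])), 1)
  ## all-zero counts -> empty expansion
  tab0 <- tab
  tab0[grep("^n_", names(tab0))] <- 0
  expect_equal(nrow(expand_plastid_table(tab0)), 0)
  ## duplicate (label, region) rows are rejected
  expect_error(expand_plastid_table(rbind(tab, tab[1, ])), "duplicate")
})
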