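test_that("marker coordinates give expected_length = end - start + 1", {
  m <- marker_def("cpINDEL1", "GTTCGATACACTGTTGTCAATATG",
                  "CTAACAAAGAAATAAACCCGAG", 4727, 4891)
  expect_equal(m$expected_length, 165L)
  expect_error(marker_def("x", "ACGTACGTACGT", "CTAACAAAGAAATAAACCCGAG",
                          1, 100), "18-27")
})

test_that("primer design brackets the variant and self-amplifies", {
  ref <- simulate_reference_genome(9, small_regions)
  v <- list(pos = 5000L, ref = substr(ref$sequence, 5000, 5010),
            alt = substr(ref$sequence, 5000, 5000))
  m <- design_primers(ref, v, locus = "m1")
  expect_s3_class(m, "marker_def")
  expect_lt(m$ref_start + nchar(m$fwd_primer) - 1L, v$pos)
  expect_gt(m$ref_end - nchar(m$rev_primer) + 1L, v$pos + nchar(v$ref) - 1L)
  prod <- insilico_pcr(ref, m)
  expect_equal(prod$length, m$expected_length)
  ## primers occur exactly once in the stated orientations
  expect_equal(length(gregexpr(m$fwd_primer, ref$sequence,
                               fixed = TRUE)[[1]]), 1)
  expect_equal(length(gregexpr(revcomp(m$rev_primer), ref$sequence,
                               fixed = TRUE)[[1]]), 1)
})

test_that("a variant inside a long exact repeat is undesignable", {
  set.seed(31)
  block <- rand_seq(400)
  genome <- paste0(rand_seq(600), block, rand_seq(600), block,
                   rand_seq(600))
  v <- list(pos = 800L, ref = substr(genome, 800, 800),
            alt = paste0(substr(genome, 800, 800), "TTTTT"))
  m <- design_primers(genome, v, locus = "rep")
  expect_s3_class(m, "marker_undesignable")
})

test_that("in-silico PCR reflects template changes", {
  ref <- simulate_reference_genome(10, small_regions)
  v <- list(pos = 7000L, ref = substr(ref$sequence, 7000, 7000),
            alt = paste0(substr(ref$sequence, 7000, 7000), "ACGTACGTAT"))
  m <- design_primers(ref, v, locus = "m2")
  expect_s3_class(m, "marker_def")
  ## a 10-nt deletion inside the amplicon shortens the product by 10
  inside <- m$ref_start + nchar(m$fwd_primer) + 3L
  del <- data.frame(pos = inside,
                    ref = substr(ref$sequence, inside, inside + 10L),
                    alt = substr(ref$sequence, inside, inside))
  g_del <- apply_variants(ref$sequence, NULL, del)
  expect_equal(insilico_pcr(g_del, m)$length, m$expected_length - 10L)
  ## a substitution in the primer footprint abolishes the product
  ch <- strsplit(ref$sequence, "")[[1]]
  fp <- m$ref_start + 5L
  ch[fp] <- setdiff(BASES, ch[fp])[1]
  expect_null(insilico_pcr(paste(ch, collapse = ""), m))
  ## duplicating the amplicon elsewhere gives an ambiguous-product error
  amp <- substr(ref$sequence, m$ref_start, m$ref_end)
  expect_error(insilico_pcr(paste0(ref$sequence, strrep("G", 50), amp),
                            m), "ambiguous")
})

test_that("allele codes rank amplicon lengths ascending within locus", {
  amp <- data.frame(accession = c("a", "b", "c"), locus = "L1",
                    amplicon_length = c(165L, 162L, 158L))
  calls <- call_genotypes(amp)
  expect_equal(calls$allele_code, c(3L, 2L, 1L))
  ## monomorphic locus: everyone code 1
  amp2 <- data.frame(accession = letters[1:4], locus = "L2",
                     amplicon_length = 180L)
  expect_true(all(call_genotypes(amp2)$allele_code == 1L))
  ## missing product stays missing
  amp3 <- data.frame(accession = c("a", "b"), locus = "L3",
                     amplicon_length = c(NA, 120L))
  expect_true(is.na(call_genotypes(amp3)$allele_code[1]))
})

test_that("rank coding equals brute force and ignores accession order", {
  set.seed(13)
  amp <- data.frame(
    accession = paste0("acc", 1:60),
    locus = sample(paste0("L", 1:5), 60, replace = TRUE),
    amplicon_length = sample(c(NA, 150:156), 60, replace = TRUE))
  calls <- call_genotypes(amp)
  expect_equal(calls$allele_code, bf_rank_codes(amp))
  perm <- amp[sample(nrow(amp)), ]
  calls_perm <- call_genotypes(perm)
  key <- paste(calls$accession, calls$locus)
  key_perm <- paste(calls_perm$accession, calls_perm$locus)
  expect_equal(calls_perm$allele_code[match(key, key_perm)],
               calls$allele_code)
  ## adding an accession with an existing length adds no new code
  amp_plus <- rbind(amp, data.frame(accession = "acc61", locus = "L1",
    amplicon_length = amp$amplicon_length[amp$locus == "L1"][1]))
  if (!is.na(amp_plus$amplicon_length[nrow(amp_plus)])) {
    cp <- call_genotypes(amp_plus)
    expect_equal(max(cp$allele_code[cp$locus == "L1"], na.rm = TRUE),
                 max(calls$allele_code[calls$locus == "L1"], na.rm = TRUE))
  }
})

test_that("marker panel genotyping distinguishes simulated lineages", {
  ref <- simulate_reference_genome(12, small_regions)
  sim <- simulate_lineages(ref, seed = 33)
  aln <- align_pair(ref$sequence, sim$genomes$bispinosa$sequence)
  ev <- extract_indels(aln)
  markers <- list()
  for (i in seq_len(nrow(ev))) {
    m <- design_primers(ref, ev[i, ], locus = sprintf("L%02d", i))
    if (inherits(m, "marker_def")) markers[[length(markers) + 1L]] <- m
  }
  expect_gt(length(markers), 0)
  calls <- call_genotypes(genotype_panel(sim$genomes, markers))
  gm <- genotype_matrix(calls)
  ## accessions carrying the INDEL differ in code from those without it
  expect_gt(length(unique(gm[[markers[[1]]$locus]])), 1)
})
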