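test_that("gap runs become anchored, left-normalized events", {
  aln <- structure(list(ref_id = "r", qry_id = "q",
                        ref_aln = "ACGGGT", qry_aln = "AC---T"),
                   class = "pairwise_alignment")
  ev <- extract_indels(aln)
  expect_equal(ev$pos, 2L)
  expect_identical(ev$ref, "CGGG")
  expect_identical(ev$alt, "C")
  expect_equal(ev$length, -3L)
  ## gapless alignment
  aln0 <- structure(list(ref_id = "r", qry_id = "q",
                         ref_aln = "ACGT", qry_aln = "ACTT"),
                    class = "pairwise_alignment")
  expect_equal(nrow(extract_indels(aln0)), 0)
})

test_that("left normalization is idempotent and shift-invariant", {
  set.seed(7)
  for (i in 1:50) {
    seqn <- paste0(rand_seq(20), strrep(sample(BASES, 1), sample(3:9, 1)),
                   rand_seq(20))
    n <- nchar(seqn)
    p <- sample(5:(n - 10), 1)
    is_del <- runif(1) < 0.5
    if (is_del) {
      len <- sample(1:5, 1)
      ev <- left_normalize_event(seqn, p, substr(seqn, p, p + len), substr(
        seqn, p, p))
    } else {
      ins <- rand_seq(sample(1:5, 1))
      ev <- left_normalize_event(seqn, p, substr(seqn, p, p),
                                 paste0(substr(seqn, p, p), ins))
    }
    ev2 <- left_normalize_event(seqn, ev$pos, ev$ref, ev$alt)
    expect_identical(ev, ev2)
    ## applying the original and the normalized event gives the same string
    alt_orig <- if (is_del)
      apply_variants(seqn, NULL, data.frame(pos = p,
        ref = substr(seqn, p, p + len), alt = substr(seqn, p, p)))
    else NULL
    if (!is.null(alt_orig)) {
      alt_norm <- apply_variants(seqn, NULL, data.frame(
        pos = ev$pos, ref = ev$ref, alt = ev$alt))
      expect_identical(alt_orig, alt_norm)
    }
  }
})

test_that("candidate screening applies strict thresholds in order", {
  tab <- data.frame(pos = 1:4,
                    coverage = c(201, 200, 1000, 250),
                    allele_fraction = c(0.61, 0.99, 0.60, 0.95))
  kept <- filter_candidates(tab, filter_spec())
  expect_equal(kept$pos, c(1L, 4L))
  expect_error(filter_candidates(data.frame(coverage = 300)), "lacks column")
  bad <- data.frame(coverage = c(300, NA), allele_fraction = c(0.9, 0.9))
  expect_error(filter_candidates(bad), "row 2")
})

test_that("screening equals a brute-force row scan and is monotone", {
  set.seed(11)
  tab <- data.frame(pos = 1:1000,
                    coverage = rpois(1000, 220),
                    allele_fraction = runif(1000))
  kept <- filter_candidates(tab, filter_spec(200, 0.6))
  expect_identical(kept, {
    o <- bf_filter(tab, 200, 0.6)
    rownames(o) <- NULL
    o
  })
  n200 <- nrow(kept)
  expect_lte(nrow(filter_candidates(tab, filter_spec(250, 0.6))), n200)
  expect_lte(nrow(filter_candidates(tab, filter_spec(200, 0.7))), n200)
})

test_that("motif classes follow their definitions on constructed events", {
  ## homopolymer insertion merging into a run of >= 8 nt total
  seqn <- paste0("GGCCTGCTGA", "AAAA", "TTGGCACTGC")
  cl <- classify_motif(14, "A", "AAAAAA", seqn)
  expect_identical(cl$primary, "single_nucleotide_repeat")
  ## the same insertion next to a short run stays unclassified
  seqn2 <- paste0("GGCCTGCTGA", "AA", "TTGGCACTGC")
  cl2 <- classify_motif(12, "A", "AAAA", seqn2)
  expect_identical(cl2$primary, "no_motif")
  ## duplication of the adjacent unit
  seqn3 <- "TTGACTGACGTCAGGCAATTGC"
  cl3 <- classify_motif(9, "C", "CGTCAG", seqn3)   # inserts second GTCAG? no:
  ## insertion of "GTCAG" after pos 9 duplicates seq[10..14] = "GTCAG"
  expect_true("tandem" %in% cl3$classes)
  ## deletion of one unit of a 4-copy microsatellite
  seqn4 <- paste0("GGTTCCAATCAG", strrep("AT", 4), "CGGATCCTTA")
  cl4 <- classify_motif(12, "GAT", "G", seqn4)
  expect_identical(cl4$primary, "ssr")
  ## window shorter than the event errors
  expect_error(classify_motif(12, "GAT", "G", seqn4, window = 1), "window")
})

test_that("published marker cores with verifiable structure classify correctly", {
  mt <- trapa_marker_table()
  row <- function(locus) which(mt$locus == locus)
  expect_setequal(classify_core_pair(mt$core_a[row("cpINDEL4")],
                                     mt$core_b[row("cpINDEL4")]),
                  "single_nucleotide_repeat")
  expect_setequal(classify_core_pair(mt$core_a[row("cpINDEL9")],
                                     mt$core_b[row("cpINDEL9")]),
                  "tandem")
  expect_setequal(classify_core_pair(mt$core_a[row("cpINDEL10")],
                                     mt$core_b[row("cpINDEL10")]),
                  "no_motif")
  ## the complex marker carries both a tandem and a homopolymer event
  expect_setequal(classify_core_pair(mt$core_a[row("cpINDEL3")],
                                     mt$core_b[row("cpINDEL3")]),
                  c("tandem", "single_nucleotide_repeat"))
})

test_that("classification agrees with the brute-force scanner", {
  set.seed(23)
  n_cases <- 1000
  mismatches <- 0
  for (i in seq_len(n_cases)) {
    kind <- sample(c("random", "homopolymer", "duplication", "microsat"),
                   1)
    ctx <- rand_seq(70)
    p <- sample(20:45, 1)
    if (kind == "homopolymer") {
      b <- sample(BASES, 1)
      run <- strrep(b, sample(2:9, 1))
      ctx <- paste0(substr(ctx, 1, p), run, substr(ctx, p + 1, 70))
      ins <- strrep(b, sample(1:8, 1))
      ev <- list(pos = p, ref = substr(ctx, p, p),
                 alt = paste0(substr(ctx, p, p), ins))
    } else if (kind == "duplication") {
      u <- sample(2:8, 1)
      unit <- substr(ctx, p - u + 1, p)
      ev <- list(pos = p, ref = substr(ctx, p, p),
                 alt = paste0(substr(ctx, p, p), unit))
    } else if (kind == "microsat") {
      unit <- rand_seq(sample(2:4, 1))
      arr <- strrep(unit, sample(3:5, 1))
      ctx <- paste0(substr(ctx, 1, p), arr, substr(ctx, p + 1, 70))
      ev <- list(pos = p, ref = substr(ctx, p, p),
                 alt = paste0(substr(ctx, p, p), unit))
    } else if (runif(1) < 0.5) {
      ev <- list(pos = p, ref = substr(ctx, p, p),
                 alt = paste0(substr(ctx, p, p), rand_seq(sample(1:9, 1))))
    } else {
      len <- sample(1:9, 1)
      ev <- list(pos = p, ref = substr(ctx, p, p + len),
                 alt = substr(ctx, p, p))
    }
    got <- classify_motif(ev$pos, ev$ref, ev$alt, ctx)
    want <- bf_classify(ev$pos, ev$ref, ev$alt, ctx)
    if (!setequal(got$classes, want$classes) ||
        !identical(got$primary, want$primary))
      mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("motif census counts primary classes and multi-label events", {
  expect_equal(sum(motif_census(data.frame(motif_primary = character(0),
    motif_classes = character(0)))$primary), 0)
  ref <- simulate_reference_genome(8, small_regions)
  sim <- simulate_lineages(ref, seed = 21)
  aln <- align_pair(ref$sequence, sim$genomes$outgroup$sequence)
  ev <- classify_variants(extract_indels(aln), ref$sequence)
  idl <- sim$truth$indels[sim$truth$indels$branch == "outgroup", ]
  cen <- motif_census(ev)
  want <- table(factor(idl$class, levels = names(cen$primary)))
  expect_equal(unname(cen$primary), as.integer(want))
})

test_that("VCF output is well-formed", {
  v <- data.frame(pos = c(10L, 30L), ref = c("A", "CTT"),
                  alt = c("ATTT", "C"),
                  motif_primary = c("single_nucleotide_repeat", "no_motif"))
  path <- tempfile(fileext = ".vcf")
  write_variants_vcf(v, path)
  lines <- readLines(path)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2)
  expect_match(body[1], "MOTIF=single_nucleotide_repeat")
})
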