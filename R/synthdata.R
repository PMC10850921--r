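## Synthetic study-condition generator: quadripartite circular plastomes
## diverging along a known lineage tree with planted SNPs and INDELs of the
## four repeat-motif classes, pileup-style variant candidates, flow-cytometry
## peak tables, and species-structured seed / CT-volume morphometrics.

#' Construct a circular plastome object
#'
#' @param id Accession label.
#' @param sequence DNA string.
#' @param regions data.frame with columns `region` (LSC, IRa, SSC, IRb),
#'   `start`, `end` (1-based inclusive).
#' @return Object of class `circular_genome`.
#' @export
circular_genome <- function(id, sequence, regions) {
  stopifnot(is.data.frame(regions),
            all(c("region", "start", "end") %in% names(regions)),
            setequal(regions$region, c("LSC", "IRa", "SSC", "IRb")))
  g <- structure(list(id = id, sequence = sequence, regions = regions,
                      circular = TRUE),
                 class = "circular_genome")
  validate_circular_genome(g)
  g
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("<circular_genome> ", x$id, ": ", nchar(x$sequence), " nt\n", sep = "")
  r <- x$regions
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-4s %8d..%-8d (%d nt)\n", r$region[i], r$start[i],
                r$end[i], r$end[i] - r$start[i] + 1L))
  invisible(x)
}

## invariants: regions partition the sequence; revcomp(IRa) == IRb
validate_circular_genome <- function(g) {
  r <- g$regions[order(g$regions$start), ]
  if (r$start[1] != 1L || r$end[nrow(r)] != nchar(g$sequence) ||
      any(r$start[-1] != r$end[-nrow(r)] + 1L))
    stop("regions must partition the sequence without gaps or overlap")
  ira <- region_seq(g, "IRa")
  irb <- region_seq(g, "IRb")
  if (revcomp(ira) != irb)
    stop("IRb must be the reverse complement of IRa")
  invisible(TRUE)
}

#' Extract the sequence of one plastome region
#' @param g A `circular_genome`.
#' @param region One of "LSC", "IRa", "SSC", "IRb".
#' @return Character scalar.
#' @export
region_seq <- function(g, region) {
  i <- match(region, g$regions$region)
  if (is.na(i)) stop("unknown region: ", region)
  substr(g$sequence, g$regions$start[i], g$regions$end[i])
}

#' Simulate a quadripartite circular reference plastome
#'
#' Draws a uniform-random LSC, IRa and SSC and sets IRb to the reverse
#' complement of IRa, in the canonical LSC-IRa-SSC-IRb order, linearized at
#' the LSC start. Default region lengths follow the assembled contig sizes of
#' a domesticated water-chestnut plastome (LSC 88,684 nt, IR 24,452 nt,
#' SSC 18,414 nt).
#'
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#' @param region_lengths Named integer vector `c(LSC=, IRa=, SSC=, IRb=)`;
#'   the two IR lengths must be equal.
#' @param id Accession label.
#' @return A `circular_genome`.
#' @export
simulate_reference_genome <- function(seed,
                                      region_lengths = c(LSC = 88684L,
                                                         IRa = 24452L,
                                                         SSC = 18414L,
                                                         IRb = 24452L),
                                      id = "reference") {
  region_lengths <- region_lengths[c("LSC", "IRa", "SSC", "IRb")]
  if (anyNA(region_lengths))
    stop("region_lengths must name LSC, IRa, SSC and IRb")
  if (any(region_lengths <= 0))
    stop("region lengths must be positive")
  if (region_lengths[["IRa"]] != region_lengths[["IRb"]])
    stop("inverted repeats must have equal lengths (IRa = ",
         region_lengths[["IRa"]], ", IRb = ", region_lengths[["IRb"]], ")")
  if (sum(region_lengths) < 1000)
    stop("total genome length must be at least 1 kb")
  set.seed(as.integer(seed))
  lsc <- random_dna(region_lengths[["LSC"]])
  ira <- random_dna(region_lengths[["IRa"]])
  ssc <- random_dna(region_lengths[["SSC"]])
  irb <- revcomp(ira)
  ends <- cumsum(region_lengths)
  regions <- data.frame(region = c("LSC", "IRa", "SSC", "IRb"),
                        start = c(1L, ends[-4] + 1L),
                        end = unname(ends))
  circular_genome(id, paste0(lsc, ira, ssc, irb), regions)
}

#' Lineage tree specification mirroring the five-taxon water-chestnut study
#'
#' Rooted edge list with per-branch mutation counts: the domesticated taxon
#' sister to natans-like, japonica-like next, incisa-like and the outgroup
#' progressively more distant.
#'
#' @param snp_scale Multiplier applied to the per-branch SNP counts.
#' @param indel_scale Multiplier applied to the per-branch INDEL counts.
#' @return data.frame with columns parent, child, n_snp, n_indel.
#' @export
fig_tree_spec <- function(snp_scale = 1, indel_scale = 1) {
  spec <- data.frame(
    parent = c("root", "root", "n1", "n1", "n2", "n2", "n3", "n3"),
    child  = c("outgroup", "n1", "incisa", "n2", "japonica", "n3",
               "natans", "bispinosa"),
    n_snp  = c(60L, 20L, 30L, 15L, 20L, 10L, 12L, 10L),
    n_indel = c(3L, 1L, 2L, 1L, 2L, 1L, 2L, 2L))
  spec$n_snp <- as.integer(round(spec$n_snp * snp_scale))
  spec$n_indel <- as.integer(round(spec$n_indel * indel_scale))
  spec
}

tree_spec_leaves <- function(tree_spec) {
  setdiff(tree_spec$child, tree_spec$parent)
}

## branches (child labels) on the path root -> leaf
tree_spec_path <- function(tree_spec, leaf) {
  path <- character(0)
  node <- leaf
  while (node != "root") {
    path <- c(node, path)
    i <- match(node, tree_spec$child)
    if (is.na(i)) stop("node without parent in tree spec: ", node)
    node <- tree_spec$parent[i]
  }
  path
}

## newick string (cladogram, branch lengths = 1) for the truth record
tree_spec_newick <- function(tree_spec) {
  children <- split(tree_spec$child, tree_spec$parent)
  rec <- function(node) {
    kids <- children[[node]]
    if (is.null(kids)) return(node)
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")")
  }
  paste0(rec("root"), ";")
}

#' Simulate diverging plastome lineages with planted variant truth
#'
#' Walks a rooted tree specification from a reference plastome, planting on
#' every branch the requested number of SNPs (HKY-like: transitions favored
#' by `kappa`) and INDELs constructed to guarantee an intended repeat-motif
#' class. Each leaf genome differs from the reference by exactly the union of
#' variants on its root path. SNPs falling in IRa are mirrored into IRb;
#' INDELs are restricted to the single-copy regions.
#'
#' @param reference A `circular_genome`.
#' @param tree_spec data.frame(parent, child, n_snp, n_indel); see
#'   [fig_tree_spec()].
#' @param motif_mix Named class proportions for planted INDELs over
#'   `single_nucleotide_repeat`, `tandem`, `ssr`, `no_motif`.
#' @param seed Integer seed.
#' @param kappa Transition/transversion rate ratio for planted SNPs.
#' @param exclusion_margin Minimum distance of any planted variant from a
#'   region boundary, in nt.
#' @param min_spacing Minimum distance between planted INDELs, in nt.
#' @param mirror_ir Mirror IRa SNPs into IRb (default TRUE).
#' @return list(genomes = named list of `circular_genome` leaves,
#'   truth = `lineage_truth` object).
#' @export
simulate_lineages <- function(reference,
                              tree_spec = fig_tree_spec(),
                              motif_mix = c(single_nucleotide_repeat = 10,
                                            tandem = 5, ssr = 1,
                                            no_motif = 3),
                              seed = 1L,
                              kappa = 2,
                              exclusion_margin = 300L,
                              min_spacing = 300L,
                              mirror_ir = TRUE) {
  stopifnot(inherits(reference, "circular_genome"))
  set.seed(as.integer(seed))
  motif_mix <- motif_mix / sum(motif_mix)
  ref <- reference$sequence
  chars <- seq_chars(ref)
  regions <- reference$regions

  ## candidate positions: inside a region, margin away from its boundaries
  in_regions <- function(region_names) {
    r <- regions[regions$region %in% region_names, ]
    unlist(lapply(seq_len(nrow(r)), function(i)
      seq.int(r$start[i] + exclusion_margin, r$end[i] - exclusion_margin)))
  }
  snp_sites <- in_regions(if (mirror_ir) c("LSC", "IRa", "SSC")
                          else c("LSC", "SSC"))
  indel_sites <- in_regions(c("LSC", "SSC"))

  n_branch <- nrow(tree_spec)
  total_snp <- sum(tree_spec$n_snp)
  total_indel <- sum(tree_spec$n_indel)
  if (total_snp > length(snp_sites))
    stop("requested SNP count exceeds available sites")

  used <- integer(0)  # occupied reference positions (all variants)

  ## --- SNPs ------------------------------------------------------------
  snp_pos <- sample(snp_sites, total_snp)
  used <- snp_pos
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"),
             C = c("A", "G"), T = c("A", "G"))
  snp_to <- vapply(snp_pos, function(p) {
    b <- chars[p]
    if (stats::runif(1) < kappa / (kappa + 2)) transitions[[b]]
    else sample(tv[[b]], 1L)
  }, "")
  snps <- data.frame(branch = rep(tree_spec$child, tree_spec$n_snp),
                     pos = snp_pos, from = chars[snp_pos], to = snp_to,
                     mirrored = rep(FALSE, length(snp_pos)),
                     stringsAsFactors = FALSE)
  if (mirror_ir && nrow(snps)) {
    ## SNPs inside IRa are mirrored to the complementary IRb position so the
    ## quadripartite invariant holds in every descendant
    ira <- regions[regions$region == "IRa", ]
    irb <- regions[regions$region == "IRb", ]
    in_ira <- snps$pos >= ira$start & snps$pos <= ira$end
    if (any(in_ira)) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      mirror <- data.frame(branch = snps$branch[in_ira],
                           pos = irb$end - (snps$pos[in_ira] - ira$start),
                           from = unname(comp[snps$from[in_ira]]),
                           to = unname(comp[snps$to[in_ira]]),
                           mirrored = TRUE, stringsAsFactors = FALSE)
      snps <- rbind(snps, mirror)
    }
  }

  ## --- INDELs ----------------------------------------------------------
  classes <- sample(names(motif_mix), total_indel, replace = TRUE,
                    prob = motif_mix)
  ssr_arrays <- if (any(classes == "ssr"))
    find_ssr_arrays(ref, indel_sites) else NULL
  indels <- plant_indels(ref, classes, indel_sites, used, min_spacing,
                         ssr_arrays)
  indels$branch <- rep(tree_spec$child, tree_spec$n_indel)

  ## --- leaf genomes -----------------------------------------------------
  leaves <- tree_spec_leaves(tree_spec)
  genomes <- lapply(leaves, function(leaf) {
    branches <- tree_spec_path(tree_spec, leaf)
    leaf_snps <- snps[snps$branch %in% branches, , drop = FALSE]
    leaf_indels <- indels[indels$branch %in% branches, , drop = FALSE]
    build_leaf_genome(reference, leaf, leaf_snps, leaf_indels)
  })
  names(genomes) <- leaves

  truth <- structure(list(tree_spec = tree_spec,
                          newick = tree_spec_newick(tree_spec),
                          snps = snps, indels = indels,
                          reference_id = reference$id,
                          mirror_ir = mirror_ir),
                     class = "lineage_truth")
  list(genomes = genomes, truth = truth)
}

#' @export
print.lineage_truth <- function(x, ...) {
  cat("<lineage_truth> tree:", x$newick, "\n")
  cat("  planted SNPs:  ", nrow(x$snps), "\n")
  cat("  planted INDELs:", nrow(x$indels),
      sprintf("(%s)", paste(names(table(x$indels$class)),
                            table(x$indels$class), sep = "=",
                            collapse = ", ")), "\n")
  invisible(x)
}

## locate microsatellite arrays (unit 2-4 nt with >= 2 distinct bases,
## >= 3 tandem copies) whose whole extent lies within allowed sites
find_ssr_arrays <- function(seq, allowed_sites) {
  allowed <- rep(FALSE, nchar(seq))
  allowed[allowed_sites] <- TRUE
  out <- list()
  for (u in 2:4) {
    m <- gregexpr(sprintf("([ACGT]{%d})\\1{2,}", u), seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      unit <- substr(seq, m[i], m[i] + u - 1L)
      if (is_homopolymer(unit)) next
      if (!all(allowed[seq.int(m[i], m[i] + len[i] - 1L)])) next
      out[[length(out) + 1L]] <- list(start = m[i], len = len[i], unit = u)
    }
  }
  out
}

## construct anchored, left-normalized INDEL events guaranteeing the intended
## motif class; enforces min spacing against `used` positions and each other
plant_indels <- function(ref, classes, indel_sites, used, min_spacing,
                         ssr_arrays) {
  chars <- seq_chars(ref)
  n <- length(classes)
  out <- data.frame(pos = integer(n), ref = character(n),
                    alt = character(n), length = integer(n),
                    class = classes, stringsAsFactors = FALSE)
  taken <- integer(0)  # INDEL footprint positions
  ok_spacing <- function(s, e) {
    !any(abs(outer(s:e, taken, "-")) < min_spacing) && !any((s:e) %in% used)
  }
  ssr_i <- 0L
  for (i in seq_len(n)) {
    cls <- classes[i]
    ev <- NULL
    for (try in 1:500) {
      cand <- switch(cls,
        single_nucleotide_repeat = {
          p <- sample(indel_sites, 1L)
          b <- chars[p]
          len <- sample(8:12, 1L)
          list(pos = p, ref = chars[p], alt = paste0(chars[p],
               strrep(b, len)))
        },
        tandem = {
          len <- sample(4:15, 1L)
          p <- sample(indel_sites, 1L)
          unit <- substr(ref, p - len + 1L, p)
          if (is_homopolymer(unit)) next
          list(pos = p, ref = chars[p], alt = paste0(chars[p], unit))
        },
        ssr = {
          if (length(ssr_arrays) == 0L)
            stop("no microsatellite array available for an ssr INDEL")
          ssr_i <- ssr_i + 1L
          a <- ssr_arrays[[((ssr_i - 1L) %% length(ssr_arrays)) + 1L]]
          p <- a$start - 1L
          list(pos = p, ref = substr(ref, p, p + a$unit),
               alt = chars[p])
        },
        no_motif = {
          p <- sample(indel_sites, 1L)
          len <- sample(4:16, 1L)
          ins <- random_dna(len)
          if (is_homopolymer(ins)) next
          list(pos = p, ref = chars[p], alt = paste0(chars[p], ins))
        },
        stop("unknown motif class: ", cls))
      norm <- left_normalize_event(ref, cand$pos, cand$ref, cand$alt)
      L <- abs(nchar(norm$ref) - nchar(norm$alt))
      s <- norm$pos
      e <- norm$pos + max(nchar(norm$ref), 1L)
      if (!ok_spacing(s, e)) next
      got <- classify_motif(norm$pos, norm$ref, norm$alt, ref)
      if (got$primary != cls) next
      ev <- norm
      break
    }
    if (is.null(ev))
      stop("could not place a ", cls,
           " INDEL: requested count exceeds available non-overlapping sites")
    out$pos[i] <- ev$pos
    out$ref[i] <- ev$ref
    out$alt[i] <- ev$alt
    out$length[i] <- nchar(ev$alt) - nchar(ev$ref)
    taken <- c(taken, seq.int(ev$pos, ev$pos + max(nchar(ev$ref), 1L)))
  }
  out
}

#' Apply planted variants to a reference sequence
#'
#' Reconstructs a descendant sequence from anchored SNP and INDEL records on
#' reference coordinates (the truth-consistency primitive: applying a leaf's
#' root-path variants regenerates the simulated leaf exactly).
#'
#' @param sequence Reference DNA string.
#' @param snps data.frame(pos, from, to) or NULL.
#' @param indels data.frame(pos, ref, alt) or NULL (anchored alleles).
#' @return The edited sequence.
#' @export
apply_variants <- function(sequence, snps = NULL, indels = NULL) {
  chars <- seq_chars(sequence)
  if (!is.null(snps) && nrow(snps)) {
    if (any(chars[snps$pos] != snps$from))
      stop("SNP 'from' allele does not match the sequence")
    chars[snps$pos] <- snps$to
  }
  sequence <- paste(chars, collapse = "")
  if (!is.null(indels) && nrow(indels)) {
    indels <- indels[order(indels$pos, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(indels))) {
      p <- indels$pos[i]
      r <- indels$ref[i]
      a <- indels$alt[i]
      if (substr(sequence, p, p + nchar(r) - 1L) != r)
        stop("INDEL ref allele does not match the sequence at ", p)
      sequence <- paste0(substr(sequence, 1L, p - 1L), a,
                         substr(sequence, p + nchar(r), nchar(sequence)))
    }
  }
  sequence
}

## build one leaf circular_genome: apply the branch's SNPs (mirror rows
## included) and INDELs, shifting region boundaries by the net length change
build_leaf_genome <- function(reference, id, snps, indels) {
  regions <- reference$regions
  seqn <- apply_variants(reference$sequence, snps, indels)
  ## shift region boundaries by INDEL length deltas upstream of each boundary
  if (nrow(indels)) {
    delta <- nchar(indels$alt) - nchar(indels$ref)
    for (j in seq_len(nrow(regions))) {
      regions$start[j] <- regions$start[j] +
        sum(delta[indels$pos < regions$start[j]])
      regions$end[j] <- regions$end[j] +
        sum(delta[indels$pos <= regions$end[j]])
    }
  }
  circular_genome(id, seqn, regions)
}

#' Simulate a pileup-style variant candidate table
#'
#' Every planted (true) variant appears with allele fraction centered at 1
#' (haploid plastome); false positives are injected per site at `fp_rate`
#' with fractions centered below 0.5.
#'
#' @param truth A `lineage_truth`.
#' @param genome_length Reference length in nt.
#' @param coverage_mean Mean read depth (Poisson).
#' @param frac_noise SD of the allele-fraction jitter.
#' @param fp_rate Per-site false-positive rate.
#' @param seed Integer seed.
#' @return data.frame(chrom, pos, ref, alt, type, coverage, allele_fraction,
#'   is_true).
#' @export
simulate_pileup_candidates <- function(truth, genome_length,
                                       coverage_mean = 300L,
                                       frac_noise = 0.05,
                                       fp_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "lineage_truth"), coverage_mean > 0,
            frac_noise >= 0, fp_rate >= 0, fp_rate <= 1)
  set.seed(as.integer(seed))
  snp <- unique(truth$snps[c("pos", "from", "to")])
  ind <- unique(truth$indels[c("pos", "ref", "alt")])
  tab <- rbind(
    data.frame(pos = snp$pos, ref = snp$from, alt = snp$to, type = "snp",
               stringsAsFactors = FALSE),
    data.frame(pos = ind$pos, ref = ind$ref, alt = ind$alt,
               type = ifelse(nchar(ind$alt) > nchar(ind$ref), "ins", "del"),
               stringsAsFactors = FALSE))
  tab$is_true <- TRUE
  n_fp <- stats::rbinom(1L, genome_length, fp_rate)
  if (n_fp > 0) {
    fpos <- sample.int(genome_length, n_fp)
    fp <- data.frame(pos = fpos,
                     ref = sample(DNA_BASES_ACGT, n_fp, replace = TRUE),
                     alt = NA_character_, type = "snp",
                     is_true = FALSE, stringsAsFactors = FALSE)
    fp$alt <- vapply(fp$ref, function(b)
      sample(setdiff(DNA_BASES_ACGT, b), 1L), "")
    tab <- rbind(tab, fp)
  }
  n <- nrow(tab)
  tab$coverage <- stats::rpois(n, coverage_mean)
  frac <- ifelse(tab$is_true,
                 1 - abs(stats::rnorm(n, 0, frac_noise)),
                 stats::runif(n, 0.05, 0.55))
  tab$allele_fraction <- pmin(1, pmax(0, frac))
  tab <- tab[order(tab$pos), c("pos", "ref", "alt", "type", "coverage",
                               "allele_fraction", "is_true")]
  tab <- cbind(chrom = "plastome", tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Default per-taxon 1C genome sizes (bp) for flow-peak simulation
#'
#' The study's estimates: domesticated bispinosa 481,616,741 nt; tetraploid
#' japonica 883,068,853 nt; natans 438,297,965 nt; incisa 406,826,068 nt.
#' @return Named numeric vector.
#' @export
default_1c_sizes <- function() {
  c(bispinosa = 481616741, japonica = 883068853,
    natans = 438297965, incisa = 406826068)
}

#' Simulate flow-cytometry peak pairs against an internal standard
#'
#' The expected sample/internal peak ratio equals `true_size/internal_size`;
#' jitter is multiplicative on the ratio with the stated SD.
#'
#' @param true_1C_sizes Named vector of true 1C sizes (bp) per taxon.
#' @param internal_size 1C size of the internal standard
#'   (default rice, 373,245,519 bp).
#' @param noise_sd Relative SD of the multiplicative peak jitter.
#' @param n_reps Replicate peak pairs per taxon.
#' @param seed Integer seed.
#' @param internal_peak_center Nominal internal-standard peak position
#'   (arbitrary fluorescence units).
#' @return data.frame(sample, taxon, rep, peak, internal_peak, internal_size).
#' @export
simulate_flow_peaks <- function(true_1C_sizes = default_1c_sizes(),
                                internal_size = 373245519,
                                noise_sd = 0.01, n_reps = 1L, seed = 1L,
                                internal_peak_center = 100) {
  stopifnot(all(true_1C_sizes > 0), internal_size > 0, noise_sd >= 0,
            n_reps >= 1)
  set.seed(as.integer(seed))
  taxa <- names(true_1C_sizes)
  n <- length(taxa) * n_reps
  taxon <- rep(taxa, each = n_reps)
  internal_peak <- internal_peak_center *
    (1 + stats::rnorm(n, 0, noise_sd))
  ratio <- (true_1C_sizes[taxon] / internal_size) *
    (1 + stats::rnorm(n, 0, noise_sd))
  data.frame(sample = paste0(taxon, "_", rep(seq_len(n_reps),
                                             length(taxa))),
             taxon = taxon, rep = rep(seq_len(n_reps), length(taxa)),
             peak = unname(internal_peak * ratio),
             internal_peak = internal_peak,
             internal_size = internal_size,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default morphometric presets per taxon
#'
#' Seed dimensions (mm) ordered incisa < japonica <= natans < bispinosa;
#' capsule volumes calibrated so the domesticated/wild total-volume ratios
#' fall in 4.2-4.5 and endosperm-volume ratios in 3.3-3.7, with endosperm
#' fractions inside 0.53-0.689 and the highest fraction in japonica.
#'
#' @return data.frame, one row per taxon.
#' @export
default_morph_params <- function() {
  data.frame(
    taxon = c("incisa", "japonica", "natans", "bispinosa"),
    height_mm = c(8, 12, 16, 20), height_sd = c(0.8, 1.2, 1.6, 2.0),
    width_mm = c(14, 22, 28, 38), width_sd = c(1.4, 2.2, 2.8, 3.8),
    total_mm3 = c(450, 1500, 1466, 6450),
    total_sd = c(45, 150, 147, 645),
    endo_frac = c(0.60, 0.68, 0.66, 0.55),
    endo_frac_sd = c(0.015, 0.015, 0.015, 0.015),
    stringsAsFactors = FALSE)
}

#' Simulate seed-dimension and capsule/endosperm-volume tables
#'
#' @param species_params Per-taxon means/SDs; see [default_morph_params()].
#' @param n_seed Named integer vector: seed-dimension records per taxon
#'   (default: the study's population counts).
#' @param n_volume Named integer vector: CT-volume records per taxon
#'   (default: the study's scanned-sample counts).
#' @param seed Integer seed.
#' @param frac_range Endosperm fractions are resampled into this closed
#'   interval, emulating the observed study range (53 to 68.9 percent).
#' @param make_masks Also emit toy voxel label masks (one per volume record).
#' @return list(seeds, volumes, masks). `masks` is NULL unless requested;
#'   otherwise a list of 3D integer arrays (0 background, 1 pericarp,
#'   2 endosperm) with attributes `voxel_edge` (mm) and `legend`.
#' @export
simulate_morphometry <- function(species_params = default_morph_params(),
                                 n_seed = c(incisa = 2L, japonica = 16L,
                                            natans = 5L, bispinosa = 22L),
                                 n_volume = c(incisa = 3L, japonica = 3L,
                                              natans = 2L, bispinosa = 7L),
                                 seed = 1L, frac_range = c(0.53, 0.689),
                                 make_masks = FALSE) {
  stopifnot(all(species_params$height_mm > 0),
            all(species_params$width_mm > 0),
            all(species_params$total_mm3 > 0),
            all(species_params$endo_frac > 0 & species_params$endo_frac < 1))
  set.seed(as.integer(seed))
  seeds <- do.call(rbind, lapply(seq_len(nrow(species_params)), function(i) {
    p <- species_params[i, ]
    n <- n_seed[[p$taxon]] %||% 0L
    if (n == 0L) return(NULL)
    data.frame(population = paste0(p$taxon, "_pop", seq_len(n)),
               taxon = p$taxon,
               height = stats::rnorm(n, p$height_mm, p$height_sd),
               width = stats::rnorm(n, p$width_mm, p$width_sd),
               stringsAsFactors = FALSE)
  }))
  volumes <- do.call(rbind, lapply(seq_len(nrow(species_params)), function(i) {
    p <- species_params[i, ]
    n <- n_volume[[p$taxon]] %||% 0L
    if (n == 0L) return(NULL)
    total <- stats::rnorm(n, p$total_mm3, p$total_sd)
    total[total <= 0] <- p$total_mm3
    frac <- stats::rnorm(n, p$endo_frac, p$endo_frac_sd)
    while (any(bad <- frac < frac_range[1] | frac > frac_range[2]))
      frac[bad] <- stats::rnorm(sum(bad), p$endo_frac, p$endo_frac_sd)
    data.frame(sample = paste0(p$taxon, "_ct", seq_len(n)),
               taxon = p$taxon, total_volume = total,
               endosperm_volume = total * frac,
               stringsAsFactors = FALSE)
  }))
  rownames(seeds) <- rownames(volumes) <- NULL
  masks <- NULL
  if (make_masks && !is.null(volumes)) {
    masks <- lapply(seq_len(nrow(volumes)), function(i)
      toy_voxel_mask(volumes$total_volume[i], volumes$endosperm_volume[i]))
    names(masks) <- volumes$sample
  }
  list(seeds = seeds, volumes = volumes, masks = masks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## toy CT label mask: nested cuboids approximating the requested volumes
toy_voxel_mask <- function(total_volume, endosperm_volume, dim = 20L) {
  voxel_edge <- (total_volume / dim^3)^(1 / 3)
  n_total <- dim^3
  n_endo <- max(1L, round(endosperm_volume / total_volume * n_total))
  side <- max(1L, min(dim, floor(n_endo^(1 / 3))))
  mask <- array(1L, dim = c(dim, dim, dim))
  off <- floor((dim - side) / 2)
  mask[off + seq_len(side), off + seq_len(side), off + seq_len(side)] <- 2L
  ## top up to the exact endosperm voxel count along one face
  extra <- n_endo - side^3
  if (extra > 0) {
    idx <- which(mask == 1L)[seq_len(extra)]
    mask[idx] <- 2L
  }
  attr(mask, "voxel_edge") <- voxel_edge
  attr(mask, "legend") <- c(background = 0L, pericarp = 1L, endosperm = 2L)
  mask
}

#' Expand a printed plastid-type matrix into per-accession genotype records
#'
#' Rows of the published genotype table carry one nine-locus allele-code
#' vector plus per-species accession counts; this emits one record per
#' counted accession, each carrying its row's code vector.
#'
#' @param type_matrix data.frame with columns `plastid_type`, `region`,
#'   marker-code columns matching `^cpINDEL`, and count columns matching
#'   `^n_` (one per taxon).
#' @return data.frame(accession, taxon, region, plastid_type, <codes>).
#' @export
expand_plastid_table <- function(type_matrix) {
  stopifnot(is.data.frame(type_matrix),
            all(c("plastid_type", "region") %in% names(type_matrix)))
  code_cols <- grep("^cpINDEL", names(type_matrix), value = TRUE)
  count_cols <- grep("^n_", names(type_matrix), value = TRUE)
  if (length(code_cols) == 0L) stop("no marker-code columns (cpINDEL*)")
  if (length(count_cols) == 0L) stop("no count columns (n_*)")
  key <- paste(type_matrix$plastid_type, type_matrix$region, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (plastid_type, region) rows: ",
         paste(key[duplicated(key)], collapse = ", "))
  counts <- as.matrix(type_matrix[count_cols])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("accession counts must be nonnegative integers")
  rows <- list()
  for (i in seq_len(nrow(type_matrix))) {
    for (cc in count_cols) {
      n <- type_matrix[[cc]][i]
      if (n == 0) next
      taxon <- sub("^n_", "", cc)
      rec <- cbind(
        data.frame(taxon = rep(taxon, n),
                   region = type_matrix$region[i],
                   plastid_type = type_matrix$plastid_type[i],
                   stringsAsFactors = FALSE),
        type_matrix[rep(i, n), code_cols, drop = FALSE])
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (length(rows) == 0L) {
    out <- cbind(data.frame(accession = character(0), taxon = character(0),
                            region = character(0),
                            plastid_type = character(0)),
                 type_matrix[0, code_cols, drop = FALSE])
    rownames(out) <- NULL
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- cbind(accession = sprintf("acc%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
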