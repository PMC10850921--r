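## End-to-end orchestration: simulate -> screen -> discover INDELs -> design
## markers -> genotype -> plastid types -> tree -> genome size -> morphometry,
## driven by one config, with stage-level logging and deterministic outputs.

#' Default pipeline configuration
#'
#' Screening thresholds mirror the study's screen (>200x coverage, >60%
#' allele fraction) and the internal standard defaults to rice
#' (373,245,519 bp). Stage parameters are nested lists; override any subset
#' via [run_pipeline()]'s config (YAML file or list).
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "trapatools_run",
    stages = list(simulate = TRUE, scan_indels = TRUE,
                  design_markers = TRUE, genotype = TRUE,
                  plastid_type = TRUE, tree = TRUE, genome_size = TRUE,
                  morphometry = TRUE),
    simulate = list(
      region_lengths = c(LSC = 88684L, IRa = 24452L, SSC = 18414L,
                         IRb = 24452L),
      snp_scale = 1, indel_scale = 1,
      coverage_mean = 300L, frac_noise = 0.05, fp_rate = 0.001),
    scan = list(min_coverage = 200L, min_fraction = 0.60,
                pair = c("bispinosa", "japonica")),
    markers = list(n_markers = 10L, amplicon_window = c(100L, 300L)),
    tree = list(outgroup = "outgroup"),
    genome_size = list(internal_size = 373245519, noise_sd = 0.01,
                       n_reps = 3L, baseline = "median-diploid"),
    morphometry = list())
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", nm)
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing per-stage outputs (TSV/CSV
#' tables, VCF, newick) under `out_dir` and accumulating a provenance log
#' (stage, record counts, parameters). Outputs are deterministic for a fixed
#' config. A failing stage halts the run with the stage named; outputs of
#' completed stages are retained.
#'
#' @param config List overriding [default_config()], or a path to a YAML file
#'   of overrides.
#' @return Object of class `trapa_report`: list of stage results plus `log`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (is.list(cfg$simulate$region_lengths))
    cfg$simulate$region_lengths <- unlist(cfg$simulate$region_lengths)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- data.frame(stage = character(0), message = character(0),
                    stringsAsFactors = FALSE)
  note <- function(stage, msg) {
    log[nrow(log) + 1L, ] <<- c(stage, msg)
  }
  out <- list(config = cfg)
  run_stage <- function(name, fn) {
    if (!isTRUE(cfg$stages[[name]])) return(NULL)
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- simulate ---------------------------------------------------------
  sim <- run_stage("simulate", function() {
    ref <- simulate_reference_genome(cfg$seed, cfg$simulate$region_lengths)
    lin <- simulate_lineages(ref,
                             fig_tree_spec(cfg$simulate$snp_scale,
                                           cfg$simulate$indel_scale),
                             seed = cfg$seed + 1L)
    cand <- simulate_pileup_candidates(
      lin$truth, genome_length = nchar(ref$sequence),
      coverage_mean = cfg$simulate$coverage_mean,
      frac_noise = cfg$simulate$frac_noise,
      fp_rate = cfg$simulate$fp_rate, seed = cfg$seed + 2L)
    write_fasta_seqs(
      c(stats::setNames(ref$sequence, ref$id),
        vapply(lin$genomes, `[[`, "", "sequence")),
      file.path(cfg$out_dir, "genomes.fasta"))
    utils::write.table(cand, file.path(cfg$out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(lin$truth$newick, file.path(cfg$out_dir, "truth_tree.nwk"))
    note("simulate", sprintf(
      "reference %d nt; %d leaves; %d planted SNPs, %d planted INDELs; %d candidates (seed %d)",
      nchar(ref$sequence), length(lin$genomes), nrow(lin$truth$snps),
      nrow(lin$truth$indels), nrow(cand), cfg$seed))
    list(reference = ref, genomes = lin$genomes, truth = lin$truth,
         candidates = cand)
  })
  out$simulate <- sim

  ## --- scan_indels ------------------------------------------------------
  scan <- run_stage("scan_indels", function() {
    if (is.null(sim)) stop("needs the simulate stage")
    spec <- filter_spec(cfg$scan$min_coverage, cfg$scan$min_fraction)
    kept <- filter_candidates(sim$candidates, spec)
    note("scan_indels", sprintf(
      "screen >%dx coverage, >%s fraction: %d of %d candidates retained",
      spec$min_coverage, spec$min_fraction, nrow(kept),
      nrow(sim$candidates)))
    a_id <- cfg$scan$pair[1]
    b_id <- cfg$scan$pair[2]
    ga <- sim$genomes[[a_id]]
    gb <- sim$genomes[[b_id]]
    if (is.null(ga) || is.null(gb))
      stop("scan pair not among simulated taxa")
    aln <- align_pair(ga$sequence, gb$sequence, ref_id = a_id,
                      qry_id = b_id)
    ind <- extract_indels(aln)
    ind <- classify_variants(ind, ga$sequence)
    write_variants_vcf(ind, file.path(cfg$out_dir, "indels.vcf"),
                       chrom = a_id)
    census <- motif_census(ind)
    note("scan_indels", sprintf(
      "%s vs %s: %d INDELs (%s); %d multi-label", a_id, b_id, nrow(ind),
      paste(names(census$primary), census$primary, sep = "=",
            collapse = ", "), census$multi_label))
    list(retained = kept, alignment = aln, indels = ind, census = census,
         anchor_genome = ga)
  })
  out$scan_indels <- scan

  ## --- design_markers ---------------------------------------------------
  markers <- run_stage("design_markers", function() {
    if (is.null(scan)) stop("needs the scan_indels stage")
    ind <- scan$indels
    n <- min(cfg$markers$n_markers, nrow(ind))
    designed <- list()
    failed <- 0L
    for (i in seq_len(n)) {
      m <- design_primers(scan$anchor_genome, ind[i, ],
                          locus = sprintf("cpINDEL%02d", i),
                          amplicon_window = cfg$markers$amplicon_window)
      if (inherits(m, "marker_undesignable")) failed <- failed + 1L
      else designed[[length(designed) + 1L]] <- m
    }
    if (length(designed))
      write_marker_table(designed, file.path(cfg$out_dir, "markers.tsv"))
    note("design_markers", sprintf(
      "%d markers designed, %d undesignable of %d targets",
      length(designed), failed, n))
    designed
  })
  out$markers <- markers

  ## --- genotype ---------------------------------------------------------
  geno <- run_stage("genotype", function() {
    if (is.null(markers) || length(markers) == 0L)
      stop("needs designed markers")
    amp <- genotype_panel(sim$genomes, markers)
    calls <- call_genotypes(amp)
    gm <- genotype_matrix(calls)
    utils::write.table(gm, file.path(cfg$out_dir, "genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    note("genotype", sprintf("%d accessions x %d loci", nrow(gm),
                             ncol(gm) - 1L))
    list(calls = calls, matrix = gm)
  })
  out$genotype <- geno

  ## --- plastid_type -----------------------------------------------------
  ptype <- run_stage("plastid_type", function() {
    if (is.null(geno)) stop("needs the genotype stage")
    pt <- assign_plastid_types(geno$matrix)
    meta <- data.frame(accession = geno$matrix$accession,
                       taxon = geno$matrix$accession,
                       stringsAsFactors = FALSE)
    tally <- tally_types_by_taxon(pt, meta)
    write_plastid_report(pt, file.path(cfg$out_dir, "plastid_types.tsv"),
                         tally)
    note("plastid_type", sprintf("%d plastid types; %d accessions excluded",
                                 nrow(pt$types), length(pt$excluded)))
    list(types = pt, tally = tally, shared = shared_types(tally))
  })
  out$plastid_type <- ptype

  ## --- tree -------------------------------------------------------------
  tree <- run_stage("tree", function() {
    if (is.null(sim)) stop("needs the simulate stage")
    seqs <- c(stats::setNames(list(sim$reference), sim$reference$id),
              sim$genomes)
    aln <- build_multi_alignment(seqs, sim$reference$id)
    aln_leaves <- multi_alignment(stats::setNames(
      apply(aln$mat[names(sim$genomes), , drop = FALSE], 1L, paste,
            collapse = ""), names(sim$genomes)))
    d <- mcl_distances(aln_leaves)
    nj <- nj_tree(d)
    rooted <- root_with_outgroup(nj, cfg$tree$outgroup)
    ape::write.tree(rooted, file.path(cfg$out_dir, "nj_tree.nwk"))
    write_phylip_dist(d, file.path(cfg$out_dir, "distances.phy"))
    nv <- count_variable_sites(aln_leaves, "variable")
    note("tree", sprintf(
      "MCL distances on %d taxa (kappa1 %.3g, kappa2 %.3g); %d variable sites; rooted on %s",
      length(sim$genomes), d$params$kappa1, d$params$kappa2, nv,
      cfg$tree$outgroup))
    list(alignment = aln_leaves, distances = d, tree = rooted,
         variable_sites = nv)
  })
  out$tree <- tree

  ## --- genome_size ------------------------------------------------------
  gsize <- run_stage("genome_size", function() {
    peaks <- simulate_flow_peaks(
      internal_size = cfg$genome_size$internal_size,
      noise_sd = cfg$genome_size$noise_sd,
      n_reps = cfg$genome_size$n_reps, seed = cfg$seed + 3L)
    peaks$diploid_flag <- peaks$taxon != "japonica"
    rep <- batch_report(peaks, baseline = cfg$genome_size$baseline)
    utils::write.csv(rep, file.path(cfg$out_dir, "genome_sizes.csv"),
                     row.names = FALSE)
    note("genome_size", sprintf(
      "%d peak pairs; baseline 1C %.0f bp; ploidy calls: %s", nrow(rep),
      attr(rep, "baseline_1C"),
      paste(unique(sprintf("%s=%dx", rep$taxon, rep$ploidy)),
            collapse = ", ")))
    rep
  })
  out$genome_size <- gsize

  ## --- morphometry ------------------------------------------------------
  morpho <- run_stage("morphometry", function() {
    mm <- simulate_morphometry(seed = cfg$seed + 4L)
    dims <- summarize_dims(mm$seeds, "taxon")
    vols <- mm$volumes
    ratio_of <- function(q) vapply(
      c("japonica", "natans", "incisa"), function(tx)
        interspecific_ratio(vols[vols$taxon == "bispinosa", ],
                            vols[vols$taxon == tx, ], q)$ratio, 0)
    ratios <- data.frame(versus = c("japonica", "natans", "incisa"),
                         total = ratio_of("total"),
                         endosperm = ratio_of("endosperm"))
    utils::write.csv(dims, file.path(cfg$out_dir, "seed_dims.csv"),
                     row.names = FALSE)
    utils::write.csv(vols, file.path(cfg$out_dir, "volumes.csv"),
                     row.names = FALSE)
    utils::write.csv(ratios, file.path(cfg$out_dir, "volume_ratios.csv"),
                     row.names = FALSE)
    note("morphometry", sprintf(
      "%d seed records, %d volume records; bispinosa/japonica total ratio %.2f",
      nrow(mm$seeds), nrow(vols), ratios$total[1]))
    list(dims = dims, volumes = vols, ratios = ratios)
  })
  out$morphometry <- morpho

  out$log <- log
  utils::write.table(log, file.path(cfg$out_dir, "run_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  structure(out, class = "trapa_report")
}

#' @export
print.trapa_report <- function(x, ...) {
  cat("<trapa_report> stages run:",
      paste(unique(x$log$stage), collapse = ", "), "\n")
  for (i in seq_len(nrow(x$log)))
    cat(sprintf("  [%s] %s\n", x$log$stage[i], x$log$message[i]))
  invisible(x)
}
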