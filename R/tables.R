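## Published study tables encoded as fixtures: flow-cytometry peak pairs,
## the 19-marker cpINDEL panel, and the plastid-type genotype matrix. These
## are the desk-scale inputs for reproducing the study's computed results.

#' Published flow-cytometry peak table
#'
#' Eight accessions with sample and internal-standard peak positions and the
#' genome sizes as printed (rice internal standard, 1C = 373,245,519 bp).
#' Species labels follow the table as printed; the running text pairs the
#' natans/incisa sizes the other way around, a discrepancy the computation
#' (which uses peaks only) does not arbitrate.
#'
#' @return data.frame(species, site, country, peak, internal_peak,
#'   internal_size, printed_size, diploid_flag).
#' @export
trapa_flow_peaks <- function() {
  data.frame(
    species = c("bispinosa", "incisa", "japonica", "natans",
                "bispinosa", "bispinosa", "bispinosa", "japonica"),
    site = c("Oki village, Fukuoka", "Fukui", "Hirosaki",
             "Kanzaki city, Saga", "Liangzhu, 4 spines, green",
             "Liangzhu, 4 spines, red", "Liangzhu, 2 spines, red", "Ninpo"),
    country = c(rep("Japan", 4), rep("China", 4)),
    peak = c(161.50, 115.55, 289.21, 133.87, 195.35, 254.66, 258.66,
             409.47),
    internal_peak = c(125.16, 98.40, 122.24, 122.82, 162.40, 197.39,
                      204.49, 187.44),
    internal_size = 373245519,
    printed_size = c(481616741, 438297965, 883068853, 406826068,
                     448974828, 481537585, 472119350, 815369412),
    diploid_flag = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Published cpINDEL marker panel
#'
#' The 19 markers with primers, aligned core-sequence pairs spanning the
#' variation (`//` separates discontiguous stretches; NA where the published
#' cell does not carry a usable pair), the motif call as printed, and
#' amplicon coordinates on the T. maximowiczii reference frame.
#'
#' @return data.frame(locus, forward, reverse, core_a, core_b, motif, start,
#'   end, length).
#' @export
trapa_marker_table <- function() {
  df <- data.frame(
    locus = paste0("cpINDEL", 1:19),
    forward = c(
      "GTTCGATACACTGTTGTCAATATG", "AATTTCGTCGGCTCTAATGG",
      "TAGAGTTCTTTTTGTATCAC", "GGATATGTGGTATAAAAATGGAG",
      "CACGTGTATGAATTCGTTAGG", "ATTGTAACAGAGGTGCAAGTG",
      "GTATACTCATACTAGCTATAAC", "GAATAGGTGGGTCAATTCCTTCC",
      "GATCGAATCAAGATGTGTCAC", "TCCCTCTTCCATTTATCTGCATAC",
      "GAATCGTAATGCTATGTACATTATC", "GGGAAAAACGGGGATATTAGTG",
      "TAGCATTGGAACTGCTATGTAGG", "CATAGATGAACTCCTATGAATG",
      "TAGCTATAGAGTATCATATC", "CTTACACTTACTTCGACTTAG",
      "ATTCACAAGAACCGCGAATTC", "ACTATTTATCTTAATATGGTTGT",
      "ATTCTTTCTTGTTCGTATTTTG"),
    reverse = c(
      "CTAACAAAGAAATAAACCCGAG", "AGTTACATTTACGTACCATC",
      "TATTCCGTAATTGATTGACA", "CTTCACGTCCAGGATTACGTCC",
      "ATTTTCTTTTGTTCAATTGAACAAAAG", "GTATAAAGTGGAAGGGAAAGAGAG",
      "TTCAAGAGACGGCTTATCTATC", "CAAAATGGGATATACCTATGAG",
      "AATTGAAGTTCTATTTCTAAGTTC", "GGACCTACCCATACTATGAAC",
      "TGAGATCCGATAGCTAGTATGG", "TTCAAGAGACGGCTTATCTATC",
      "GGAACCACGGGAGGAATAGTG", "CTTGAAATGAGACATGTACC",
      "AAAATCCATTCTTGTCTTATC", "TTTCGTTGCAATCACAACCC",
      "CATTATAACAAGTCACACACTC", "TTAAGTTATTACTCACAACAAAG",
      "ACTTTGCTAAAAAATGACATAG"),
    core_a = c(
      NA,
      "TATTATTATTA-------TTTTTTTTTTAAATAA",
      "TTTCTATTTATTTCTATTTAAA//ATTTTTTT-TTTTCA",
      "CTTTTTTTTTTTTTAAAAAAAAAAAA----TGATC",
      "TATTTTTTTTTTTTTTTTTTTATTATTATTTATTC",
      "TGGGTGGGGTGGGTACTTT//G-AAAAAAAAAAAC",
      "AAATAAAGATTTCAACCTTTTTTTTTTTATTCTAA",
      "CCCATTTTTTTT---ATTTACCCTATCTAATTGAA",
      "GTTTAGAAATACTATAAATACTATATTAGATATTA",
      "AAAGCAGATTGGTTTTT---------TTTATTTTA",
      "TATACAGTATATTAT----GGTATTGTTACATTAC",
      "AAATAAAGATTTCAACCTTTTTTTTTTTATTCTAAA",
      "TGGTTCAAGGCGT----AGCATTGGAACTGCTTGTA",
      "AGTCGATTAAATT--------TTGTCAAGCCATCCAT",
      "CAACAAGATAAA-AAAAAAAAAAGAAAATCCTGCCTT",
      "TAAAGTAAAGTTAAGTAAAGTAATAATAATATAGTAATATTA",
      "AACCGCGAATTCTT-----ATTAATACTTTTATACTTA",
      "TAATATAAATATAGAAAAGTAAAAA-----CCTATTG",
      "TTTGAAAATCCAATCCAAATAAAGTATTTTCTCTTGA"),
    core_b = c(
      NA,
      "TATTATTATTATTTTTATTTTTTTTTTTAAATAA",
      "TTTCTATTTA----------AA//ATTTTTTTTTTTTCA",
      "C--------TTTTTAAAAAAAAAAAAAAAATGATC",
      "TATTTTTTTTTTTTTTTTTTT--TATTATTTATTC",
      "TGGG-----TGGGTACTTT//GAAAAAAAAAAAAC",
      "AATAAAGATTTCAACC--TTTTTTTTTTATTCTAA",
      "TCCCATTTTTTTTTTATTTACCCTATCTAATTGAA",
      "GTTTAGAAATACTATA----------------TTA",
      "AAAGCAGATTGGTTTTTCTTTTGTTTTTTATTTTA",
      "TATACAGTATATTATGTATGGTATTGTTACATTAC",
      "AATAAAGATTTCAACC--TTTTTTTTTTATTCTAAA",
      "TGGTTCAAGGCGTACCAAGCATTGGAACTGCTTGTA",
      "AGTCGATTAAATTGGAATTAATTGTCAAGCCATCCAT",
      "CAACAAGATAAAAAAAAAAAAAAGAAAATCCTGCCTT",
      "T----TAAAGTTAAGTAAAGTAATAATAATATAGTA-----A",
      "AACCGCGAATTCTTACTTTATTAATACTTTTATACTTA",
      "TAATATAAATATAGAAAAGTAAAAATTTTTCCTATTG",
      "TTTGA------AATCCAAATAAAGTATTTTCTCTTGA"),
    motif = c(
      "Single nucleotide repeat", "Single nucleotide repeat",
      "Tandem/Single nucleotide repeat", "Single nucleotide repeat",
      "Single nucleotide repeat", "Single nucleotide repeat",
      "Single nucleotide repeat", "Single nucleotide repeat",
      "Tandem", "No motif", "Tandem", "Single nucleotide repeat",
      "No motif", "Tandem", "Single nucleotide repeat", "SSR",
      "No motif", "Single nucleotide repeat", "Tandem"),
    start = c(4727L, 12533L, 13987L, 8331L, 15341L, 32643L, 34025L,
              45032L, 71742L, 86751L, 30898L, 33967L, 47208L, 53227L,
              62375L, 71159L, 78991L, 123167L, 130558L),
    end = c(4891L, 12694L, 14168L, 8514L, 15495L, 32810L, 34159L,
            45178L, 71910L, 86955L, 31076L, 34159L, 47398L, 53381L,
            62542L, 71408L, 79205L, 123346L, 130730L),
    length = c(165L, 162L, 182L, 184L, 155L, 168L, 135L, 147L, 169L,
               205L, 179L, 193L, 191L, 155L, 168L, 250L, 215L, 180L,
               173L),
    stringsAsFactors = FALSE)
  df
}

#' Published plastid-type genotype matrix
#'
#' The twelve printed rows: plastid-type label, sampling region, allele codes
#' at the nine polymorphic cpINDEL loci, and accession counts per species.
#'
#' @return data.frame(plastid_type, region, cpINDEL2...cpINDEL19,
#'   n_incisa, n_japonica, n_natans, n_bispinosa).
#' @export
trapa_genotype_table <- function() {
  codes <- rbind(
    c(5, 1, 1, 1, 2, 2, 2, 1, 1),   # incisa A, Japan
    c(2, 3, 3, 1, 2, 2, 1, 2, 2),   # incisa B, Japan
    c(1, 3, 2, 2, 1, 3, 2, 1, 1),   # W, Japan
    c(1, 3, 2, 2, 1, 3, 2, 1, 1),   # W, China
    c(1, 2, 2, 2, 1, 2, 2, 1, 1),   # natans-bispinosa 1, China
    c(2, 1, 1, 1, 2, 1, 2, 1, 1),   # natans-bispinosa 2, China
    c(2, 1, 2, 1, 2, 2, 2, 1, 1),   # natans-bispinosa 3, China
    c(3, 1, 1, 1, 2, 2, 2, 1, 1),   # natans-bispinosa 4, Japan
    c(3, 1, 1, 1, 2, 2, 2, 1, 1),   # natans-bispinosa 5, China
    c(3, 2, 2, 1, 2, 2, 2, 1, 1),   # natans-bispinosa 6, China
    c(4, 2, 1, 1, 2, 1, 2, 1, 1),   # natans-bispinosa 7, Japan
    c(4, 2, 1, 1, 2, 1, 2, 1, 1))   # natans-bispinosa 8, China
  colnames(codes) <- paste0("cpINDEL", c(2, 3, 7, 9, 10, 12, 13, 17, 19))
  cbind(
    data.frame(
      plastid_type = c("incisa A", "incisa B", "W", "W",
                       paste("natans-bispinosa", 1:8)),
      region = c("Japan", "Japan", "Japan", "China", "China", "China",
                 "China", "Japan", "China", "China", "Japan", "China"),
      stringsAsFactors = FALSE),
    as.data.frame(codes),
    data.frame(
      n_incisa   = c(2, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
      n_japonica = c(0, 0, 5, 11, 0, 0, 0, 0, 0, 0, 0, 0),
      n_natans   = c(0, 0, 0, 0, 5, 1, 0, 3, 1, 0, 0, 0),
      n_bispinosa = c(0, 0, 0, 0, 0, 6, 2, 4, 5, 3, 4, 25)))
}

#' Map a printed motif label to motif-class names
#' @param label Motif column entry (slash-separated for multi-label).
#' @return Character vector of class names.
#' @export
parse_motif_label <- function(label) {
  map <- c("Single nucleotide repeat" = "single_nucleotide_repeat",
           "Tandem" = "tandem", "SSR" = "ssr", "No motif" = "no_motif")
  parts <- trimws(strsplit(label, "/", fixed = TRUE)[[1]])
  unknown <- setdiff(parts, names(map))
  if (length(unknown)) stop("unknown motif label: ", unknown[1])
  unname(map[parts])
}

#' Classify the aligned core-sequence pair of one marker
#'
#' Splits the pair at `//` into contiguous aligned stretches, extracts the
#' INDEL events of each stretch, classifies them in their local context, and
#' returns the union of primary classes across events.
#'
#' @param core_a,core_b Equal-length gapped strings.
#' @param window Flank window for [classify_motif()].
#' @return Character vector of primary classes (one per distinct class).
#' @export
classify_core_pair <- function(core_a, core_b, window = 30L) {
  seg_a <- strsplit(core_a, "//", fixed = TRUE)[[1]]
  seg_b <- strsplit(core_b, "//", fixed = TRUE)[[1]]
  if (length(seg_a) != length(seg_b))
    stop("core rows have different segment counts")
  classes <- character(0)
  for (k in seq_along(seg_a)) {
    aln <- structure(list(ref_id = "a", qry_id = "b",
                          ref_aln = seg_a[k], qry_aln = seg_b[k]),
                     class = "pairwise_alignment")
    ev <- extract_indels(aln)
    if (nrow(ev) == 0L) next
    refseq <- gsub("-", "", seg_a[k], fixed = TRUE)
    for (i in seq_len(nrow(ev))) {
      cl <- classify_motif(ev$pos[i], ev$ref[i], ev$alt[i], refseq,
                           window = max(window, abs(ev$length[i])))
      classes <- c(classes, cl$primary)
    }
  }
  unique(classes)
}
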