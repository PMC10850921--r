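## Primer-pair marker design around discovered INDELs, in-silico PCR, and
## size-coded genotype calling.

#' Construct a marker definition
#'
#' @param locus Marker name.
#' @param fwd_primer,rev_primer Primer sequences, 5'->3' (the reverse primer
#'   as ordered, i.e. the reverse complement of the + strand).
#' @param ref_start,ref_end 1-based inclusive amplicon coordinates on the
#'   design reference.
#' @return Object of class `marker_def` with `expected_length`
#'   (= ref_end - ref_start + 1).
#' @export
marker_def <- function(locus, fwd_primer, rev_primer, ref_start, ref_end) {
  for (p in c(fwd_primer, rev_primer))
    if (nchar(p) < 18L || nchar(p) > 27L)
      stop("primers must be 18-27 nt (", p, " is ", nchar(p), ")")
  if (ref_end < ref_start) stop("ref_end must be >= ref_start")
  structure(list(locus = locus, fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 ref_start = as.integer(ref_start),
                 ref_end = as.integer(ref_end),
                 expected_length = as.integer(ref_end - ref_start + 1L)),
            class = "marker_def")
}

#' @export
print.marker_def <- function(x, ...) {
  cat("<marker_def>", x$locus, ":", x$ref_start, "..", x$ref_end,
      sprintf("(%d nt)\n", x$expected_length))
  cat("  F:", x$fwd_primer, "\n  R:", x$rev_primer, "\n")
  invisible(x)
}

## Wallace-rule melting temperature: 2(A+T) + 4(G+C)
primer_tm <- function(p) {
  ch <- seq_chars(p)
  2L * sum(ch %in% c("A", "T")) + 4L * sum(ch %in% c("G", "C"))
}

## all start positions of fixed pattern `pat` in `x`
find_sites <- function(x, pat) {
  m <- gregexpr(pat, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Design a primer-pair marker bracketing an INDEL
#'
#' Searches variant flanks for primer sites that occur exactly once in the
#' reference (forward on the + strand; reverse as a reverse complement on the
#' - strand), melting temperature within `tm_window` of `tm_target` by the
#' 2AT+4GC rule, and a total amplicon length within `amplicon_window`. The
#' site pair closest to the variant wins. Returns an undesignable result
#' (not an error) when no unique site pair exists, modeling markers that fail
#' at the design stage.
#'
#' @param reference A `circular_genome` or DNA string.
#' @param variant list or one-row data.frame with `pos`, `ref`, `alt`.
#' @param locus Name for the marker.
#' @param primer_len Primer length used in the scan.
#' @param amplicon_window Allowed amplicon lengths, `c(min, max)`.
#' @param tm_target,tm_window Melting-temperature screen, degrees C.
#' @return A `marker_def`, or an object of class `marker_undesignable`
#'   carrying the reason.
#' @export
design_primers <- function(reference, variant, locus = "marker",
                           primer_len = 20L,
                           amplicon_window = c(100L, 300L),
                           tm_target = 60, tm_window = 5) {
  seqn <- if (inherits(reference, "circular_genome")) reference$sequence
          else reference
  vpos <- variant$pos
  vend <- variant$pos + nchar(variant$ref) - 1L
  min_len <- amplicon_window[1]
  max_len <- amplicon_window[2]
  primer_ok <- function(p, fwd) {
    if (abs(primer_tm(p) - tm_target) > tm_window) return(FALSE)
    if (fwd) length(find_sites(seqn, p)) == 1L
    else length(find_sites(seqn, revcomp(p))) == 1L
  }
  ## forward starts scanned outward from the variant
  f_lo <- max(1L, vend - max_len + primer_len + 1L)
  f_hi <- vpos - primer_len
  if (f_hi < f_lo)
    return(undesignable(locus, "no room for a forward primer"))
  for (fs in seq(f_hi, f_lo, by = -1L)) {
    fwd <- substr(seqn, fs, fs + primer_len - 1L)
    if (!primer_ok(fwd, fwd = TRUE)) next
    r_lo <- max(vend + primer_len, fs + min_len - 1L)
    r_hi <- min(nchar(seqn), fs + max_len - 1L)
    if (r_hi < r_lo) next
    for (re in seq(r_lo, r_hi)) {
      plus <- substr(seqn, re - primer_len + 1L, re)
      rev <- revcomp(plus)
      if (!primer_ok(rev, fwd = FALSE)) next
      return(marker_def(locus, fwd, rev, fs, re))
    }
  }
  undesignable(locus, "no unique primer pair in the flanking windows")
}

undesignable <- function(locus, reason) {
  structure(list(locus = locus, reason = reason),
            class = "marker_undesignable")
}

#' @export
print.marker_undesignable <- function(x, ...) {
  cat("<marker_undesignable>", x$locus, "-", x$reason, "\n")
  invisible(x)
}

#' In-silico PCR of one marker against a genome
#'
#' Exact-match primer binding: a product is reported iff exactly one forward
#' site pairs with exactly one downstream reverse site within
#' `max_product` nt. Multiple alternative products raise an error listing the
#' sites; no valid pair returns NULL (no product).
#'
#' @param genome A `circular_genome` or DNA string.
#' @param marker A `marker_def`.
#' @param max_product Maximum product size in nt.
#' @return list(locus, start, end, length, sequence) or NULL.
#' @export
insilico_pcr <- function(genome, marker, max_product = 2000L) {
  seqn <- if (inherits(genome, "circular_genome")) genome$sequence else genome
  f_sites <- find_sites(seqn, marker$fwd_primer)
  r_sites <- find_sites(seqn, revcomp(marker$rev_primer))
  if (length(f_sites) == 0L || length(r_sites) == 0L) return(NULL)
  r_len <- nchar(marker$rev_primer)
  f_len <- nchar(marker$fwd_primer)
  pairs <- list()
  for (f in f_sites) {
    for (r in r_sites) {
      end <- r + r_len - 1L
      if (r >= f + f_len && end - f + 1L <= max_product)
        pairs[[length(pairs) + 1L]] <- c(f, end)
    }
  }
  if (length(pairs) == 0L) return(NULL)
  if (length(pairs) > 1L)
    stop("ambiguous products for ", marker$locus, ": ",
         paste(vapply(pairs, function(p)
           sprintf("%d..%d", p[1], p[2]), ""), collapse = ", "))
  p <- pairs[[1]]
  list(locus = marker$locus, start = p[1], end = p[2],
       length = p[2] - p[1] + 1L, sequence = substr(seqn, p[1], p[2]))
}

#' Run a marker panel across accessions
#'
#' @param genomes Named list of `circular_genome`s or named character vector.
#' @param markers List of `marker_def`s.
#' @param max_product Passed to [insilico_pcr()].
#' @return data.frame(accession, locus, amplicon_length) with NA for no
#'   product.
#' @export
genotype_panel <- function(genomes, markers, max_product = 2000L) {
  stopifnot(!is.null(names(genomes)))
  rows <- list()
  for (acc in names(genomes)) {
    for (m in markers) {
      prod <- insilico_pcr(genomes[[acc]], m, max_product)
      rows[[length(rows) + 1L]] <-
        data.frame(accession = acc, locus = m$locus,
                   amplicon_length = if (is.null(prod)) NA_integer_
                                     else prod$length,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Encode amplicon lengths as integer allele codes
#'
#' Within each locus, distinct observed lengths are mapped to codes 1, 2, ...
#' in ascending length order (code 1 = shortest allele; a coding convention,
#' not implied by the published tables). No product stays missing.
#'
#' @param amplicons data.frame(accession, locus, amplicon_length).
#' @return `amplicons` with an added `allele_code` integer column.
#' @export
call_genotypes <- function(amplicons) {
  stopifnot(all(c("accession", "locus", "amplicon_length") %in%
                names(amplicons)))
  if (any(!is.na(amplicons$amplicon_length) & amplicons$amplicon_length <= 0))
    stop("amplicon lengths must be positive")
  amplicons$allele_code <- NA_integer_
  for (loc in unique(amplicons$locus)) {
    i <- amplicons$locus == loc & !is.na(amplicons$amplicon_length)
    lens <- sort(unique(amplicons$amplicon_length[i]))
    amplicons$allele_code[i] <-
      match(amplicons$amplicon_length[i], lens)
  }
  amplicons
}

#' Pivot genotype calls into an accession x locus code matrix
#'
#' @param calls Output of [call_genotypes()].
#' @param loci Column order; defaults to order of appearance.
#' @return data.frame with `accession` plus one integer column per locus
#'   (NA = missing).
#' @export
genotype_matrix <- function(calls, loci = unique(calls$locus)) {
  accs <- unique(calls$accession)
  out <- data.frame(accession = accs, stringsAsFactors = FALSE)
  for (loc in loci) {
    sub <- calls[calls$locus == loc, ]
    out[[loc]] <- sub$allele_code[match(accs, sub$accession)]
  }
  out
}

#' Write a marker panel as TSV
#'
#' Columns mirror the published marker table: locus, primers, motif,
#' reference coordinates, expected length.
#'
#' @param markers List of `marker_def`s.
#' @param path Output path.
#' @param motifs Optional character vector of motif labels per marker.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path, motifs = NULL) {
  df <- do.call(rbind, lapply(markers, function(m)
    data.frame(locus = m$locus, forward = m$fwd_primer,
               reverse = m$rev_primer, start = m$ref_start,
               end = m$ref_end, length = m$expected_length,
               stringsAsFactors = FALSE)))
  if (!is.null(motifs)) df$motif <- motifs
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
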