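## INDEL extraction from pairwise alignments, VCF-style left normalization,
## coverage/allele-fraction screening, and repeat-motif classification.

MOTIF_CLASSES <- c("single_nucleotide_repeat", "tandem", "ssr", "no_motif")

#' Left-normalize an anchored INDEL event
#'
#' Shifts an anchored (pos, ref, alt) representation left through repeat
#' context until it can shift no further without changing the alleles; the
#' standard VCF left-alignment. Idempotent.
#'
#' @param sequence Reference sequence the event is anchored on.
#' @param pos 1-based position of the anchor base.
#' @param ref,alt Anchored alleles (one a strict prefix of the other).
#' @return list(pos, ref, alt).
#' @export
left_normalize_event <- function(sequence, pos, ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  if (lr == la) stop("not an INDEL: alleles have equal length")
  if (substr(sequence, pos, pos + lr - 1L) != ref)
    stop("ref allele does not match the sequence at ", pos)
  if (lr < la) {                       # insertion of S after pos
    s <- substr(alt, 2L, la)
    L <- nchar(s)
    p <- pos
    while (p > 1L && substr(s, L, L) == substr(sequence, p, p)) {
      s <- paste0(substr(s, L, L), substr(s, 1L, L - 1L))
      p <- p - 1L
    }
    anchor <- substr(sequence, p, p)
    list(pos = p, ref = anchor, alt = paste0(anchor, s))
  } else {                             # deletion of sequence[(pos+1)..e]
    s <- pos + 1L
    e <- pos + lr - 1L
    while (s > 2L &&
           substr(sequence, s - 1L, s - 1L) == substr(sequence, e, e)) {
      s <- s - 1L
      e <- e - 1L
    }
    anchor <- substr(sequence, s - 1L, s - 1L)
    list(pos = s - 1L, ref = paste0(anchor, substr(sequence, s, e)),
         alt = anchor)
  }
}

#' Extract INDEL variants from a pairwise alignment
#'
#' Maximal gap runs become single events in anchored (VCF-style) allele
#' representation, left-normalized against the reference and sorted by
#' position. Columns gapped in the reference row are insertions; columns
#' gapped in the query row are deletions.
#'
#' @param aln A `pairwise_alignment` (reference row first).
#' @return data.frame(pos, ref, alt, length, type); `length` is signed
#'   (insertions positive).
#' @export
extract_indels <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  rc <- seq_chars(aln$ref_aln)
  qc <- seq_chars(aln$qry_aln)
  if (any(rc == "-" & qc == "-"))
    stop("alignment has a column gapped in both rows")
  refseq <- gsub("-", "", aln$ref_aln, fixed = TRUE)
  gap <- rc == "-" | qc == "-"
  if (!any(gap))
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), length = integer(0),
                      type = character(0)))
  runs <- rle(gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ref_pos <- cumsum(rc != "-")
  out <- list()
  for (i in which(runs$values)) {
    cols <- starts[i]:ends[i]
    p <- if (starts[i] == 1L) 0L else ref_pos[starts[i] - 1L]
    if (all(rc[cols] == "-")) {          # insertion
      ins <- paste(qc[cols], collapse = "")
      if (p == 0L) {                     # event at alignment start: anchor right
        anchor <- substr(refseq, 1L, 1L)
        ev <- list(pos = 1L, ref = anchor, alt = paste0(ins, anchor))
      } else {
        anchor <- substr(refseq, p, p)
        ev <- left_normalize_event(refseq, p, anchor, paste0(anchor, ins))
      }
      type <- "ins"
    } else if (all(qc[cols] == "-")) {   # deletion
      del <- paste(rc[cols], collapse = "")
      if (p == 0L) {
        ev <- list(pos = 1L, ref = paste0(del, substr(refseq, nchar(del) + 1L,
                                                      nchar(del) + 1L)),
                   alt = substr(refseq, nchar(del) + 1L, nchar(del) + 1L))
      } else {
        anchor <- substr(refseq, p, p)
        ev <- left_normalize_event(refseq, p, paste0(anchor, del), anchor)
      }
      type <- "del"
    } else {
      ## mixed run (insertion adjacent to deletion): split into sub-runs
      sub <- rle(rc[cols] == "-")
      sub_ends <- cumsum(sub$lengths)
      sub_starts <- sub_ends - sub$lengths + 1L
      for (j in seq_along(sub$values)) {
        scols <- cols[sub_starts[j]:sub_ends[j]]
        pj <- if (scols[1] == 1L) 0L else ref_pos[scols[1] - 1L]
        if (sub$values[j]) {
          ins <- paste(qc[scols], collapse = "")
          anchor <- substr(refseq, max(pj, 1L), max(pj, 1L))
          ev <- if (pj == 0L)
            list(pos = 1L, ref = anchor, alt = paste0(ins, anchor))
          else left_normalize_event(refseq, pj, anchor, paste0(anchor, ins))
          type <- "ins"
        } else {
          del <- paste(rc[scols], collapse = "")
          anchor <- substr(refseq, pj, pj)
          ev <- left_normalize_event(refseq, pj, paste0(anchor, del), anchor)
          type <- "del"
        }
        out[[length(out) + 1L]] <-
          data.frame(pos = ev$pos, ref = ev$ref, alt = ev$alt,
                     length = nchar(ev$alt) - nchar(ev$ref), type = type,
                     stringsAsFactors = FALSE)
      }
      next
    }
    out[[length(out) + 1L]] <-
      data.frame(pos = ev$pos, ref = ev$ref, alt = ev$alt,
                 length = nchar(ev$alt) - nchar(ev$ref), type = type,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screening thresholds for variant candidates
#'
#' Defaults follow the study's screen: retain candidates with more than 200x
#' coverage and more than 60% allele fraction (both strict).
#'
#' @param min_coverage Coverage threshold (strict `>`).
#' @param min_fraction Allele-fraction threshold (strict `>`).
#' @return list(min_coverage, min_fraction).
#' @export
filter_spec <- function(min_coverage = 200L, min_fraction = 0.60) {
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must be in [0, 1]")
  list(min_coverage = min_coverage, min_fraction = min_fraction)
}

#' Filter variant candidates by coverage and allele fraction
#'
#' Retains rows with `coverage > min_coverage` and
#' `allele_fraction > min_fraction` (strict inequalities), preserving order.
#'
#' @param candidates data.frame with `coverage` and `allele_fraction`.
#' @param spec See [filter_spec()].
#' @return The retained subset.
#' @export
filter_candidates <- function(candidates, spec = filter_spec()) {
  for (col in c("coverage", "allele_fraction")) {
    if (!col %in% names(candidates))
      stop("candidates table lacks column '", col, "'")
    bad <- which(is.na(candidates[[col]]))
    if (length(bad))
      stop("missing ", col, " in row ", bad[1])
  }
  keep <- candidates$coverage > spec$min_coverage &
    candidates$allele_fraction > spec$min_fraction
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the repeat-motif structure of an INDEL
#'
#' Examines the event in its reference context (window of `window` nt on each
#' side) under every placement equivalent to the given one (shifting through
#' repeat context), and reports all matching classes plus a primary class by
#' fixed precedence ssr > tandem > single_nucleotide_repeat > no_motif:
#'
#' * `single_nucleotide_repeat`: the gap allele is a homopolymer and merges
#'   with an adjacent run of the same base to a total of >= 8 nt;
#' * `tandem`: the gap allele (length >= 2, not a homopolymer) equals an
#'   immediately adjacent substring, or starts/ends with one full copy
#'   (>= 4 nt, not itself a homopolymer) of the immediately adjacent
#'   sequence (duplication or contraction of a unit at the event boundary);
#' * `ssr`: the gap lies within a microsatellite of unit 2-6 nt (unit with at
#'   least two distinct bases) with >= 3 tandem copies and spans a whole
#'   number of units;
#' * `no_motif`: none of the above.
#'
#' @param pos,ref,alt Anchored event on `sequence`.
#' @param sequence Reference sequence (or a context string containing the
#'   event with at least `window` nt of flank where available).
#' @param window Flank width examined on each side of the event.
#' @return list(classes = character vector, primary = character scalar).
#' @export
classify_motif <- function(pos, ref, alt, sequence, window = 30L) {
  lr <- nchar(ref)
  la <- nchar(alt)
  if (lr == la) stop("not an INDEL")
  if (substr(sequence, pos, pos + lr - 1L) != ref)
    stop("ref allele does not match the sequence at ", pos)
  L <- abs(la - lr)
  if (window < L)
    stop("context window (", window, ") shorter than the event (", L, ")")
  ## 'long' local string: the sequence version that contains the gap allele
  is_ins <- la > lr
  ctx_start <- max(1L, pos - window)
  ctx_end <- min(nchar(sequence), pos + lr - 1L + window)
  ctx <- substr(sequence, ctx_start, ctx_end)
  off <- pos - ctx_start + 1L          # anchor position within ctx
  if (is_ins) {
    long <- paste0(substr(ctx, 1L, off), substr(alt, 2L, la),
                   substr(ctx, off + 1L, nchar(ctx)))
    s <- off + 1L
  } else {
    long <- ctx
    s <- off + 1L
  }
  e <- s + L - 1L
  lc <- seq_chars(long)
  n <- length(lc)

  ## all placements equivalent to [s, e] within the window
  placements <- list(c(s, e))
  si <- s; ei <- e
  while (si > 1L && lc[si - 1L] == lc[ei]) {
    si <- si - 1L; ei <- ei - 1L
    placements[[length(placements) + 1L]] <- c(si, ei)
  }
  si <- s; ei <- e
  while (ei < n && lc[ei + 1L] == lc[si]) {
    si <- si + 1L; ei <- ei + 1L
    placements[[length(placements) + 1L]] <- c(si, ei)
  }

  classes <- character(0)
  for (pl in placements) {
    si <- pl[1]; ei <- pl[2]
    allele <- lc[si:ei]
    hp <- length(unique(allele)) == 1L
    if (hp) {
      b <- allele[1]
      total <- L + run_left(lc, si - 1L, b) + run_right(lc, ei + 1L, b)
      if (total >= 8L)
        classes <- c(classes, "single_nucleotide_repeat")
    } else if (L >= 2L) {
      ## duplication/contraction of a unit adjacent to the gap: either the
      ## whole allele equals the neighboring substring, or the allele starts/
      ## ends with one full copy (>= 4 nt) of it
      units <- unique(c(L, seq_len(L)[seq_len(L) >= 4L & seq_len(L) < L]))
      for (u in units) {
        left_ok <- si - u >= 1L &&
          length(unique(allele[1:u])) > 1L &&
          all(lc[(si - u):(si - 1L)] == allele[1:u])
        right_ok <- ei + u <= n &&
          length(unique(allele[(L - u + 1L):L])) > 1L &&
          all(lc[(ei + 1L):(ei + u)] == allele[(L - u + 1L):L])
        if (left_ok || right_ok) {
          classes <- c(classes, "tandem")
          break
        }
      }
    }
    for (u in 2:6) {
      if (L %% u != 0L) next
      ## the gap allele itself must be periodic with period u
      if (L > u && !all(lc[si:(ei - u)] == lc[(si + u):ei])) next
      ## maximal period-u stretch around [si, ei]
      lo <- si
      while (lo - 1L >= 1L && lo - 1L + u <= n && lc[lo - 1L] == lc[lo - 1L + u])
        lo <- lo - 1L
      hi <- ei
      while (hi + 1L <= n && hi + 1L - u >= 1L && lc[hi + 1L] == lc[hi + 1L - u])
        hi <- hi + 1L
      arr_len <- hi - lo + 1L
      if (arr_len < 3L * u || arr_len < L + u) next
      unit <- lc[si:(si + u - 1L)]
      if (length(unique(unit)) < 2L) next
      classes <- c(classes, "ssr")
    }
  }
  classes <- unique(classes)
  if (length(classes) == 0L) classes <- "no_motif"
  primary <- MOTIF_CLASSES[c(3L, 2L, 1L, 4L)]
  primary <- primary[primary %in% classes][1]
  list(classes = classes, primary = primary)
}

#' Classify every INDEL in a variant table
#'
#' @param variants data.frame(pos, ref, alt, ...).
#' @param sequence Reference sequence.
#' @param window Flank width; see [classify_motif()].
#' @return `variants` with added columns `motif_primary` and `motif_classes`
#'   (comma-joined).
#' @export
classify_variants <- function(variants, sequence, window = 30L) {
  res <- lapply(seq_len(nrow(variants)), function(i)
    classify_motif(variants$pos[i], variants$ref[i], variants$alt[i],
                   sequence, window))
  variants$motif_primary <- vapply(res, `[[`, "", "primary")
  variants$motif_classes <- vapply(res, function(r)
    paste(r$classes, collapse = ","), "")
  variants
}

#' Census of INDEL motif classes
#'
#' Counts variants by primary class; events matching several classes are
#' counted once under their primary class and tallied separately.
#'
#' @param variants data.frame with `motif_primary` and `motif_classes`
#'   (from [classify_variants()]).
#' @return list(primary = named integer vector over the four classes,
#'   multi_label = integer count of events with more than one class).
#' @export
motif_census <- function(variants) {
  counts <- stats::setNames(integer(length(MOTIF_CLASSES)), MOTIF_CLASSES)
  if (nrow(variants)) {
    tt <- table(variants$motif_primary)
    counts[names(tt)] <- as.integer(tt)
  }
  multi <- if (nrow(variants))
    sum(vapply(strsplit(variants$motif_classes, ",", fixed = TRUE),
               length, 1L) > 1L)
  else 0L
  list(primary = counts, multi_label = multi)
}

#' Write variants as a minimal VCF 4.2 file
#'
#' @param variants data.frame(pos, ref, alt) with optional `motif_primary`,
#'   `coverage`, `allele_fraction`.
#' @param path Output path.
#' @param chrom Chromosome name.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, chrom = "plastome") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"Primary repeat-motif class\">",
           "##INFO=<ID=COV,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character(0)
    if (!is.null(variants$motif_primary))
      parts <- c(parts, paste0("MOTIF=", variants$motif_primary[i]))
    if (!is.null(variants$coverage))
      parts <- c(parts, paste0("COV=", variants$coverage[i]))
    if (!is.null(variants$allele_fraction))
      parts <- c(parts, paste0("AF=", signif(variants$allele_fraction[i], 4)))
    if (length(parts) == 0L) "." else paste(parts, collapse = ";")
  }, "")
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", chrom, variants$pos,
                  variants$ref, variants$alt, info)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
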