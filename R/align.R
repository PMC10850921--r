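## Global pairwise alignment of whole plastomes by anchor-and-chain: unique
## shared k-mers are chained colinearly and the short inter-anchor segments
## are solved by full affine-gap dynamic programming (Biostrings). On anchor
## -free inputs small enough for DP the result is identical to full DP.

#' Alignment scoring parameters
#'
#' Defaults favor single long gaps over scattered ones, matching the discrete
#' INDELs that separate near-identical plastomes.
#'
#' @param match Match score.
#' @param mismatch Mismatch score.
#' @param gap_open Gap-opening penalty (positive cost).
#' @param gap_ext Gap-extension penalty (positive cost).
#' @param k Anchor k-mer size.
#' @param stride Minimum spacing kept between chained anchors; wider spacing
#'   leaves longer (still cheap) inter-anchor segments.
#' @param max_dp_cells Largest m*n solved by direct dynamic programming.
#' @return list of scoring parameters.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = 10,
                         gap_ext = 0.5, k = 21L, stride = 400L,
                         max_dp_cells = 4e6) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext, k = as.integer(k),
       stride = max(as.integer(stride), as.integer(k)),
       max_dp_cells = max_dp_cells)
}

#' Global end-to-end alignment of two genome sequences
#'
#' @param a,b DNA strings (reference and query); uppercase A/C/G/T (N
#'   tolerated).
#' @param params See [align_params()].
#' @param ref_id,qry_id Labels carried into the result.
#' @return Object of class `pairwise_alignment`: list(ref_id, qry_id,
#'   ref_aln, qry_aln) with equal-length gapped strings.
#' @export
align_pair <- function(a, b, params = align_params(),
                       ref_id = "ref", qry_id = "qry") {
  check_dna(a, allow = "ACGTN", what = "sequence 'a'")
  check_dna(b, allow = "ACGTN", what = "sequence 'b'")
  if (is.null(params$submat))
    params$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  aln <- align_rec(a, b, params)
  out <- structure(list(ref_id = ref_id, qry_id = qry_id,
                        ref_aln = aln[[1]], qry_aln = aln[[2]]),
                   class = "pairwise_alignment")
  validate_alignment(out, a, b)
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  n <- nchar(x$ref_aln)
  gaps_r <- n - nchar(gsub("-", "", x$ref_aln, fixed = TRUE))
  gaps_q <- n - nchar(gsub("-", "", x$qry_aln, fixed = TRUE))
  cat("<pairwise_alignment> ", x$ref_id, " vs ", x$qry_id, ": ", n,
      " columns, ", gaps_r, " ref gaps, ", gaps_q, " query gaps\n", sep = "")
  invisible(x)
}

validate_alignment <- function(aln, a, b) {
  if (nchar(aln$ref_aln) != nchar(aln$qry_aln))
    stop("aligned rows differ in length")
  if (gsub("-", "", aln$ref_aln, fixed = TRUE) != a ||
      gsub("-", "", aln$qry_aln, fixed = TRUE) != b)
    stop("alignment does not round-trip to the input sequences")
  invisible(TRUE)
}

## recursive anchor-and-chain; returns list(ref_aln, qry_aln)
align_rec <- function(a, b, params) {
  na <- nchar(a)
  nb <- nchar(b)
  if (na == 0L && nb == 0L) return(list("", ""))
  if (na == 0L) return(list(strrep("-", nb), b))
  if (nb == 0L) return(list(a, strrep("-", na)))
  if (a == b) return(list(a, b))
  if (na == nb) {
    ## an ungapped alignment is provably optimal when the mismatch count is
    ## small: any gapped alternative of equal-length sequences pays at least
    ## two gap openings, which exceeds the largest possible mismatch gain
    mism <- sum(seq_chars(a) != seq_chars(b))
    if (mism * (params$match - params$mismatch) < 2 * params$gap_open)
      return(list(a, b))
  }
  if (as.double(na) * nb <= params$max_dp_cells)
    return(align_dp(a, b, params))
  anchors <- chain_anchors(a, b, params$k, params$stride)
  if (nrow(anchors) == 0L) {
    for (k2 in c(15L, 11L, 8L)) {
      anchors <- chain_anchors(a, b, k2, params$stride)
      if (nrow(anchors) > 0L) break
    }
    if (nrow(anchors) == 0L)
      stop("sequences too divergent to anchor and too long for direct ",
           "dynamic programming (", na, " x ", nb, ")")
  }
  k <- attr(anchors, "k")
  ref_parts <- character(0)
  qry_parts <- character(0)
  pa <- 1L
  pb <- 1L
  for (i in seq_len(nrow(anchors))) {
    sa <- anchors$a[i]
    sb <- anchors$b[i]
    seg <- align_rec(substr(a, pa, sa - 1L), substr(b, pb, sb - 1L), params)
    ref_parts <- c(ref_parts, seg[[1]], substr(a, sa, sa + k - 1L))
    qry_parts <- c(qry_parts, seg[[2]], substr(b, sb, sb + k - 1L))
    pa <- sa + k
    pb <- sb + k
  }
  seg <- align_rec(substr(a, pa, na), substr(b, pb, nb), params)
  list(paste0(paste(ref_parts, collapse = ""), seg[[1]]),
       paste0(paste(qry_parts, collapse = ""), seg[[2]]))
}

## k-mers occurring exactly once in each sequence, chained colinearly
## (longest increasing subsequence), then trimmed to be non-overlapping
chain_anchors <- function(a, b, k, stride = 400L) {
  empty <- data.frame(a = integer(0), b = integer(0))
  attr(empty, "k") <- k
  ka <- unique_kmers(a, k)
  if (length(ka) == 0L) return(empty)
  kb <- unique_kmers(b, k)
  if (length(kb) == 0L) return(empty)
  shared <- intersect(names(ka), names(kb))
  if (length(shared) == 0L) return(empty)
  pa <- unname(ka[shared])
  pb <- unname(kb[shared])
  o <- order(pa)
  pa <- pa[o]
  pb <- pb[o]
  lis <- lis_indices(pb)
  pa <- pa[lis]
  pb <- pb[lis]
  ## thin the chain: keep anchors at least `stride` apart (and never
  ## overlapping) in both sequences
  gap <- max(stride, k)
  keep <- logical(length(pa))
  last_a <- -gap
  last_b <- -gap
  for (i in seq_along(pa)) {
    if (pa[i] >= last_a + gap && pb[i] >= last_b + gap) {
      keep[i] <- TRUE
      last_a <- pa[i]
      last_b <- pb[i]
    }
  }
  m <- data.frame(a = pa[keep], b = pb[keep])
  attr(m, "k") <- k
  m
}

## start positions of k-mers occurring exactly once; names are the k-mers
unique_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(x, starts, starts + k - 1L)
  once <- !(duplicated(km) | duplicated(km, fromLast = TRUE))
  pos <- starts[once]
  names(pos) <- km[once]
  pos
}

## indices of a longest strictly-increasing subsequence (patience sorting)
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (!is.unsorted(x, strictly = TRUE)) return(seq_len(n))
  tails <- integer(0)   # indices into x of the smallest tail per length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L
    hi <- length(tails) + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  j <- tails[length(tails)]
  for (i in rev(seq_along(tails))) {
    out[i] <- j
    j <- prev[j]
  }
  out
}

## direct affine-gap global DP on a short segment (Biostrings backend)
align_dp <- function(a, b, params) {
  mat <- params$submat
  if (is.null(mat))
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_ext)
  list(as.character(Biostrings::alignedPattern(aln)),
       as.character(Biostrings::alignedSubject(aln)))
}

#' Map alignment columns to ungapped 1-based coordinates
#'
#' @param aln A `pairwise_alignment`.
#' @return data.frame(column, ref_pos, qry_pos); gap columns carry the
#'   position of the last preceding base (0 before the first).
#' @export
alignment_coords <- function(aln, ...) {
  rc <- seq_chars(aln$ref_aln)
  qc <- seq_chars(aln$qry_aln)
  data.frame(column = seq_along(rc),
             ref_pos = cumsum(rc != "-"),
             qry_pos = cumsum(qc != "-"))
}
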