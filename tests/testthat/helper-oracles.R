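## Independent brute-force oracles and small fixture builders. These follow
## the documented rules by direct string/row scanning, deliberately avoiding
## the package's index arithmetic.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                              collapse = "")

## --- brute-force motif scanner ----------------------------------------

## all placements of a deletion/insertion equivalent to the given one, found
## by exhaustive string equality: every interval of the long string whose
## removal yields the same short string
bf_placements <- function(long, s, e) {
  L <- e - s + 1L
  n <- nchar(long)
  short0 <- paste0(substr(long, 1L, s - 1L), substr(long, e + 1L, n))
  out <- list()
  for (s2 in seq_len(n - L + 1L)) {
    e2 <- s2 + L - 1L
    short <- paste0(substr(long, 1L, s2 - 1L), substr(long, e2 + 1L, n))
    if (short == short0) out[[length(out) + 1L]] <- c(s2, e2)
  }
  out
}

bf_is_homo <- function(x) length(unique(strsplit(x, "")[[1]])) == 1L

## maximal run of base b in long containing column i (0 if long[i] != b)
bf_run_span <- function(long, i, b) {
  ch <- strsplit(long, "")[[1]]
  if (ch[i] != b) return(0L)
  lo <- i
  while (lo > 1L && ch[lo - 1L] == b) lo <- lo - 1L
  hi <- i
  while (hi < length(ch) && ch[hi + 1L] == b) hi <- hi + 1L
  hi - lo + 1L
}

bf_classify <- function(pos, ref, alt, sequence, window = 30L) {
  L <- abs(nchar(alt) - nchar(ref))
  is_ins <- nchar(alt) > nchar(ref)
  ctx_start <- max(1L, pos - window)
  ctx_end <- min(nchar(sequence), pos + nchar(ref) - 1L + window)
  ctx <- substr(sequence, ctx_start, ctx_end)
  off <- pos - ctx_start + 1L
  if (is_ins) {
    long <- paste0(substr(ctx, 1L, off), substr(alt, 2L, nchar(alt)),
                   substr(ctx, off + 1L, nchar(ctx)))
  } else {
    long <- ctx
  }
  s <- off + 1L
  e <- s + L - 1L
  classes <- character(0)
  for (pl in bf_placements(long, s, e)) {
    si <- pl[1]
    ei <- pl[2]
    allele <- substr(long, si, ei)
    ## single-nucleotide repeat
    if (bf_is_homo(allele)) {
      b <- substr(allele, 1L, 1L)
      if (bf_run_span(long, si, b) >= 8L)
        classes <- c(classes, "single_nucleotide_repeat")
    }
    ## tandem: whole allele, or a >= 4 nt non-homopolymer boundary unit
    if (L >= 2L && !bf_is_homo(allele)) {
      for (u in unique(c(L, setdiff(4:max(4L, L - 1L), 0)))) {
        if (u > L || u < 2L) next
        if (u < L && u < 4L) next
        pre <- substr(allele, 1L, u)
        suf <- substr(allele, L - u + 1L, L)
        left <- if (si - u >= 1L) substr(long, si - u, si - 1L) else NULL
        right <- if (ei + u <= nchar(long))
          substr(long, ei + 1L, ei + u) else NULL
        hit <- (!is.null(left) && !bf_is_homo(pre) && left == pre) ||
          (!is.null(right) && !bf_is_homo(suf) && right == suf)
        if (hit) {
          classes <- c(classes, "tandem")
          break
        }
      }
    }
    ## ssr: gap = whole number of units of a >= 3-copy microsatellite
    for (u in 2:6) {
      if (L %% u != 0L) next
      if (L > u) {
        periodic <- substr(long, si, ei - u) ==
          substr(long, si + u, ei)
        if (!periodic) next
      }
      lo <- si
      while (lo - 1L >= 1L &&
             substr(long, lo - 1L, lo - 1L) ==
             substr(long, lo - 1L + u, lo - 1L + u) &&
             lo - 1L + u <= nchar(long))
        lo <- lo - 1L
      hi <- ei
      while (hi + 1L <= nchar(long) && hi + 1L - u >= 1L &&
             substr(long, hi + 1L, hi + 1L) ==
             substr(long, hi + 1L - u, hi + 1L - u))
        hi <- hi + 1L
      if (hi - lo + 1L < 3L * u || hi - lo + 1L < L + u) next
      if (bf_is_homo(substr(long, si, si + u - 1L))) next
      classes <- c(classes, "ssr")
    }
  }
  classes <- unique(classes)
  if (length(classes) == 0L) classes <- "no_motif"
  prim <- c("ssr", "tandem", "single_nucleotide_repeat", "no_motif")
  list(classes = classes, primary = prim[prim %in% classes][1])
}

## --- other oracles ------------------------------------------------------

bf_filter <- function(tab, min_cov, min_frac) {
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab)))
    keep[i] <- tab$coverage[i] > min_cov && tab$allele_fraction[i] > min_frac
  tab[keep, , drop = FALSE]
}

bf_rank_codes <- function(amplicons) {
  codes <- rep(NA_integer_, nrow(amplicons))
  for (loc in unique(amplicons$locus)) {
    rows <- which(amplicons$locus == loc & !is.na(amplicons$amplicon_length))
    lens <- sort(unique(amplicons$amplicon_length[rows]))
    for (r in rows)
      codes[r] <- which(lens == amplicons$amplicon_length[r])
  }
  codes
}

bf_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  s <- if (length(x) > 1L) sqrt(sum((x - m)^2) / (length(x) - 1L)) else 0
  c(mean = m, sd = s)
}

bf_usable <- function(mat) {
  n <- nrow(mat)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cnt <- 0L
    for (col in seq_len(ncol(mat)))
      if (mat[i, col] %in% BASES && mat[j, col] %in% BASES)
        cnt <- cnt + 1L
    out[i, j] <- cnt
  }
  dimnames(out) <- list(rownames(mat), rownames(mat))
  out
}

bf_variable_sites <- function(mat, mode) {
  cnt <- 0L
  for (col in seq_len(ncol(mat))) {
    x <- mat[, col]
    x <- x[x %in% BASES]
    if (length(x) < 2L) next
    tt <- table(x)
    if (mode == "variable" && length(tt) >= 2L) cnt <- cnt + 1L
    if (mode == "parsimony" && sum(tt >= 2L) >= 2L) cnt <- cnt + 1L
  }
  cnt
}

jc_closed_form <- function(p) -3 / 4 * log(1 - 4 * p / 3)

## random rooted tree -> additive distance matrix (path lengths)
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
  D <- stats::cophenetic(tr)
  list(tree = tr, D = D[order(rownames(D)), order(colnames(D))])
}

## newick string of the five-taxon generating topology
truth_topology <- function() {
  ape::read.tree(text = "(outgroup,(incisa,(japonica,(natans,bispinosa))));")
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

small_regions <- c(LSC = 12000L, IRa = 3000L, SSC = 2500L, IRb = 3000L)
tiny_regions <- c(LSC = 4000L, IRa = 1000L, SSC = 800L, IRb = 1000L)
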