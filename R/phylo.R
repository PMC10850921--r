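## Maximum-composite-likelihood (TN93-family) pairwise distances with
## pairwise deletion, neighbor-joining, outgroup rooting, and site census.

#' Construct a multiple alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences over
#'   A, C, G, T, `-`, N.
#' @return Object of class `multi_alignment` (character matrix, taxa in
#'   rows).
#' @export
multi_alignment <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), length(seqs) >= 2L)
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length")
  bad <- gsub("[ACGTN-]", "", paste(seqs, collapse = ""))
  if (nchar(bad) > 0L)
    stop("alignment alphabet is {A,C,G,T,-,N}; found: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  structure(list(taxa = names(seqs), mat = mat), class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat("<multi_alignment>", length(x$taxa), "taxa x", ncol(x$mat),
      "columns\n")
  invisible(x)
}

#' Build a reference-projected multiple alignment from unaligned genomes
#'
#' Each genome is aligned pairwise to the chosen reference and the rows are
#' merged on reference coordinates: every column is one reference position,
#' deletions appear as gaps, and insertions relative to the reference are
#' dropped. Adequate for near-identical plastomes; substitution distances use
#' ungapped columns only.
#'
#' @param genomes Named list of `circular_genome`s or named character vector
#'   of sequences (the reference included or supplied separately).
#' @param ref_id Name of the reference record within `genomes`.
#' @param params Alignment scoring; see [align_params()].
#' @return A `multi_alignment` whose column count equals the reference
#'   length.
#' @export
build_multi_alignment <- function(genomes, ref_id, params = align_params()) {
  seqs <- vapply(genomes, function(g)
    if (inherits(g, "circular_genome")) g$sequence else g, "")
  if (!ref_id %in% names(seqs)) stop("ref_id not among genomes")
  ref <- seqs[[ref_id]]
  out <- list()
  for (id in names(seqs)) {
    if (id == ref_id) {
      out[[id]] <- ref
      next
    }
    aln <- align_pair(ref, seqs[[id]], params, ref_id = ref_id, qry_id = id)
    rc <- seq_chars(aln$ref_aln)
    qc <- seq_chars(aln$qry_aln)
    out[[id]] <- paste(qc[rc != "-"], collapse = "")
  }
  multi_alignment(unlist(out))
}

## integer-coded alignment matrix: A=1 C=2 G=3 T=4, other=0
code_matrix <- function(aln) {
  m <- matrix(match(aln$mat, c("A", "C", "G", "T"), nomatch = 0L),
              nrow = nrow(aln$mat))
  rownames(m) <- aln$taxa
  m
}

#' Per-pair usable site counts under pairwise deletion
#'
#' A column is usable for a pair iff both rows hold an unambiguous base
#' (A/C/G/T); gap and N columns are excluded for that pair only.
#'
#' @param aln A `multi_alignment`.
#' @return Symmetric integer matrix of usable-site counts.
#' @export
pairwise_usable_sites <- function(aln) {
  m <- code_matrix(aln)
  n <- nrow(m)
  out <- matrix(0L, n, n, dimnames = list(aln$taxa, aln$taxa))
  ok <- m > 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sum(ok[i, ] & ok[j, ])
    }
  }
  out
}

## 16-category ordered pair-state counts for one pair (4*(x-1)+y)
pair_counts16 <- function(m, i, j) {
  use <- m[i, ] > 0L & m[j, ] > 0L
  tabulate(4L * (m[i, use] - 1L) + m[j, use], nbins = 16L)
}

## TN93 transition-probability matrix at transversion depth b (= beta*t),
## rate ratios k1 (purine transitions), k2 (pyrimidine transitions)
tn93_pmatrix <- function(b, k1, k2, pi) {
  piR <- pi["A"] + pi["G"]
  piY <- pi["C"] + pi["T"]
  e2 <- exp(-b)
  e3 <- exp(-(piR * k1 + piY) * b)
  e4 <- exp(-(piY * k2 + piR) * b)
  P <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  ## purines
  P["A", "A"] <- pi["A"] + pi["A"] * piY / piR * e2 + pi["G"] / piR * e3
  P["A", "G"] <- pi["G"] + pi["G"] * piY / piR * e2 - pi["G"] / piR * e3
  P["G", "G"] <- pi["G"] + pi["G"] * piY / piR * e2 + pi["A"] / piR * e3
  P["G", "A"] <- pi["A"] + pi["A"] * piY / piR * e2 - pi["A"] / piR * e3
  ## pyrimidines
  P["C", "C"] <- pi["C"] + pi["C"] * piR / piY * e2 + pi["T"] / piY * e4
  P["C", "T"] <- pi["T"] + pi["T"] * piR / piY * e2 - pi["T"] / piY * e4
  P["T", "T"] <- pi["T"] + pi["T"] * piR / piY * e2 + pi["C"] / piY * e4
  P["T", "C"] <- pi["C"] + pi["C"] * piR / piY * e2 - pi["C"] / piY * e4
  ## transversions
  for (x in c("A", "G")) for (y in c("C", "T")) P[x, y] <- pi[y] * (1 - e2)
  for (x in c("C", "T")) for (y in c("A", "G")) P[x, y] <- pi[y] * (1 - e2)
  P
}

## expected substitutions per site at depth b
tn93_distance_at <- function(b, k1, k2, pi) {
  piR <- pi["A"] + pi["G"]
  piY <- pi["C"] + pi["T"]
  unname(2 * b * (k1 * pi["A"] * pi["G"] + k2 * pi["C"] * pi["T"] +
                  piR * piY))
}

## joint pair-state probabilities pi_x * P_xy as a 16-vector in category
## order 4*(x-1)+y over A,C,G,T (row-major)
tn93_joint16 <- function(b, k1, k2, pi) {
  piA <- pi[[1]]; piC <- pi[[2]]; piG <- pi[[3]]; piT <- pi[[4]]
  piR <- piA + piG
  piY <- piC + piT
  e2 <- exp(-b)
  e3 <- exp(-(piR * k1 + piY) * b)
  e4 <- exp(-(piY * k2 + piR) * b)
  rr <- piY / piR * e2
  yy <- piR / piY * e2
  tv <- 1 - e2
  pAA <- piA + piA * rr + piG / piR * e3
  pAG <- piG + piG * rr - piG / piR * e3
  pGG <- piG + piG * rr + piA / piR * e3
  pGA <- piA + piA * rr - piA / piR * e3
  pCC <- piC + piC * yy + piT / piY * e4
  pCT <- piT + piT * yy - piT / piY * e4
  pTT <- piT + piT * yy + piC / piY * e4
  pTC <- piC + piC * yy - piC / piY * e4
  c(piA * pAA, piA * piC * tv, piA * pAG, piA * piT * tv,
    piC * piA * tv, piC * pCC, piC * piG * tv, piC * pCT,
    piG * pGA, piG * piC * tv, piG * pGG, piG * piT * tv,
    piT * piA * tv, piT * pTC, piT * piG * tv, piT * pTT)
}

## pair log-likelihood of 16-category counts at depth b
tn93_ll <- function(counts16, b, k1, k2, pi) {
  M <- tn93_joint16(b, k1, k2, pi)
  nz <- counts16 > 0L
  if (any(M[nz] <= 0)) return(-Inf)
  sum(counts16[nz] * log(M[nz]))
}

## ML transversion depth for one pair at fixed (k1, k2, pi); golden-section
## bracket then Newton polish to high precision
pair_ml_b <- function(counts16, k1, k2, pi, b_max = 10, polish = TRUE) {
  diff_idx <- which(as.vector(t(outer(1:4, 1:4, "!="))))
  if (sum(counts16[diff_idx]) == 0L) return(0)
  f <- function(b) tn93_ll(counts16, b, k1, k2, pi)
  opt <- stats::optimize(f, interval = c(1e-10, b_max), maximum = TRUE,
                         tol = if (polish) 1e-10 else 1e-7)
  b <- opt$maximum
  if (!polish) return(b)
  h <- 1e-6
  for (i in 1:30) {
    g1 <- (f(b + h) - f(b - h)) / (2 * h)
    g2 <- (f(b + h) - 2 * f(b) + f(b - h)) / h^2
    if (!is.finite(g1) || !is.finite(g2) || g2 >= 0) break
    step <- g1 / g2
    b_new <- b - step
    if (b_new <= 0 || b_new >= b_max) break
    b <- b_new
    if (abs(step) < 1e-14) break
  }
  b
}

#' Maximum-composite-likelihood pairwise distances (TN93 family)
#'
#' Substitution-rate parameters (two transition classes relative to the
#' transversion class) and base frequencies are shared across all sequence
#' pairs: frequencies are the pooled empirical composition, and the rate
#' ratios maximize the composite (summed pairwise) log-likelihood, profiled
#' over per-pair depths. Ambiguous positions are removed per pair (pairwise
#' deletion). Distances are expected substitutions per site.
#'
#' @param aln A `multi_alignment` with >= 2 taxa.
#' @param fixed_params Optional list(kappa1, kappa2, freqs) to skip the
#'   shared-parameter optimization (e.g. `kappa1 = 1, kappa2 = 1,
#'   freqs = rep(0.25, 4)` forces the Jukes-Cantor special case).
#' @param pgtol Projected-gradient tolerance of the outer L-BFGS-B
#'   optimization.
#' @param b_max Saturation bound on the per-pair depth; a pair whose ML depth
#'   reaches it is flagged and its distance set to NA.
#' @return Object of class `mcl_dist`: list(d = symmetric distance matrix,
#'   usable = per-pair site counts, params = list(kappa1, kappa2, freqs),
#'   flags = data.frame of saturated pairs).
#' @export
mcl_distances <- function(aln, fixed_params = NULL, pgtol = 1e-8,
                          b_max = 10) {
  stopifnot(inherits(aln, "multi_alignment"))
  m <- code_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least two taxa")
  taxa <- aln$taxa
  pairs <- utils::combn(n, 2L)
  counts <- lapply(seq_len(ncol(pairs)), function(p)
    pair_counts16(m, pairs[1, p], pairs[2, p]))
  usable <- pairwise_usable_sites(aln)
  if (any(usable[upper.tri(usable)] < 1L))
    stop("every pair needs at least one usable site")

  if (is.null(fixed_params)) {
    tot <- m[m > 0L]
    pi <- tabulate(tot, 4L) / length(tot)
    names(pi) <- c("A", "C", "G", "T")
    profile_nll <- function(logk) {
      k1 <- exp(logk[1])
      k2 <- exp(logk[2])
      -sum(vapply(counts, function(cc)
        tn93_ll(cc, pair_ml_b(cc, k1, k2, pi, b_max, polish = FALSE),
                k1, k2, pi), 0))
    }
    opt <- stats::optim(c(log(2), log(2)), profile_nll, method = "L-BFGS-B",
                        lower = log(1e-3), upper = log(1e3),
                        control = list(pgtol = pgtol, factr = 10))
    k1 <- exp(opt$par[1])
    k2 <- exp(opt$par[2])
  } else {
    pi <- fixed_params$freqs
    if (is.null(names(pi))) names(pi) <- c("A", "C", "G", "T")
    k1 <- fixed_params$kappa1
    k2 <- fixed_params$kappa2
  }

  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  flags <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    b <- pair_ml_b(counts[[p]], k1, k2, pi, b_max)
    if (b >= b_max * 0.999) {
      d[i, j] <- d[j, i] <- NA_real_
      flags[[length(flags) + 1L]] <-
        data.frame(taxon_a = taxa[i], taxon_b = taxa[j],
                   reason = "saturated: ML depth at bound",
                   stringsAsFactors = FALSE)
    } else {
      d[i, j] <- d[j, i] <- tn93_distance_at(b, k1, k2, pi)
    }
  }
  structure(list(d = d, usable = usable,
                 params = list(kappa1 = k1, kappa2 = k2, freqs = pi),
                 flags = if (length(flags)) do.call(rbind, flags)
                         else NULL),
            class = "mcl_dist")
}

#' @export
print.mcl_dist <- function(x, ...) {
  cat("<mcl_dist>", nrow(x$d), "taxa; kappa1 =",
      signif(x$params$kappa1, 4), "kappa2 =", signif(x$params$kappa2, 4),
      "\n")
  print(signif(x$d, 5))
  if (!is.null(x$flags)) {
    cat("flagged pairs:\n")
    print(x$flags, row.names = FALSE)
  }
  invisible(x)
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration. Ties in the rate-corrected criterion
#' are broken toward the lowest taxon-index pair; a negative branch length is
#' clamped to zero with the deficit transferred to its sister branch so the
#' pair sum is preserved.
#'
#' @param d Symmetric distance matrix with zero diagonal (or an `mcl_dist`).
#' @return Unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "mcl_dist")) d <- d$d
  if (!is.matrix(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix must be symmetric")
  if (anyNA(d)) stop("distance matrix contains NA (saturated pairs?)")
  n <- nrow(d)
  if (n < 3L) stop("need at least three taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- labels                     # newick fragment per active cluster
  active <- seq_len(n)
  D <- d
  while (length(active) > 3L) {
    na <- length(active)
    r <- rowSums(D)
    Q <- (na - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    best <- NULL
    for (i in seq_len(na - 1L)) {
      for (j in seq.int(i + 1L, na)) {
        if (Q[i, j] <= qmin + tol) {
          best <- c(i, j)
          break
        }
      }
      if (!is.null(best)) break
    }
    i <- best[1]
    j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (na - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(na), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    frag <- c(frag[keep], newfrag)
    active <- seq_len(na - 1L)
  }
  ## closing trifurcation: three-point formulas
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- pmax(c(la, lb, lc), 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", frag[1], ls[1],
                 frag[2], ls[2], frag[3], ls[3])
  ape::read.tree(text = txt)
}

#' Root a tree on an outgroup's pendant branch
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#' Idempotent on the topology.
#'
#' @param tree A `phylo`.
#' @param outgroup Tip label.
#' @return Rooted `phylo` with a degree-2 root.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  tip <- match(outgroup, tree$tip.label)
  if (is.na(tip)) stop("outgroup '", outgroup, "' is not a leaf")
  edge <- which(tree$edge[, 2] == tip)
  h <- tree$edge.length[edge]
  phytools::reroot(tree, node.number = tip, position = h / 2)
}

#' Count variable or parsimony-informative alignment columns
#'
#' Gaps and ambiguity codes are excluded from each column (pairwise-deletion
#' spirit). A column is variable when the rows present carry >= 2 distinct
#' bases; parsimony-informative when >= 2 distinct bases each occur in >= 2
#' rows.
#'
#' @param aln A `multi_alignment`.
#' @param mode "variable" or "parsimony".
#' @return Integer count.
#' @export
count_variable_sites <- function(aln, mode = c("variable", "parsimony")) {
  mode <- match.arg(mode)
  m <- code_matrix(aln)
  cnt <- 0L
  for (col in seq_len(ncol(m))) {
    x <- m[, col]
    x <- x[x > 0L]
    if (length(x) < 2L) next
    tt <- tabulate(x, 4L)
    if (mode == "variable") {
      if (sum(tt > 0L) >= 2L) cnt <- cnt + 1L
    } else {
      if (sum(tt >= 2L) >= 2L) cnt <- cnt + 1L
    }
  }
  cnt
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d Matrix or `mcl_dist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  if (inherits(d, "mcl_dist")) d <- d$d
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.8f", d[i, ]), collapse = " ")), con)
  invisible(path)
}
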