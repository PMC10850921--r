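## Collapsing multi-locus genotype vectors into plastid types (maternal
## lineages) and tallying them by taxon.

#' Assign plastid types from a genotype code matrix
#'
#' Two accessions share a plastid type iff their allele-code vectors are
#' identical at every panel locus. Accessions with a missing call at any
#' panel locus are excluded and reported. Types get deterministic systematic
#' labels (T01, T02, ...) in lexicographic vector order, so the result is
#' invariant under input row order; an optional alias map renames them.
#'
#' @param genotypes data.frame with an `accession` column and one integer
#'   code column per locus (e.g. from [genotype_matrix()]).
#' @param panel Ordered locus (column) names; default: every column except
#'   `accession`.
#' @param aliases Optional named character vector mapping systematic labels
#'   to user names.
#' @return Object of class `plastid_types`: list(types = data.frame(label,
#'   vector, size), membership = data.frame(accession, label, vector),
#'   excluded = character vector of accession ids, panel).
#' @export
assign_plastid_types <- function(genotypes, panel = NULL, aliases = NULL) {
  stopifnot(is.data.frame(genotypes), "accession" %in% names(genotypes))
  if (is.null(panel)) panel <- setdiff(names(genotypes), "accession")
  if (length(panel) == 0L) stop("empty marker panel")
  missing_cols <- setdiff(panel, names(genotypes))
  if (length(missing_cols))
    stop("panel loci absent from genotypes: ",
         paste(missing_cols, collapse = ", "))
  codes <- genotypes[panel]
  complete <- stats::complete.cases(codes)
  excluded <- genotypes$accession[!complete]
  g <- genotypes[complete, , drop = FALSE]
  vec <- apply(g[panel], 1L, paste, collapse = "-")
  uv <- sort(unique(vec))                     # lexicographic label order
  labels <- sprintf("T%02d", seq_along(uv))
  names(labels) <- uv
  if (!is.null(aliases)) {
    hit <- names(aliases)[match(labels, names(aliases))]
    labels[!is.na(hit)] <- aliases[labels[!is.na(hit)]]
  }
  membership <- data.frame(accession = g$accession,
                           label = unname(labels[vec]), vector = vec,
                           stringsAsFactors = FALSE)
  types <- data.frame(label = unname(labels), vector = uv,
                      size = as.integer(table(vec)[uv]),
                      stringsAsFactors = FALSE)
  structure(list(types = types, membership = membership,
                 excluded = excluded, panel = panel),
            class = "plastid_types")
}

#' @export
print.plastid_types <- function(x, ...) {
  cat("<plastid_types>", nrow(x$types), "types over",
      nrow(x$membership), "accessions",
      if (length(x$excluded)) sprintf("(%d excluded: missing calls)",
                                      length(x$excluded)) else "", "\n")
  print(x$types, row.names = FALSE)
  invisible(x)
}

#' Tally plastid types by taxon (and optionally region)
#'
#' @param types A `plastid_types` object.
#' @param metadata data.frame(accession, taxon) covering every member.
#' @return Object of class `plastid_tally`: list(table = type x taxon count
#'   matrix, type_totals, taxon_totals).
#' @export
tally_types_by_taxon <- function(types, metadata) {
  stopifnot(inherits(types, "plastid_types"),
            all(c("accession", "taxon") %in% names(metadata)))
  m <- types$membership
  idx <- match(m$accession, metadata$accession)
  if (anyNA(idx))
    stop("accessions missing from metadata: ",
         paste(m$accession[is.na(idx)], collapse = ", "))
  taxa <- metadata$taxon[idx]
  tab <- table(factor(m$label, levels = types$types$label), taxa)
  tab <- unclass(tab)[, sort(colnames(tab)), drop = FALSE]
  structure(list(table = tab,
                 type_totals = rowSums(tab),
                 taxon_totals = colSums(tab)),
            class = "plastid_tally")
}

#' @export
print.plastid_tally <- function(x, ...) {
  print(cbind(x$table, total = x$type_totals))
  cat("taxon totals:",
      paste(names(x$taxon_totals), x$taxon_totals, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Plastid types observed in two or more taxa
#'
#' @param tally A `plastid_tally`.
#' @return data.frame(label, taxa) sorted by label; `taxa` is a comma-joined
#'   list of member taxa. Empty when no type is shared.
#' @export
shared_types <- function(tally) {
  stopifnot(inherits(tally, "plastid_tally"))
  tab <- tally$table
  nz <- tab > 0
  shared <- rowSums(nz) >= 2L
  out <- data.frame(
    label = rownames(tab)[shared],
    taxa = apply(nz[shared, , drop = FALSE], 1L, function(r)
      paste(colnames(tab)[r], collapse = ",")),
    stringsAsFactors = FALSE)
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a plastid-type report as TSV
#'
#' @param types A `plastid_types`.
#' @param tally Optional `plastid_tally` to append per-taxon counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plastid_report <- function(types, path, tally = NULL) {
  df <- types$types
  if (!is.null(tally))
    df <- cbind(df, as.data.frame(tally$table[df$label, , drop = FALSE]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
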