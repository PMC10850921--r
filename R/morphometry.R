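## Seed-dimension summaries, capsule/endosperm volumes from voxel label
## masks, and interspecific volume ratios.

#' Per-group mean and SD of seed dimensions
#'
#' @param records data.frame with `height`, `width`, and the grouping column.
#' @param group_by Grouping column name ("taxon" or "population").
#' @return data.frame(group, n, height_mean, height_sd, width_mean, width_sd,
#'   sd_defined). Singleton groups report SD 0 with `sd_defined = FALSE`.
#' @export
summarize_dims <- function(records, group_by = "taxon") {
  stopifnot(all(c("height", "width", group_by) %in% names(records)),
            nrow(records) >= 1L)
  groups <- split(records, records[[group_by]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    r <- groups[[g]]
    n <- nrow(r)
    sdh <- if (n > 1L) stats::sd(r$height) else 0
    sdw <- if (n > 1L) stats::sd(r$width) else 0
    data.frame(group = g, n = n,
               height_mean = mean(r$height), height_sd = sdh,
               width_mean = mean(r$width), width_sd = sdw,
               sd_defined = n > 1L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Capsule and endosperm volumes from a voxel label mask
#'
#' Labels follow the mask legend (default 0 background, 1 pericarp,
#' 2 endosperm). Total volume is the labeled (pericarp + endosperm) voxel
#' count times the voxel volume; endosperm volume likewise.
#'
#' @param mask Integer array (any shape) of voxel labels.
#' @param voxel_edge Voxel edge length (e.g. mm); defaults to the mask's
#'   `voxel_edge` attribute, else 1.
#' @param legend Named labels; defaults to the mask's `legend` attribute.
#' @param sample,taxon Identifiers carried into the record.
#' @return data.frame(sample, taxon, total_volume, endosperm_volume).
#' @export
volumes_from_mask <- function(mask, voxel_edge = NULL, legend = NULL,
                              sample = "mask", taxon = NA_character_) {
  voxel_edge <- voxel_edge %||% attr(mask, "voxel_edge") %||% 1
  legend <- legend %||% attr(mask, "legend") %||%
    c(background = 0L, pericarp = 1L, endosperm = 2L)
  if (voxel_edge <= 0) stop("voxel_edge must be positive")
  known <- mask %in% legend
  if (!all(known)) stop("mask contains labels outside the legend")
  n_endo <- sum(mask == legend[["endosperm"]])
  n_peri <- sum(mask == legend[["pericarp"]])
  if (n_endo == 0L) stop("mask has no endosperm voxels")
  v <- voxel_edge^3
  data.frame(sample = sample, taxon = taxon,
             total_volume = (n_endo + n_peri) * v,
             endosperm_volume = n_endo * v, stringsAsFactors = FALSE)
}

#' Endosperm fraction of a volume record
#'
#' @param volumes data.frame with `total_volume` and `endosperm_volume`.
#' @return Numeric vector of fractions in (0, 1].
#' @export
endosperm_fraction <- function(volumes) {
  if (any(volumes$endosperm_volume <= 0) ||
      any(volumes$endosperm_volume > volumes$total_volume))
    stop("need 0 < endosperm_volume <= total_volume")
  volumes$endosperm_volume / volumes$total_volume
}

#' Interspecific ratio of group-mean volumes
#'
#' `mean(a) / mean(b)` for the chosen quantity — the aggregate convention
#' behind reported domesticated/wild volume ratios (individual seeds are not
#' paired across species).
#'
#' @param a,b data.frames of volume records (numerator and denominator
#'   groups).
#' @param quantity "total" or "endosperm".
#' @return list(ratio, n_a, n_b, quantity).
#' @export
interspecific_ratio <- function(a, b, quantity = c("total", "endosperm")) {
  quantity <- match.arg(quantity)
  col <- if (quantity == "total") "total_volume" else "endosperm_volume"
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both groups must be nonempty")
  list(ratio = mean(a[[col]]) / mean(b[[col]]),
       n_a = nrow(a), n_b = nrow(b), quantity = quantity)
}
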