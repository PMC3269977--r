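#' Phased haplotype panel
#'
#' A population's phased haplotypes: an H x M matrix of alleles coded 0/1
#' aligned to a [marker_map()], H even so haplotypes pair into diploids
#' (rows 2i-1 and 2i are individual i). The 0/1 coding must keep the same
#' reference allele per marker across all populations compared later, so
#' that the sign of r is comparable between panels.
#'
#' @param population single population label.
#' @param map a [marker_map()] with one row per matrix column.
#' @param haplotypes integer matrix in {0,1}, haplotypes in rows.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(population, map, haplotypes) {
  .assert(is.matrix(haplotypes), "haplotypes must be a matrix")
  .assert(nrow(haplotypes) %% 2 == 0,
          "haplotype count must be even (haplotypes pair into diploids)")
  .assert(ncol(haplotypes) == nrow(map),
          "haplotype matrix has %d columns but map has %d markers",
          ncol(haplotypes), nrow(map))
  .assert(all(haplotypes %in% c(0L, 1L)), "alleles must be coded 0/1")
  storage.mode(haplotypes) <- "integer"
  colnames(haplotypes) <- map$marker_id
  structure(list(population = as.character(population),
                 map = map,
                 haplotypes = haplotypes),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> population '%s': %d haplotypes (%d diploids) x %d markers on %d chromosome(s)\n",
              x$population, nrow(x$haplotypes), nrow(x$haplotypes) / 2,
              ncol(x$haplotypes), length(unique(x$map$chrom))))
  invisible(x)
}

#' Reference-allele frequencies of a panel
#'
#' Frequency of the 1-coded (reference) allele at each marker, counted over
#' all haplotypes in the panel.
#'
#' @param panel a [haplotype_panel()].
#' @return Named numeric vector, one frequency per marker.
#' @export
allele_frequencies <- function(panel) {
  colMeans(panel$haplotypes)
}

#' Restrict a panel to a subset of markers
#'
#' @param panel a [haplotype_panel()].
#' @param marker_ids character vector of marker ids to keep (map order is
#'   preserved regardless of the order given here).
#' @return A `haplotype_panel` on the reduced map.
#' @export
subset_panel <- function(panel, marker_ids) {
  keep <- panel$map$marker_id %in% marker_ids
  .assert(any(keep), "no markers left after subsetting")
  map <- panel$map[keep, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  haplotype_panel(panel$population, map, panel$haplotypes[, keep, drop = FALSE])
}

#' Thin a panel to every k-th marker
#'
#' Convenience wrapper: applies [thin_markers()] to the panel's map and
#' subsets the haplotype matrix accordingly.
#'
#' @inheritParams thin_markers
#' @param panel a [haplotype_panel()].
#' @return The thinned `haplotype_panel`.
#' @export
thin_panel <- function(panel, keep_every) {
  thinned <- thin_markers(panel$map, keep_every)
  subset_panel(panel, thinned$marker_id)
}
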