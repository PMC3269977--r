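#' Marker map
#'
#' An ordered table of biallelic marker coordinates: one row per marker with
#' its chromosome, identifier, 1-based base-pair position and an autosomal
#' flag used by the QC cascade. Within each chromosome positions must be
#' strictly increasing and marker identifiers unique across the map.
#'
#' @param chrom character or factor vector of chromosome labels.
#' @param marker_id character vector of unique marker identifiers.
#' @param pos_bp integer-like vector of 1-based physical positions.
#' @param autosomal logical vector; non-autosomal markers are dropped by the
#'   QC cascade. Defaults to `TRUE` for every marker.
#' @return A `data.frame` of class `marker_map` with columns `chrom`,
#'   `marker_id`, `pos_bp`, `autosomal`.
#' @examples
#' marker_map(rep("1", 3), c("m1", "m2", "m3"), c(100, 2000, 45000))
#' @export
marker_map <- function(chrom, marker_id, pos_bp, autosomal = TRUE) {
  n <- length(marker_id)
  .assert(length(chrom) == n && length(pos_bp) == n,
          "chrom, marker_id and pos_bp must have equal length")
  if (length(autosomal) == 1) autosomal <- rep(autosomal, n)
  map <- data.frame(chrom = as.character(chrom),
                    marker_id = as.character(marker_id),
                    pos_bp = as.numeric(pos_bp),
                    autosomal = as.logical(autosomal),
                    stringsAsFactors = FALSE)
  validate_marker_map(map)
  class(map) <- c("marker_map", "data.frame")
  map
}

#' @keywords internal
validate_marker_map <- function(map) {
  .assert(!anyDuplicated(map$marker_id), "marker ids must be unique")
  .assert(all(map$pos_bp >= 1), "positions must be 1-based (>= 1)")
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    .assert(all(diff(p) > 0),
            "positions must be strictly increasing within chromosome %s", ch)
  }
  invisible(map)
}

#' Thin a marker map by keeping every k-th marker
#'
#' Emulates a lower-density genotyping panel: within each chromosome the
#' markers at map-order indices 1, 1+k, 1+2k, ... are retained. Selection
#' depends only on map order, never on allele frequencies, so the same
#' thinning applies identically to every population.
#'
#' @param map a [marker_map()].
#' @param keep_every integer k >= 1; `k = 1` is the identity.
#' @return The thinned `marker_map`.
#' @seealso [thinning_series()] for the LD-vs-density summary.
#' @export
thin_markers <- function(map, keep_every) {
  .assert(length(keep_every) == 1 && keep_every >= 1 &&
            keep_every == as.integer(keep_every),
          "keep_every must be a single integer >= 1")
  keep <- unlist(lapply(split(seq_len(nrow(map)), map$chrom), function(ix) {
    ix[seq(1, length(ix), by = keep_every)]
  }), use.names = FALSE)
  out <- map[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_map", "data.frame")
  out
}
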