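# Readers and writers: phased VCF, PLINK-style PED/MAP (phased-column
# convention for panels, unphased genotypes for trios), TSV summaries and
# the run manifest.

.REF_ALLELE <- "A"   # letter written for the 1-coded (reference) allele
.ALT_ALLELE <- "C"

#' Write a phased haplotype panel as VCF
#'
#' Plain-text VCFv4.2 with one diploid sample per haplotype pair and phased
#' GT (`|` separator). The 1-coded allele is written as REF, so a round
#' trip through [read_phased_panel()] preserves the panel's allele coding
#' exactly.
#'
#' @param panel a [haplotype_panel()].
#' @param path output file path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  H <- nrow(panel$haplotypes)
  n_ind <- H / 2
  samples <- sprintf("%s_ind%03d", panel$population, seq_len(n_ind))
  gt <- matrix("", nrow(panel$map), n_ind)
  a1 <- t(panel$haplotypes[seq(1, H, 2), , drop = FALSE])
  a2 <- t(panel$haplotypes[seq(2, H, 2), , drop = FALSE])
  # our coding: 1 = reference allele = VCF allele index 0
  gt[] <- paste0(1L - a1, "|", 1L - a2)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=ldphase %s", as.character(utils::packageVersion("ldphase"))),
              sprintf("##contig=<ID=%s>", unique(panel$map$chrom)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- cbind(panel$map$chrom, format(panel$map$pos_bp, scientific = FALSE, trim = TRUE),
                panel$map$marker_id, .REF_ALLELE, .ALT_ALLELE, ".", "PASS",
                ".", "GT", gt)
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a phased haplotype panel
#'
#' Reads one population's phased biallelic haplotypes from a VCF (phased GT
#' records) or a PED/MAP pair written with the package's phased-column
#' convention (first allele column = first haplotype). Alleles are recoded
#' 0/1 with the reference allele taken from the file's REF column (VCF) or
#' the PED dialect's first-listed allele letter, so panels read from files
#' sharing marker ids stay sign-comparable.
#'
#' Unphased or multiallelic records, mixed ploidy, duplicate marker ids and
#' unsorted positions are rejected with the offending marker named.
#'
#' @param path VCF file, or the PED path / common prefix of a PED/MAP pair.
#' @param format `"vcf"` or `"ped"`.
#' @param population population label; defaults to the file base name.
#' @return A [haplotype_panel()].
#' @export
read_phased_panel <- function(path, format = c("vcf", "ped"),
                              population = NULL) {
  format <- match.arg(format)
  if (format == "vcf") .read_phased_vcf(path, population)
  else .read_phased_ped(path, population)
}

#' @keywords internal
.read_phased_vcf <- function(path, population = NULL) {
  population <- population %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
    nchar(fix[, "ALT"]) != 1
  .assert(!any(multi), "multiallelic or non-SNP record(s): %s",
          paste(utils::head(ids[multi], 5), collapse = ", "))
  dup <- duplicated(ids)
  .assert(!any(dup), "duplicate marker id(s): %s",
          paste(utils::head(ids[dup], 5), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  bad_ploidy <- matrix(!grepl("^[01][|/][01]$", gt), nrow(gt))
  .assert(!any(bad_ploidy), "missing or mixed-ploidy genotype(s) at: %s",
          paste(utils::head(ids[rowSums(bad_ploidy) > 0], 5), collapse = ", "))
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow(gt))
  .assert(!any(unphased), "unphased genotype(s) at: %s",
          paste(utils::head(ids[rowSums(unphased) > 0], 5), collapse = ", "))
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    .assert(all(diff(p) > 0), "positions not strictly increasing on chromosome %s", ch)
  }
  map <- marker_map(chrom, ids, pos)
  # VCF allele 0 is REF; our coding sets the reference allele to 1
  a1 <- 1L - as.integer(substr(gt, 1, 1))
  a2 <- 1L - as.integer(substr(gt, 3, 3))
  M <- nrow(gt); n_ind <- ncol(gt)
  hap <- matrix(0L, 2L * n_ind, M)
  hap[seq(1, 2 * n_ind, 2), ] <- t(matrix(a1, M, n_ind))
  hap[seq(2, 2 * n_ind, 2), ] <- t(matrix(a2, M, n_ind))
  haplotype_panel(population, map, hap)
}

#' Write a panel or trio set as PLINK-style PED/MAP
#'
#' MAP columns: chromosome, marker id, 0, position. For a
#' [haplotype_panel()] the PED allele columns are phased (first allele =
#' first haplotype); for a [trio_set()] genotypes are unphased, family and
#' parent columns are populated so trios are recoverable, and missing
#' genotypes are written `0 0`.
#'
#' @param x a [haplotype_panel()] or [trio_set()].
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return `prefix`, invisibly.
#' @export
write_ped_map <- function(x, prefix) {
  map_df <- data.frame(x$map$chrom, x$map$marker_id, 0, x$map$pos_bp)
  utils::write.table(map_df, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  allele <- function(a) ifelse(is.na(a), "0", ifelse(a == 1L, .REF_ALLELE, .ALT_ALLELE))
  if (inherits(x, "haplotype_panel")) {
    H <- nrow(x$haplotypes)
    n_ind <- H / 2
    a1 <- x$haplotypes[seq(1, H, 2), , drop = FALSE]
    a2 <- x$haplotypes[seq(2, H, 2), , drop = FALSE]
    geno <- matrix("", n_ind, 2 * ncol(a1))
    geno[, seq(1, ncol(geno), 2)] <- allele(a1)
    geno[, seq(2, ncol(geno), 2)] <- allele(a2)
    lead <- cbind(x$population, sprintf("%s_ind%03d", x$population, seq_len(n_ind)),
                  "0", "0", "0", "-9")
    utils::write.table(cbind(lead, geno), paste0(prefix, ".ped"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else if (inherits(x, "trio_set")) {
    geno_rows <- function(g) {
      # unphased genotype as allele pair: 2 -> A A, 1 -> A C, 0 -> C C
      first <- ifelse(is.na(g), "0", ifelse(g >= 1L, .REF_ALLELE, .ALT_ALLELE))
      second <- ifelse(is.na(g), "0", ifelse(g == 2L, .REF_ALLELE, .ALT_ALLELE))
      out <- matrix("", nrow(g), 2 * ncol(g))
      out[, seq(1, ncol(out), 2)] <- first
      out[, seq(2, ncol(out), 2)] <- second
      out
    }
    n <- length(x$trio_id)
    sire_id <- paste0(x$trio_id, "_sire")
    dam_id <- paste0(x$trio_id, "_dam")
    off_id <- paste0(x$trio_id, "_off")
    lead <- rbind(cbind(x$population, sire_id, "0", "0", "1", "-9"),
                  cbind(x$population, dam_id, "0", "0", "2", "-9"),
                  cbind(x$population, off_id, sire_id, dam_id, "0", "-9"))
    geno <- rbind(geno_rows(x$sire), geno_rows(x$dam), geno_rows(x$offspring))
    utils::write.table(cbind(lead, geno), paste0(prefix, ".ped"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else stop("unsupported object", call. = FALSE)
  invisible(prefix)
}

#' @keywords internal
.read_map_file <- function(path) {
  m <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  marker_map(m[[1]], m[[2]], m[[4]])
}

#' @keywords internal
.ped_paths <- function(prefix) {
  prefix <- sub("\\.ped$", "", prefix)
  list(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map"))
}

#' @keywords internal
.read_phased_ped <- function(prefix, population = NULL) {
  paths <- .ped_paths(prefix)
  map <- .read_map_file(paths$map)
  ped <- utils::read.table(paths$ped, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  .assert(ncol(ped) == 6 + 2 * nrow(map),
          "PED has %d genotype columns but map lists %d markers",
          ncol(ped) - 6, nrow(map))
  population <- population %||% ped[1, 1]
  geno <- as.matrix(ped[, -(1:6), drop = FALSE])
  .assert(!any(geno == "0"), "phased PED panels cannot contain missing alleles")
  code <- function(a) {
    .assert(all(a %in% c(.REF_ALLELE, .ALT_ALLELE)), "unknown allele letter in PED")
    ifelse(a == .REF_ALLELE, 1L, 0L)
  }
  n_ind <- nrow(ped)
  hap <- matrix(0L, 2L * n_ind, nrow(map))
  hap[seq(1, 2 * n_ind, 2), ] <- code(geno[, seq(1, ncol(geno), 2), drop = FALSE])
  hap[seq(2, 2 * n_ind, 2), ] <- code(geno[, seq(2, ncol(geno), 2), drop = FALSE])
  haplotype_panel(population, map, hap)
}

#' Read trio genotypes from a PED/MAP pair
#'
#' Expects the family structure written by [write_ped_map()]: offspring
#' rows carry their sire and dam individual ids in the paternal/maternal
#' columns. Genotypes are recoded to 0/1/2 reference-allele counts with
#' `0 0` as missing.
#'
#' @param prefix path prefix of the PED/MAP pair.
#' @param population optional population label override.
#' @return A [trio_set()].
#' @export
read_trios_ped <- function(prefix, population = NULL) {
  paths <- .ped_paths(prefix)
  map <- .read_map_file(paths$map)
  ped <- utils::read.table(paths$ped, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  geno <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- geno[, seq(1, ncol(geno), 2), drop = FALSE]
  a2 <- geno[, seq(2, ncol(geno), 2), drop = FALSE]
  g <- (a1 == .REF_ALLELE) + (a2 == .REF_ALLELE)
  g[a1 == "0" | a2 == "0"] <- NA_integer_
  storage.mode(g) <- "integer"
  iid <- ped[[2]]
  off_rows <- which(ped[[3]] != "0" & ped[[4]] != "0")
  .assert(length(off_rows) > 0, "no offspring rows (non-zero parent ids) in PED")
  sire_rows <- match(ped[[3]][off_rows], iid)
  dam_rows <- match(ped[[4]][off_rows], iid)
  .assert(!anyNA(sire_rows) && !anyNA(dam_rows),
          "parent id(s) referenced by offspring not present in PED")
  trio_set(population %||% ped[1, 1], map,
           g[sire_rows, , drop = FALSE], g[dam_rows, , drop = FALSE],
           g[off_rows, , drop = FALSE],
           sub("_off$", "", iid[off_rows]))
}

#' @keywords internal
.write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = digits, format = "g"))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write per-stage TSV summaries and a run manifest
#'
#' Writes one TSV per completed stage (`qc_report`, `ld_bins`, `adjacent`,
#' `thinning`, `phase_bins`, `divergence`) with deterministic column order
#' and fixed float formatting, plus `manifest.yaml` recording the pipeline
#' configuration, seed and package version. Identical inputs produce
#' byte-identical files (no timestamps).
#'
#' @param results list returned by [run_pipeline()].
#' @param out_dir output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
write_summaries <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  .assert(ok && file.access(out_dir, 2) == 0, "cannot write to '%s'", out_dir)
  if (!is.null(results$qc))
    .write_tsv(results$qc$report, file.path(out_dir, "qc_report.tsv"))
  if (!is.null(results$ld_bins))
    .write_tsv(results$ld_bins, file.path(out_dir, "ld_bins.tsv"))
  if (!is.null(results$adjacent))
    .write_tsv(results$adjacent, file.path(out_dir, "adjacent.tsv"))
  if (!is.null(results$thinning))
    .write_tsv(results$thinning, file.path(out_dir, "thinning.tsv"))
  if (!is.null(results$phase_bins))
    .write_tsv(results$phase_bins, file.path(out_dir, "phase_bins.tsv"))
  if (!is.null(results$divergence))
    .write_tsv(results$divergence, file.path(out_dir, "divergence.tsv"))
  manifest <- list(
    package = "ldphase",
    version = as.character(utils::packageVersion("ldphase")),
    config = .config_to_list(results$config),
    stages_written = intersect(c("qc", "ld_bins", "adjacent", "thinning",
                                 "phase_bins", "divergence"), names(results)),
    partial = results$partial %||% FALSE)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
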