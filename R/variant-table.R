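#' @importFrom stats median cor rbeta rbinom rpois runif setNames
#' @importFrom utils read.delim write.table combn
NULL

# Genotype codes used throughout: 0 = HOM_REF, 1 = HET, 2 = HOM_ALT, NA = MISSING.
GT_HOM_REF <- 0L
GT_HET     <- 1L
GT_HOM_ALT <- 2L

#' Construct a biallelic SNP genotype table
#'
#' The central container of the package: an ordered set of contigs, a site
#' table of biallelic SNPs, and a strains-by-sites genotype matrix using
#' integer codes 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
#' alternate) and \code{NA} (missing). Positions are 1-based as in VCF;
#' all interval structures in the package (masks, windows) are 0-based
#' half-open as in BED.
#'
#' @param contigs data.frame with columns \code{name}, \code{length}.
#' @param sites data.frame with columns \code{contig}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}; single-nucleotide alleles only.
#' @param geno integer matrix, strains in rows (rownames = strain ids),
#'   sites in columns.
#' @param phase optional integer matrix of the same shape: for phased HET
#'   calls the allele (0/1) carried by the first haplotype, \code{NA}
#'   elsewhere.
#' @return An object of class \code{VariantTable}.
#' @export
variant_table <- function(contigs, sites, geno, phase = NULL) {
  stopifnot(is.data.frame(contigs), all(c("name", "length") %in% names(contigs)))
  stopifnot(is.data.frame(sites), all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) != nrow(sites))
    stop("genotype matrix has ", ncol(geno), " columns but ", nrow(sites), " sites")
  if (is.null(rownames(geno)))
    stop("genotype matrix must carry strain ids as rownames")
  bad <- setdiff(unique(sites$contig), contigs$name)
  if (length(bad))
    stop("sites reference contigs absent from the contig table: ",
         paste(bad, collapse = ", "))
  # positions strictly increasing within each contig
  for (ctg in unique(sites$contig)) {
    p <- sites$pos[sites$contig == ctg]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on contig ", ctg)
  }
  if (!all(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L))
    stop("all sites must be single-nucleotide biallelic SNPs")
  if (!is.null(phase)) {
    phase <- as.matrix(phase)
    storage.mode(phase) <- "integer"
    stopifnot(identical(dim(phase), dim(geno)))
  }
  structure(
    list(contigs = contigs, sites = sites, geno = geno, phase = phase,
         strain_ids = rownames(geno)),
    class = "VariantTable"
  )
}

#' @export
print.VariantTable <- function(x, ...) {
  cat("VariantTable:", nrow(x$geno), "strains x", ncol(x$geno), "sites on",
      nrow(x$contigs), "contig(s)\n")
  het <- sum(x$geno == GT_HET, na.rm = TRUE)
  mis <- sum(is.na(x$geno))
  cat("  HET calls:", het, " missing calls:", mis, "\n")
  invisible(x)
}

#' @export
dim.VariantTable <- function(x) dim(x$geno)

#' Number of strains / sites
#' @param vt a \code{VariantTable}
#' @return integer count.
#' @export
n_strains <- function(vt) nrow(vt$geno)

#' @rdname n_strains
#' @export
n_sites <- function(vt) ncol(vt$geno)

#' Subset a VariantTable by strains and/or sites
#'
#' @param vt a \code{VariantTable}
#' @param strains character or integer index of strains to keep.
#' @param sites integer index of site columns to keep.
#' @return a \code{VariantTable}.
#' @export
subset_variants <- function(vt, strains = NULL, sites = NULL) {
  if (is.null(strains)) strains <- seq_len(nrow(vt$geno))
  if (is.null(sites))   sites   <- seq_len(ncol(vt$geno))
  g <- vt$geno[strains, sites, drop = FALSE]
  ph <- if (!is.null(vt$phase)) vt$phase[strains, sites, drop = FALSE] else NULL
  variant_table(vt$contigs, vt$sites[sites, , drop = FALSE], g, ph)
}

parse_gt_codes <- function(gt) {
  # gt: character matrix of GT strings (sites x samples), NA allowed
  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- !is.na(gt) & (a1 %in% c("0", "1")) & (a2 %in% c("0", "1"))
  n1 <- (a1 == "1") + (a2 == "1")
  code[ok] <- n1[ok]
  phase <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ph <- ok & code == 1L & sep == "|"
  phase[ph] <- as.integer(a1[ph])
  list(code = code, phase = phase)
}

#' Read a multi-sample VCF into a VariantTable
#'
#' Non-SNP and (optionally) multi-allelic records are dropped with a message
#' reporting the count. Genotypes are collapsed to the package's integer
#' codes; the phased separator \code{|} on a HET call records the first
#' haplotype's allele in the phase matrix.
#'
#' @param path path to a VCF 4.x file (plain text or gzipped).
#' @param biallelic_only drop multi-allelic records (default TRUE; they are
#'   never decomposed).
#' @return a \code{VariantTable}.
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!"GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !any(grepl("GT", v@fix[, "INFO"], fixed = TRUE))) {
    # vcfR stores FORMAT per record; check the FORMAT column directly
  }
  fmt <- unlist(v@gt[, "FORMAT"])
  if (nrow(v@gt) > 0 && !all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, TRUE)))
    stop("VCF records lack a GT field")
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n0 <- nrow(fix)
  is_snp <- nchar(fix$REF) == 1L & !is.na(fix$ALT) &
    vapply(strsplit(fix$ALT, ","), function(a) all(nchar(a) == 1L), TRUE)
  keep <- is_snp
  if (biallelic_only) keep <- keep & !grepl(",", fix$ALT, fixed = TRUE)
  dropped <- n0 - sum(keep)
  if (dropped > 0)
    message("read_vcf: dropped ", dropped, " non-SNP/multi-allelic record(s) of ", n0)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  meta <- v@meta
  ctg_lines <- grep("^##contig", meta, value = TRUE)
  ids <- sub(".*ID=([^,>]+).*", "\\1", ctg_lines)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg_lines)))
  body_ctg <- unique(fix$CHROM)
  if (length(ctg_lines)) {
    missing_ctg <- setdiff(body_ctg, ids)
    if (length(missing_ctg))
      stop("contig(s) in VCF body absent from header: ",
           paste(missing_ctg, collapse = ", "))
    contigs <- data.frame(name = ids, length = lens, stringsAsFactors = FALSE)
    contigs <- contigs[contigs$name %in% body_ctg | !is.na(contigs$length), , drop = FALSE]
  } else {
    # no header contigs: infer lengths, rounded up to a 50-kb multiple
    W <- 50000
    pos_max <- tapply(as.numeric(fix$POS), fix$CHROM, max)
    warning("VCF header has no contig lines; inferring contig lengths")
    contigs <- data.frame(name = names(pos_max),
                          length = ceiling((as.numeric(pos_max) + W) / W) * W,
                          stringsAsFactors = FALSE)
  }
  sites <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  pg <- parse_gt_codes(gt)
  variant_table(contigs, sites, t(pg$code), t(pg$phase))
}

#' Read a strain metadata table
#'
#' Expects a TSV with header and at least the columns \code{strain},
#' \code{population}, \code{subpopulation}, \code{latitude},
#' \code{longitude}, \code{site}, \code{host}, \code{substrate}; an optional
#' \code{host2} column carries a second (fungal) host for strains isolated
#' from mushrooms growing on trees.
#'
#' @param path TSV path.
#' @return data.frame of class \code{StrainMeta}.
#' @export
read_meta <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain", "subpopulation", "latitude", "longitude")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  validate_meta(m)
}

SUBSTRATE_CLASSES <- c("soil", "bark", "leaves", "seed", "mushroom", "unknown")

validate_meta <- function(m) {
  ok_lat <- is.na(m$latitude) | abs(m$latitude) <= 90
  ok_lon <- is.na(m$longitude) | abs(m$longitude) <= 180
  if (!all(ok_lat)) stop("latitude out of range for: ",
                         paste(m$strain[!ok_lat], collapse = ", "))
  if (!all(ok_lon)) stop("longitude out of range for: ",
                         paste(m$strain[!ok_lon], collapse = ", "))
  if ("substrate" %in% names(m)) {
    bad <- !is.na(m$substrate) & !(m$substrate %in% SUBSTRATE_CLASSES)
    if (any(bad))
      stop("substrate outside {", paste(SUBSTRATE_CLASSES, collapse = ", "),
           "}: ", paste(unique(m$substrate[bad]), collapse = ", "))
  }
  class(m) <- c("StrainMeta", "data.frame")
  m
}

#' Read a per-window depth table
#'
#' Long format: \code{strain}, \code{reference}, \code{contig},
#' \code{window_start}, \code{window_end}, \code{mean_depth}
#' (0-based half-open windows).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_depth_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain", "reference", "contig", "window_start", "window_end", "mean_depth")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("depth table lacks column(s): ", paste(miss, collapse = ", "))
  d
}

#' Write / read a tabular output
#'
#' All tabular outputs of the package are TSVs with a header; writing then
#' re-reading a table round-trips its values.
#'
#' @param x data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)
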