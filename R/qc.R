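#' Per-strain heterozygosity summary
#'
#' The heterozygous fraction is computed over variant calls only
#' (HET + HOM_ALT; missing calls excluded), the construction under which a
#' strain with 41 HET calls among 100 variant calls scores 0.41. Classes:
#' low (< 5\%), moderate (< 10\%), high (>= 10\%); strains whose absolute
#' HET call count exceeds \code{highly_het_n} are additionally flagged.
#' Summaries should be computed on the pre-mask table.
#'
#' @param vt a \code{VariantTable}.
#' @param strain strain id, or NULL for all strains.
#' @param highly_het_n absolute HET-call threshold for the
#'   \code{highly_het} flag (default 20000; an absolute count, so it does
#'   not transfer to toy genomes — configure accordingly).
#' @return data.frame: strain, calls, het_calls, fraction, class, highly_het.
#' @export
het_summary <- function(vt, strain = NULL, highly_het_n = 20000L) {
  ids <- if (is.null(strain)) vt$strain_ids else strain
  stopifnot(all(ids %in% vt$strain_ids))
  rows <- lapply(ids, function(s) {
    g <- vt$geno[s, ]
    het <- sum(g == GT_HET, na.rm = TRUE)
    calls <- het + sum(g == GT_HOM_ALT, na.rm = TRUE)
    if (calls == 0L) {
      warning("strain ", s, " has zero variant calls; het fraction set to 0")
      frac <- 0
    } else frac <- het / calls
    data.frame(strain = s, calls = calls, het_calls = het, fraction = frac,
               class = if (frac < 0.05) "low" else if (frac < 0.10) "moderate" else "high",
               highly_het = het > highly_het_n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply masks (and optionally drop heterozygous calls)
#'
#' Calls at masked positions become missing for every strain; with
#' \code{drop_het}, HET calls become missing per strain (other strains'
#' homozygous information at the site is preserved). Sites left with no
#' called strain are dropped. The operation is idempotent.
#'
#' @param vt a \code{VariantTable}.
#' @param masks a \code{MaskSet} (may be empty).
#' @param drop_het set HET calls to missing (default FALSE).
#' @return a filtered \code{VariantTable}.
#' @export
apply_masks <- function(vt, masks = mask_set(), drop_het = FALSE) {
  g <- vt$geno
  ph <- vt$phase
  masked <- sites_masked(vt, masks)
  if (any(masked)) {
    g[, masked] <- NA_integer_
    if (!is.null(ph)) ph[, masked] <- NA_integer_
  }
  if (drop_het) {
    h <- which(g == GT_HET)
    g[h] <- NA_integer_
    if (!is.null(ph)) ph[h] <- NA_integer_
  }
  keep <- colSums(!is.na(g)) > 0
  variant_table(vt$contigs, vt$sites[keep, , drop = FALSE],
                g[, keep, drop = FALSE],
                if (!is.null(ph)) ph[, keep, drop = FALSE] else NULL)
}

#' Derive coverage masks from a per-window depth profile
#'
#' Windows whose depth, normalized to the genome-wide median, falls below
#' \code{low_q} or above \code{high_q} are masked (labels low_coverage /
#' high_coverage).
#'
#' @param depth data.frame: \code{contig}, \code{window_start},
#'   \code{window_end}, \code{mean_depth} for one strain or a cohort median.
#' @param low_q lower bound on normalized depth (default 0.25).
#' @param high_q upper bound on normalized depth (default 2.0).
#' @return a \code{MaskSet}.
#' @export
coverage_masks <- function(depth, low_q = 0.25, high_q = 2.0) {
  med <- median(depth$mean_depth)
  if (med == 0) {
    warning("median depth is zero; masking every window")
    lo <- rep(TRUE, nrow(depth)); hi <- rep(FALSE, nrow(depth))
  } else {
    nd <- depth$mean_depth / med
    lo <- nd < low_q
    hi <- nd > high_q
  }
  rows <- rbind(
    if (any(lo)) data.frame(contig = depth$contig[lo], start = depth$window_start[lo],
                            end = depth$window_end[lo], label = "low_coverage",
                            stringsAsFactors = FALSE),
    if (any(hi)) data.frame(contig = depth$contig[hi], start = depth$window_start[hi],
                            end = depth$window_end[hi], label = "high_coverage",
                            stringsAsFactors = FALSE))
  if (is.null(rows)) return(mask_set())
  mask_set(rows)
}

#' Split a phased heterozygous strain into two pseudo-haplotypes
#'
#' At HET sites the phase-0 row receives the first haplotype's allele and
#' the phase-1 row the second; homozygous calls are shared. Both
#' pseudo-haplotypes are appended to the table as homozygous strains with
#' suffixed ids, so each can be assigned to a population with the ordinary
#' divergence machinery. Phasing must come from the input (phased VCF or
#' simulation truth); no phasing is performed internally.
#'
#' @param vt a \code{VariantTable}.
#' @param strain strain id to split.
#' @return a \code{VariantTable} with two added strains
#'   \code{<strain>_phase0}, \code{<strain>_phase1}.
#' @export
phase_split <- function(vt, strain) {
  stopifnot(strain %in% vt$strain_ids)
  g <- vt$geno[strain, ]
  het <- which(g == GT_HET)
  ph <- if (!is.null(vt$phase)) vt$phase[strain, ] else rep(NA_integer_, length(g))
  if (length(het) && any(is.na(ph[het])))
    stop("strain ", strain, " has unphased HET calls; supply phased input")
  h0 <- h1 <- g
  if (length(het)) {
    h0[het] <- 2L * ph[het]          # allele 0 -> HOM_REF, allele 1 -> HOM_ALT
    h1[het] <- 2L * (1L - ph[het])
  }
  g2 <- rbind(vt$geno, h0, h1)
  rownames(g2) <- c(vt$strain_ids, paste0(strain, "_phase0"), paste0(strain, "_phase1"))
  ph2 <- NULL
  if (!is.null(vt$phase)) {
    ph2 <- rbind(vt$phase, NA_integer_, NA_integer_)
    rownames(ph2) <- rownames(g2)
  }
  variant_table(vt$contigs, vt$sites, g2, ph2)
}
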