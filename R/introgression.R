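#' Normalize a dual-reference depth table
#'
#' Per strain, window depths against both references are divided by the
#' strain's sequencing depth, estimated as the larger of the two
#' per-reference genome-wide median depths (the genome is almost entirely
#' one species' material, so that median is the strain's true coverage;
#' the other reference sees mostly cross-mapping leakage). The reference
#' the strain derives from therefore has median normalized depth ~ 1,
#' while pure-leakage windows sit near the leakage rate.
#'
#' @param depth long data.frame: strain, reference, contig, window_start,
#'   window_end, mean_depth.
#' @return the input with a \code{norm_depth} column, class
#'   \code{CoverageProfile}.
#' @export
coverage_profile <- function(depth) {
  stopifnot(all(c("strain", "reference", "contig", "window_start",
                  "window_end", "mean_depth") %in% names(depth)))
  out <- do.call(rbind, lapply(split(depth, depth$strain), function(d) {
    med <- tapply(d$mean_depth, d$reference, median)
    denom <- max(med)
    if (denom == 0) stop("strain ", d$strain[1], " has zero depth everywhere")
    d$norm_depth <- d$mean_depth / denom
    d
  }))
  rownames(out) <- NULL
  class(out) <- c("CoverageProfile", "data.frame")
  out
}

#' Detect heterospecific introgression tracts from dual-reference depth
#'
#' A window is donor-present when the donor reference's normalized depth
#' is at least \code{theta_hi} AND the recipient reference's normalized
#' depth is at most \code{theta_lo}; runs of adjacent donor-present
#' windows (no gap bridging) are merged into tracts. The two references'
#' profiles must share one window grid (homologous contigs aligned by
#' window index).
#'
#' @param profile a \code{CoverageProfile} for one strain (both
#'   references).
#' @param recipient_ref,donor_ref reference names in the profile.
#' @param theta_hi donor presence threshold (default 0.5).
#' @param theta_lo recipient absence threshold (default 0.25).
#' @return data.frame of tracts: contig, start, end, length_bp, n_windows.
#' @export
detect_tracts <- function(profile, recipient_ref, donor_ref,
                          theta_hi = 0.5, theta_lo = 0.25) {
  if (!"norm_depth" %in% names(profile)) profile <- coverage_profile(profile)
  rec <- profile[profile$reference == recipient_ref, , drop = FALSE]
  don <- profile[profile$reference == donor_ref, , drop = FALSE]
  if (!nrow(rec) || !nrow(don)) stop("profile lacks one of the references")
  rec <- rec[order(rec$contig, rec$window_start), ]
  don <- don[order(don$contig, don$window_start), ]
  if (nrow(rec) != nrow(don) ||
      !all(rec$window_start == don$window_start) || !all(rec$contig == don$contig))
    stop("reference window grids are mismatched")
  present <- don$norm_depth >= theta_hi & rec$norm_depth <= theta_lo
  tracts <- list()
  i <- 1L
  while (i <= length(present)) {
    if (present[i]) {
      j <- i
      while (j < length(present) && present[j + 1L] &&
             don$contig[j + 1L] == don$contig[i] &&
             don$window_start[j + 1L] == don$window_end[j]) j <- j + 1L
      tracts[[length(tracts) + 1L]] <- data.frame(
        contig = don$contig[i], start = don$window_start[i],
        end = don$window_end[j], length_bp = don$window_end[j] - don$window_start[i],
        n_windows = j - i + 1L, stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(tracts))
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      length_bp = integer(), n_windows = integer()))
  do.call(rbind, tracts)
}

#' Group strains sharing identical tract breakpoints
#'
#' Strains whose full tract sets (contig, start, end triples) match
#' exactly at window resolution form one group; shared breakpoints across
#' independently sequenced strains indicate a single ancestral
#' hybridization event. Strains with no tracts are omitted.
#'
#' @param tract_lists named list (by strain) of tract data.frames from
#'   \code{\link{detect_tracts}}.
#' @return data.frame: group id, strain, tract signature, group size;
#'   zero rows when no strain has a tract.
#' @export
shared_breakpoints <- function(tract_lists) {
  stopifnot(length(names(tract_lists)) == length(tract_lists))
  sig <- vapply(tract_lists, function(t) {
    if (!nrow(t)) return(NA_character_)
    t <- t[order(t$contig, t$start), ]
    paste(sprintf("%s:%d-%d", t$contig, t$start, t$end), collapse = ";")
  }, "")
  keep <- !is.na(sig)
  if (!any(keep))
    return(data.frame(group = integer(), strain = character(),
                      signature = character(), group_size = integer()))
  sig <- sig[keep]
  grp <- match(sig, unique(sig))
  size <- table(grp)
  data.frame(group = grp, strain = names(sig), signature = unname(sig),
             group_size = as.integer(size[as.character(grp)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank candidate donor populations for an introgressed tract
#'
#' Within the tract's sites, computes the query's divergence to the
#' nearest member of each candidate donor panel and ranks panels
#' ascending.
#'
#' @param vt a \code{VariantTable} on the donor reference's coordinates.
#' @param query introgressed strain id.
#' @param donor_panels named list of candidate donor panel strain ids.
#' @param tract one tract row (contig, start, end), 0-based half-open.
#' @return data.frame ranked ascending (panel, min_divergence, n_sites);
#'   zero rows (with a warning) when the tract has no called sites.
#' @export
assign_donor <- function(vt, query, donor_panels, tract) {
  in_tract <- vt$sites$contig == tract$contig &
    vt$sites$pos - 1L >= tract$start & vt$sites$pos - 1L < tract$end
  hap <- haploidize(vt, c(query, unlist(donor_panels)))
  q <- hap[query, in_tract]
  n_called <- sum(!is.na(q))
  if (!any(in_tract) || n_called == 0) {
    warning("tract has no called sites for ", query)
    return(data.frame(panel = character(), min_divergence = numeric(),
                      n_sites = integer()))
  }
  L <- tract$end - tract$start
  d <- vapply(donor_panels, function(members) {
    hm <- hap[members, in_tract, drop = FALSE]
    qm <- matrix(q, nrow(hm), length(q), byrow = TRUE)
    min(rowSums(hm != qm, na.rm = TRUE)) / L
  }, numeric(1))
  out <- data.frame(panel = names(d), min_divergence = unname(d),
                    n_sites = n_called, stringsAsFactors = FALSE)
  out <- out[order(out$min_divergence), , drop = FALSE]
  rownames(out) <- NULL
  out
}
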