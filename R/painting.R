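#' Windowed minimum-divergence ancestry painting
#'
#' For every window, computes the query's minimum pairwise divergence to
#' any member of panel A (dA) and of panel B (dB), and the log2 ratio
#' r = log2((dA + eps) / (dB + eps)) with eps one SNP-equivalent over the
#' window's callable bp, so a window identical to a panel member never
#' takes a log of zero. Sign convention: r < 0 means the window is closer
#' to panel A (PA), r > 0 closer to panel B (PB); r = 0 is ambiguous.
#' Windows are no-data when callable bp falls below
#' \code{min_callable_fraction} of the window length or when fewer than
#' \code{min_sites} informative sites (sites where the nearest A and
#' nearest B members carry different alleles) support the call. Genome
#' summary fractions are taken over classified (non-NODATA, non-AMBIG)
#' windows and sum to 1.
#'
#' @param vt a \code{VariantTable} with HET calls already masked/dropped.
#' @param query strain id to paint; must not be in either panel.
#' @param panelA,panelB character vectors of panel strain ids.
#' @param grid a \code{WindowGrid} (default: 50-kbp tiling of the table's
#'   contigs).
#' @param masks a \code{MaskSet} for callable-bp accounting.
#' @param min_callable_fraction minimum callable fraction per window
#'   (default 0.5).
#' @param min_sites minimum informative sites per classified window
#'   (default 5).
#' @return object of class \code{AncestryProfile}: \code{windows}
#'   data.frame (contig, start, end, callable_bp, informative, dA, dB, r,
#'   class), \code{pa_fraction}, \code{pb_fraction}, \code{n_classified},
#'   \code{query}.
#' @export
paint <- function(vt, query, panelA, panelB, grid = NULL, masks = mask_set(),
                  min_callable_fraction = 0.5, min_sites = 5L) {
  if (query %in% c(panelA, panelB))
    stop("query '", query, "' must be excluded from both panels")
  if (!length(panelA) || !length(panelB)) stop("panels must be non-empty")
  if (is.null(grid)) grid <- make_windows(vt$contigs)
  hap <- haploidize(vt, c(query, panelA, panelB))
  q <- hap[query, ]
  hA <- hap[panelA, , drop = FALSE]
  hB <- hap[panelB, , drop = FALSE]
  callable <- callable_by_window(grid, masks)
  swin <- site_windows(vt, grid)
  W <- grid$end - grid$start

  n_w <- nrow(grid)
  dA <- dB <- r <- rep(NA_real_, n_w)
  informative <- integer(n_w)
  cls <- rep("NODATA", n_w)
  for (w in seq_len(n_w)) {
    if (callable[w] < min_callable_fraction * W[w]) next
    cols <- which(swin == grid$window[w])
    qm <- matrix(q[cols], nrow(hA), length(cols), byrow = TRUE)
    diffsA <- rowSums(hA[, cols, drop = FALSE] != qm, na.rm = TRUE)
    qmB <- matrix(q[cols], nrow(hB), length(cols), byrow = TRUE)
    diffsB <- rowSums(hB[, cols, drop = FALSE] != qmB, na.rm = TRUE)
    a_star <- which.min(diffsA); b_star <- which.min(diffsB)
    informative[w] <- sum(hA[a_star, cols] != hB[b_star, cols], na.rm = TRUE)
    dA[w] <- diffsA[a_star] / callable[w]
    dB[w] <- diffsB[b_star] / callable[w]
    eps <- 1 / callable[w]
    r[w] <- log2((dA[w] + eps) / (dB[w] + eps))
    if (informative[w] < min_sites) next
    cls[w] <- if (r[w] < 0) "PA" else if (r[w] > 0) "PB" else "AMBIG"
  }
  n_cl <- sum(cls %in% c("PA", "PB"))
  structure(list(
    windows = data.frame(contig = grid$contig, start = grid$start,
                         end = grid$end, callable_bp = callable,
                         informative = informative, dA = dA, dB = dB, r = r,
                         class = cls, stringsAsFactors = FALSE),
    pa_fraction = if (n_cl) sum(cls == "PA") / n_cl else NA_real_,
    pb_fraction = if (n_cl) sum(cls == "PB") / n_cl else NA_real_,
    n_classified = n_cl, query = query), class = "AncestryProfile")
}

#' @export
print.AncestryProfile <- function(x, ...) {
  cat("AncestryProfile for", x$query, "-", nrow(x$windows), "windows,",
      x$n_classified, "classified\n")
  cat(sprintf("  PA fraction %.3f | PB fraction %.3f\n",
              x$pa_fraction, x$pb_fraction))
  invisible(x)
}

#' Classify a painted strain as pure, introgressed or admixed
#'
#' Based on the minor-ancestry fraction m = min(PA, PB fraction):
#' pure when m < \code{bounds[1]} (default 0.02), introgressed when
#' \code{bounds[1]} <= m <= \code{bounds[2]} (default 0.12; the band in
#' which small cross-population tracts are detectable), admixed above.
#'
#' @param profile an \code{AncestryProfile}.
#' @param bounds numeric length-2 minor-fraction band (default
#'   \code{c(0.02, 0.12)}).
#' @param min_windows minimum classified windows required to assign a
#'   label (default 20).
#' @return list: \code{label} ("pure"/"introgressed"/"admixed", or NA when
#'   withheld), \code{minor_fraction}.
#' @export
classify_strain <- function(profile, bounds = c(0.02, 0.12), min_windows = 20L) {
  if (profile$n_classified < min_windows)
    return(list(label = NA_character_, minor_fraction = NA_real_))
  m <- min(profile$pa_fraction, profile$pb_fraction)
  label <- if (m < bounds[1]) "pure" else if (m <= bounds[2]) "introgressed" else "admixed"
  list(label = label, minor_fraction = m)
}

#' Rank donor subpopulations for one side of a painted genome
#'
#' Restricted to windows classified to the chosen side, computes the mean
#' (over windows) of the query's divergence to the nearest member of each
#' subpanel, and ranks subpanels ascending; the winner's margin is the gap
#' to the runner-up.
#'
#' @param vt a \code{VariantTable}.
#' @param query painted strain id.
#' @param subpanels named list of strain-id vectors partitioning the
#'   chosen side's panel.
#' @param profile the query's \code{AncestryProfile}.
#' @param side "PA" or "PB": which window class to use.
#' @param grid the \code{WindowGrid} used for painting.
#' @param masks \code{MaskSet} used for painting.
#' @return data.frame ranked ascending by mean divergence (subpop,
#'   mean_divergence, n_windows), with attribute \code{margin}; empty when
#'   no windows carry the class.
#' @export
donor_subpop <- function(vt, query, subpanels, profile, side = c("PA", "PB"),
                         grid = NULL, masks = mask_set()) {
  side <- match.arg(side)
  if (is.null(grid)) grid <- make_windows(vt$contigs)
  use_w <- which(profile$windows$class == side)
  if (!length(use_w))
    return(structure(data.frame(subpop = character(), mean_divergence = numeric(),
                                n_windows = integer()), margin = NA_real_))
  hap <- haploidize(vt, c(query, unlist(subpanels)))
  q <- hap[query, ]
  swin <- site_windows(vt, grid)
  callable <- profile$windows$callable_bp
  means <- vapply(subpanels, function(members) {
    hs <- hap[members, , drop = FALSE]
    d <- vapply(use_w, function(w) {
      cols <- which(swin == grid$window[w])
      qm <- matrix(q[cols], nrow(hs), length(cols), byrow = TRUE)
      min(rowSums(hs[, cols, drop = FALSE] != qm, na.rm = TRUE)) / callable[w]
    }, numeric(1))
    mean(d)
  }, numeric(1))
  out <- data.frame(subpop = names(means), mean_divergence = unname(means),
                    n_windows = length(use_w), stringsAsFactors = FALSE)
  out <- out[order(out$mean_divergence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "margin") <- if (nrow(out) >= 2) out$mean_divergence[2] - out$mean_divergence[1] else NA_real_
  out
}

#' Group strains with identical ancestry profiles and count the SNPs that
#' differentiate them
#'
#' Strains whose per-window class vectors are identical form a clonal
#' group; within a group, the differentiating SNPs are the sites at which
#' any two members' genotypes differ (jointly called). Used to establish
#' that a set of admixed isolates descends from a single outcrossing
#' event, with only location-accumulated variants distinguishing them.
#'
#' @param profiles named list of \code{AncestryProfile}s on one grid.
#' @param vt the \code{VariantTable} holding the profiled strains.
#' @return list of groups, each with \code{members},
#'   \code{diff_snp_count}, \code{diff_sites} (site column indices) and
#'   \code{genotypes} (members x differentiating-site submatrix); sorted
#'   by decreasing group size.
#' @export
profile_identity <- function(profiles, vt) {
  stopifnot(length(names(profiles)) == length(profiles))
  keys <- vapply(profiles, function(p) paste(p$windows$class, collapse = ""), "")
  groups <- split(names(profiles), keys)
  out <- lapply(groups, function(members) {
    g <- vt$geno[members, , drop = FALSE]
    if (length(members) >= 2) {
      ndist <- apply(g, 2, function(col) length(unique(col[!is.na(col)])))
      diff_sites <- which(ndist >= 2)
    } else diff_sites <- integer()
    list(members = members, diff_snp_count = length(diff_sites),
         diff_sites = diff_sites,
         genotypes = g[, diff_sites, drop = FALSE])
  })
  out <- out[order(-vapply(out, function(x) length(x$members), integer(1)))]
  names(out) <- NULL
  out
}
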