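#' Collapse homozygous diploid genotypes to haplotypes
#'
#' Wild strains of this species live predominantly as homozygous diploids,
#' so each strain contributes a single haplotype: HOM_REF -> 0,
#' HOM_ALT -> 1, missing propagates. Residual HET calls are an error —
#' mask or drop them first (\code{\link{apply_masks}} with
#' \code{drop_het = TRUE}).
#'
#' @param vt a \code{VariantTable}.
#' @param strains strain ids to include (default all).
#' @return integer matrix strains x sites with values 0/1/NA.
#' @export
haploidize <- function(vt, strains = NULL) {
  if (is.null(strains)) strains <- vt$strain_ids
  stopifnot(all(strains %in% vt$strain_ids))
  g <- vt$geno[strains, , drop = FALSE]
  if (any(g == GT_HET, na.rm = TRUE))
    stop("residual HET calls present; apply_masks(drop_het = TRUE) first")
  h <- g
  h[g == GT_HOM_ALT] <- 1L
  h
}

#' Per-site pairwise divergence between two haplotypes
#'
#' d = (number of jointly-called differing sites) / callable bp. A window
#' with zero callable bp has no defined divergence (\code{NA}), which is
#' distinct from zero divergence.
#'
#' @param a,b haplotype vectors (0/1/NA).
#' @param callable_bp callable basepairs of the region compared.
#' @return divergence per site, or NA when callable_bp is 0.
#' @export
pairwise_divergence <- function(a, b, callable_bp) {
  if (is.na(callable_bp) || callable_bp <= 0) return(NA_real_)
  sum(a != b, na.rm = TRUE) / callable_bp
}

#' Genome-wide divergence matrix between strains
#'
#' @param hap haplotype matrix (strains x sites).
#' @param callable_bp total callable bp of the genome compared.
#' @return symmetric matrix of per-site divergences, zero diagonal.
#' @export
divergence_matrix <- function(hap, callable_bp) {
  n <- nrow(hap)
  d <- matrix(0, n, n, dimnames = list(rownames(hap), rownames(hap)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- pairwise_divergence(hap[i, ], hap[j, ], callable_bp)
  }
  d
}

# Per-site unbiased diversity contribution: 2 p (1-p) n/(n-1) at sites with
# >= 2 called haplotypes, 0 elsewhere. Returns a vector over sites.
site_pi <- function(hap) {
  n <- colSums(!is.na(hap))
  c1 <- colSums(hap == 1L, na.rm = TRUE)
  out <- numeric(ncol(hap))
  ok <- n >= 2
  p <- c1[ok] / n[ok]
  out[ok] <- 2 * p * (1 - p) * n[ok] / (n[ok] - 1)
  out
}

#' Nucleotide diversity of a panel
#'
#' pi = sum over sites of 2 p (1-p) n/(n-1), divided by callable bp
#' (n = called haplotypes at the site). On a complete matrix this equals
#' the average over all strain pairs of \code{\link{pairwise_divergence}}
#' exactly.
#'
#' @param hap haplotype matrix (panel strains x sites).
#' @param callable_bp callable bp of the region.
#' @return pi per site, NA when no site has >= 2 called haplotypes or
#'   callable_bp is 0.
#' @export
nucleotide_diversity <- function(hap, callable_bp) {
  if (is.na(callable_bp) || callable_bp <= 0) return(NA_real_)
  if (all(colSums(!is.na(hap)) < 2)) return(NA_real_)
  sum(site_pi(hap)) / callable_bp
}

#' Watterson's theta of a panel
#'
#' theta_W = S / a1(n) / callable bp with a1(n) = sum_{i=1}^{n-1} 1/i,
#' computed per site with that site's called haplotype count.
#'
#' @inheritParams nucleotide_diversity
#' @return theta_W per site.
#' @export
wattersons_theta <- function(hap, callable_bp) {
  if (is.na(callable_bp) || callable_bp <= 0) return(NA_real_)
  n <- colSums(!is.na(hap))
  c1 <- colSums(hap == 1L, na.rm = TRUE)
  seg <- n >= 2 & c1 >= 1 & c1 < n
  if (!any(seg)) return(0)
  a1 <- vapply(n[seg], function(k) sum(1 / seq_len(k - 1)), numeric(1))
  sum(1 / a1) / callable_bp
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D of a panel in a region
#'
#' Standard normalized difference between mean pairwise differences and
#' Watterson's estimator (Tajima 1989). Scale-free, so no per-bp
#' normalization. Reported only when the region has at least \code{S_min}
#' segregating sites and >= 4 called haplotypes; with missing data the
#' haplotype count entering the constants is the median called count over
#' segregating sites.
#'
#' @param hap haplotype matrix.
#' @param S_min minimum segregating sites (default 3).
#' @return D, or NA when preconditions fail.
#' @export
tajimas_d <- function(hap, S_min = 3L) {
  ncall <- colSums(!is.na(hap))
  c1 <- colSums(hap == 1L, na.rm = TRUE)
  seg <- ncall >= 2 & c1 >= 1 & c1 < ncall
  S <- sum(seg)
  if (S < S_min) return(NA_real_)
  n <- round(median(ncall[seg]))
  if (n < 4) return(NA_real_)
  # mean pairwise differences, summed over segregating sites
  ns <- ncall[seg]; cs <- c1[seg]
  khat <- sum(2 * cs * (ns - cs) / (ns * (ns - 1)))
  k <- tajima_constants(n)
  num <- khat - S / k$a1
  den <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (den == 0) return(NA_real_)
  num / den
}

# Hudson F_ST building blocks: per-region sums of between-panel diversity
# and mean within-panel diversity over sites where both panels have >= 2
# called haplotypes. Genome-wide aggregation is the ratio of summed
# components (ratio of sums), never a mean of window ratios.
hudson_components <- function(hapA, hapB) {
  nA <- colSums(!is.na(hapA)); cA <- colSums(hapA == 1L, na.rm = TRUE)
  nB <- colSums(!is.na(hapB)); cB <- colSums(hapB == 1L, na.rm = TRUE)
  ok <- nA >= 2 & nB >= 2
  if (!any(ok)) return(list(within = 0, between = 0, n_sites = 0L))
  pA <- cA[ok] / nA[ok]; pB <- cB[ok] / nB[ok]
  piA <- 2 * pA * (1 - pA) * nA[ok] / (nA[ok] - 1)
  piB <- 2 * pB * (1 - pB) * nB[ok] / (nB[ok] - 1)
  within <- 0.5 * (piA + piB)
  between <- pA * (1 - pB) + pB * (1 - pA)
  list(within = sum(within), between = sum(between), n_sites = sum(ok))
}

#' Hudson's F_ST between two panels
#'
#' F_ST = 1 - mean within-panel diversity / between-panel diversity, with
#' the within term the unweighted mean of the two panels' unbiased
#' diversities (Hudson 1992 convention) and aggregation over sites as a
#' ratio of sums. Symmetric in the panels; bounded above by 1; slightly
#' negative values are possible in small samples and are reported as-is.
#'
#' @param hapA,hapB haplotype matrices of the two panels.
#' @return F_ST, or NA when between-panel diversity is 0 (undefined).
#' @export
hudson_fst <- function(hapA, hapB) {
  h <- hudson_components(hapA, hapB)
  if (h$between == 0) return(NA_real_)
  1 - h$within / h$between
}

#' Windowed diversity and differentiation statistics
#'
#' Computes, for every window and panel, segregating sites, callable bp,
#' pi, Watterson's theta and Tajima's D; and for every panel pair, the
#' windowed Hudson F_ST plus a genome-wide ratio-of-sums F_ST. Windows with
#' callable bp below \code{min_callable_fraction} of the window length are
#' reported as no-data.
#'
#' @param vt a \code{VariantTable} (HET calls already masked/dropped).
#' @param grid a \code{WindowGrid}.
#' @param panels named list of strain-id vectors.
#' @param masks a \code{MaskSet} used for callable-bp accounting.
#' @param min_callable_fraction minimum callable fraction per window
#'   (default 0.5).
#' @param S_min minimum segregating sites for Tajima's D (default 3).
#' @return list with \code{stats} (long data.frame over windows x panels),
#'   \code{fst} (long data.frame over windows x panel pairs) and
#'   \code{fst_genome} (data.frame per panel pair).
#' @export
window_stats <- function(vt, grid, panels, masks = mask_set(),
                         min_callable_fraction = 0.5, S_min = 3L) {
  stopifnot(length(names(panels)) == length(panels))
  callable <- callable_by_window(grid, masks)
  swin <- site_windows(vt, grid)
  haps <- lapply(panels, function(p) haploidize(vt, p))
  W <- grid$end - grid$start

  stats <- list(); fst <- list()
  pair_idx <- if (length(panels) >= 2) combn(names(panels), 2, simplify = FALSE) else list()
  fst_num <- fst_den <- setNames(numeric(length(pair_idx)),
                                 vapply(pair_idx, paste, "", collapse = "|"))
  for (w in seq_len(nrow(grid))) {
    cols <- which(swin == grid$window[w])
    ok_win <- callable[w] >= min_callable_fraction * W[w]
    for (pn in names(panels)) {
      h <- haps[[pn]][, cols, drop = FALSE]
      ncall <- colSums(!is.na(h)); c1 <- colSums(h == 1L, na.rm = TRUE)
      S <- sum(ncall >= 2 & c1 >= 1 & c1 < ncall)
      stats[[length(stats) + 1L]] <- data.frame(
        contig = grid$contig[w], start = grid$start[w], end = grid$end[w],
        panel = pn, n = nrow(h), callable_bp = callable[w], S = S,
        pi = if (ok_win) nucleotide_diversity(h, callable[w]) else NA_real_,
        theta_w = if (ok_win) wattersons_theta(h, callable[w]) else NA_real_,
        tajima_d = if (ok_win) tajimas_d(h, S_min) else NA_real_,
        stringsAsFactors = FALSE)
    }
    for (k in seq_along(pair_idx)) {
      pr <- pair_idx[[k]]
      hc <- hudson_components(haps[[pr[1]]][, cols, drop = FALSE],
                              haps[[pr[2]]][, cols, drop = FALSE])
      fst_num[k] <- fst_num[k] + hc$within
      fst_den[k] <- fst_den[k] + hc$between
      fst[[length(fst) + 1L]] <- data.frame(
        contig = grid$contig[w], start = grid$start[w], end = grid$end[w],
        panel1 = pr[1], panel2 = pr[2],
        fst = if (ok_win && hc$between > 0) 1 - hc$within / hc$between else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  fst_genome <- data.frame(
    panel1 = vapply(pair_idx, `[`, "", 1), panel2 = vapply(pair_idx, `[`, "", 2),
    fst = ifelse(fst_den > 0, 1 - fst_num / fst_den, NA_real_),
    stringsAsFactors = FALSE)
  list(stats = do.call(rbind, stats), fst = do.call(rbind, fst),
       fst_genome = fst_genome)
}

#' Linkage-disequilibrium decay curve
#'
#' r-squared for all within-contig site pairs up to \code{max_dist} apart
#' whose minor allele frequencies (on the panel) are both at least
#' \code{maf_min}, computed on jointly called haplotypes; means are taken
#' per distance bin and smoothed with a monotone non-increasing (isotonic)
#' fit, from which the half-decay distance is the smallest bin midpoint
#' whose smoothed mean drops to half the first bin's smoothed mean.
#'
#' @param hap haplotype matrix.
#' @param sites site table aligned with \code{hap}'s columns
#'   (\code{contig}, \code{pos}).
#' @param max_dist maximum pair distance in bp (default 25000).
#' @param bin_width distance bin width in bp (default 500).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @return list of class \code{LDDecayCurve}: \code{bins} data.frame
#'   (mid, mean_r2, smoothed_r2, n_pairs) and \code{half_decay_bp}
#'   (NA when the curve never reaches half its initial value).
#' @export
ld_decay <- function(hap, sites, max_dist = 25000L, bin_width = 500L,
                     maf_min = 0.05) {
  stopifnot(ncol(hap) == nrow(sites))
  n <- colSums(!is.na(hap))
  p <- colSums(hap == 1L, na.rm = TRUE) / pmax(n, 1L)
  maf <- pmin(p, 1 - p)
  use <- which(n >= 2 & maf >= maf_min)
  nb <- ceiling(max_dist / bin_width)
  sum_r2 <- cnt <- numeric(nb)
  for (ctg in unique(sites$contig)) {
    idx <- use[sites$contig[use] == ctg]
    if (length(idx) < 2) next
    pos <- sites$pos[idx]
    o <- order(pos); idx <- idx[o]; pos <- pos[o]
    for (ii in seq_len(length(idx) - 1)) {
      jj <- ii + 1L
      while (jj <= length(idx) && pos[jj] - pos[ii] <= max_dist) {
        x <- hap[, idx[ii]]; y <- hap[, idx[jj]]
        both <- !is.na(x) & !is.na(y)
        if (sum(both) >= 2) {
          r <- suppressWarnings(cor(x[both], y[both]))
          if (!is.na(r)) {
            b <- ceiling((pos[jj] - pos[ii]) / bin_width)
            sum_r2[b] <- sum_r2[b] + r^2
            cnt[b] <- cnt[b] + 1
          }
        }
        jj <- jj + 1L
      }
    }
  }
  mids <- (seq_len(nb) - 0.5) * bin_width
  keep <- cnt > 0
  if (!any(keep))
    return(structure(list(bins = data.frame(mid = numeric(), mean_r2 = numeric(),
                                            smoothed_r2 = numeric(), n_pairs = numeric()),
                          half_decay_bp = NA_real_), class = "LDDecayCurve"))
  means <- sum_r2[keep] / cnt[keep]
  # monotone non-increasing fit: isotonic regression on the negated values
  sm <- -stats::isoreg(seq_along(means), -means)$yf
  bins <- data.frame(mid = mids[keep], mean_r2 = means, smoothed_r2 = sm,
                     n_pairs = cnt[keep])
  half <- bins$mid[sm <= 0.5 * sm[1]]
  structure(list(bins = bins,
                 half_decay_bp = if (length(half)) min(half) else NA_real_),
            class = "LDDecayCurve")
}

#' @export
print.LDDecayCurve <- function(x, ...) {
  cat("LDDecayCurve:", nrow(x$bins), "bins; half-decay",
      if (is.na(x$half_decay_bp)) "undefined" else paste(x$half_decay_bp, "bp"), "\n")
  invisible(x)
}

#' Differentiation network edge list
#'
#' Undirected edges between panels whose pairwise F_ST falls below a
#' threshold; node attributes carry panel diversity, matching the standard
#' presentation where edge thickness encodes 1 - F_ST and node size pi.
#'
#' @param fst_matrix symmetric matrix of pairwise F_ST (panel names on
#'   dimnames).
#' @param threshold edges kept where F_ST < threshold (default 0.8).
#' @param pi optional named vector of panel diversities.
#' @return list with \code{edges} (from, to, fst) and \code{nodes}
#'   (panel, pi).
#' @export
fst_network <- function(fst_matrix, threshold = 0.8, pi = NULL) {
  stopifnot(isSymmetric(unname(fst_matrix)))
  pn <- rownames(fst_matrix)
  edges <- list()
  for (i in seq_len(nrow(fst_matrix) - 1)) for (j in (i + 1):ncol(fst_matrix)) {
    v <- fst_matrix[i, j]
    if (!is.na(v) && v < threshold)
      edges[[length(edges) + 1L]] <- data.frame(from = pn[i], to = pn[j], fst = v,
                                                stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), fst = numeric())
  nodes <- data.frame(panel = pn,
                      pi = if (is.null(pi)) NA_real_ else unname(pi[pn]),
                      stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}
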