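# Shared toy builders and independent oracles. Oracles are deliberately
# written as plain loops / enumerations, independent of the package's
# vectorized implementations.

toy_vt <- function(geno, positions = NULL, contig_len = NULL, phase = NULL,
                   contig = "c1") {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("s", seq_len(nrow(geno)))
  if (is.null(positions)) positions <- seq(100, by = 100, length.out = ncol(geno))
  if (is.null(contig_len)) contig_len <- max(positions) + 100
  variant_table(
    contigs = data.frame(name = contig, length = contig_len),
    sites = data.frame(contig = contig, pos = as.integer(positions),
                       ref = "A", alt = "T", stringsAsFactors = FALSE),
    geno = geno, phase = phase)
}

small_panel_config <- function(seed, ...) {
  scenario_config(seed, n_sites = 4000L, contig_length = 3e6,
                  strains_per_subpop = 4L,
                  subpops = list(PA = c("PA-1", "PA-2"), PB = "PB-1"), ...)
}

# callable bp by per-basepair boolean array
oracle_callable <- function(window, masks) {
  covered <- rep(FALSE, window$end - window$start)
  m <- masks[masks$contig == window$contig, , drop = FALSE]
  for (k in seq_len(nrow(m))) {
    lo <- max(m$start[k], window$start); hi <- min(m$end[k], window$end)
    if (hi > lo) covered[(lo - window$start + 1):(hi - window$start)] <- TRUE
  }
  sum(!covered)
}

# per-site Hudson F_ST by explicit pair loops, aggregated as ratio of sums
oracle_hudson <- function(hapA, hapB) {
  sw <- sb <- 0
  pair_diff_mean <- function(h) {
    n <- nrow(h); tot <- 0; np <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(h[i, 1]) && !is.na(h[j, 1])) {
        tot <- tot + (h[i, 1] != h[j, 1]); np <- np + 1
      }
    }
    if (np == 0) NA else tot / np
  }
  for (s in seq_len(ncol(hapA))) {
    a <- hapA[, s, drop = FALSE]; b <- hapB[, s, drop = FALSE]
    na <- sum(!is.na(a)); nb <- sum(!is.na(b))
    if (na < 2 || nb < 2) next
    wA <- pair_diff_mean(a); wB <- pair_diff_mean(b)
    btot <- 0; np <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (!is.na(a[i, 1]) && !is.na(b[j, 1])) {
        btot <- btot + (a[i, 1] != b[j, 1]); np <- np + 1
      }
    }
    sw <- sw + 0.5 * (wA + wB)
    sb <- sb + btot / np
  }
  if (sb == 0) NA_real_ else 1 - sw / sb
}

# Tajima's D from the textbook constants, pairwise differences by loops
oracle_tajima <- function(hap) {
  n <- nrow(hap)
  S <- 0
  for (s in seq_len(ncol(hap))) {
    v <- hap[, s]
    if (length(unique(v)) > 1) S <- S + 1
  }
  khat <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    khat <- khat + sum(hap[i, ] != hap[j, ])
    np <- np + 1
  }
  khat <- khat / np
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# two-sided Fisher p by full hypergeometric enumeration over fixed margins
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  if (N == 0) return(1)
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(ks, c1, N - c1, r1)
  p_obs <- dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# r^2 from the 2x2 haplotype frequency table
oracle_r2 <- function(x, y) {
  both <- !is.na(x) & !is.na(y)
  x <- x[both]; y <- y[both]
  pA <- mean(x); pB <- mean(y); pAB <- mean(x == 1 & y == 1)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}
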