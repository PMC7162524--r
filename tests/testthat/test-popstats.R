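test_that("haploidize maps homozygous codes and refuses HET", {
  vt <- toy_vt(rbind(a = c(2L, 0L, NA), b = c(0L, 0L, 2L)))
  h <- haploidize(vt)
  expect_equal(unname(h["a", ]), c(1L, 0L, NA))
  expect_equal(unname(h["b", ]), c(0L, 0L, 1L))
  vth <- toy_vt(rbind(a = c(1L, 0L)))
  expect_error(haploidize(vth), "HET")
})

test_that("pairwise divergence counts joint differences over callable bp", {
  expect_equal(pairwise_divergence(c(0, 1, 1), c(0, 1, 1), 1000), 0)
  a <- c(rep(1, 5), rep(0, 15)); b <- rep(0, 20)
  expect_equal(pairwise_divergence(a, b, 50000), 1e-4)
  expect_true(is.na(pairwise_divergence(a, b, 0)))

  set.seed(77)
  for (rep in 1:10) {
    x <- sample(c(0L, 1L, NA), 10, replace = TRUE)
    y <- sample(c(0L, 1L, NA), 10, replace = TRUE)
    loop <- 0
    for (s in 1:10) if (!is.na(x[s]) && !is.na(y[s]) && x[s] != y[s]) loop <- loop + 1
    expect_equal(pairwise_divergence(x, y, 100), loop / 100)
  }
})

test_that("pi equals the all-pairs mean of pairwise divergence", {
  h3 <- rbind(a = 0L, b = 0L, c = 1L)
  expect_equal(nucleotide_diversity(h3, 1000), (2 * (1/3) * (2/3) * 1.5) / 1000)
  expect_equal(nucleotide_diversity(h3, 1000), (0 + 1 + 1) / 3 / 1000)

  expect_equal(nucleotide_diversity(matrix(1L, 4, 6), 500), 0)  # monomorphic

  set.seed(19)
  for (rep in 1:5) {
    h <- matrix(rbinom(6 * 15, 1, 0.4), 6, 15,
                dimnames = list(paste0("s", 1:6), NULL))
    pairs <- combn(6, 2)
    dbar <- mean(apply(pairs, 2, function(p)
      pairwise_divergence(h[p[1], ], h[p[2], ], 300)))
    expect_equal(nucleotide_diversity(h, 300), dbar, tolerance = 1e-12)
  }
})

test_that("Tajima's D has the textbook value, sign behavior, and S_min gate", {
  # all singletons: strong negative
  h_sing <- matrix(0L, 10, 8)
  for (s in 1:8) h_sing[s, s] <- 1L
  expect_lt(tajimas_d(h_sing), 0)

  # balanced intermediate frequencies: positive
  h_bal <- matrix(0L, 10, 8); h_bal[1:5, ] <- 1L
  expect_gt(tajimas_d(h_bal), 0)

  set.seed(23)
  for (rep in 1:10) {
    h <- matrix(rbinom(6 * 25, 1, runif(1, 0.2, 0.8)), 6, 25)
    seg <- apply(h, 2, function(v) length(unique(v)) > 1)
    if (sum(seg) < 3) next
    expect_equal(tajimas_d(h), oracle_tajima(h), tolerance = 1e-10)
  }

  h2 <- matrix(0L, 10, 10); h2[1, 1] <- 1L; h2[2, 2] <- 1L
  expect_true(is.na(tajimas_d(h2)))  # S = 2 < S_min
})

test_that("Hudson F_ST: limits, symmetry, bound, and the per-site oracle", {
  set.seed(5)
  # one unstructured panel split in two halves -> ~0
  p_site <- runif(2000, 0.2, 0.8)
  h <- t(vapply(1:20, function(i) rbinom(2000, 1, p_site), integer(2000)))
  expect_lt(abs(hudson_fst(h[1:10, ], h[11:20, ])), 0.02)

  # alternative fixation -> 1
  expect_equal(hudson_fst(matrix(0L, 3, 8), matrix(1L, 3, 8)), 1)

  for (rep in 1:5) {
    hA <- matrix(rbinom(5 * 30, 1, 0.3), 5, 30)
    hB <- matrix(rbinom(5 * 30, 1, 0.7), 5, 30)
    f <- hudson_fst(hA, hB)
    expect_equal(f, hudson_fst(hB, hA))           # label symmetry
    expect_lte(f, 1)                              # bounded above
    expect_equal(f, oracle_hudson(hA, hB), tolerance = 1e-12)
  }
  # monomorphic identical panels: undefined, not 0
  expect_true(is.na(hudson_fst(matrix(0L, 3, 5), matrix(0L, 3, 5))))
})

test_that("LD r2 matches the 2x2 haplotype-table oracle and the curve is
           monotone after smoothing", {
  # duplicated site at distance d: r2 = 1 in d's bin
  set.seed(13)
  x <- rbinom(12, 1, 0.5)
  hap <- cbind(x, x)
  curve <- ld_decay(hap, data.frame(contig = "c1", pos = c(100L, 400L)),
                    max_dist = 1000L, bin_width = 500L, maf_min = 0.05)
  expect_equal(curve$bins$mean_r2[1], 1)

  # 20-site toy: every binned value equals the direct 2x2 oracle
  n_sites <- 20
  pos <- cumsum(sample(3:9, n_sites, replace = TRUE))
  hap20 <- matrix(rbinom(10 * n_sites, 1, 0.5), 10, n_sites)
  sites <- data.frame(contig = "c1", pos = pos)
  cv <- ld_decay(hap20, sites, max_dist = 200L, bin_width = 1L, maf_min = 0)
  for (k in seq_len(nrow(cv$bins))) {
    d <- cv$bins$mid[k] + 0.5
    prs <- which(outer(pos, pos, function(a, b) b - a) == d, arr.ind = TRUE)
    if (cv$bins$n_pairs[k] == 1 && nrow(prs) == 1) {
      expect_equal(cv$bins$mean_r2[k],
                   oracle_r2(hap20[, prs[1, 1]], hap20[, prs[1, 2]]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(diff(cv$bins$smoothed_r2) <= 1e-12))

  # independent sites: mean r2 ~ 1/n, matching a permutation oracle
  n_h <- 20
  hap_i <- matrix(rbinom(n_h * 150, 1, 0.5), n_h, 150)
  pos_i <- seq(10, by = 10, length.out = 150)
  cv_i <- ld_decay(hap_i, data.frame(contig = "c1", pos = pos_i),
                   max_dist = 300L, bin_width = 300L, maf_min = 0.05)
  perm <- apply(hap_i, 2, sample)
  cv_p <- ld_decay(perm, data.frame(contig = "c1", pos = pos_i),
                   max_dist = 300L, bin_width = 300L, maf_min = 0.05)
  expect_lt(abs(cv_i$bins$mean_r2[1] - cv_p$bins$mean_r2[1]), 0.03)
  expect_lt(abs(cv_i$bins$mean_r2[1] - 1 / n_h), 0.05)

  empty <- ld_decay(matrix(0L, 4, 2), data.frame(contig = "c1", pos = c(1L, 5L)),
                    maf_min = 0.05)
  expect_equal(nrow(empty$bins), 0L)
  expect_true(is.na(empty$half_decay_bp))
})

test_that("half-decay distance reads off the smoothed curve", {
  # construct perfectly correlated block then independent noise
  set.seed(99)
  n <- 40
  block <- rbinom(n, 1, 0.5)
  hap <- cbind(block, block, block,
               matrix(rbinom(n * 6, 1, 0.5), n, 6))
  pos <- c(100L, 200L, 300L, seq(2000L, by = 1000L, length.out = 6))
  cv <- ld_decay(hap, data.frame(contig = "c1", pos = pos),
                 max_dist = 8000L, bin_width = 500L, maf_min = 0.05)
  expect_false(is.na(cv$half_decay_bp))
  expect_gt(cv$bins$smoothed_r2[1], 0.9)
})

test_that("the F_ST network keeps edges under the threshold only", {
  fm <- matrix(0.9, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(fm) <- 0
  expect_equal(nrow(fst_network(fm, 0.8)$edges), 0L)
  fm["A", "B"] <- fm["B", "A"] <- 0.5
  nw <- fst_network(fm, 0.8, pi = c(A = 0.01, B = 0.02, C = 0.03))
  expect_equal(nrow(nw$edges), 1L)
  expect_equal(nw$edges$fst, 0.5)
  expect_equal(nw$nodes$pi, c(0.01, 0.02, 0.03))
  expect_equal(nrow(fst_network(fm, 1.01)$edges), 3L)  # complete graph
})

test_that("windowed statistics table respects callable thresholds and
           aggregates F_ST as a ratio of sums", {
  cfg <- small_panel_config(71)
  panel <- simulate_structured_panel(cfg)
  grid <- make_windows(panel$vt$contigs, 500000L)
  panels <- split(panel$meta$strain, panel$meta$subpopulation)
  ws <- window_stats(panel$vt, grid, panels)
  expect_equal(nrow(ws$stats), nrow(grid) * length(panels))
  expect_true(all(ws$stats$pi >= 0, na.rm = TRUE))
  expect_true(all(ws$fst$fst <= 1, na.rm = TRUE))

  # genome-wide value is the ratio of summed components, not a mean of windows
  hA <- haploidize(panel$vt, panels[["PA-1"]])
  hB <- haploidize(panel$vt, panels[["PB-1"]])
  direct <- hudson_fst(hA, hB)
  row <- ws$fst_genome[ws$fst_genome$panel1 == "PA-1" & ws$fst_genome$panel2 == "PB-1", ]
  expect_equal(row$fst, direct, tolerance = 1e-12)

  # fully masked genome: every window no-data
  full_mask <- mask_set(data.frame(contig = panel$vt$contigs$name, start = 0,
                                   end = panel$vt$contigs$length, label = "repeat"))
  ws0 <- window_stats(panel$vt, grid, panels["PA-1"], full_mask)
  expect_true(all(is.na(ws0$stats$pi)))
})

test_that("Tajima's D is centered near zero for neutral-spectrum panels", {
  set.seed(8)
  vals <- replicate(200, {
    cfg <- scenario_config(sample.int(1e6, 1), n_sites = 250L,
                           contig_length = 5e5, strains_per_subpop = 10L,
                           F_pop = 1e-9, F_sub = 1e-9, spectrum = "neutral",
                           subpops = list(PA = "PA-1", PB = "PB-1"))
    p <- simulate_structured_panel(cfg)
    h <- haploidize(p$vt, p$meta$strain[p$meta$subpopulation == "PA-1"])
    tajimas_d(h)
  })
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.3)
})
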