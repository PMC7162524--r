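test_that("nested drift hits its differentiation targets", {
  # near-zero drift: realized between-subpopulation F_ST ~ 0
  cfg0 <- scenario_config(101, n_sites = 20000L, contig_length = 5e6,
                          strains_per_subpop = 10L, F_pop = 1e-9, F_sub = 1e-9,
                          subpops = list(PA = "PA-1", PB = "PB-1"))
  p0 <- simulate_structured_panel(cfg0)
  hA <- haploidize(p0$vt, p0$meta$strain[p0$meta$subpopulation == "PA-1"])
  hB <- haploidize(p0$vt, p0$meta$strain[p0$meta$subpopulation == "PB-1"])
  expect_lt(abs(hudson_fst(hA, hB)), 0.02)

  # strong drift: implementation agrees with the per-site loop oracle
  cfg1 <- scenario_config(102, n_sites = 20000L, contig_length = 5e6,
                          strains_per_subpop = 10L, F_pop = 0.45, F_sub = 0.15,
                          subpops = list(PA = "PA-1", PB = "PB-1"))
  p1 <- simulate_structured_panel(cfg1)
  hA <- haploidize(p1$vt, p1$meta$strain[p1$meta$subpopulation == "PA-1"])
  hB <- haploidize(p1$vt, p1$meta$strain[p1$meta$subpopulation == "PB-1"])
  fst <- hudson_fst(hA, hB)
  # oracle on a subset of sites for speed; ratio-of-sums over those sites
  sub <- seq(1, 20000, by = 10)
  expect_lt(abs(hudson_fst(hA[, sub], hB[, sub]) -
                oracle_hudson(hA[, sub], hB[, sub])), 1e-12)
  expect_lt(abs(fst - oracle_hudson(hA[, sub], hB[, sub])), 0.08)
  expect_gt(fst, 0.2)  # strong differentiation actually realized
})

test_that("heterozygosity fraction is honored (h = 0 means no HET calls)", {
  p <- simulate_structured_panel(small_panel_config(7))
  expect_equal(sum(p$vt$geno == 1L, na.rm = TRUE), 0L)
  ph <- simulate_structured_panel(small_panel_config(7, het_fraction = 0.1))
  hs <- het_summary(ph$vt, ph$meta$strain[1])
  expect_gt(hs$het_calls, 0)
})

test_that("degenerate generator configs are rejected", {
  expect_error(simulate_structured_panel(scenario_config(1, n_sites = 0L)),
               "degenerate")
  expect_error(scenario_config(1, soam = list(pa_prob = 1.5)))
})

test_that("NoAm lineage: clones are identical up to site-private SNPs that
           delineate geography", {
  cfg <- small_panel_config(19)
  panel <- simulate_structured_panel(cfg)

  # no private SNPs: all clone rows identical
  cfg0 <- cfg; cfg0$noam$private_snps <- 0L
  n0 <- simulate_noam_lineage(cfg0, panel)
  rows <- n0$vt$geno[n0$truth$clone_ids, ]
  expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))

  # 571 private SNPs: pairwise clone differences = sum of their sites' counts
  n1 <- simulate_noam_lineage(cfg, panel)
  expect_equal(sum(n1$truth$private_per_site), 571L)
  ids <- n1$truth$clone_ids
  site_of <- n1$truth$geo_site
  cnt <- n1$truth$private_per_site
  for (pair in list(c(1, 7), c(2, 21), c(10, 15))) {
    a <- ids[pair[1]]; b <- ids[pair[2]]
    observed <- sum(n1$vt$geno[a, ] != n1$vt$geno[b, ], na.rm = TRUE)
    expected <- if (site_of[a] == site_of[b]) 0L else
      unname(cnt[site_of[a]] + cnt[site_of[b]])
    expect_equal(observed, expected)
  }

  # window ancestry draw is Bernoulli(pa_prob): realized fraction within
  # binomial 99% bounds
  nw <- length(n1$truth$window_ancestry)
  k <- sum(n1$truth$window_ancestry == "PA-2")
  expect_gt(k, qbinom(0.005, nw, 0.5) - 1)
  expect_lt(k, qbinom(0.995, nw, 0.5) + 1)
})

test_that("SoAm mosaic: PA probability and donor split behave as configured", {
  cfg <- small_panel_config(23)
  panel <- simulate_structured_panel(cfg)

  cfg1 <- cfg; cfg1$soam$pa_prob <- 1
  s1 <- simulate_soam_strain(cfg1, panel)
  expect_true(all(s1$truth$window_is_pa))

  s <- simulate_soam_strain(cfg, panel)
  expect_equal(s$truth$pa_fraction, mean(s$truth$window_is_pa))
  # PA windows split ~50/50 between PA-1 and PA-2 donors
  pa_d <- s$truth$window_donor[s$truth$window_is_pa]
  k <- sum(pa_d == "PA-1"); n <- length(pa_d)
  expect_gt(k, qbinom(0.005, n, 0.5) - 1)
  expect_lt(k, qbinom(0.995, n, 0.5) + 1)
})

test_that("type-strain scenario injects the configured PA-1 window fraction", {
  cfg <- small_panel_config(29, n_sites = 5000L, contig_length = 12.5e6)
  panel <- simulate_structured_panel(cfg)

  cfg0 <- cfg; cfg0$typestrain$pa_fraction <- 0
  t0 <- simulate_typestrain(cfg0, panel)
  pb1 <- eubpop:::first_strain_of(panel$meta, "PB-1")
  expect_equal(unname(t0$vt$geno["TypeStrain", ]),
               unname(t0$vt$geno[pb1, ]))

  t <- simulate_typestrain(cfg, panel)   # 250 windows at fraction 0.04
  k <- sum(t$truth$window_is_pa)
  expect_gte(k, 2); expect_lte(k, 20)

  cfg1 <- cfg; cfg1$typestrain$pa_fraction <- 1
  t1 <- simulate_typestrain(cfg1, panel)
  expect_true(all(t1$truth$window_is_pa))
})

test_that("dual-reference depth: tract windows, leakage and normalization", {
  cfg <- scenario_config(17)
  dd <- simulate_dual_depth(cfg)
  expect_equal(dd$truth$tract_windows, 7:9)  # [300000,450000) at W = 50 kb

  cp <- coverage_profile(dd$depth)
  rec <- cp[cp$reference == "Seub", ]
  expect_lt(abs(median(rec$norm_depth) - 1), 0.1)

  # no tract: donor-reference normalized depth stays below 0.25 everywhere
  cfg0 <- scenario_config(37, introgression = list(tract = NULL))
  dd0 <- simulate_dual_depth(cfg0)
  cp0 <- coverage_profile(dd0$depth)
  expect_true(all(cp0$norm_depth[cp0$reference == "Suva"] < 0.25))

  expect_error(simulate_dual_depth(scenario_config(1, introgression = list(leakage = 1.2))),
               "leakage")
  expect_error(scenario_config(1, introgression = list(tract = c(1.9e6, 2.1e6))),
               "past its contig")
})

test_that("geography scenario produces isolation by distance in its truth", {
  expect_error(simulate_geography(scenario_config(1, geography = list(n_geo_sites = 2L))),
               "at least 3")
  g <- simulate_geography(scenario_config(41))
  lt <- lower.tri(g$truth$geo_km)
  expect_gt(cor(g$truth$geo_km[lt], g$truth$genetic_diff[lt]), 0)
  # realized genotype differences equal the truth expectation exactly
  ids <- rownames(g$truth$geo_km)
  for (pair in list(c(1, 24), c(3, 12))) {
    obs <- sum(g$vt$geno[ids[pair[1]], ] != g$vt$geno[ids[pair[2]], ])
    expect_equal(obs, unname(g$truth$genetic_diff[pair[1], pair[2]]))
  }
})

test_that("generation is bit-identical under a fixed seed and round-trips
           through VCF", {
  a <- simulate_structured_panel(small_panel_config(55))
  b <- simulate_structured_panel(small_panel_config(55))
  expect_identical(a$vt$geno, b$vt$geno)
  expect_identical(a$truth$p_sub, b$truth$p_sub)

  p <- tempfile(fileext = ".vcf")
  write_variant_vcf(a$vt, p)
  vt2 <- read_vcf(p)
  expect_identical(unname(a$vt$geno), unname(vt2$geno))
  expect_equal(a$vt$sites$pos, vt2$sites$pos)
  expect_equal(a$vt$contigs$length, vt2$contigs$length)
})

test_that("named fixtures materialize and re-read consistently", {
  dir <- tempfile("fx")
  fx <- make_fixture("noam", seed = 3, dir = dir,
                     config = small_panel_config(3))
  vt <- read_vcf(fx$vcf)
  expect_equal(sum(grepl("^NoAm_", vt$strain_ids)), 21L)
  expect_identical(unname(attr(fx, "vt")$geno), unname(vt$geno))
  meta <- read_meta(fx$meta)
  expect_equal(nrow(meta), n_strains(vt))
  expect_error(make_fixture("volcano", 1), "unknown scenario")
})
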