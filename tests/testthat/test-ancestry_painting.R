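make_paint_fixture <- function(seed = 11) {
  cfg <- small_panel_config(seed)
  panel <- simulate_structured_panel(cfg)
  pa <- panel$meta$strain[panel$meta$population == "PA"]
  pb <- panel$meta$strain[panel$meta$population == "PB"]
  list(cfg = cfg, panel = panel, pa = pa, pb = pb)
}

test_that("a clone of a panel member paints entirely to that panel", {
  fx <- make_paint_fixture(83)
  vt <- fx$panel$vt
  clone <- matrix(vt$geno[fx$pa[1], ], 1, dimnames = list("cloneQ", NULL))
  vt2 <- eubpop:::augment_panel(vt, clone)
  pr <- paint(vt2, "cloneQ", fx$pa, fx$pb)
  expect_equal(pr$pa_fraction, 1)
  expect_true(all(pr$windows$class[pr$windows$class != "NODATA"] == "PA"))
})

test_that("equidistant windows are AMBIG and panel swap negates r exactly", {
  # hand-built: query equidistant from the A and B member
  g <- rbind(q = rep(0L, 20), a = c(rep(2L, 5), rep(0L, 15)),
             b = c(rep(0L, 15), rep(2L, 5)))
  vt <- toy_vt(g, positions = seq(10, 200, by = 10), contig_len = 250)
  grid <- make_windows(vt$contigs, 250L)
  pr <- paint(vt, "q", "a", "b", grid = grid)
  expect_equal(pr$windows$r, 0)
  expect_equal(pr$windows$class, "AMBIG")

  fx <- make_paint_fixture(89)
  soam <- simulate_soam_strain(fx$cfg, fx$panel)
  p1 <- paint(soam$vt, "SoAm", fx$pa, fx$pb)
  p2 <- paint(soam$vt, "SoAm", fx$pb, fx$pa)  # swapped panels
  expect_equal(p1$windows$r, -p2$windows$r)
  expect_equal(p1$windows$class == "PA", p2$windows$class == "PB")
  expect_equal(p1$pa_fraction, p2$pb_fraction)
})

test_that("query must be excluded from the panels", {
  fx <- make_paint_fixture(97)
  expect_error(paint(fx$panel$vt, fx$pa[1], fx$pa, fx$pb), "excluded")
})

test_that("minor-ancestry classification bands: pure / introgressed / admixed", {
  fx <- make_paint_fixture(13)

  # m = 0: a pure clone
  clone <- matrix(fx$panel$vt$geno[fx$pb[1], ], 1, dimnames = list("pureQ", NULL))
  vtc <- eubpop:::augment_panel(fx$panel$vt, clone)
  prc <- paint(vtc, "pureQ", fx$pa, fx$pb)
  expect_equal(classify_strain(prc)$label, "pure")

  ts <- simulate_typestrain(fx$cfg, fx$panel)
  prt <- paint(ts$vt, "TypeStrain", fx$pa, fx$pb)
  clt <- classify_strain(prt)
  m_true <- ts$truth$pa_fraction
  band <- if (m_true < 0.02) "pure" else if (m_true <= 0.12) "introgressed" else "admixed"
  expect_equal(clt$label, band)
  expect_lt(abs(clt$minor_fraction - m_true), 0.02)

  soam <- simulate_soam_strain(fx$cfg, fx$panel)
  prs <- paint(soam$vt, "SoAm", fx$pa, fx$pb)
  expect_equal(classify_strain(prs)$label, "admixed")

  # too few classified windows: label withheld
  expect_true(is.na(classify_strain(prs, min_windows = 10000L)$label))
})

test_that("donor subpopulation ranking recovers the generating parents", {
  cfg <- scenario_config(31, n_sites = 6000L, contig_length = 3e6,
                         strains_per_subpop = 4L,
                         subpops = list(PA = c("PA-1", "PA-2"),
                                        PB = c("PB-1", "PB-2")))
  panel <- simulate_structured_panel(cfg)
  pa <- panel$meta$strain[panel$meta$population == "PA"]
  pb <- panel$meta$strain[panel$meta$population == "PB"]
  noam <- simulate_noam_lineage(cfg, panel)
  q <- noam$truth$clone_ids[1]
  pr <- paint(noam$vt, q, pa, pb)
  sub_of <- split(panel$meta$strain, panel$meta$subpopulation)
  rk_pa <- donor_subpop(noam$vt, q, sub_of[c("PA-1", "PA-2")], pr, "PA")
  rk_pb <- donor_subpop(noam$vt, q, sub_of[c("PB-1", "PB-2")], pr, "PB")
  expect_equal(rk_pa$subpop[1], "PA-2")
  expect_equal(rk_pb$subpop[1], "PB-1")
  expect_gt(attr(rk_pa, "margin"), 0)

  # no windows of a class on a pure clone: empty ranking
  clone <- matrix(panel$vt$geno[pb[1], ], 1, dimnames = list("cl", NULL))
  vtc <- eubpop:::augment_panel(panel$vt, clone)
  prc <- paint(vtc, "cl", pa, pb)
  expect_equal(nrow(donor_subpop(vtc, "cl", sub_of[c("PA-1", "PA-2")], prc, "PA")), 0L)

  # a clone of a PB-2 strain ranks PB-2 first on the PB side
  pb2 <- sub_of[["PB-2"]][1]
  cl2 <- matrix(panel$vt$geno[pb2, ], 1, dimnames = list("cl2", NULL))
  vt2 <- eubpop:::augment_panel(panel$vt, cl2)
  pr2 <- paint(vt2, "cl2", pa, pb)
  rk2 <- donor_subpop(vt2, "cl2", sub_of[c("PB-1", "PB-2")], pr2, "PB")
  expect_equal(rk2$subpop[1], "PB-2")
})

test_that("SoAm PA windows draw on both PA-1 and PA-2 donors", {
  fx <- make_paint_fixture(37)
  soam <- simulate_soam_strain(fx$cfg, fx$panel)
  d <- soam$truth$window_donor[soam$truth$window_is_pa]
  expect_true(all(c("PA-1", "PA-2") %in% d))
})

test_that("profile identity groups clones and counts differentiating SNPs", {
  cfg <- small_panel_config(41)
  panel <- simulate_structured_panel(cfg)
  pa <- panel$meta$strain[panel$meta$population == "PA"]
  pb <- panel$meta$strain[panel$meta$population == "PB"]

  cfg0 <- cfg; cfg0$noam$private_snps <- 0L; cfg0$noam$n_clones <- 4L
  n0 <- simulate_noam_lineage(cfg0, panel)
  profs0 <- lapply(setNames(n0$truth$clone_ids, n0$truth$clone_ids), function(q)
    paint(n0$vt, q, pa, pb))
  g0 <- profile_identity(profs0, n0$vt)
  expect_equal(length(g0[[1]]$members), 4L)
  expect_equal(g0[[1]]$diff_snp_count, 0L)

  # two unrelated strains: singleton groups
  profs_u <- lapply(setNames(c(pa[1], pb[1]), c(pa[1], pb[1])), function(q)
    paint(panel$vt, q, setdiff(pa, q), setdiff(pb, q)))
  gu <- profile_identity(profs_u, panel$vt)
  expect_equal(lengths(lapply(gu, `[[`, "members")), c(1L, 1L))
})

test_that("window-class accuracy and ancestry-fraction recovery across seeds", {
  errs <- c(); accs <- c()
  for (seed in 1:50) {
    cfg <- scenario_config(seed, n_sites = 4000L, contig_length = 3e6,
                           strains_per_subpop = 4L,
                           subpops = list(PA = c("PA-1", "PA-2"), PB = "PB-1"))
    panel <- simulate_structured_panel(cfg)
    pa <- panel$meta$strain[panel$meta$population == "PA"]
    pb <- panel$meta$strain[panel$meta$population == "PB"]
    soam <- simulate_soam_strain(cfg, panel)
    pr <- paint(soam$vt, "SoAm", pa, pb)
    called <- pr$windows$class %in% c("PA", "PB")
    truth_cls <- ifelse(soam$truth$window_is_pa, "PA", "PB")
    accs <- c(accs, mean(pr$windows$class[called] == truth_cls[called]))
    errs <- c(errs, pr$pa_fraction - cfg$soam$pa_prob)
  }
  expect_gte(mean(accs), 0.95)
  expect_lt(abs(mean(errs)), 0.02)
})
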