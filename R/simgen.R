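# Deterministic substream seeding: every scenario block draws from its own
# substream derived from the single top-level seed, so adding one scenario
# never perturbs another. Kept below 2^31.
substream_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1000003
  as.integer(((seed %% 50021) * 40009 + h * 17 + 1) %% 2147483647)
}

SUBPOP_COORDS <- list(
  "PA-1" = c(-41.06, -71.53), "PA-2" = c(-40.70, -71.80),
  "PB-1" = c(-41.13, -71.31), "PB-2" = c(-42.00, -71.52),
  "PB-3" = c(-50.30, -72.30), "Holarctic" = c(44.05, 142.35))

NOAM_SITES <- data.frame(
  site = c("Wisconsin", "NewBrunswick", "NorthCarolina", "SouthCarolina"),
  latitude = c(43.08, 45.96, 35.59, 34.95),
  longitude = c(-89.43, -66.64, -82.55, -82.44), stringsAsFactors = FALSE)

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults encode the reference conditions the generator emulates: a 12-Mbp
#' genome tiled by 240 windows of 50 kbp; two populations (PA, PB) split
#' into six subpopulations with strong nested drift (Balding-Nichols
#' F_pop = 0.45, F_sub = 0.15); homozygous diploid strains; a clonal
#' admixed NoAm lineage of 21 strains over four geographic sites carrying
#' 571 site-private SNPs; a ~45/55 PA/PB admixed SoAm strain whose PA
#' parent is an equal PA-1/PA-2 mosaic; a type strain with a 4% PA-1
#' window fraction on a PB-1 background; a 150-kbp heterospecific tract
#' at [300000, 450000) with Poisson read depth 30 and 5% cross-mapping
#' leakage; and a 400-km transect with distance-proportional divergence.
#'
#' @param seed integer master seed; every scenario block derives its own
#'   substream from it.
#' @param ... overrides for any default listed above (see the returned
#'   list's names).
#' @return list of class \code{ScenarioConfig}.
#' @export
scenario_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_contigs = 1L, contig_length = 12e6, n_sites = 24000L, W = 50000L,
    spectrum = "uniform",
    F_pop = 0.45, F_sub = 0.15, strains_per_subpop = 6L, het_fraction = 0,
    subpops = list(PA = c("PA-1", "PA-2"),
                   PB = c("PB-1", "PB-2", "PB-3", "Holarctic")),
    noam = list(n_clones = 21L, n_geo_sites = 4L, private_snps = 571L,
                pa_prob = 0.5, pa_parent = "PA-2", pb_parent = "PB-1"),
    soam = list(pa_prob = 0.45, pa_parents = c("PA-1", "PA-2"),
                pb_parent = "PB-1"),
    typestrain = list(pa_fraction = 0.04, pa_parent = "PA-1",
                      pb_parent = "PB-1"),
    introgression = list(contig = "chrXIV_syn", contig_length = 2e6,
                         tract = c(300000, 450000), depth_mean = 30,
                         leakage = 0.05, n_strains = 1L,
                         recipient_ref = "Seub", donor_ref = "Suva"),
    geography = list(n_geo_sites = 6L, n_strains = 24L, transect_km = 400,
                     slope_per_km = 0.5, noise_loci = 30, n_bg_sites = 2000L,
                     contig_length = 2e6, origin = c(-41.0, -71.5)))
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(cfg) && is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  stopifnot(cfg$F_pop > 0, cfg$F_pop < 1, cfg$F_sub > 0, cfg$F_sub < 1,
            cfg$het_fraction >= 0, cfg$het_fraction <= 1,
            cfg$noam$pa_prob >= 0, cfg$noam$pa_prob <= 1,
            cfg$soam$pa_prob >= 0, cfg$soam$pa_prob <= 1,
            cfg$typestrain$pa_fraction >= 0, cfg$typestrain$pa_fraction <= 1)
  if (!is.null(cfg$introgression$tract) &&
      cfg$introgression$tract[2] > cfg$introgression$contig_length)
    stop("introgression tract extends past its contig")
  class(cfg) <- "ScenarioConfig"
  cfg
}

# Balding-Nichols draw: Beta with mean p and variance F p (1-p).
bn_draw <- function(p, F) {
  if (F < 1e-9) return(p)
  rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

draw_ancestral_freq <- function(n, spectrum) {
  if (spectrum == "neutral") {
    # density proportional to 1/p: gives the ~1/k site frequency spectrum
    # expected under neutrality (support wide enough to admit singletons)
    lo <- 0.001; hi <- 0.999
    lo * (hi / lo)^runif(n)
  } else {
    runif(n, 0.05, 0.95)
  }
}

#' Simulate a structured homozygous-diploid panel
#'
#' Nested Balding-Nichols drift: an ancestral allele frequency per site,
#' a population frequency Beta-distributed around it with variance scaled
#' by \code{F_pop}, and a subpopulation frequency likewise with
#' \code{F_sub}. Each strain samples one allele per site and doubles it
#' (homozygous diploid); a fraction \code{het_fraction} of calls per strain
#' is forced heterozygous with a random phase.
#'
#' @param config a \code{ScenarioConfig}.
#' @return list: \code{vt} (VariantTable), \code{meta} (StrainMeta),
#'   \code{truth} (all generating frequencies and assignments).
#' @export
simulate_structured_panel <- function(config) {
  cfg <- config
  if (cfg$n_sites < 1 || cfg$strains_per_subpop < 1)
    stop("degenerate config: need at least one site and one strain per subpopulation")
  set.seed(substream_seed(cfg$seed, "panel"))

  contigs <- data.frame(name = paste0("ctg", seq_len(cfg$n_contigs)),
                        length = cfg$contig_length, stringsAsFactors = FALSE)
  per_ctg <- diff(round(seq(0, cfg$n_sites, length.out = cfg$n_contigs + 1)))
  sites <- do.call(rbind, lapply(seq_len(cfg$n_contigs), function(i) {
    data.frame(contig = contigs$name[i],
               pos = sort(sample.int(cfg$contig_length, per_ctg[i])),
               stringsAsFactors = FALSE)
  }))
  nt <- c("A", "C", "G", "T")
  sites$ref <- sample(nt, nrow(sites), replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(nt, r), 1), "")

  ns <- nrow(sites)
  p0 <- draw_ancestral_freq(ns, cfg$spectrum)
  pops <- names(cfg$subpops)
  p_pop <- lapply(setNames(pops, pops), function(p) bn_draw(p0, cfg$F_pop))
  subs <- unlist(cfg$subpops, use.names = FALSE)
  sub_pop <- rep(pops, lengths(cfg$subpops))
  p_sub <- lapply(seq_along(subs), function(i) bn_draw(p_pop[[sub_pop[i]]], cfg$F_sub))
  names(p_sub) <- subs

  strain_sub <- rep(subs, each = cfg$strains_per_subpop)
  ids <- paste0(gsub("-", "", strain_sub), "_s",
                sequence(rep(cfg$strains_per_subpop, length(subs))))
  geno <- matrix(NA_integer_, length(ids), ns, dimnames = list(ids, NULL))
  phase <- matrix(NA_integer_, length(ids), ns, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    allele <- rbinom(ns, 1L, p_sub[[strain_sub[i]]])
    geno[i, ] <- 2L * allele
    if (cfg$het_fraction > 0) {
      k <- round(cfg$het_fraction * ns)
      if (k > 0) {
        hs <- sample.int(ns, k)
        geno[i, hs] <- GT_HET
        phase[i, hs] <- rbinom(k, 1L, 0.5)
      }
    }
  }
  vt <- variant_table(contigs, sites, geno, phase)

  coords <- do.call(rbind, SUBPOP_COORDS[strain_sub])
  meta <- validate_meta(data.frame(
    strain = ids,
    population = rep(rep(pops, lengths(cfg$subpops)), each = cfg$strains_per_subpop),
    subpopulation = strain_sub,
    latitude = coords[, 1], longitude = coords[, 2],
    site = strain_sub, host = "unknown", host2 = NA_character_,
    substrate = "unknown", stringsAsFactors = FALSE))
  truth <- list(seed = cfg$seed, p0 = p0, p_pop = p_pop, p_sub = p_sub,
                subpop = setNames(strain_sub, ids),
                F_pop = cfg$F_pop, F_sub = cfg$F_sub)
  list(vt = vt, meta = meta, truth = truth)
}

# Allele (0/1) carried by a homozygous strain; HET treated as alt-carrier
# only for HOM_ALT — generator parents are fully homozygous.
parent_haplotype <- function(vt, strain) as.integer(vt$geno[strain, ] == GT_HOM_ALT)

first_strain_of <- function(meta, subpop) {
  s <- meta$strain[meta$subpopulation == subpop]
  if (!length(s)) stop("panel lacks subpopulation ", subpop)
  s[1]
}

# Append extra strains (matrix rows, genotype codes) and optionally extra
# site-private SNP columns to a panel's VariantTable.
augment_panel <- function(vt, new_geno, new_sites = NULL, carriers = NULL) {
  geno <- rbind(vt$geno, new_geno)
  sites <- vt$sites
  if (!is.null(new_sites) && nrow(new_sites)) {
    add <- matrix(GT_HOM_REF, nrow(geno), nrow(new_sites),
                  dimnames = list(rownames(geno), NULL))
    for (k in seq_len(nrow(new_sites))) add[carriers[[k]], k] <- GT_HOM_ALT
    sites <- rbind(sites, new_sites)
    geno <- cbind(geno, add)
    o <- order(match(sites$contig, vt$contigs$name), sites$pos)
    sites <- sites[o, , drop = FALSE]
    rownames(sites) <- NULL
    geno <- geno[, o, drop = FALSE]
  }
  variant_table(vt$contigs, sites, geno)
}

random_new_positions <- function(vt, contig, n) {
  used <- vt$sites$pos[vt$sites$contig == contig]
  L <- vt$contigs$length[vt$contigs$name == contig]
  pool <- sample.int(L, min(L, n * 3 + length(used)))
  pool <- setdiff(pool, used)
  if (length(pool) < n) stop("contig too small for extra private sites")
  sort(pool[seq_len(n)])
}

#' Simulate the clonal admixed NoAm lineage
#'
#' One mosaic haplotype is built by choosing, per 50-kbp window, the PA-2
#' or the PB-1 parental haplotype (Bernoulli with the configured PA
#' probability); it is cloned as homozygous diploids, the clones are
#' distributed over four geographic sites, and each site receives a fixed
#' number of site-private derived SNPs at fresh positions, so clones from
#' different sites differ by the sum of their sites' private counts.
#'
#' @param config a \code{ScenarioConfig}.
#' @param panel output of \code{\link{simulate_structured_panel}}.
#' @return list: \code{vt} (panel + clones), \code{meta}, \code{truth}
#'   (window ancestry vector, private-SNP bookkeeping, parent ids).
#' @export
simulate_noam_lineage <- function(config, panel) {
  cfg <- config$noam
  set.seed(substream_seed(config$seed, "noam"))
  vt <- panel$vt
  pa_parent <- first_strain_of(panel$meta, cfg$pa_parent)
  pb_parent <- first_strain_of(panel$meta, cfg$pb_parent)
  grid <- make_windows(vt$contigs, config$W)
  swin <- site_windows(vt, grid)

  anc <- ifelse(rbinom(nrow(grid), 1L, cfg$pa_prob) == 1L, cfg$pa_parent, cfg$pb_parent)
  hap_pa <- parent_haplotype(vt, pa_parent)
  hap_pb <- parent_haplotype(vt, pb_parent)
  mosaic <- ifelse(anc[swin] == cfg$pa_parent, hap_pa, hap_pb)

  ids <- sprintf("NoAm_c%02d", seq_len(cfg$n_clones))
  clone_geno <- matrix(rep(2L * mosaic, each = cfg$n_clones), cfg$n_clones,
                       dimnames = list(ids, NULL))
  geo <- NOAM_SITES[seq_len(cfg$n_geo_sites), , drop = FALSE]
  assign <- sort(rep_len(seq_len(cfg$n_geo_sites), cfg$n_clones))

  per_site <- diff(round(seq(0, cfg$private_snps, length.out = cfg$n_geo_sites + 1)))
  new_sites <- NULL; carriers <- list()
  if (cfg$private_snps > 0) {
    ctg <- vt$contigs$name[1]
    pos <- random_new_positions(vt, ctg, cfg$private_snps)
    grp <- rep(seq_len(cfg$n_geo_sites), per_site)
    new_sites <- data.frame(contig = ctg, pos = pos, ref = "A", alt = "T",
                            stringsAsFactors = FALSE)
    carriers <- lapply(grp, function(g) ids[assign == g])
  }
  out_vt <- augment_panel(vt, clone_geno, new_sites, carriers)
  meta <- rbind(panel$meta, data.frame(
    strain = ids, population = "admixed", subpopulation = "NoAm",
    latitude = geo$latitude[assign], longitude = geo$longitude[assign],
    site = geo$site[assign], host = "unknown", host2 = NA_character_,
    substrate = "unknown", stringsAsFactors = FALSE))
  truth <- list(window_ancestry = anc, clone_ids = ids,
                geo_site = setNames(geo$site[assign], ids),
                private_per_site = setNames(per_site, geo$site),
                private_positions = if (!is.null(new_sites)) new_sites$pos else integer(),
                private_group = if (cfg$private_snps > 0) geo$site[rep(seq_len(cfg$n_geo_sites), per_site)] else character(),
                pa_parent = pa_parent, pb_parent = pb_parent,
                pa_fraction = mean(anc == cfg$pa_parent))
  list(vt = out_vt, meta = validate_meta(meta), truth = truth)
}

#' Simulate the SoAm admixed strain
#'
#' PA-ancestry windows are drawn with the configured probability (default
#' 0.45); each PA window copies a PA-1 or PA-2 parental haplotype with
#' equal probability (the PA parent was itself an equal mosaic of the
#' two), and the remaining windows copy a PB-1 haplotype.
#'
#' @inheritParams simulate_noam_lineage
#' @return list: \code{vt}, \code{meta}, \code{truth} (per-window donor
#'   subpopulation, realized PA fraction).
#' @export
simulate_soam_strain <- function(config, panel) {
  cfg <- config$soam
  set.seed(substream_seed(config$seed, "soam"))
  vt <- panel$vt
  parents <- c(vapply(cfg$pa_parents, function(s) first_strain_of(panel$meta, s), ""),
               setNames(first_strain_of(panel$meta, cfg$pb_parent), cfg$pb_parent))
  grid <- make_windows(vt$contigs, config$W)
  swin <- site_windows(vt, grid)

  is_pa <- rbinom(nrow(grid), 1L, cfg$pa_prob) == 1L
  donor <- ifelse(is_pa, sample(cfg$pa_parents, nrow(grid), replace = TRUE), cfg$pb_parent)
  haps <- vapply(parents, function(s) parent_haplotype(vt, s), integer(ncol(vt$geno)))
  allele <- haps[cbind(seq_len(ncol(vt$geno)), match(donor[swin], names(parents)))]

  geno <- matrix(2L * allele, 1, dimnames = list("SoAm", NULL))
  out_vt <- augment_panel(vt, geno)
  meta <- rbind(panel$meta, data.frame(
    strain = "SoAm", population = "admixed", subpopulation = "SoAm",
    latitude = -41.0, longitude = -71.3, site = "NahuelHuapiEast",
    host = "unknown", host2 = NA_character_, substrate = "unknown",
    stringsAsFactors = FALSE))
  truth <- list(window_donor = donor, window_is_pa = is_pa,
                parents = parents, pa_fraction = mean(is_pa))
  list(vt = out_vt, meta = validate_meta(meta), truth = truth)
}

#' Simulate the introgressed taxonomic type strain
#'
#' PB-1 background with a configured fraction of windows (default 0.04)
#' replaced by a PA-1 parental haplotype.
#'
#' @inheritParams simulate_noam_lineage
#' @return list: \code{vt}, \code{meta}, \code{truth} (PA-1 windows and
#'   realized fraction).
#' @export
simulate_typestrain <- function(config, panel) {
  cfg <- config$typestrain
  set.seed(substream_seed(config$seed, "typestrain"))
  vt <- panel$vt
  pa_parent <- first_strain_of(panel$meta, cfg$pa_parent)
  pb_parent <- first_strain_of(panel$meta, cfg$pb_parent)
  grid <- make_windows(vt$contigs, config$W)
  swin <- site_windows(vt, grid)
  is_pa <- rbinom(nrow(grid), 1L, cfg$pa_fraction) == 1L
  allele <- ifelse(is_pa[swin], parent_haplotype(vt, pa_parent),
                   parent_haplotype(vt, pb_parent))
  geno <- matrix(2L * allele, 1, dimnames = list("TypeStrain", NULL))
  out_vt <- augment_panel(vt, geno)
  meta <- rbind(panel$meta, data.frame(
    strain = "TypeStrain", population = "PB", subpopulation = "PB-1",
    latitude = -41.13, longitude = -71.31, site = "TypeLocality",
    host = "unknown", host2 = NA_character_, substrate = "unknown",
    stringsAsFactors = FALSE))
  truth <- list(window_is_pa = is_pa, pa_fraction = mean(is_pa),
                pa_parent = pa_parent, pb_parent = pb_parent)
  list(vt = out_vt, meta = validate_meta(meta), truth = truth)
}

#' Simulate per-window read depth against two reference genomes
#'
#' Where the strain's genome derives from a reference's species, window
#' depth is Poisson with the configured mean; elsewhere only cross-mapping
#' leakage remains (Poisson with mean leakage x depth). Donor-tract
#' windows have donor-reference presence and recipient-reference absence.
#'
#' @param config a \code{ScenarioConfig}; the \code{introgression} block
#'   holds contig, tract interval (set \code{tract = NULL} for none),
#'   depth mean, leakage rate and number of strains.
#' @return list: \code{depth} (long data.frame: strain, reference, contig,
#'   window_start, window_end, mean_depth), \code{truth} (tract interval
#'   and window indices).
#' @export
simulate_dual_depth <- function(config) {
  cfg <- config$introgression
  if (cfg$leakage >= 1) stop("leakage rate must be < 1")
  set.seed(substream_seed(config$seed, "depth"))
  contigs <- data.frame(name = cfg$contig, length = cfg$contig_length,
                        stringsAsFactors = FALSE)
  grid <- make_windows(contigs, config$W)
  in_tract <- if (is.null(cfg$tract)) rep(FALSE, nrow(grid)) else
    grid$start >= cfg$tract[1] & grid$end <= cfg$tract[2]
  ids <- sprintf("intro_s%d", seq_len(cfg$n_strains))
  rows <- lapply(ids, function(s) {
    recip <- rpois(nrow(grid), cfg$depth_mean * ifelse(in_tract, cfg$leakage, 1))
    donor <- rpois(nrow(grid), cfg$depth_mean * ifelse(in_tract, 1, cfg$leakage))
    rbind(
      data.frame(strain = s, reference = cfg$recipient_ref, contig = grid$contig,
                 window_start = grid$start, window_end = grid$end,
                 mean_depth = recip, stringsAsFactors = FALSE),
      data.frame(strain = s, reference = cfg$donor_ref, contig = grid$contig,
                 window_start = grid$start, window_end = grid$end,
                 mean_depth = donor, stringsAsFactors = FALSE))
  })
  list(depth = do.call(rbind, rows),
       truth = list(tract = cfg$tract, tract_windows = which(in_tract),
                    strains = ids))
}

#' Simulate a clonal lineage with isolation by distance
#'
#' Geographic sites are placed on a north-south transect with known
#' great-circle spacing; all strains are clones of one founder haplotype,
#' plus (i) distance-ordered derived alleles — a site at transect distance
#' d carries derived alleles at the first round(slope x d) of a shared
#' ladder of loci, so pairwise genetic distance grows linearly with
#' geographic separation — and (ii) per-strain private noise loci (Poisson
#' count) so that distances are non-degenerate under the null slope of 0.
#' This emulates a recently dispersed clonal lineage accumulating
#' location-specific variants.
#'
#' @param config a \code{ScenarioConfig}; the \code{geography} block holds
#'   the transect length, number of sites (>= 3), slope (new derived loci
#'   per km) and noise intensity.
#' @return list: \code{vt}, \code{meta}, \code{truth} (site distances,
#'   per-strain locus counts, geographic and expected genetic distance
#'   matrices, generating slope).
#' @export
simulate_geography <- function(config) {
  cfg <- config$geography
  if (cfg$n_geo_sites < 3) stop("need at least 3 geographic sites")
  set.seed(substream_seed(config$seed, "geography"))
  d_site <- seq(0, cfg$transect_km, length.out = cfg$n_geo_sites)
  lat <- cfg$origin[1] - d_site / 111.19493  # ~km per degree latitude
  lon <- rep(cfg$origin[2], cfg$n_geo_sites)
  site_names <- sprintf("T%d", seq_len(cfg$n_geo_sites))

  ids <- sprintf("geo_s%02d", seq_len(cfg$n_strains))
  assign <- sort(rep_len(seq_len(cfg$n_geo_sites), cfg$n_strains))
  k_site <- round(cfg$slope_per_km * d_site)
  M <- max(k_site)
  nu <- rpois(cfg$n_strains, cfg$noise_loci)
  n_total <- cfg$n_bg_sites + M + sum(nu)

  contigs <- data.frame(name = "geo_ctg", length = cfg$contig_length,
                        stringsAsFactors = FALSE)
  pos <- sort(sample.int(cfg$contig_length, n_total))
  founder <- rbinom(cfg$n_bg_sites, 1L, 0.5)
  # column blocks: background | distance ladder | per-strain noise
  geno <- matrix(GT_HOM_REF, cfg$n_strains, n_total, dimnames = list(ids, NULL))
  idx_bg <- seq_len(cfg$n_bg_sites)
  idx_ladder <- cfg$n_bg_sites + seq_len(M)
  idx_noise <- cfg$n_bg_sites + M + seq_len(sum(nu))
  noise_owner <- rep(seq_len(cfg$n_strains), nu)
  order_cols <- sample.int(n_total)  # scatter blocks along the genome
  for (i in seq_len(cfg$n_strains)) {
    hap <- integer(n_total)
    hap[idx_bg] <- founder
    k <- k_site[assign[i]]
    if (k > 0) hap[idx_ladder[seq_len(k)]] <- 1L
    hap[idx_noise[noise_owner == i]] <- 1L
    geno[i, ] <- 2L * hap[order_cols]
  }
  sites <- data.frame(contig = "geo_ctg", pos = pos, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  vt <- variant_table(contigs, sites, geno)
  meta <- validate_meta(data.frame(
    strain = ids, population = "GEO", subpopulation = "GEO",
    latitude = lat[assign], longitude = lon[assign],
    site = site_names[assign], host = "unknown", host2 = NA_character_,
    substrate = "unknown", stringsAsFactors = FALSE))

  geo_km <- outer(seq_len(cfg$n_strains), seq_len(cfg$n_strains),
                  Vectorize(function(i, j)
                    haversine(lat[assign[i]], lon[assign[i]],
                              lat[assign[j]], lon[assign[j]])))
  k_strain <- k_site[assign]
  gen_diff <- outer(k_strain, k_strain, function(a, b) abs(a - b)) +
    outer(nu, nu, `+`) * (1 - diag(cfg$n_strains))
  dimnames(geo_km) <- dimnames(gen_diff) <- list(ids, ids)
  truth <- list(slope_per_km = cfg$slope_per_km, site_km = d_site,
                strain_site = setNames(site_names[assign], ids),
                k_strain = setNames(k_strain, ids), noise = setNames(nu, ids),
                geo_km = geo_km, genetic_diff = gen_diff)
  list(vt = vt, meta = meta, truth = truth)
}

#' Write a VariantTable as a minimal VCF 4.2 file
#'
#' GT-only records with contig header lines; phased HET calls use the
#' \code{|} separator with the recorded first-haplotype allele. Intended
#' for fixture generation; re-reading through \code{\link{read_vcf}}
#' reproduces the matrix exactly.
#'
#' @param vt a \code{VariantTable}.
#' @param path output path (plain text).
#' @return \code{path}, invisibly.
#' @export
write_variant_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", vt$contigs$name,
                       as.integer(vt$contigs$length)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vt$strain_ids), collapse = "\t")), con)
  gt_str <- matrix("./.", nrow(vt$geno), ncol(vt$geno))
  gt_str[vt$geno == GT_HOM_REF] <- "0/0"
  gt_str[vt$geno == GT_HOM_ALT] <- "1/1"
  gt_str[vt$geno == GT_HET] <- "0/1"
  if (!is.null(vt$phase)) {
    ph <- which(vt$geno == GT_HET & !is.na(vt$phase))
    gt_str[ph] <- ifelse(vt$phase[ph] == 0L, "0|1", "1|0")
  }
  body <- paste(vt$sites$contig, vt$sites$pos, ".", vt$sites$ref, vt$sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Materialize a named scenario as an on-disk fixture
#'
#' Writes VCF, metadata TSV, truth JSON (and a depth TSV for the
#' introgression scenario) for one of the named scenarios.
#'
#' @param scenario one of baseline, noam, soam, typestrain, introgression,
#'   ibd, null_ibd.
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @param config optional \code{ScenarioConfig} overriding the defaults
#'   (its seed is replaced by \code{seed}).
#' @return named list of file paths, plus the in-memory objects
#'   (invisibly attached as attributes "vt", "meta", "truth", "depth").
#' @export
make_fixture <- function(scenario, seed = 1L, dir = tempfile("fixture"),
                         config = NULL) {
  scenarios <- c("baseline", "noam", "soam", "typestrain", "introgression",
                 "ibd", "null_ibd")
  if (!scenario %in% scenarios)
    stop("unknown scenario '", scenario, "'; choose one of: ",
         paste(scenarios, collapse = ", "))
  cfg <- if (is.null(config)) scenario_config(seed) else { config$seed <- as.integer(seed); config }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  depth <- NULL
  if (scenario == "introgression") {
    sim <- simulate_dual_depth(cfg)
    depth <- sim$depth; truth <- sim$truth; vt <- NULL; meta <- NULL
  } else if (scenario %in% c("ibd", "null_ibd")) {
    if (scenario == "null_ibd") cfg$geography$slope_per_km <- 0
    sim <- simulate_geography(cfg)
    vt <- sim$vt; meta <- sim$meta; truth <- sim$truth
  } else {
    panel <- simulate_structured_panel(cfg)
    sim <- switch(scenario,
                  baseline = panel,
                  noam = simulate_noam_lineage(cfg, panel),
                  soam = simulate_soam_strain(cfg, panel),
                  typestrain = simulate_typestrain(cfg, panel))
    vt <- sim$vt; meta <- sim$meta; truth <- sim$truth
  }
  paths <- list()
  if (!is.null(vt)) {
    paths$vcf <- file.path(dir, paste0(scenario, ".vcf"))
    write_variant_vcf(vt, paths$vcf)
    paths$meta <- file.path(dir, paste0(scenario, "_meta.tsv"))
    write_tsv(meta, paths$meta)
  }
  if (!is.null(depth)) {
    paths$depth <- file.path(dir, paste0(scenario, "_depth.tsv"))
    write_tsv(depth, paths$depth)
  }
  paths$truth <- file.path(dir, paste0(scenario, "_truth.json"))
  tr <- truth
  tr$geo_km <- NULL; tr$genetic_diff <- NULL  # matrices stay in-memory only
  jsonlite::write_json(tr, paths$truth, auto_unbox = TRUE, digits = NA)
  out <- paths
  attr(out, "vt") <- vt; attr(out, "meta") <- meta
  attr(out, "truth") <- truth; attr(out, "depth") <- depth
  out
}
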