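EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between two coordinates
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius), via the geosphere package.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @return distance in km.
#' @export
haversine <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(c(lon1, lat1), c(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Pairwise geographic and genetic distance matrices for a strain set
#'
#' @param meta \code{StrainMeta} rows for the strains (with coordinates).
#' @param hap haplotype matrix for the same strains (rownames = ids).
#' @param callable_bp genome callable bp for the per-site divergence.
#' @return list of class \code{DistanceMatrices}: \code{geo_km},
#'   \code{genetic} (aligned symmetric matrices, zero diagonal),
#'   \code{strains}.
#' @export
distance_matrices <- function(meta, hap, callable_bp) {
  ids <- intersect(rownames(hap), meta$strain)
  meta <- meta[match(ids, meta$strain), , drop = FALSE]
  drop <- is.na(meta$latitude) | is.na(meta$longitude)
  if (any(drop)) {
    warning("excluding ", sum(drop), " strain(s) without coordinates")
    ids <- ids[!drop]; meta <- meta[!drop, , drop = FALSE]
  }
  n <- length(ids)
  geo <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    geo[i, j] <- geo[j, i] <- haversine(meta$latitude[i], meta$longitude[i],
                                        meta$latitude[j], meta$longitude[j])
  }
  gen <- divergence_matrix(hap[ids, , drop = FALSE], callable_bp)
  structure(list(geo_km = geo, genetic = gen, strains = ids),
            class = "DistanceMatrices")
}

#' Geographic range and area of a subpopulation
#'
#' Range is the maximum pairwise great-circle distance between collection
#' points; area is the spherical area of the convex hull of the points
#' (geosphere), zero for fewer than 3 non-collinear points.
#'
#' @param lat,lon coordinate vectors (decimal degrees).
#' @return list: \code{n}, \code{range_km}, \code{area_km2}.
#' @export
range_metrics <- function(lat, lon) {
  stopifnot(length(lat) == length(lon), length(lat) >= 1)
  n <- length(lat)
  rng <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      rng <- max(rng, haversine(lat[i], lon[i], lat[j], lon[j]))
  }
  area <- 0
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) >= 3) {
    hull <- grDevices::chull(pts)
    if (length(hull) >= 3) {
      poly <- pts[hull, , drop = FALSE]
      # sphere radius passed deliberately; geosphere warns that its
      # ellipsoidal algorithm is preferred
      area <- suppressWarnings(
        abs(geosphere::areaPolygon(poly, r = EARTH_RADIUS_KM * 1000)) / 1e6)
    }
  }
  list(n = n, range_km = rng, area_km2 = area)
}

#' Mantel test for isolation by distance
#'
#' Genetic distances are transformed log10(d + eps) with eps one tenth of
#' the smallest positive observed distance (clonal pairs can be at d = 0),
#' then the Pearson correlation with geographic distance is computed over
#' the lower triangle and assessed by whole-row/column permutations with
#' the one-sided (positive-IBD) alternative:
#' p = (1 + #permuted r >= observed r) / (permutations + 1).
#'
#' @param dm a \code{DistanceMatrices} object.
#' @param permutations number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @param transform "log10" (default) or "identity" for the genetic axis.
#' @return list: \code{r}, \code{r_squared}, \code{p}, \code{n_strains},
#'   \code{permutations}; r and p are NA when a matrix is constant.
#' @export
mantel_ibd <- function(dm, permutations = 10000L, seed = 7L,
                       transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  n <- length(dm$strains)
  if (n < 4) stop("Mantel test needs at least 4 strains")
  g <- dm$genetic
  if (transform == "log10") {
    pos <- g[lower.tri(g)][g[lower.tri(g)] > 0]
    eps <- if (length(pos)) min(pos) * 0.1 else 1
    g <- log10(g + eps)
  }
  lt <- lower.tri(g)
  x <- dm$geo_km[lt]; y <- g[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                n_strains = n, permutations = permutations))
  r_obs <- cor(x, y)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(permutations)) {
    pm <- sample.int(n)
    r_b <- cor(dm$geo_km[pm, pm][lt], y)
    if (r_b >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, r_squared = r_obs^2, p = (1 + hits) / (permutations + 1),
       n_strains = n, permutations = permutations)
}

#' Split strains at a latitude and summarize diversity on each side
#'
#' The default threshold of -43 degrees is the Patagonian glacial-refugium
#' boundary: "north" is latitude >= threshold, "south" below it. Pooled
#' diversity is computed per side, and a per-collection-site table gives
#' each site's diversity and subpopulation composition.
#'
#' @param meta \code{StrainMeta}.
#' @param vt \code{VariantTable} (HET-free) for diversity; NULL to skip pi.
#' @param callable_bp genome callable bp.
#' @param threshold_lat split latitude (default -43).
#' @return list: \code{sides} data.frame (side, n, pi), \code{composition}
#'   (side x subpopulation counts), \code{site_table} (site, n, pi, and
#'   subpopulation fractions as a nested data.frame attribute).
#' @export
latitude_split <- function(meta, vt = NULL, callable_bp = NULL,
                           threshold_lat = -43) {
  has_coord <- !is.na(meta$latitude)
  if (any(!has_coord)) {
    warning("excluding ", sum(!has_coord), " strain(s) without coordinates")
    meta <- meta[has_coord, , drop = FALSE]
  }
  side <- ifelse(meta$latitude >= threshold_lat, "north", "south")
  pool_pi <- function(ids) {
    if (is.null(vt) || length(ids) < 2) return(NA_real_)
    nucleotide_diversity(haploidize(vt, intersect(ids, vt$strain_ids)), callable_bp)
  }
  sides <- data.frame(side = c("north", "south"),
                      n = c(sum(side == "north"), sum(side == "south")),
                      pi = c(pool_pi(meta$strain[side == "north"]),
                             pool_pi(meta$strain[side == "south"])),
                      stringsAsFactors = FALSE)
  comp <- table(side = factor(side, c("north", "south")), subpop = meta$subpopulation)
  st <- do.call(rbind, lapply(split(meta, meta$site), function(m) {
    fr <- table(m$subpopulation) / nrow(m)
    data.frame(site = m$site[1], n = nrow(m), latitude = m$latitude[1],
               pi = pool_pi(m$strain),
               top_subpop = names(fr)[which.max(fr)],
               top_fraction = max(fr), stringsAsFactors = FALSE)
  }))
  rownames(st) <- NULL
  list(sides = sides, composition = comp, site_table = st,
       threshold_lat = threshold_lat)
}
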