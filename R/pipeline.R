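#' Assemble a pipeline run configuration
#'
#' Collects input paths, stage toggles and every analysis threshold with
#' its default: 50-kbp windows; heterozygosity classes at 5\%/10\% with
#' the 20,000-call high-heterozygosity flag; painting pseudocount of one
#' SNP-equivalent and 5 informative sites; pure/introgressed/admixed
#' bounds 0.02/0.12; F_ST network threshold 0.8; tract thresholds
#' 0.5/0.25; Mantel with 10,000 permutations; latitude split at -43;
#' contingency minimums 3 (subpopulation) and 5 (host).
#'
#' @param vcf,meta paths to the VCF and metadata TSV (required for
#'   genotype stages).
#' @param masks named character vector of BED paths, names = mask labels.
#' @param depth optional dual-reference depth TSV.
#' @param out_dir optional output directory for TSV/JSON reports.
#' @param seed seed recorded in the report and used for the Mantel stage.
#' @param stages character vector of stages to run, in order, from:
#'   qc, stats, paint, introgress, geo, hosts.
#' @param paint_queries strain ids to paint (panel A/B from the metadata's
#'   population column).
#' @param ... threshold overrides (window_size, het_bounds, highly_het_n,
#'   min_callable_fraction, min_sites, classify_bounds, fst_threshold,
#'   theta_hi, theta_lo, mantel_permutations, lat_threshold, min_subpop,
#'   min_host, recipient_ref, donor_ref).
#' @return list of class \code{RunConfig}.
#' @export
run_config <- function(vcf = NULL, meta = NULL, masks = character(),
                       depth = NULL, out_dir = NULL, seed = 7L,
                       stages = c("qc", "stats", "paint", "introgress",
                                  "geo", "hosts"),
                       paint_queries = character(), ...) {
  cfg <- list(vcf = vcf, meta = meta, masks = masks, depth = depth,
              out_dir = out_dir, seed = as.integer(seed), stages = stages,
              paint_queries = paint_queries,
              window_size = 50000L, het_bounds = c(0.05, 0.10),
              highly_het_n = 20000L, min_callable_fraction = 0.5,
              min_sites = 5L, classify_bounds = c(0.02, 0.12),
              fst_threshold = 0.8, theta_hi = 0.5, theta_lo = 0.25,
              mantel_permutations = 10000L, lat_threshold = -43,
              min_subpop = 3L, min_host = 5L,
              recipient_ref = "Seub", donor_ref = "Suva")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$window_size > 0, cfg$theta_lo < cfg$theta_hi,
            all(cfg$classify_bounds >= 0), all(cfg$classify_bounds <= 1))
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the analysis pipeline end to end
#'
#' Executes ingest, then the configured stages in order (qc, stats, paint,
#' introgress, geo, hosts), skipping any that are toggled off or lack
#' inputs, and returns a report list (also written as JSON plus per-stage
#' TSVs when \code{out_dir} is set). Reruns with the same inputs and seed
#' are deterministic. A stage failure halts the run naming the stage.
#'
#' @param cfg a \code{RunConfig}.
#' @return report list with one element per executed stage plus an
#'   \code{inputs} section (paths, md5 checksums, seed, package version).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  report <- list(inputs = list(
    vcf = cfg$vcf, meta = cfg$meta, masks = as.list(cfg$masks),
    depth = cfg$depth, seed = cfg$seed,
    checksums = as.list(tools::md5sum(unlist(Filter(Negate(is.null),
      c(cfg$vcf, cfg$meta, cfg$masks, cfg$depth))))),
    package_version = as.character(utils::packageVersion("eubpop"))))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  vt <- meta <- masks <- NULL
  if (!is.null(cfg$vcf)) {
    run_stage("ingest", {
      vt <- read_vcf(cfg$vcf)
      meta <- if (!is.null(cfg$meta)) read_meta(cfg$meta) else NULL
      masks <- if (length(cfg$masks))
        do.call(combine_masks, Map(read_mask_bed, cfg$masks, names(cfg$masks)))
      else mask_set()
    })
  }
  grid <- if (!is.null(vt)) make_windows(vt$contigs, cfg$window_size)
  genome_bp <- if (!is.null(vt)) sum(vt$contigs$length)

  if ("qc" %in% cfg$stages && !is.null(vt)) {
    run_stage("qc", {
      hs <- het_summary(vt, highly_het_n = cfg$highly_het_n)
      report$qc <- list(het = hs)
      vt <- apply_masks(vt, masks, drop_het = TRUE)
    })
  }

  panels <- NULL
  if (!is.null(meta) && !is.null(vt)) {
    sp <- split(meta$strain, meta$subpopulation)
    panels <- Filter(function(s) length(s) >= 2,
                     lapply(sp, intersect, y = vt$strain_ids))
  }

  if ("stats" %in% cfg$stages && !is.null(panels) && length(panels)) {
    run_stage("stats", {
      ws <- window_stats(vt, grid, panels, masks,
                         min_callable_fraction = cfg$min_callable_fraction)
      pi_g <- vapply(panels, function(p)
        nucleotide_diversity(haploidize(vt, p), genome_bp), numeric(1))
      fm <- matrix(NA_real_, length(panels), length(panels),
                   dimnames = list(names(panels), names(panels)))
      diag(fm) <- 0
      for (k in seq_len(nrow(ws$fst_genome))) {
        fm[ws$fst_genome$panel1[k], ws$fst_genome$panel2[k]] <-
          fm[ws$fst_genome$panel2[k], ws$fst_genome$panel1[k]] <- ws$fst_genome$fst[k]
      }
      report$stats <- list(windows = ws$stats, fst_windows = ws$fst,
                           fst_genome = ws$fst_genome, pi_genome = pi_g,
                           network = fst_network(fm, cfg$fst_threshold, pi_g))
    })
  }

  if ("paint" %in% cfg$stages && length(cfg$paint_queries) && !is.null(meta)) {
    run_stage("paint", {
      pa <- meta$strain[meta$population == "PA"]
      pb <- meta$strain[meta$population == "PB"]
      pa <- intersect(pa, vt$strain_ids); pb <- intersect(pb, vt$strain_ids)
      profs <- lapply(setNames(cfg$paint_queries, cfg$paint_queries), function(q)
        paint(vt, q, setdiff(pa, q), setdiff(pb, q), grid, masks,
              cfg$min_callable_fraction, cfg$min_sites))
      labels <- lapply(profs, classify_strain, bounds = cfg$classify_bounds)
      report$paint <- list(
        profiles = lapply(profs, `[[`, "windows"),
        summary = data.frame(
          strain = names(profs),
          pa_fraction = vapply(profs, `[[`, 0, "pa_fraction"),
          pb_fraction = vapply(profs, `[[`, 0, "pb_fraction"),
          label = vapply(labels, function(l) ifelse(is.na(l$label), "NA", l$label), ""),
          stringsAsFactors = FALSE))
    })
  }

  if ("introgress" %in% cfg$stages && !is.null(cfg$depth)) {
    run_stage("introgress", {
      dp <- coverage_profile(read_depth_table(cfg$depth))
      tracts <- lapply(split(dp, dp$strain), detect_tracts,
                       recipient_ref = cfg$recipient_ref,
                       donor_ref = cfg$donor_ref,
                       theta_hi = cfg$theta_hi, theta_lo = cfg$theta_lo)
      report$introgress <- list(tracts = tracts,
                                shared = shared_breakpoints(tracts))
    })
  }

  if ("geo" %in% cfg$stages && !is.null(meta) && !is.null(vt)) {
    run_stage("geo", {
      hap <- haploidize(vt)
      mant <- list()
      for (pn in names(panels)) {
        ids <- panels[[pn]]
        if (length(ids) < 4) next
        dm <- distance_matrices(meta[meta$strain %in% ids, ], hap[ids, , drop = FALSE],
                                genome_bp)
        if (length(unique(dm$geo_km[lower.tri(dm$geo_km)])) < 2) next
        mant[[pn]] <- mantel_ibd(dm, cfg$mantel_permutations, seed = cfg$seed)
      }
      report$geo <- list(mantel = mant,
                         latitude = latitude_split(meta, vt, genome_bp,
                                                   cfg$lat_threshold))
    })
  }

  if ("hosts" %in% cfg$stages && !is.null(meta) &&
      any(!is.na(meta$host) & meta$host != "unknown")) {
    run_stage("hosts", {
      tab <- build_contingency(meta, "host", cfg$min_subpop, cfg$min_host)
      report$hosts <- list(table = tab, screen = association_screen(tab))
    })
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$qc)) write_tsv(report$qc$het, file.path(cfg$out_dir, "het_report.tsv"))
    if (!is.null(report$stats)) {
      write_tsv(report$stats$windows, file.path(cfg$out_dir, "window_stats.tsv"))
      write_tsv(report$stats$fst_genome, file.path(cfg$out_dir, "fst_genome.tsv"))
    }
    if (!is.null(report$paint))
      write_tsv(report$paint$summary, file.path(cfg$out_dir, "paint_summary.tsv"))
    jsonlite::write_json(report_for_json(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# Trim the report to JSON-friendly pieces (drop big per-window frames).
report_for_json <- function(report) {
  out <- report
  if (!is.null(out$stats)) out$stats$windows <- NULL
  if (!is.null(out$stats)) out$stats$fst_windows <- NULL
  if (!is.null(out$paint)) out$paint$profiles <- NULL
  if (!is.null(out$geo)) out$geo$latitude$composition <-
      as.data.frame(out$geo$latitude$composition)
  if (!is.null(out$hosts)) out$hosts$table <- as.data.frame(out$hosts$table)
  out
}
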