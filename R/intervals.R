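MASK_LABELS <- c("repeat", "low_coverage", "high_coverage", "heterozygous")

#' Construct a set of masked genomic intervals
#'
#' Intervals are 0-based half-open (BED convention) and are merged within
#' each (contig, label) so the stored set is sorted and disjoint per label.
#'
#' @param df data.frame with columns \code{contig}, \code{start}, \code{end},
#'   \code{label}; label one of repeat, low_coverage, high_coverage,
#'   heterozygous.
#' @param contigs optional contig table (\code{name}, \code{length}) used to
#'   check that intervals do not extend past contig ends.
#' @return data.frame of class \code{MaskSet}.
#' @export
mask_set <- function(df = data.frame(contig = character(), start = integer(),
                                     end = integer(), label = character()),
                     contigs = NULL) {
  stopifnot(all(c("contig", "start", "end", "label") %in% names(df)))
  if (nrow(df)) {
    if (any(df$start >= df$end)) stop("mask interval with start >= end")
    if (any(df$start < 0)) stop("negative mask interval start")
    bad <- setdiff(unique(df$label), MASK_LABELS)
    if (length(bad)) stop("unknown mask label(s): ", paste(bad, collapse = ", "))
    if (!is.null(contigs)) {
      len <- setNames(contigs$length, contigs$name)
      over <- !is.na(len[df$contig]) & df$end > len[df$contig]
      if (any(over)) stop("mask interval extends past contig end")
    }
    pieces <- lapply(split(df, list(df$contig, df$label), drop = TRUE), function(p) {
      ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
      data.frame(contig = p$contig[1], start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir), label = p$label[1],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, pieces)
    df <- df[order(df$contig, df$start, df$label), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("MaskSet", "data.frame")
  df
}

#' Read a BED mask file
#'
#' 3+ column headerless BED, 0-based half-open; overlapping intervals are
#' merged and tagged with one mask label.
#'
#' @param path BED path.
#' @param label mask label to attach (repeat, low_coverage, high_coverage,
#'   heterozygous).
#' @param contigs optional contig table for bounds checking.
#' @return a \code{MaskSet}.
#' @export
read_mask_bed <- function(path, label, contigs = NULL) {
  n <- tryCatch(nrow(read.delim(path, header = FALSE, nrows = 1)), error = function(e) 0L)
  if (is.null(n) || n == 0L || file.size(path) == 0)
    return(mask_set())
  b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  mask_set(data.frame(contig = as.character(b[[1]]), start = as.integer(b[[2]]),
                      end = as.integer(b[[3]]), label = label,
                      stringsAsFactors = FALSE),
           contigs = contigs)
}

#' Combine mask sets
#' @param ... MaskSet objects.
#' @return merged \code{MaskSet}.
#' @export
combine_masks <- function(...) {
  parts <- Filter(function(x) nrow(x) > 0, list(...))
  if (!length(parts)) return(mask_set())
  mask_set(do.call(rbind, lapply(parts, as.data.frame)))
}

#' Tile contigs with non-overlapping windows
#'
#' Windows are 0-based half-open, abut exactly, and only the terminal window
#' of a contig may be shorter than \code{W}. The default window length of
#' 50 kbp is the resolution at which all windowed statistics and the
#' ancestry painter operate.
#'
#' @param contigs contig table (\code{name}, \code{length}).
#' @param W window length in bp (default 50000).
#' @return data.frame of class \code{WindowGrid} with columns \code{contig},
#'   \code{start}, \code{end} and a \code{window} index.
#' @export
make_windows <- function(contigs, W = 50000L) {
  stopifnot(W > 0)
  out <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(i) {
    L <- contigs$length[i]
    starts <- seq(0L, L - 1L, by = W)
    data.frame(contig = contigs$name[i], start = starts,
               end = pmin(starts + W, L), stringsAsFactors = FALSE)
  }))
  out$window <- seq_len(nrow(out))
  attr(out, "W") <- W
  class(out) <- c("WindowGrid", "data.frame")
  out
}

#' Callable basepairs of a window after masking
#'
#' Window length minus the union (over all mask labels) of masked bases
#' overlapping the window.
#'
#' @param window one row of a \code{WindowGrid} (or a list with
#'   \code{contig}, \code{start}, \code{end}).
#' @param masks a \code{MaskSet}.
#' @return callable bp (integer).
#' @export
callable_sites <- function(window, masks) {
  len <- window$end - window$start
  if (!nrow(masks)) return(as.integer(len))
  m <- masks[masks$contig == window$contig, , drop = FALSE]
  if (!nrow(m)) return(as.integer(len))
  mask_u <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
  win <- IRanges::IRanges(window$start + 1L, window$end)
  ov <- IRanges::intersect(mask_u, win)
  as.integer(len - sum(IRanges::width(ov)))
}

#' Callable bp for every window of a grid
#' @param grid a \code{WindowGrid}.
#' @param masks a \code{MaskSet}.
#' @return integer vector, one entry per window.
#' @export
callable_by_window <- function(grid, masks) {
  vapply(seq_len(nrow(grid)), function(i)
    callable_sites(grid[i, , drop = FALSE], masks), integer(1))
}

# Map each site of a VariantTable onto a window index of the grid (NA if the
# site's contig has no windows). Sites and windows both live on contig
# coordinates; VCF positions are 1-based so site pos-1 is the 0-based offset.
site_windows <- function(vt, grid) {
  idx <- rep(NA_integer_, nrow(vt$sites))
  for (ctg in unique(vt$sites$contig)) {
    s <- which(vt$sites$contig == ctg)
    g <- grid[grid$contig == ctg, , drop = FALSE]
    if (!nrow(g)) next
    k <- findInterval(vt$sites$pos[s] - 1L, g$start)
    ok <- k >= 1 & (vt$sites$pos[s] - 1L) < g$end[pmax(k, 1L)]
    idx[s[ok]] <- g$window[k[ok]]
  }
  idx
}

# TRUE for sites falling inside any mask interval (union over labels).
sites_masked <- function(vt, masks) {
  out <- logical(nrow(vt$sites))
  if (!nrow(masks)) return(out)
  for (ctg in unique(vt$sites$contig)) {
    s <- which(vt$sites$contig == ctg)
    m <- masks[masks$contig == ctg, , drop = FALSE]
    if (!nrow(m)) next
    ir <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
    hit <- IRanges::countOverlaps(IRanges::IRanges(vt$sites$pos[s], width = 1L), ir) > 0
    out[s[hit]] <- TRUE
  }
  out
}
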