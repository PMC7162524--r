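#' Build a subpopulation-by-host (or substrate) contingency table
#'
#' Strains with unknown values on the chosen axis are excluded; then
#' subpopulation rows with fewer than \code{min_subpop} isolates and (for
#' host axes) host columns with fewer than \code{min_host} isolates are
#' dropped. For the mushroom axis, strains isolated from a fungus growing
#' on a tree carry two hosts (tree in \code{host}, fungus in
#' \code{host2}); the fungal host is used there, so such strains
#' contribute to both the tree-level and mushroom-level analyses.
#'
#' @param meta \code{StrainMeta} with columns subpopulation, host,
#'   optionally host2 and substrate.
#' @param axis "host" (tree level), "mushroom" (fungal level) or
#'   "substrate".
#' @param min_subpop minimum isolates per subpopulation row (default 3).
#' @param min_host minimum isolates per host column (default 5; host axes
#'   only).
#' @return a counts matrix (class \code{ContingencyTable}) with
#'   subpopulations in rows.
#' @export
build_contingency <- function(meta, axis = c("host", "mushroom", "substrate"),
                              min_subpop = 3L, min_host = 5L) {
  axis <- match.arg(axis)
  val <- switch(axis,
    host = meta$host,
    mushroom = if ("host2" %in% names(meta)) meta$host2 else rep(NA_character_, nrow(meta)),
    substrate = meta$substrate)
  known <- !is.na(val) & val != "unknown" & val != "" &
    !is.na(meta$subpopulation) & meta$subpopulation != "unknown"
  m <- meta[known, , drop = FALSE]; val <- val[known]
  if (!nrow(m)) stop("no strains with known ", axis, " information")
  tab <- table(subpop = m$subpopulation, category = val)
  tab <- tab[rowSums(tab) >= min_subpop, , drop = FALSE]
  if (axis != "substrate")
    tab <- tab[, colSums(tab) >= min_host, drop = FALSE]
  if (!nrow(tab) || !ncol(tab))
    stop("contingency table empty after minimum-count filtering")
  class(tab) <- c("ContingencyTable", class(tab))
  tab
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's (computed by \code{stats::fisher.test}; verified in
#' the test suite against a full enumeration for every table with
#' n <= 60).
#'
#' @param a,b,c,d cell counts (focal-subpop/focal-host layout
#'   \code{rbind(c(a, b), c(c, d))}).
#' @return two-sided p-value; 1 for an all-zero table.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) return(1)
  stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
}

#' One-vs-rest association screen over a contingency table
#'
#' Each (subpopulation, category) cell is collapsed to a 2x2 (focal
#' subpopulation vs rest, focal category vs rest) and tested with the
#' two-sided Fisher's exact test; Bonferroni adjustment multiplies by the
#' number of cells tested in this table (the per-axis family). The
#' descriptive percentage is the cell count as a share of the focal
#' subpopulation's isolates (\code{percent_of_subpop}); the alternative
#' reading, share of the category's isolates, is also reported
#' (\code{percent_of_category}).
#'
#' @param tab a \code{ContingencyTable}.
#' @return data.frame: subpop, category, count, row_total, col_total,
#'   percent_of_subpop, percent_of_category, p_raw, p_bonferroni, n_tests.
#' @export
association_screen <- function(tab) {
  rt <- rowSums(tab); ct <- colSums(tab); N <- sum(tab)
  cells <- expand.grid(subpop = rownames(tab), category = colnames(tab),
                       stringsAsFactors = FALSE)
  n_tests <- nrow(cells)
  res <- lapply(seq_len(n_tests), function(k) {
    i <- cells$subpop[k]; j <- cells$category[k]
    a <- tab[i, j]; b <- rt[i] - a; c <- ct[j] - a; d <- N - a - b - c
    p <- fisher_exact_2x2(a, b, c, d)
    data.frame(subpop = i, category = j, count = as.integer(a),
               row_total = as.integer(rt[i]), col_total = as.integer(ct[j]),
               percent_of_subpop = 100 * a / rt[i],
               percent_of_category = 100 * a / ct[j],
               p_raw = p, p_bonferroni = min(1, p * n_tests),
               n_tests = n_tests, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p_raw), , drop = FALSE]
}
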