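# Degree analysis: per-node in-/out-degree tables, the distributions with
# the field's node-exclusion conventions, and threshold-based TF ranking.
#
# Degrees count distinct interaction partners (the networks are
# deduplicated at the pair level). Auto-regulation contributes one unit to
# both degrees of the node.

#' Per-node in- and out-degree table
#'
#' @param net a `regnet`.
#' @return data.frame of class `degree_table` with columns `node`,
#'   `in_degree` (number of distinct regulating TFs) and `out_degree`
#'   (number of distinct regulated genes), one row per node, sorted by node.
#' @export
degree_table <- function(net) {
  nodes <- network_nodes(net)
  outd <- table(factor(net$interactions$tf, levels = nodes))
  ind <- table(factor(net$interactions$target, levels = nodes))
  out <- data.frame(node = nodes,
                    in_degree = as.integer(ind),
                    out_degree = as.integer(outd),
                    stringsAsFactors = FALSE)
  class(out) <- c("degree_table", "data.frame")
  out
}

#' In-degree distribution
#'
#' Counts of genes per in-degree value. With `exclude_unregulated = TRUE`
#' (the convention of the in-degree literature) nodes with in-degree 0 --
#' pure regulators -- are dropped and their number recorded.
#'
#' @param table a [degree_table()].
#' @param exclude_unregulated drop in-degree-0 nodes?
#' @return a `degree_distribution`: data.frame (`degree`, `count`) with
#'   attributes `excluded` (dropped node count) and `direction = "in"`.
#' @export
in_degree_distribution <- function(table, exclude_unregulated = TRUE) {
  d <- table$in_degree
  excluded <- 0L
  if (exclude_unregulated) {
    excluded <- sum(d == 0)
    d <- d[d > 0]
  }
  tab <- base::table(d)
  out <- data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
  structure(out, excluded = excluded, direction = "in",
            class = c("degree_distribution", "data.frame"))
}

#' Binned out-degree distribution of the TFs
#'
#' Counts of TFs (out-degree >= 1) per half-open out-degree bin
#' `[k*w, (k+1)*w)`. The default width of 200 matches the convention of
#' published TF out-degree histograms; `truncate_at` optionally drops bins
#' starting at or above a cutoff.
#'
#' @param table a [degree_table()].
#' @param bin_width positive integer bin width.
#' @param truncate_at optional upper cutoff; bins with `bin_lo >=
#'   truncate_at` are dropped.
#' @return a `degree_distribution`: data.frame (`bin_lo`, `bin_hi`,
#'   `count`) with attributes `direction = "out"` and `excluded` (TFs beyond
#'   the truncation point, 0 when not truncating). Empty intermediate bins
#'   are kept with count 0.
#' @export
out_degree_distribution <- function(table, bin_width = 200,
                                    truncate_at = NULL) {
  stopifnot(bin_width >= 1)
  d <- table$out_degree[table$out_degree >= 1]
  if (length(d) == 0) {
    out <- data.frame(bin_lo = integer(0), bin_hi = integer(0),
                      count = integer(0))
    return(structure(out, excluded = 0L, direction = "out",
                     class = c("degree_distribution", "data.frame")))
  }
  k <- d %/% bin_width
  kmax <- max(k)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  out <- data.frame(bin_lo = (0:kmax) * bin_width,
                    bin_hi = (1:(kmax + 1L)) * bin_width,
                    count = counts)
  excluded <- 0L
  if (!is.null(truncate_at)) {
    drop <- out$bin_lo >= truncate_at
    excluded <- sum(out$count[drop])
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, excluded = as.integer(excluded), direction = "out",
            class = c("degree_distribution", "data.frame"))
}

#' Rank TFs by out-degree with tie inclusion
#'
#' Selects the `k` highest (or lowest) out-degree TFs. The out-degree of the
#' k-th ranked TF becomes the reported threshold and all TFs tied with it
#' are included, so the returned set may exceed `k`.
#'
#' @param table a [degree_table()].
#' @param k number of TFs to select; must not exceed the TF count.
#' @param end `"top"` (highest out-degrees, descending) or `"bottom"`
#'   (lowest, ascending).
#' @return list with `records` (data.frame `node`, `out_degree` in rank
#'   order; ties broken alphabetically) and `threshold` (the cut value: for
#'   `"top"`, selected TFs have out-degree >= threshold; for `"bottom"`,
#'   <= threshold).
#' @export
rank_tfs <- function(table, k = 25, end = c("top", "bottom")) {
  end <- match.arg(end)
  if (!is.numeric(k) || k <= 0) stop("k must be a positive count")
  tfs <- table[table$out_degree >= 1, c("node", "out_degree")]
  if (nrow(tfs) < k)
    stop("only ", nrow(tfs), " TFs available, cannot rank k = ", k)
  ord <- if (end == "top") order(-tfs$out_degree, tfs$node)
         else order(tfs$out_degree, tfs$node)
  tfs <- tfs[ord, , drop = FALSE]
  threshold <- tfs$out_degree[k]
  keep <- if (end == "top") tfs$out_degree >= threshold
          else tfs$out_degree <= threshold
  records <- tfs[keep, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, threshold = threshold, end = end, k = k)
}
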