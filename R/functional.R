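# Functional analysis: chi-squared merging of consecutive in-degrees into
# bins, and functional-category distributions per bin.
#
# The idea: genes with similar numbers of regulators are grouped only while
# their functional-category composition is statistically homogeneous.
# Scanning in-degrees left to right, the accumulated bin is compared with
# the next in-degree's category counts by a chi-squared test on the 2 x C
# contingency table; the degree joins the bin while the test cannot tell
# them apart (p > alpha), otherwise a new bin starts.

#' Bin specification over in-degrees
#'
#' @param lo,hi integer vectors of equal length: contiguous, disjoint,
#'   inclusive intervals `[lo_i, hi_i]` with `lo_1 = 1` and
#'   `lo_{i+1} = hi_i + 1`.
#' @return data.frame of class `bin_spec` with columns `lo`, `hi`, `label`
#'   (e.g. `"1-4"`).
#' @export
bin_spec <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == length(hi), length(lo) >= 1, all(lo <= hi))
  if (lo[1] != 1L) stop("first bin must start at in-degree 1")
  if (length(lo) > 1 && !all(lo[-1] == hi[-length(hi)] + 1L))
    stop("bins must be contiguous and disjoint")
  out <- data.frame(lo = lo, hi = hi,
                    label = ifelse(lo == hi, as.character(lo),
                                   paste0(lo, "-", hi)))
  class(out) <- c("bin_spec", "data.frame")
  out
}

# Pool contingency-table columns whose expected count under homogeneity
# falls below min_expected into an "other" column, then chi-squared test.
# Returns NA when fewer than 2 informative columns survive.
.chisq_2xC <- function(top, bottom, min_expected) {
  tab <- rbind(top, bottom)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2) return(NA_real_)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  small <- apply(expected, 2, min) < min_expected
  if (any(small) && sum(!small) >= 1) {
    pooled <- rowSums(tab[, small, drop = FALSE])
    tab <- cbind(tab[, !small, drop = FALSE], other = pooled)
  }
  if (ncol(tab) < 2) return(NA_real_)
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Merge consecutive in-degrees into homogeneous bins
#'
#' Greedy left-to-right agglomeration: starting from the smallest observed
#' in-degree, the next degree's per-category gene counts are tested against
#' the accumulated bin (chi-squared on the 2 x C table, categories with
#' expected count below `min_expected` pooled into "other"); the degree is
#' merged while `p > alpha` and opens a new bin otherwise. A degree slice
#' with zero genes, or one where no informative test is possible, merges
#' unconditionally (with a warning for the zero-total case). Deterministic
#' for fixed inputs.
#'
#' @param contingency integer matrix: one row per in-degree value (row
#'   names = degree values, ascending), one column per functional category.
#' @param alpha significance level for the homogeneity test (default 0.05).
#' @param min_expected expected-count threshold below which categories are
#'   pooled (default 5).
#' @return a [bin_spec()] covering `[1, max observed degree]`.
#' @export
chi_square_bin_merge <- function(contingency, alpha = 0.05,
                                 min_expected = 5) {
  stopifnot(is.matrix(contingency), nrow(contingency) >= 1,
            all(contingency >= 0))
  degrees <- as.integer(rownames(contingency))
  if (anyNA(degrees)) stop("contingency row names must be in-degree values")
  ord <- order(degrees)
  contingency <- contingency[ord, , drop = FALSE]
  degrees <- degrees[ord]
  if (nrow(contingency) == 1)
    return(bin_spec(1L, degrees))

  breaks <- integer(0)  # last degree of each closed bin
  acc <- contingency[1, ]
  for (i in 2:nrow(contingency)) {
    slice <- contingency[i, ]
    if (sum(slice) == 0) {
      warning("in-degree ", degrees[i],
              " has no genes; merged unconditionally")
      next
    }
    p <- .chisq_2xC(acc, slice, min_expected)
    if (!is.na(p) && p <= alpha) {
      breaks <- c(breaks, degrees[i - 1])
      acc <- slice
    } else {
      acc <- acc + slice
    }
  }
  hi <- c(breaks, degrees[length(degrees)])
  lo <- c(1L, utils::head(hi, -1) + 1L)
  bin_spec(lo, hi)
}

#' Functional-category distribution across in-degree bins
#'
#' Cross-tabulates the regulated genes (in-degree >= 1) of a network by
#' functional category and in-degree bin, with within-category percentages.
#' Genes absent from the annotation map are tallied separately, never
#' silently dropped.
#'
#' @param table a [degree_table()].
#' @param annotations named character vector gene -> category (see
#'   [read_annotations()]).
#' @param bins a [bin_spec()] covering every regulated gene's in-degree.
#' @return a `category_distribution`: list with `counts` (category x bin
#'   matrix), `pct` (within-category percentages, 2-decimal), `bin_totals`
#'   (annotated genes per bin), `n_annotated`, `unannotated` (character
#'   vector of regulated genes without annotation).
#' @export
category_distribution <- function(table, annotations, bins) {
  stopifnot(inherits(bins, "bin_spec"))
  reg <- table[table$in_degree >= 1, , drop = FALSE]
  over <- reg$in_degree > max(bins$hi)
  if (any(over))
    stop("in-degree of gene '", reg$node[which(over)[1]],
         "' (", reg$in_degree[which(over)[1]], ") outside all bins")
  idx <- findInterval(reg$in_degree, bins$lo)
  known <- reg$node %in% names(annotations)
  unannotated <- reg$node[!known]
  cat_of <- annotations[reg$node[known]]
  counts <- base::table(
    factor(cat_of, levels = sort(unique(unname(annotations)))),
    factor(bins$label[idx[known]], levels = bins$label))
  counts <- unclass(counts)[, , drop = FALSE]
  row_tot <- rowSums(counts)
  pct <- counts
  pct[] <- 0
  nz <- row_tot > 0
  pct[nz, ] <- pct2(100 * counts[nz, , drop = FALSE] / row_tot[nz])
  structure(list(counts = counts, pct = pct,
                 bin_totals = colSums(counts),
                 n_annotated = sum(known),
                 unannotated = sort(unannotated)),
            class = "category_distribution")
}
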