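# Whole-network summary statistics: size/density rows, the evidence Venn
# partition, cross-network interaction overlap, and literature-support
# statistics.

#' Summary statistics from raw counts
#'
#' The density denominator is `n_tfs * n_nodes`: every identified TF could in
#' principle regulate every node (including other TFs and itself). For a
#' network with 152 TFs and 3937 nodes that is 152 x 3937 = 598,424 possible
#' interactions.
#'
#' @param n_nodes,n_interactions,n_tfs,n_tgs counts.
#' @return an object of class `network_summary` with fields `n_nodes`,
#'   `n_interactions`, `n_tfs`, `n_tgs`, `n_possible`, `density_pct`
#'   (2-decimal percentage) and `density_raw`.
#' @export
network_summary <- function(n_nodes, n_interactions, n_tfs, n_tgs) {
  stopifnot(n_tfs <= n_nodes, n_tgs <= n_nodes, n_tfs > 0, n_nodes > 0)
  possible <- as.double(n_tfs) * as.double(n_nodes)
  raw <- 100 * n_interactions / possible
  structure(list(n_nodes = n_nodes, n_interactions = n_interactions,
                 n_tfs = n_tfs, n_tgs = n_tgs, n_possible = possible,
                 density_pct = pct2(raw), density_raw = raw),
            class = "network_summary")
}

#' Summarize a regulatory network
#'
#' Node, interaction, TF and TG counts plus network density as a percentage
#' of the possible interactions (see [network_summary()] for the
#' denominator convention).
#'
#' @param net a non-empty `regnet`.
#' @return a `network_summary`.
#' @export
summarize_network <- function(net) {
  if (n_interactions(net) == 0)
    stop("cannot summarize an empty network (density undefined)")
  network_summary(n_nodes = length(network_nodes(net)),
                  n_interactions = n_interactions(net),
                  n_tfs = length(network_tfs(net)),
                  n_tgs = length(network_tgs(net)))
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "nodes %d | interactions %d | TFs %d | TGs %d | density %.2f%% (of %.0f)\n",
    x$n_nodes, x$n_interactions, x$n_tfs, x$n_tgs, x$density_pct,
    x$n_possible))
  invisible(x)
}

#' Evidence partition from raw counts
#'
#' @param n_expression_only,n_binding_only,n_both counts of the three cells
#'   of the evidence Venn diagram.
#' @param sign_tallies optional named counts of signs among
#'   expression-supported interactions.
#' @return an `evidence_partition` with counts, the union size, and
#'   2-decimal percentages of the union.
#' @export
evidence_partition <- function(n_expression_only, n_binding_only, n_both,
                               sign_tallies = NULL) {
  n_union <- n_expression_only + n_binding_only + n_both
  stopifnot(n_union > 0)
  structure(list(
    n_expression_only = n_expression_only,
    n_binding_only = n_binding_only,
    n_both = n_both,
    n_union = n_union,
    pct_expression_only = pct_of(n_expression_only, n_union),
    pct_binding_only = pct_of(n_binding_only, n_union),
    pct_both = pct_of(n_both, n_union),
    sign_tallies = sign_tallies), class = "evidence_partition")
}

#' Venn partition of a network by evidence class
#'
#' Splits the interactions into expression-only, binding-only and doubly
#' supported classes, with percentages over the whole interaction set, and
#' tallies the aggregated signs of all expression-supported interactions.
#'
#' @param net a `regnet`.
#' @return an `evidence_partition`.
#' @export
venn_partition <- function(net) {
  x <- net$interactions
  both <- x$has_binding & x$has_expression
  e_only <- x$has_expression & !x$has_binding
  b_only <- x$has_binding & !x$has_expression
  tal <- table(factor(x$sign[x$has_expression],
                      levels = c("positive", "negative", "dual", "unknown")))
  evidence_partition(sum(e_only), sum(b_only), sum(both),
                     sign_tallies = as.list(tal))
}

#' Overlap statistics from raw counts
#'
#' @param n_common number of interactions shared by the two networks.
#' @param n_a,n_b interaction counts of networks A and B.
#' @return an `overlap_stats` with `n_common`, `pct_of_a`, `pct_of_b`.
#' @export
overlap_stats <- function(n_common, n_a, n_b) {
  stopifnot(n_common <= n_a, n_common <= n_b)
  structure(list(n_common = n_common,
                 pct_of_a = pct_of(n_common, n_a),
                 pct_of_b = pct_of(n_common, n_b)),
            class = "overlap_stats")
}

#' Interaction overlap between two networks
#'
#' Interactions match on exact `(tf, target)` identity (identifiers are
#' case-normalized at construction); evidence annotations play no role.
#'
#' @param a,b `regnet` objects.
#' @return an `overlap_stats`.
#' @export
network_overlap <- function(a, b) {
  ka <- paste(a$interactions$tf, a$interactions$target, sep = "\r")
  kb <- paste(b$interactions$tf, b$interactions$target, sep = "\r")
  overlap_stats(sum(ka %in% kb), length(ka), length(kb))
}

#' Literature-support statistics of a network
#'
#' Per-reference interaction counts, per-reference exclusive counts
#' (interactions whose reference set is exactly that single reference), and
#' the two support means: interactions per reference and references per
#' interaction.
#'
#' @param net a `regnet` whose interactions carry reference sets.
#' @return a `reference_support_stats` object with fields
#'   `per_reference_counts`, `per_reference_exclusive` (named integer
#'   vectors, decreasing by count), `mean_interactions_per_reference`,
#'   `mean_references_per_interaction`, `n_references`.
#' @export
reference_support_stats <- function(net) {
  refs <- net$interactions$references
  nref_per_int <- lengths(refs)
  all_refs <- unlist(refs)
  if (length(all_refs) == 0)
    stop("no interaction carries references")
  counts <- table(all_refs)
  exclusive_refs <- unlist(refs[nref_per_int == 1])
  excl <- table(factor(exclusive_refs, levels = names(counts)))
  ord <- order(-as.integer(counts), names(counts))
  structure(list(
    per_reference_counts = stats::setNames(as.integer(counts), names(counts))[ord],
    per_reference_exclusive = stats::setNames(as.integer(excl), names(excl))[ord],
    mean_interactions_per_reference = mean(as.integer(counts)),
    mean_references_per_interaction = mean(nref_per_int),
    n_references = length(counts)), class = "reference_support_stats")
}
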