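# Directed triad census over the 13 connected 3-node isomorphism classes.
#
# Canonical form: on an ordered node triple (n1, n2, n3) the induced
# subgraph (self-loops excluded) is encoded as a 6-bit integer, MSB first,
# over the off-diagonal adjacency cells in row-major order
#   (1,2) (1,3) (2,1) (2,3) (3,1) (3,2);
# the canonical code of a triad is the minimum of this integer over the six
# node permutations. Exactly 13 canonical codes correspond to weakly
# connected triads.
#
# Display ids 1..13 follow the convention of triad-significance-profile
# plots: the feed-forward loop is id 7 and the mutual dyad regulating a
# common target is id 10. The full ordering ships as an editable mapping in
# inst/extdata/triad_classes.tsv; only ids 7 and 10 are contractual.

.triad_env <- new.env(parent = emptyenv())

# bit weights for cells (1,2),(1,3),(2,1),(2,3),(3,1),(3,2)
.TRIAD_PAIRS <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 1L),
                      c(2L, 3L), c(3L, 1L), c(3L, 2L))
.TRIAD_PERMS <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                      c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

.raw_code <- function(A) sum(A[.TRIAD_PAIRS] * 2^(5:0))

.canonical_code <- function(A) {
  min(apply(.TRIAD_PERMS, 1, function(p) .raw_code(A[p, p])))
}

#' The 13 connected directed triad classes
#'
#' @param mapping_file optional path to an alternative display-id mapping
#'   (TSV with columns `display_id`, `code`, `man`, `name`); defaults to the
#'   table shipped with the package.
#' @return data.frame with columns `display_id` (1..13), `code` (canonical
#'   6-bit code), `man` (the dyad-census M-A-N label, e.g. `"030T"`),
#'   `name`, and `edges` (canonical representative as `"1>2;1>3;2>3"`).
#' @export
triad_classes <- function(mapping_file = NULL) {
  if (is.null(mapping_file)) {
    if (!is.null(.triad_env$classes)) return(.triad_env$classes)
    mapping_file <- system.file("extdata", "triad_classes.tsv",
                                package = "trntopo", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  df <- utils::read.delim(mapping_file, stringsAsFactors = FALSE)
  stopifnot(all(c("display_id", "code", "man", "name", "edges") %in% names(df)))
  df <- df[order(df$display_id), , drop = FALSE]
  if (!identical(df$display_id, 1:13) || anyDuplicated(df$code))
    stop("triad class mapping must bijectively map ids 1..13 to the 13 codes")
  if (cache) .triad_env$classes <- df
  df
}

# display id for every raw 6-bit code (NA = disconnected); vectorized lookup
.code_to_id <- function() {
  if (!is.null(.triad_env$code_map)) return(.triad_env$code_map)
  classes <- triad_classes()
  map <- rep(NA_integer_, 64)
  for (raw in 0:63) {
    bits <- as.integer(intToBits(raw))[6:1]
    A <- matrix(0L, 3, 3)
    A[.TRIAD_PAIRS] <- bits
    U <- (A | t(A))
    if (sum(U[upper.tri(U)]) < 2) next  # < 2 undirected pairs: disconnected
    cc <- .canonical_code(A)
    map[raw + 1L] <- classes$display_id[match(cc, classes$code)]
  }
  .triad_env$code_map <- map
  map
}

#' Classify a 3-node directed subgraph
#'
#' @param edges two-column matrix or data.frame of directed edges (from,
#'   to) over at most 3 distinct node labels; self-loops are an error (strip
#'   them upstream, see [strip_self_loops()]).
#' @param nodes optional vector of the 3 node labels, needed when some node
#'   carries no edge.
#' @return the display id (integer in 1..13), or `NA` when the underlying
#'   undirected graph does not connect the three nodes.
#' @export
classify_triad <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (nrow(edges) > 0 && ncol(edges) != 2)
    stop("edges must be a 2-column matrix")
  from <- as.character(edges[, 1]); to <- as.character(edges[, 2])
  if (any(from == to)) stop("self-loop present; strip self-loops upstream")
  labels <- sort(unique(c(from, to, as.character(nodes))))
  if (length(labels) != 3) stop("expected exactly 3 distinct nodes, got ",
                                length(labels))
  A <- matrix(0L, 3, 3)
  A[cbind(match(from, labels), match(to, labels))] <- 1L
  if (nrow(unique(cbind(from, to))) != sum(A)) stop("duplicate edges")
  U <- (A | t(A))
  if (sum(U[upper.tri(U)]) < 2) return(NA_integer_)
  classes <- triad_classes()
  classes$display_id[match(.canonical_code(A), classes$code)]
}

#' Census of connected triads in a network
#'
#' Counts, for every unordered node triple whose induced subgraph
#' (self-loops removed) is weakly connected, the triad class of that
#' subgraph. Enumeration expands neighbourhoods over the underlying
#' undirected graph (the subquadratic triple-listing scheme of the triad
#' census literature), so only connected triples are ever touched; the
#' result equals a brute-force scan of all C(n, 3) triples.
#'
#' @param net a `regnet`, or a 2-column matrix/data.frame of directed
#'   edges.
#' @return a `triad_census`: named integer vector of length 13 (names =
#'   display ids) with attribute `n_connected_triples`.
#' @export
triad_census <- function(net) {
  if (inherits(net, "regnet")) {
    net <- strip_self_loops(net)
    from <- net$interactions$tf
    to <- net$interactions$target
  } else {
    em <- as.matrix(net)
    from <- as.character(em[, 1]); to <- as.character(em[, 2])
    keep <- from != to
    from <- from[keep]; to <- to[keep]
  }
  counts <- integer(13)
  names(counts) <- as.character(1:13)
  if (length(from) == 0)
    return(structure(counts, n_connected_triples = 0L,
                     class = "triad_census"))

  nodes <- sort(unique(c(from, to)))
  n <- length(nodes)
  fi <- match(from, nodes); ti <- match(to, nodes)
  # dedupe directed pairs
  key <- (fi - 1) * n + ti
  dup <- duplicated(key)
  fi <- fi[!dup]; ti <- ti[!dup]

  adj <- matrix(FALSE, n, n)          # directed adjacency
  adj[cbind(fi, ti)] <- TRUE
  und <- lapply(seq_len(n), function(u)
    sort(unique(c(ti[fi == u], fi[ti == u]))))
  code_map <- .code_to_id()

  for (u in seq_len(n)) {
    nu <- und[[u]]
    for (v in nu[nu > u]) {
      S <- setdiff(union(nu, und[[v]]), c(u, v))
      if (length(S) == 0) next
      in_nu <- S %in% nu
      keep <- (S > v) | (S > u & S < v & !in_nu)
      w <- S[keep]
      if (length(w) == 0) next
      code <- 32L * adj[u, v] + 16L * adj[u, w] + 8L * adj[v, u] +
        4L * adj[v, w] + 2L * adj[w, u] + adj[w, v]
      ids <- code_map[code + 1L]
      counts <- counts + tabulate(ids, nbins = 13L)
    }
  }
  structure(counts, n_connected_triples = sum(counts),
            class = "triad_census")
}

#' @export
print.triad_census <- function(x, ...) {
  cat("triad census (", attr(x, "n_connected_triples"),
      " connected triples)\n", sep = "")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}
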