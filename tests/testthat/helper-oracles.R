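# Shared fixtures and independent oracles for the test suite.

# Random directed graph without self-loops; returns a 2-column data.frame.
random_digraph <- function(n, p, seed) {
  withr::with_seed(seed, {
    from <- rep(seq_len(n), each = n)
    to <- rep(seq_len(n), times = n)
    keep <- from != to & stats::runif(n * n) < p
  })
  data.frame(from = sprintf("N%03d", from[keep]),
             to = sprintf("N%03d", to[keep]),
             stringsAsFactors = FALSE)
}

# Independent census oracle built on igraph's C triad census (16 MAN
# classes), mapped to display ids through the class table's MAN labels.
igraph_census <- function(edges, n_nodes = NULL) {
  skip_if_not_installed("igraph")
  man_order <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                 "111U", "030T", "030C", "201", "120D", "120U", "120C",
                 "210", "300")
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  tc <- suppressWarnings(igraph::triad_census(g))
  names(tc) <- man_order
  cls <- triad_classes()
  stats::setNames(as.integer(tc[cls$man]), cls$display_id)
}

# Second independent route: brute force over all C(n,3) triples, each
# induced subgraph classified by igraph isomorphism against the 13
# reference triads. Only for small n.
brute_census_iso <- function(edges, nodes = NULL) {
  skip_if_not_installed("igraph")
  cls <- triad_classes()
  refs <- lapply(cls$edges, function(e) {
    em <- do.call(rbind, lapply(strsplit(e, ";")[[1]],
                                function(s) strsplit(s, ">")[[1]]))
    igraph::graph_from_data_frame(as.data.frame(em), directed = TRUE,
                                  vertices = data.frame(name = c("1", "2", "3")))
  })
  from <- as.character(edges[, 1]); to <- as.character(edges[, 2])
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  nodes <- sort(unique(c(from, to, nodes)))
  counts <- stats::setNames(integer(13), 1:13)
  if (length(nodes) < 3) return(counts)
  for (tri in utils::combn(length(nodes), 3, simplify = FALSE)) {
    sel <- from %in% nodes[tri] & to %in% nodes[tri]
    if (!any(sel)) next
    sub <- unique(data.frame(from = from[sel], to = to[sel]))
    g <- igraph::graph_from_data_frame(
      sub, directed = TRUE, vertices = data.frame(name = nodes[tri]))
    if (!igraph::is_connected(g, mode = "weak")) next
    for (k in 1:13) {
      if (igraph::isomorphic(g, refs[[k]])) {
        counts[k] <- counts[k] + 1L
        break
      }
    }
  }
  counts
}

# In-/out-degree recount straight from an interaction table (independent of
# degree_table's implementation).
recount_degrees <- function(net) {
  x <- net$interactions
  nodes <- sort(unique(c(x$tf, x$target)))
  data.frame(
    node = nodes,
    in_degree = vapply(nodes, function(nd) sum(x$target == nd), 0L),
    out_degree = vapply(nodes, function(nd) sum(x$tf == nd), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Small annotated network written to a temp TSV; returns the path.
write_demo_network_file <- function(dir = tempdir(), n_seed = 11) {
  spec <- synthetic_spec(n_tf = 12, n_tg = 60,
                         in_degree_law = list(law = "geometric", p = 0.45),
                         seed = n_seed)
  net <- generate_trn(spec)$net
  path <- file.path(dir, sprintf("demo_net_%d.tsv", n_seed))
  write_network(net, path)
  path
}

published_path <- function(file)
  system.file("extdata", file, package = "trntopo", mustWork = TRUE)
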