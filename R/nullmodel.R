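# Degree-preserving randomization, ensemble statistics, Z-scores and the
# triad significance profile.
#
# The null model is the standard edge-switching Markov chain: repeatedly
# pick two edges (a -> b, c -> d) and rewire them to (a -> d, c -> b),
# rejecting any swap that would create a self-loop or a duplicate edge.
# Every node keeps its exact in- and out-degree, so the ensemble controls
# for the degree sequences while scrambling higher-order structure.

#' Degree-preserving edge-switching randomization
#'
#' Runs `ceiling(swap_factor * m)` attempted swaps on the `m` interactions
#' of the network. Rejected moves (self-loop, duplicate edge, or -- with
#' `preserve_mutual` -- a change in the number of mutual dyads) leave the
#' state unchanged, as the Markov chain requires. The result is
#' deterministic given `seed`. Edge annotations travel with the source
#' endpoint's original edge; only the topology is the object of interest.
#'
#' @param net a `regnet` with at least 2 interactions.
#' @param swap_factor positive real: attempted swaps per edge (default 10).
#' @param seed integer seed (mandatory; the global RNG state is left
#'   untouched).
#' @param preserve_mutual also reject swaps changing the count of mutually
#'   connected node pairs? Default `FALSE`.
#' @return a randomized `regnet` with identical in- and out-degree
#'   sequences.
#' @export
degree_preserving_randomize <- function(net, swap_factor = 10, seed,
                                        preserve_mutual = FALSE) {
  if (missing(seed)) stop("an explicit seed is required")
  if (!is.numeric(swap_factor) || swap_factor <= 0)
    stop("swap_factor must be positive")
  m <- n_interactions(net)
  if (m < 2) stop("need at least 2 interactions to randomize")
  nodes <- network_nodes(net)
  n <- length(nodes)
  from <- match(net$interactions$tf, nodes)
  to <- match(net$interactions$target, nodes)
  adj <- matrix(FALSE, n, n)
  adj[cbind(from, to)] <- TRUE

  attempts <- as.integer(ceiling(swap_factor * m))
  withr::with_seed(seed, {
    ei <- sample.int(m, attempts, replace = TRUE)
    ej <- sample.int(m, attempts, replace = TRUE)
  })
  for (t in seq_len(attempts)) {
    i <- ei[t]; j <- ej[t]
    if (i == j) next
    a <- from[i]; b <- to[i]; c <- from[j]; d <- to[j]
    if (a == d || c == b) next            # would create a self-loop
    if (adj[a, d] || adj[c, b]) next      # would create a duplicate edge
    if (preserve_mutual) {
      destroyed <- adj[b, a] + adj[d, c]
      created <- adj[d, a] + adj[b, c]
      if (destroyed != created) next
    }
    adj[a, b] <- FALSE; adj[c, d] <- FALSE
    adj[a, d] <- TRUE; adj[c, b] <- TRUE
    to[i] <- d; to[j] <- b
  }
  out <- net
  x <- net$interactions
  x$target <- nodes[to]
  ord <- order(x$tf, x$target, method = "radix")
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  out$interactions <- x
  out$label <- paste0(net$label, " [randomized]")
  out
}

#' Triad-census statistics of a random ensemble
#'
#' Generates `R` independently seeded degree-preserving randomizations of
#' the network (child seed for replicate i derived reproducibly from
#' `base_seed`), computes each census, and returns per-class mean and
#' population standard deviation.
#'
#' @param net a `regnet` (self-loops are stripped before analysis).
#' @param R ensemble size (>= 1). Published genome-scale profiles use
#'   10,000; desk-scale work uses 200-1000.
#' @param base_seed integer base seed.
#' @param swap_factor,preserve_mutual passed to
#'   [degree_preserving_randomize()].
#' @return a `random_ensemble_stats`: list with `mean`, `sd` (length-13
#'   numeric vectors named by display id), `R`, `base_seed`.
#' @export
ensemble_stats <- function(net, R = 1000, base_seed, swap_factor = 10,
                           preserve_mutual = FALSE) {
  if (missing(base_seed)) stop("an explicit base_seed is required")
  stopifnot(R >= 1)
  net <- strip_self_loops(net)
  counts <- matrix(0, nrow = R, ncol = 13,
                   dimnames = list(NULL, as.character(1:13)))
  for (i in seq_len(R)) {
    r <- degree_preserving_randomize(net, swap_factor = swap_factor,
                                     seed = derive_seed(base_seed, i),
                                     preserve_mutual = preserve_mutual)
    counts[i, ] <- as.integer(triad_census(r))
  }
  mu <- colMeans(counts)
  sdev <- sqrt(colMeans(sweep(counts, 2, mu)^2))  # population sd
  structure(list(mean = mu, sd = sdev, R = R, base_seed = base_seed),
            class = "random_ensemble_stats")
}

#' Triad Z-scores against a random ensemble
#'
#' `z_i = (N_i - mean_i) / sd_i`, with two corrections: the Z-score of a
#' class observed fewer than `min_count` times in the real network is set
#' to 0 (the small-count correction of the significance-profile method,
#' default 4), and a degenerate ensemble (`sd = 0`) also yields 0 -- the
#' conservative choice for a class the null model cannot vary.
#'
#' @param real a [triad_census()] of the observed network.
#' @param ensemble a [ensemble_stats()] result.
#' @param min_count zero the Z-score below this real-count threshold.
#' @return named numeric vector of 13 Z-scores.
#' @export
zscores <- function(real, ensemble, min_count = 4) {
  stopifnot(inherits(ensemble, "random_ensemble_stats"))
  nreal <- as.numeric(real)
  z <- rep(0, 13)
  ok <- nreal >= min_count & ensemble$sd > 0
  z[ok] <- (nreal[ok] - ensemble$mean[ok]) / ensemble$sd[ok]
  names(z) <- as.character(1:13)
  z
}

#' Triad significance profile
#'
#' Normalizes the Z-score vector to unit Euclidean length,
#' `SP_i = Z_i / sqrt(sum_j Z_j^2)`, making profiles of networks of very
#' different sizes comparable. An all-zero Z vector maps to an all-zero
#' profile.
#'
#' @param z numeric vector of 13 Z-scores.
#' @return named numeric vector of 13 SP values in `[-1, 1]`.
#' @export
significance_profile <- function(z) {
  stopifnot(length(z) == 13)
  norm <- sqrt(sum(z^2))
  sp <- if (norm > 0) z / norm else rep(0, 13)
  names(sp) <- as.character(1:13)
  sp
}

#' Motif (triad significance) profiles of one or more networks
#'
#' Full pipeline per network: strip self-loops, census, degree-preserving
#' random ensemble, Z-scores with the small-count correction, unit-length
#' normalization.
#'
#' @param nets a `regnet` or a (optionally named) list of them.
#' @param R ensemble size.
#' @param base_seed integer base seed (each network's ensemble is seeded
#'   from it and the network's position).
#' @param swap_factor,preserve_mutual null-model options.
#' @param min_count small-count correction threshold for [zscores()].
#' @return a `motif_profiles` list: `sp` and `z` (data.frames: `network`,
#'   `id_1` .. `id_13`) and `census` (real censuses, same layout).
#' @export
motif_profile <- function(nets, R = 1000, base_seed, swap_factor = 10,
                          preserve_mutual = FALSE, min_count = 4) {
  if (inherits(nets, "regnet")) nets <- list(nets)
  if (is.null(names(nets)))
    names(nets) <- vapply(nets, function(n) n$label, "")
  rows_sp <- rows_z <- rows_c <- list()
  for (k in seq_along(nets)) {
    net <- strip_self_loops(nets[[k]])
    real <- triad_census(net)
    z <- rep(0, 13)
    if (n_interactions(net) >= 2 && attr(real, "n_connected_triples") > 0) {
      ens <- ensemble_stats(net, R = R,
                            base_seed = derive_seed(base_seed, 1000L + k),
                            swap_factor = swap_factor,
                            preserve_mutual = preserve_mutual)
      z <- zscores(real, ens, min_count = min_count)
    }
    rows_sp[[k]] <- significance_profile(z)
    rows_z[[k]] <- z
    rows_c[[k]] <- as.numeric(real)
  }
  as_df <- function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- paste0("id_", 1:13)
    cbind(data.frame(network = names(nets), stringsAsFactors = FALSE),
          as.data.frame(m))
  }
  structure(list(sp = as_df(rows_sp), z = as_df(rows_z),
                 census = as_df(rows_c)),
            class = "motif_profiles")
}
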