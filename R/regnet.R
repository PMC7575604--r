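# Core data model: an evidence-annotated transcriptional regulatory network.
#
# A `regnet` stores one row per deduplicated TF -> target-gene association,
# with orthogonal evidence flags (has_binding, has_expression), an aggregated
# regulation sign, a set of environmental condition tags and a set of
# supporting reference identifiers. Node / TF / TG sets are always derived
# from the surviving interactions, so a network can never contain an
# isolated node.

#' Recognised regulation signs
#'
#' Signs derive from expression evidence only: a TF deletion/overexpression
#' assay shows the target going up (`positive`), down (`negative`), both
#' across publications (`dual`), or changing with no consistent direction
#' (`unknown`). Associations supported by binding evidence alone carry
#' `not_applicable`.
#' @export
SIGN_LEVELS <- c("positive", "negative", "dual", "unknown", "not_applicable")

#' Environmental condition vocabulary
#'
#' The condition tags used by curated yeast regulatory-association databases;
#' the synthetic generator and examples draw from this list. Filtering is not
#' restricted to it: any free-form tag present in the data can be used.
#' @export
CONDITION_TAGS <- c(
  "Biofilm formation",
  "Carbon source quality/availability",
  "Cell cycle/morphology",
  "Human niche conditions",
  "In vitro",
  "Lipid supplementation",
  "Nitrogen source quality/availability",
  "Oxygen availability",
  "Stress",
  "Unstressed log-phase growth (control)"
)

#' Construct a regulatory network from an interaction table
#'
#' @param interactions data.frame with columns `tf`, `target` (character),
#'   `has_binding`, `has_expression` (logical), `sign` (one of
#'   [SIGN_LEVELS]), and list columns `conditions`, `references` (character
#'   vectors). Missing annotation columns are filled with defaults
#'   (no conditions, no references, sign `not_applicable`/`unknown`).
#' @param label human-readable network label.
#' @return an object of class `regnet`.
#' @details Invariants enforced: every interaction has at least one kind of
#'   evidence; a sign other than `not_applicable` requires expression
#'   evidence; `(tf, target)` pairs are unique; gene identifiers are
#'   uppercased so that cross-network comparison is by exact string match.
#' @export
regnet <- function(interactions, label = "network") {
  stopifnot(is.data.frame(interactions))
  n <- nrow(interactions)
  need <- c("tf", "target")
  if (!all(need %in% names(interactions)))
    stop("interaction table must have 'tf' and 'target' columns")
  tf <- toupper(as.character(interactions$tf))
  target <- toupper(as.character(interactions$target))
  hb <- if ("has_binding" %in% names(interactions))
    as.logical(interactions$has_binding) else rep(FALSE, n)
  he <- if ("has_expression" %in% names(interactions))
    as.logical(interactions$has_expression) else rep(FALSE, n)
  sign <- if ("sign" %in% names(interactions))
    as.character(interactions$sign) else ifelse(he, "unknown", "not_applicable")
  conditions <- if ("conditions" %in% names(interactions))
    lapply(interactions$conditions, as.character) else rep(list(character(0)), n)
  references <- if ("references" %in% names(interactions))
    lapply(interactions$references, as.character) else rep(list(character(0)), n)

  if (any(!hb & !he))
    stop("every interaction needs binding and/or expression evidence; ",
         sum(!hb & !he), " rows have neither")
  bad_sign <- !sign %in% SIGN_LEVELS
  if (any(bad_sign))
    stop("unknown sign value(s): ", paste(unique(sign[bad_sign]), collapse = ", "),
         "; accepted: ", paste(SIGN_LEVELS, collapse = ", "))
  if (any(sign != "not_applicable" & !he))
    stop("a directional/unknown sign requires expression evidence")
  if (any(sign == "not_applicable" & he))
    stop("expression-supported interactions must carry a sign ",
         "(use 'unknown' when no direction was observed)")
  key <- paste(tf, target, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (tf, target) pairs; merge annotations before construction")

  ord <- order(tf, target, method = "radix")
  x <- data.frame(tf = unname(tf[ord]), target = unname(target[ord]),
                  stringsAsFactors = FALSE)
  x$has_binding <- unname(hb[ord])
  x$has_expression <- unname(he[ord])
  x$sign <- unname(sign[ord])
  x$conditions <- I(unname(lapply(conditions[ord],
                                  function(v) sort(unique(unname(v))))))
  x$references <- I(unname(lapply(references[ord],
                                  function(v) sort(unique(unname(v))))))
  rownames(x) <- NULL
  structure(list(interactions = x, label = as.character(label)),
            class = "regnet")
}

#' Build a network from bare TF -> target edges
#'
#' Convenience constructor for plain edge lists (e.g. published binding
#' networks distributed without annotations): all interactions get the same
#' evidence class.
#'
#' @param tf,target character vectors of equal length.
#' @param evidence `"binding"` (default), `"expression"` or `"both"`.
#' @param label network label.
#' @return a `regnet`. Duplicate pairs are collapsed.
#' @export
regnet_from_edges <- function(tf, target, evidence = "binding",
                              label = "network") {
  evidence <- match.arg(evidence, c("binding", "expression", "both"))
  stopifnot(length(tf) == length(target))
  df <- unique(data.frame(tf = toupper(as.character(tf)),
                          target = toupper(as.character(target)),
                          stringsAsFactors = FALSE))
  df$has_binding <- evidence %in% c("binding", "both")
  df$has_expression <- evidence %in% c("expression", "both")
  df$sign <- if (evidence == "binding") "not_applicable" else "unknown"
  regnet(df, label = label)
}

#' @export
print.regnet <- function(x, ...) {
  cat(sprintf("regnet '%s': %d interactions, %d nodes (%d TFs, %d TGs)\n",
              x$label, n_interactions(x), length(network_nodes(x)),
              length(network_tfs(x)), length(network_tgs(x))))
  invisible(x)
}

#' Number of interactions in a network
#' @param net a `regnet`.
#' @export
n_interactions <- function(net) nrow(net$interactions)

#' Node set of a network
#'
#' The union of all TF and target identifiers; by construction no node is
#' isolated.
#' @param net a `regnet`.
#' @return sorted character vector.
#' @export
network_nodes <- function(net)
  sort(unique(c(net$interactions$tf, net$interactions$target)))

#' Transcription factors of a network (out-degree >= 1)
#' @param net a `regnet`.
#' @export
network_tfs <- function(net) sort(unique(net$interactions$tf))

#' Target genes of a network (in-degree >= 1)
#' @param net a `regnet`.
#' @export
network_tgs <- function(net) sort(unique(net$interactions$target))

#' Test equality of two networks
#'
#' Networks are equal when they hold the same annotated interaction set
#' (labels are ignored).
#' @param a,b `regnet` objects.
#' @export
regnet_equal <- function(a, b) {
  ia <- a$interactions; ib <- b$interactions
  if (nrow(ia) != nrow(ib)) return(FALSE)
  isTRUE(all.equal(ia$tf, ib$tf)) &&
    isTRUE(all.equal(ia$target, ib$target)) &&
    identical(ia$has_binding, ib$has_binding) &&
    identical(ia$has_expression, ib$has_expression) &&
    identical(ia$sign, ib$sign) &&
    identical(unclass(ia$conditions), unclass(ib$conditions)) &&
    identical(unclass(ia$references), unclass(ib$references))
}

#' Remove auto-regulation (self-loop) interactions
#'
#' Triad analysis operates on the 13 connected 3-node classes, which are
#' defined without self-loops; auto-regulation is a 1-node motif and is
#' stripped before any census.
#' @param net a `regnet`.
#' @return a `regnet` without `tf == target` interactions.
#' @export
strip_self_loops <- function(net) {
  keep <- net$interactions$tf != net$interactions$target
  out <- net
  out$interactions <- net$interactions[keep, , drop = FALSE]
  rownames(out$interactions) <- NULL
  out
}

#' Aggregate per-publication regulation signs
#'
#' Collapses the signs observed across publications for one association into
#' a single label: all positive -> `positive`; all negative -> `negative`;
#' conflicting directions or any explicit `dual` -> `dual`. `unknown`
#' observations (no directionality) never override a consistent directional
#' sign; only-unknown input stays `unknown`.
#'
#' @param observed_signs character vector of per-publication signs from
#'   \{positive, negative, dual, unknown\}.
#' @return a single sign string.
#' @export
aggregate_sign <- function(observed_signs) {
  if (length(observed_signs) == 0) stop("empty sign multiset")
  s <- as.character(observed_signs)
  bad <- setdiff(unique(s), c("positive", "negative", "dual", "unknown"))
  if (length(bad))
    stop("unknown sign token(s): ", paste(bad, collapse = ", "))
  has_pos <- "positive" %in% s
  has_neg <- "negative" %in% s
  if ("dual" %in% s || (has_pos && has_neg)) return("dual")
  if (has_pos) return("positive")
  if (has_neg) return("negative")
  "unknown"
}
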