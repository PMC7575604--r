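# Evidence- and condition-based sub-network extraction.

#' Extract an evidence-defined sub-network
#'
#' The four canonical evidence sets of an annotated regulatory network:
#' `B` (at least one binding publication), `E` (at least one expression
#' publication), `B_and_E` (both kinds), `B_or_E` (any kind, i.e. the whole
#' network). Node, TF and TG sets are recomputed from the surviving
#' interactions, so no isolated node is retained. The interaction counts
#' satisfy inclusion-exclusion: |B| + |E| - |B&E| = |B|E|.
#'
#' @param net a `regnet`.
#' @param selector one of `"B"`, `"E"`, `"B_or_E"`, `"B_and_E"`.
#' @return the filtered `regnet`, labelled `"<label> [<selector>]"`.
#' @export
filter_by_evidence <- function(net, selector) {
  if (!is.character(selector) || length(selector) != 1 ||
      !selector %in% c("B", "E", "B_or_E", "B_and_E"))
    stop("unknown evidence selector; use one of B, E, B_or_E, B_and_E")
  x <- net$interactions
  keep <- switch(selector,
    B = x$has_binding,
    E = x$has_expression,
    B_and_E = x$has_binding & x$has_expression,
    B_or_E = rep(TRUE, nrow(x)))
  out <- net
  out$interactions <- x[keep, , drop = FALSE]
  rownames(out$interactions) <- NULL
  out$label <- paste0(net$label, " [", selector, "]")
  out
}

#' Extract the sub-network active under an environmental condition
#'
#' Keeps interactions whose condition-tag set contains `condition` (exact
#' string match). A tag occurring nowhere in the network yields an empty
#' network with a warning.
#'
#' @param net a `regnet`.
#' @param condition a condition tag, e.g. `"Stress"` or
#'   `"Unstressed log-phase growth (control)"`.
#' @return the filtered `regnet`.
#' @export
filter_by_condition <- function(net, condition) {
  stopifnot(is.character(condition), length(condition) == 1)
  keep <- vapply(net$interactions$conditions,
                 function(tags) condition %in% tags, TRUE)
  if (!any(keep))
    warning("condition tag '", condition, "' matches no interaction in '",
            net$label, "'")
  out <- net
  out$interactions <- net$interactions[keep, , drop = FALSE]
  rownames(out$interactions) <- NULL
  out$label <- paste0(net$label, " [", condition, "]")
  out
}
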