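# Reading and writing annotated regulatory networks.
#
# The native dialect is a UTF-8 TSV with a header row and columns
#   tf  target  evidence  sign  conditions  references
# where evidence / conditions / references hold semicolon-separated tokens
# and several rows per (tf, target) pair are permitted (one row per
# publication, as curated databases export them). Rows lacking any evidence
# token are dropped with a warning, mirroring the handling of the handful of
# database associations that still lack evidence annotation.

EVIDENCE_TOKENS <- c("binding", "expression")

#' Read an annotated regulatory network
#'
#' Parses the TSV dialect described above, merges duplicate `(tf, target)`
#' rows (evidence flags OR-ed, condition and reference sets unioned, signs
#' aggregated via [aggregate_sign()]), and drops rows carrying no evidence
#' annotation (their count is reported in a warning).
#'
#' @param path path to a TSV file.
#' @param dialect named list mapping the roles `tf`, `target`, `evidence`,
#'   `sign`, `conditions`, `references` to column names in the file. Only
#'   the first three are mandatory.
#' @param label network label; defaults to the file name.
#' @return a [regnet()].
#' @export
read_network <- function(path, dialect = list(), label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::modifyList(
    list(tf = "tf", target = "target", evidence = "evidence",
         sign = "sign", conditions = "conditions", references = "references"),
    dialect)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  for (role in c("tf", "target", "evidence"))
    if (!d[[role]] %in% header)
      stop("column '", d[[role]], "' (", role, ") missing from ", path)
  col <- function(role) match(d[[role]], header)
  ncol_exp <- length(header)

  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  fields <- strsplit(body, "\t", fixed = TRUE)
  # trailing empty fields are dropped by strsplit; pad, but flag excess
  lens <- lengths(fields)
  if (any(lens > ncol_exp))
    stop("malformed row at line ", which(lens > ncol_exp)[1] + 1L,
         ": more fields than header columns")
  get_field <- function(role) {
    j <- col(role)
    if (is.na(j)) return(rep("", n))
    vapply(fields, function(f) if (length(f) >= j) f[[j]] else "", "")
  }
  tf <- trimws(get_field("tf"))
  target <- trimws(get_field("target"))
  bad <- !nzchar(tf) | !nzchar(target)
  if (any(bad))
    stop("malformed row at line ", which(bad)[1] + 1L,
         ": empty tf or target field")
  ev_raw <- get_field("evidence")
  ev_tokens <- lapply(ev_raw, split_set)
  unknown <- setdiff(unique(unlist(ev_tokens)), EVIDENCE_TOKENS)
  if (length(unknown))
    stop("unknown evidence token(s): ", paste(unknown, collapse = ", "),
         "; accepted vocabulary: ", paste(EVIDENCE_TOKENS, collapse = ", "))
  no_evidence <- lengths(ev_tokens) == 0
  if (any(no_evidence))
    warning(sum(no_evidence),
            " row(s) without evidence annotation dropped from ", basename(path))
  keep <- !no_evidence
  tf <- toupper(tf[keep]); target <- toupper(target[keep])
  ev_tokens <- ev_tokens[keep]
  sign_raw <- trimws(get_field("sign"))[keep]
  cond <- lapply(get_field("conditions")[keep], split_set)
  refs <- lapply(get_field("references")[keep], split_set)

  has_b <- vapply(ev_tokens, function(t) "binding" %in% t, TRUE)
  has_e <- vapply(ev_tokens, function(t) "expression" %in% t, TRUE)
  # per-row observed sign: expression rows default to unknown when blank
  row_sign <- ifelse(nzchar(sign_raw), sign_raw,
                     ifelse(has_e, "unknown", "not_applicable"))
  bad_sign <- !row_sign %in% SIGN_LEVELS
  if (any(bad_sign))
    stop("unknown sign value(s): ",
         paste(unique(row_sign[bad_sign]), collapse = ", "),
         "; accepted: ", paste(SIGN_LEVELS, collapse = ", "))

  key <- paste(tf, target, sep = "\r")
  idx <- split(seq_along(key), key)
  merged <- lapply(idx, function(i) {
    he <- any(has_e[i])
    obs <- row_sign[i][has_e[i] & row_sign[i] != "not_applicable"]
    list(tf = tf[i[1]], target = target[i[1]],
         has_binding = any(has_b[i]), has_expression = he,
         sign = if (he && length(obs)) aggregate_sign(obs)
                else if (he) "unknown" else "not_applicable",
         conditions = sort(unique(unlist(cond[i]))),
         references = sort(unique(unlist(refs[i]))))
  })
  df <- data.frame(
    tf = vapply(merged, `[[`, "", "tf"),
    target = vapply(merged, `[[`, "", "target"),
    stringsAsFactors = FALSE)
  df$has_binding <- vapply(merged, `[[`, TRUE, "has_binding")
  df$has_expression <- vapply(merged, `[[`, TRUE, "has_expression")
  df$sign <- vapply(merged, `[[`, "", "sign")
  df$conditions <- I(lapply(merged, `[[`, "conditions"))
  df$references <- I(lapply(merged, `[[`, "references"))
  regnet(df, label = label)
}

#' Write a network in the native TSV dialect
#'
#' Output is deterministic: interactions ordered lexicographically by
#' `(tf, target)`, set-valued fields sorted and semicolon-joined. A network
#' written and re-read round-trips losslessly.
#'
#' @param net a `regnet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  x <- net$interactions
  ev <- mapply(function(b, e) join_set(c(if (b) "binding", if (e) "expression")),
               x$has_binding, x$has_expression)
  if (nrow(x) == 0) ev <- character(0)
  out <- data.frame(
    tf = x$tf, target = x$target, evidence = ev, sign = x$sign,
    conditions = vapply(x$conditions, join_set, ""),
    references = vapply(x$references, join_set, ""),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               if (nrow(out)) do.call(paste, c(unname(out), sep = "\t"))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a plain two-column edge list
#'
#' For binding networks distributed as bare TF -> target edge lists. A
#' header row `tf <TAB> target` is recognised and skipped; otherwise every
#' line is data.
#'
#' @param path path to a 2-column TSV.
#' @param evidence evidence class to assign to every edge
#'   (default `"binding"`).
#' @param label network label.
#' @return a [regnet()].
#' @export
read_edge_list <- function(path, evidence = "binding",
                           label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(fields[[1]][1:2]), c("tf", "target"))) {
    fields <- fields[-1]
    lines <- lines[-1]
  }
  lens <- lengths(fields)
  if (any(lens < 2))
    stop("malformed row at line ", which(lens < 2)[1], ": expected 2 columns")
  regnet_from_edges(vapply(fields, `[[`, "", 1),
                    vapply(fields, `[[`, "", 2),
                    evidence = evidence, label = label)
}

#' Read a gene-to-functional-category annotation table
#'
#' @param path TSV with header columns `gene` and `category`.
#' @return named character vector mapping uppercased gene identifiers to
#'   category labels (an annotation map).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (!all(c("gene", "category") %in% names(df)))
    stop("annotation table needs 'gene' and 'category' columns")
  gene <- toupper(trimws(df$gene))
  if (anyDuplicated(gene)) {
    dup <- unique(gene[duplicated(gene)])
    conflicting <- vapply(dup, function(g)
      length(unique(df$category[gene == g])) > 1, TRUE)
    if (any(conflicting))
      stop("conflicting categories for gene(s): ",
           paste(dup[conflicting], collapse = ", "))
  }
  m <- trimws(df$category)
  names(m) <- gene
  m[!duplicated(gene)]
}
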