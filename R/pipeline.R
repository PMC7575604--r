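# End-to-end orchestration: a validated configuration drives evidence /
# condition filtering, summaries, degree and functional analyses and motif
# profiling, writing a deterministic TSV/JSON report bundle with a
# manifest. Identical configuration => byte-identical bundle.

#' Build and validate a pipeline configuration
#'
#' @param networks named character vector or list: network name -> path to
#'   an input file in the native TSV dialect (see [read_network()]).
#' @param out_dir output directory (created if missing).
#' @param evidence_selector optional evidence filter applied to every
#'   network (`"B"`, `"E"`, `"B_or_E"`, `"B_and_E"`).
#' @param condition optional condition tag filter.
#' @param annotations optional path to a gene/category TSV for the
#'   functional analysis.
#' @param degree list of degree options: `exclude_unregulated`,
#'   `bin_width`, `rank_k`.
#' @param chi2 list: `alpha`, `min_expected` for the in-degree bin merge.
#' @param motifs list: `R`, `swap_factor`, `seed`, `preserve_mutual`,
#'   `min_count`. The seed is mandatory: the pipeline never seeds from the
#'   wall clock.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(networks, out_dir,
                            evidence_selector = NULL,
                            condition = NULL,
                            annotations = NULL,
                            degree = list(),
                            chi2 = list(),
                            motifs = list()) {
  networks <- as.list(networks)
  if (length(networks) == 0) stop("at least one input network is required")
  if (is.null(names(networks)) || any(!nzchar(names(networks))))
    stop("every network needs a name")
  for (p in networks)
    if (!file.exists(p)) stop("input network file not found: ", p)
  if (!is.null(annotations) && !file.exists(annotations))
    stop("annotation file not found: ", annotations)
  if (!is.null(evidence_selector) &&
      !evidence_selector %in% c("B", "E", "B_or_E", "B_and_E"))
    stop("unknown evidence selector")
  degree <- utils::modifyList(
    list(exclude_unregulated = TRUE, bin_width = 200, rank_k = 25), degree)
  chi2 <- utils::modifyList(list(alpha = 0.05, min_expected = 5), chi2)
  motifs <- utils::modifyList(
    list(R = 1000, swap_factor = 10, preserve_mutual = FALSE,
         min_count = 4, seed = NULL), motifs)
  if (is.null(motifs$seed))
    stop("motifs$seed is mandatory (no wall-clock seeding)")
  structure(list(networks = networks, out_dir = out_dir,
                 evidence_selector = evidence_selector,
                 condition = condition, annotations = annotations,
                 degree = degree, chi2 = chi2, motifs = motifs),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose top-level keys match
#'   the arguments of [pipeline_config()].
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cells <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.6g", col) else as.character(col)
  })
  writeLines(c(paste(names(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(cells, sep = "\t"))),
             con, sep = "\n", useBytes = TRUE)
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the full analysis pipeline
#'
#' For every configured network: evidence/condition filtering, a summary
#' row, the evidence Venn partition, degree table and distributions,
#' ranked-TF tables, the functional bin/category tables (when annotations
#' are configured), and the triad significance profile. A manifest records
#' the configuration hash, the seeds and the MD5 of every artifact. Any
#' stage failure aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  annotations <- if (!is.null(config$annotations))
    stage("annotations", read_annotations(config$annotations))
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  summary_rows <- list()
  for (nm in names(config$networks)) {
    net <- stage(paste0(nm, "/read"),
                 read_network(config$networks[[nm]], label = nm))
    if (!is.null(config$evidence_selector))
      net <- stage(paste0(nm, "/evidence"),
                   filter_by_evidence(net, config$evidence_selector))
    if (!is.null(config$condition))
      net <- stage(paste0(nm, "/condition"),
                   filter_by_condition(net, config$condition))
    if (n_interactions(net) == 0)
      stop("stage '", nm, "' failed: no interactions after filtering",
           call. = FALSE)
    pfx <- function(what) file.path(config$out_dir, paste0(nm, "_", what))

    s <- stage(paste0(nm, "/summary"), summarize_network(net))
    summary_rows[[nm]] <- data.frame(
      network = nm, n_nodes = s$n_nodes, n_interactions = s$n_interactions,
      n_tfs = s$n_tfs, n_tgs = s$n_tgs, density_pct = s$density_pct,
      stringsAsFactors = FALSE)

    vp <- stage(paste0(nm, "/venn"), venn_partition(net))
    emit(.write_json(unclass(vp), pfx("venn.json")))

    dt <- stage(paste0(nm, "/degrees"), degree_table(net))
    emit(.write_tsv(dt, pfx("degree_table.tsv")))
    ind <- in_degree_distribution(
      dt, exclude_unregulated = config$degree$exclude_unregulated)
    emit(.write_tsv(as.data.frame(ind), pfx("in_degree_dist.tsv")))
    outd <- out_degree_distribution(dt, bin_width = config$degree$bin_width)
    emit(.write_tsv(as.data.frame(outd), pfx("out_degree_dist.tsv")))

    n_tf_avail <- sum(dt$out_degree >= 1)
    k <- min(config$degree$rank_k, n_tf_avail)
    for (end in c("top", "bottom")) {
      rk <- stage(paste0(nm, "/rank_", end), rank_tfs(dt, k = k, end = end))
      emit(.write_tsv(rk$records, pfx(paste0("tfs_", end, ".tsv"))))
    }

    if (!is.null(annotations)) {
      bins_cd <- stage(paste0(nm, "/functional"), {
        reg <- dt[dt$in_degree >= 1, ]
        known <- reg$node %in% names(annotations)
        cont <- base::table(
          factor(reg$in_degree[known], levels = sort(unique(reg$in_degree))),
          annotations[reg$node[known]])
        cont <- matrix(as.integer(cont), nrow = nrow(cont),
                       dimnames = dimnames(cont))
        bins <- chi_square_bin_merge(cont, alpha = config$chi2$alpha,
                                     min_expected = config$chi2$min_expected)
        list(bins = bins, cd = category_distribution(dt, annotations, bins))
      })
      emit(.write_tsv(as.data.frame(bins_cd$bins), pfx("in_degree_bins.tsv")))
      cd <- bins_cd$cd
      long <- data.frame(
        category = rep(rownames(cd$counts), ncol(cd$counts)),
        bin = rep(colnames(cd$counts), each = nrow(cd$counts)),
        count = as.integer(cd$counts), pct = as.numeric(cd$pct),
        stringsAsFactors = FALSE)
      emit(.write_tsv(long, pfx("category_bins.tsv")))
    }

    mp <- stage(paste0(nm, "/motifs"), motif_profile(
      net, R = config$motifs$R, base_seed = config$motifs$seed,
      swap_factor = config$motifs$swap_factor,
      preserve_mutual = config$motifs$preserve_mutual,
      min_count = config$motifs$min_count))
    emit(.write_tsv(mp$sp, pfx("motif_sp.tsv")))
    emit(.write_tsv(mp$z, pfx("motif_z.tsv")))
  }
  emit(.write_tsv(do.call(rbind, unname(summary_rows)),
                  file.path(config$out_dir, "summary.tsv")))

  cfg_json <- tempfile(fileext = ".json")
  .write_json(unclass(config), cfg_json)
  config_hash <- unname(tools::md5sum(cfg_json))
  unlink(cfg_json)
  manifest <- list(
    config_hash = config_hash,
    seeds = list(motifs = config$motifs$seed),
    outputs = lapply(sort(outputs), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  .write_json(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
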