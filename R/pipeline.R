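#' Pipeline configuration
#'
#' Collects every stage's inputs and thresholds in one serialisable object.
#' Either `simulate` is a [sim_config()] (the pipeline generates its own
#' inputs) or `inputs` names the on-disk files (per-class FASTA and count
#' TSVs, sample map, mapped totals, optional GMT).
#'
#' @param out_dir Output directory.
#' @param simulate Optional [sim_config()].
#' @param inputs Optional named list of paths: `fasta` (named by class),
#'   `counts` (named by class), `sample_map`, `mapped_totals`, `gmt`.
#' @param thresholds A [de_thresholds()].
#' @param cutoffs Target-prediction cutoffs, `list(context = 50, energy = -10)`.
#' @param top_k Hub-ranking size.
#' @param share_mrna Quad rule: require the shared mRNA (default `TRUE`).
#' @param require_anticorrelation Direction rule for edges (default `TRUE`).
#' @param predict_de_only Restrict target prediction to DE features (a pure
#'   optimisation: non-DE features can never form edges; default `TRUE`).
#' @param gmt Optional GMT path for enrichment.
#' @param seed Integer seed for any stage randomness.
#' @param log_level `"quiet"` or `"info"`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, inputs = NULL,
                            thresholds = de_thresholds(),
                            cutoffs = list(context = 50, energy = -10),
                            top_k = 10L, share_mrna = TRUE,
                            require_anticorrelation = TRUE,
                            predict_de_only = TRUE, gmt = NULL,
                            seed = 1L, log_level = "info") {
  if (is.null(simulate) && is.null(inputs)) {
    stop_domain("pipeline_config needs either a sim_config or input paths")
  }
  if (!all(is.finite(c(cutoffs$context, cutoffs$energy)))) {
    stop_domain("cutoffs must be finite")
  }
  structure(list(out_dir = out_dir, simulate = simulate, inputs = inputs,
                 thresholds = thresholds, cutoffs = cutoffs,
                 top_k = as.integer(top_k), share_mrna = share_mrna,
                 require_anticorrelation = require_anticorrelation,
                 predict_de_only = predict_de_only, gmt = gmt,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Serialise / deserialise a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `read_config` returns the reconstructed `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$simulate)) {
    x$simulate <- unclass(x$simulate)
    # named vectors must become objects, not bare arrays, to keep their names
    x$simulate$n_features <- as.list(x$simulate$n_features)
    x$simulate$de_fraction <- as.list(x$simulate$de_fraction)
  }
  x$thresholds <- unclass(x$thresholds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- if (!is.null(x$simulate)) {
    x$simulate$n_features <- unlist(x$simulate$n_features)
    x$simulate$de_fraction <- unlist(x$simulate$de_fraction)
    do.call(sim_config, x$simulate)
  }
  thr <- do.call(de_thresholds, as.list(x$thresholds))
  pipeline_config(out_dir = x$out_dir, simulate = sim, inputs = x$inputs,
                  thresholds = thr, cutoffs = as.list(x$cutoffs),
                  top_k = x$top_k, share_mrna = x$share_mrna,
                  require_anticorrelation = x$require_anticorrelation,
                  predict_de_only = x$predict_de_only, gmt = x$gmt,
                  seed = x$seed, log_level = x$log_level %||% "info")
}

pipe_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message("[spongenet] ", ...)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    sim_dir <- file.path(config$out_dir, "simulated")
    write_dataset(sim, sim_dir)
    return(list(sequences = sim$sequences, topology = sim$topology,
                counts = sim$counts, sample_map = sim$sample_map,
                mapped_totals = sim$mapped_totals, truth = sim$truth))
  }
  ins <- config$inputs
  sm <- read_sample_map(ins$sample_map)
  totals <- read_mapped_totals(ins$mapped_totals)
  counts <- list(); sequences <- list(); topology <- c()
  for (cl in RNA_CLASSES) {
    if (!is.null(ins$counts[[cl]])) {
      counts[[cl]] <- read_counts(ins$counts[[cl]], sm, class = cl)
    }
    if (!is.null(ins$fasta[[cl]])) {
      fa <- read_fasta(ins$fasta[[cl]])
      sequences[[cl]] <- setNames(fa$seq, fa$id)
      topology[cl] <- if (any(fa$topology == "circular")) "circular" else "linear"
    }
  }
  list(sequences = sequences, topology = topology, counts = counts,
       sample_map = sm, mapped_totals = totals, truth = NULL)
}

#' Run the full ceRNA pipeline
#'
#' Stages: (optional) simulate, differential expression per class, dual
#' target prediction with intersection filtering, direction-consistent
#' network assembly with integration and hub ranking, and (when a GMT is
#' configured) hypergeometric enrichment. Every stage's table is written
#' under `out_dir` with a provenance comment line; a manifest of all files
#' is returned and written as JSON. Identical config + seed gives
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Manifest `data.frame` (`file`, `rows`), invisibly also written to
#'   `manifest.json`. The full result objects are attached as attributes
#'   `de`, `pairs`, `network`, `hubs`, `enrichment`, `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  set.seed(config$seed)
  prov <- provenance_line("spongenet", list(
    seed = config$seed, lfc = config$thresholds$lfc,
    alpha = config$thresholds$alpha_default,
    alpha_mirna = config$thresholds$alpha_mirna,
    context_cutoff = config$cutoffs$context,
    energy_cutoff = config$cutoffs$energy))
  manifest <- list()
  note <- function(file, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, rows = rows, stringsAsFactors = FALSE)
  }
  emit <- function(df, file) {
    write_tsv_commented(df, file.path(config$out_dir, file), prov)
    note(file, nrow(df))
  }

  pipe_log(config, "loading inputs")
  dat <- load_pipeline_inputs(config)

  pipe_log(config, "differential expression")
  de <- tryCatch(
    call_differential(dat$counts, dat$sample_map, dat$mapped_totals,
                      config$thresholds),
    error = function(e) stop("stage diffexpr failed: ", conditionMessage(e),
                             call. = FALSE))
  for (cl in names(dat$counts)) {
    emit(de[de$class == cl, , drop = FALSE], paste0("de_", tolower(cl), ".tsv"))
  }

  pipe_log(config, "target prediction")
  pairs <- tryCatch({
    de_ids <- de$feature_id[de$direction != "ns"]
    mirnas <- dat$sequences$miRNA
    if (config$predict_de_only) mirnas <- mirnas[names(mirnas) %in% de_ids]
    res <- list()
    for (cl in TARGET_CLASSES) {
      tseqs <- dat$sequences[[cl]]
      if (is.null(tseqs) || !length(tseqs) || !length(mirnas)) next
      if (config$predict_de_only) tseqs <- tseqs[names(tseqs) %in% de_ids]
      if (!length(tseqs)) next
      res[[cl]] <- predict_targets(
        mirnas, tseqs, target_class = cl,
        topology = if (identical(unname(dat$topology[cl]), "circular"))
          "circular" else "linear",
        cutoffs = config$cutoffs)
    }
    if (length(res)) do.call(rbind, res) else
      predict_targets(character(0), character(0))
  }, error = function(e) stop("stage targetpred failed: ", conditionMessage(e),
                              call. = FALSE))
  rownames(pairs) <- NULL
  emit(pairs, "target_pairs.tsv")

  pipe_log(config, "network assembly")
  network <- tryCatch({
    edges <- build_edges(de, pairs, config$require_anticorrelation)
    triads <- assemble_triads(edges)
    integ <- integrate_networks(triads, config$share_mrna)
    full <- cerna_network(edges, triads, integ$quads)
    list(full = full, integrated = integ$network, triads = triads,
         quads = integ$quads)
  }, error = function(e) stop("stage cernet failed: ", conditionMessage(e),
                              call. = FALSE))
  emit(network$full$edges, "edges.tsv")
  emit(network$triads, "triads.tsv")
  emit(network$quads, "quads.tsv")
  files <- export_network(network$full, config$out_dir, prefix = "network")
  for (f in files) note(basename(f), NA_integer_)
  hubs <- hub_ranking(network$full, config$top_k)
  emit(hubs, "hub_ranking.tsv")

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    pipe_log(config, "enrichment")
    enrichment <- tryCatch({
      terms <- read_gmt(config$gmt)
      universe <- de$feature_id[de$class == "mRNA"]
      coll <- term_collection(terms, universe)
      withCallingHandlers(
        enrich_terms(de[de$class == "mRNA", , drop = FALSE], coll,
                     lfc = config$thresholds$lfc,
                     alpha = config$thresholds$alpha_default),
        warning = function(w) invokeRestart("muffleWarning"))
    }, error = function(e) stop("stage enrich failed: ", conditionMessage(e),
                                call. = FALSE))
    emit(enrichment, "enrichment.tsv")
  }

  out <- do.call(rbind, manifest)
  jsonlite::write_json(out, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  attr(out, "de") <- de
  attr(out, "pairs") <- pairs
  attr(out, "network") <- network
  attr(out, "hubs") <- hubs
  attr(out, "enrichment") <- enrichment
  attr(out, "truth") <- dat$truth
  invisible(out)
}
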