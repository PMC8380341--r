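#' Build direction-consistent ceRNA edges
#'
#' One edge per passing target pair whose miRNA and partner are both
#' differentially expressed with opposite directions (the sponge hypothesis:
#' a miRNA and the transcripts it represses move in opposite directions).
#' Non-significant (`ns`) features never enter the network.
#'
#' @param de_records DE table from [call_differential()] covering every
#'   feature referenced by `target_pairs`.
#' @param target_pairs Pair table from [predict_targets()].
#' @param require_anticorrelation Set `FALSE` for a permissive exploratory
#'   mode that only requires both endpoints to be DE.
#' @return `data.frame` of edges: `mirna_id`, `mirna_direction`,
#'   `partner_id`, `partner_class`, `partner_direction`, `site_type`,
#'   `context_score`, `energy`.
#' @export
build_edges <- function(de_records, target_pairs, require_anticorrelation = TRUE) {
  empty <- data.frame(mirna_id = character(0), mirna_direction = character(0),
                      partner_id = character(0), partner_class = character(0),
                      partner_direction = character(0), site_type = character(0),
                      context_score = numeric(0), energy = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(target_pairs) == 0L) return(empty)
  missing <- setdiff(c(target_pairs$mirna_id, target_pairs$target_id),
                     de_records$feature_id)
  if (length(missing)) {
    stop_domain("target pairs reference features absent from the DE table: ",
                paste(head(missing, 5), collapse = ", "))
  }
  dirs <- setNames(de_records$direction, de_records$feature_id)
  tp <- target_pairs[target_pairs$passes, , drop = FALSE]
  if (nrow(tp) == 0L) return(empty)
  md <- unname(dirs[tp$mirna_id])
  pd <- unname(dirs[tp$target_id])
  keep <- md %in% c("up", "down") & pd %in% c("up", "down")
  if (require_anticorrelation) keep <- keep & md != pd
  tp <- tp[keep, , drop = FALSE]
  out <- data.frame(mirna_id = tp$mirna_id, mirna_direction = md[keep],
                    partner_id = tp$target_id, partner_class = tp$class,
                    partner_direction = pd[keep], site_type = tp$site_type,
                    context_score = tp$context_score, energy = tp$energy,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$partner_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble sponge-miRNA-mRNA triads from edges
#'
#' Joins every sponge edge (lncRNA or circRNA partner) with every mRNA edge
#' of the same miRNA whose sponge and mRNA share a direction, yielding the
#' `up-down-up` / `down-up-down` patterns.
#'
#' @param edges Edge table from [build_edges()].
#' @return `data.frame`: `sponge_id`, `sponge_class`, `sponge_direction`,
#'   `mirna_id`, `mirna_direction`, `mrna_id`, `mrna_direction`, `pattern`.
#' @export
assemble_triads <- function(edges) {
  empty <- data.frame(sponge_id = character(0), sponge_class = character(0),
                      sponge_direction = character(0), mirna_id = character(0),
                      mirna_direction = character(0), mrna_id = character(0),
                      mrna_direction = character(0), pattern = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) return(empty)
  sponge <- edges[edges$partner_class %in% c("lncRNA", "circRNA"), , drop = FALSE]
  mrna <- edges[edges$partner_class == "mRNA", , drop = FALSE]
  if (nrow(sponge) == 0L || nrow(mrna) == 0L) return(empty)
  tri <- merge(
    data.frame(sponge_id = sponge$partner_id, sponge_class = sponge$partner_class,
               sponge_direction = sponge$partner_direction,
               mirna_id = sponge$mirna_id, mirna_direction = sponge$mirna_direction,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = mrna$mirna_id, mrna_id = mrna$partner_id,
               mrna_direction = mrna$partner_direction, stringsAsFactors = FALSE),
    by = "mirna_id")
  tri <- tri[tri$sponge_direction == tri$mrna_direction, , drop = FALSE]
  if (nrow(tri) == 0L) return(empty)
  tri$pattern <- ifelse(tri$sponge_direction == "up", "up-down-up", "down-up-down")
  tri <- tri[c("sponge_id", "sponge_class", "sponge_direction", "mirna_id",
               "mirna_direction", "mrna_id", "mrna_direction", "pattern")]
  tri <- unique(tri)
  tri <- tri[order(tri$sponge_id, tri$mirna_id, tri$mrna_id), , drop = FALSE]
  rownames(tri) <- NULL
  tri
}

#' Integrate lncRNA- and circRNA-sponge networks
#'
#' A quad joins one lncRNA triad and one circRNA triad that share both the
#' miRNA and the mRNA (set `share_mrna = FALSE` for the permissive
#' miRNA-only rule). The integrated network is the union graph of all
#' contributing triads' nodes and edges.
#'
#' @param triads Triad table from [assemble_triads()] (both sponge classes).
#' @param share_mrna Require the shared mRNA as well as the shared miRNA.
#' @return List with `quads` (`lncRNA_id`, `circRNA_id`, `mirna_id`,
#'   `mrna_id`, `pattern`) and `network` (a `cerna_network`).
#' @export
integrate_networks <- function(triads, share_mrna = TRUE) {
  lnc <- triads[triads$sponge_class == "lncRNA", , drop = FALSE]
  circ <- triads[triads$sponge_class == "circRNA", , drop = FALSE]
  by_cols <- if (share_mrna) c("mirna_id", "mrna_id") else "mirna_id"
  quads <- merge(
    data.frame(lncRNA_id = lnc$sponge_id, mirna_id = lnc$mirna_id,
               mrna_id = lnc$mrna_id, pattern = lnc$pattern,
               stringsAsFactors = FALSE),
    data.frame(circRNA_id = circ$sponge_id, mirna_id = circ$mirna_id,
               circ_mrna_id = circ$mrna_id, stringsAsFactors = FALSE),
    by.x = by_cols[1], by.y = "mirna_id")
  if (share_mrna) {
    quads <- quads[quads$mrna_id == quads$circ_mrna_id, , drop = FALSE]
  }
  quads <- unique(quads[c("lncRNA_id", "circRNA_id", "mirna_id", "mrna_id",
                          "pattern")])
  quads <- quads[order(quads$lncRNA_id, quads$circRNA_id, quads$mirna_id,
                       quads$mrna_id), , drop = FALSE]
  rownames(quads) <- NULL
  list(quads = quads, network = network_from_triads(triads, quads))
}

# Union graph of the nodes and edges of a triad set.
network_from_triads <- function(triads, quads = NULL) {
  if (nrow(triads) == 0L) {
    return(cerna_network(
      edges = data.frame(mirna_id = character(0), mirna_direction = character(0),
                         partner_id = character(0), partner_class = character(0),
                         partner_direction = character(0), stringsAsFactors = FALSE),
      triads = triads, quads = quads))
  }
  e1 <- data.frame(mirna_id = triads$mirna_id,
                   mirna_direction = triads$mirna_direction,
                   partner_id = triads$sponge_id,
                   partner_class = triads$sponge_class,
                   partner_direction = triads$sponge_direction,
                   stringsAsFactors = FALSE)
  e2 <- data.frame(mirna_id = triads$mirna_id,
                   mirna_direction = triads$mirna_direction,
                   partner_id = triads$mrna_id, partner_class = "mRNA",
                   partner_direction = triads$mrna_direction,
                   stringsAsFactors = FALSE)
  cerna_network(unique(rbind(e1, e2)), triads, quads)
}

#' Construct a ceRNA network container
#'
#' @param edges Edge table (`mirna_id`, `mirna_direction`, `partner_id`,
#'   `partner_class`, `partner_direction`, optional evidence columns).
#' @param triads,quads Optional triad/quad tables carried along.
#' @return A `cerna_network`: `nodes` (id, class, direction, degree),
#'   `edges`, `triads`, `quads`. Degree counts incident edges.
#' @export
cerna_network <- function(edges, triads = NULL, quads = NULL) {
  edges <- unique(edges)
  edges <- edges[order(edges$mirna_id, edges$partner_id), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (nrow(edges)) {
    unique(rbind(
      data.frame(id = edges$mirna_id, class = "miRNA",
                 direction = edges$mirna_direction, stringsAsFactors = FALSE),
      data.frame(id = edges$partner_id, class = edges$partner_class,
                 direction = edges$partner_direction, stringsAsFactors = FALSE)))
  } else {
    data.frame(id = character(0), class = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(nodes)) {
    deg <- table(c(edges$mirna_id, edges$partner_id))
    nodes$degree <- as.integer(deg[nodes$id])
    nodes <- nodes[order(nodes$id), , drop = FALSE]
    rownames(nodes) <- NULL
  } else {
    nodes <- data.frame(id = character(0), class = character(0),
                        direction = character(0), degree = integer(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, triads = triads, quads = quads),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("ceRNA network: %d nodes, %d edges, %d triads, %d quads\n",
              nrow(x$nodes), nrow(x$edges),
              if (is.null(x$triads)) 0L else nrow(x$triads),
              if (is.null(x$quads)) 0L else nrow(x$quads)))
  invisible(x)
}

#' Rank hub mRNAs by distinct-miRNA degree
#'
#' @param network A `cerna_network`.
#' @param top_k Number of top mRNAs to return (>= 1).
#' @return `data.frame` `mrna_id`, `degree`, sorted by degree descending,
#'   ties broken lexicographically by id.
#' @export
hub_ranking <- function(network, top_k = 10L) {
  stopifnot(inherits(network, "cerna_network"))
  if (top_k < 1L) stop_domain("top_k must be >= 1")
  e <- network$edges[network$edges$partner_class == "mRNA", , drop = FALSE]
  if (nrow(e) == 0L) {
    return(data.frame(mrna_id = character(0), degree = integer(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- unique(e[c("partner_id", "mirna_id")])
  deg <- table(pairs$partner_id)
  out <- data.frame(mrna_id = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_k)
}

edge_interaction <- function(partner_class) {
  c(mRNA = "mir_mrna", lncRNA = "mir_lnc", circRNA = "mir_circ")[partner_class]
}

#' Export a ceRNA network in Cytoscape-readable formats
#'
#' `sif` writes `source<TAB>interaction<TAB>target` lines with interaction
#' in `{mir_mrna, mir_lnc, mir_circ}`; `graphml` (via igraph) carries class,
#' direction, and degree as node attributes; `tsv` writes node and edge
#' tables (plus triads/quads when present). Output ordering is deterministic.
#'
#' @param network A `cerna_network`.
#' @param out_dir Output directory.
#' @param formats Subset of `c("sif", "graphml", "tsv")`.
#' @param prefix File-name prefix (default `"network"`).
#' @return Character vector of written paths, invisibly.
#' @export
export_network <- function(network, out_dir,
                           formats = c("sif", "graphml", "tsv"),
                           prefix = "network") {
  stopifnot(inherits(network, "cerna_network"))
  bad <- setdiff(formats, c("sif", "graphml", "tsv"))
  if (length(bad)) stop_domain("unknown export format: ", paste(bad, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  if ("sif" %in% formats) {
    p <- file.path(out_dir, paste0(prefix, ".sif"))
    lines <- if (nrow(network$edges)) {
      paste(network$edges$mirna_id,
            edge_interaction(network$edges$partner_class),
            network$edges$partner_id, sep = "\t")
    } else character(0)
    writeLines(lines, p)
    written <- c(written, p)
  }
  if ("graphml" %in% formats) {
    p <- file.path(out_dir, paste0(prefix, ".graphml"))
    g <- as_igraph(network)
    igraph::write_graph(g, p, format = "graphml")
    written <- c(written, p)
  }
  if ("tsv" %in% formats) {
    pn <- file.path(out_dir, paste0(prefix, "_nodes.tsv"))
    pe <- file.path(out_dir, paste0(prefix, "_edges.tsv"))
    write_tsv_commented(network$nodes, pn)
    write_tsv_commented(network$edges, pe)
    written <- c(written, pn, pe)
    if (!is.null(network$triads)) {
      pt <- file.path(out_dir, paste0(prefix, "_triads.tsv"))
      write_tsv_commented(network$triads, pt)
      written <- c(written, pt)
    }
    if (!is.null(network$quads)) {
      pq <- file.path(out_dir, paste0(prefix, "_quads.tsv"))
      write_tsv_commented(network$quads, pq)
      written <- c(written, pq)
    }
  }
  invisible(written)
}

#' Convert a ceRNA network to an igraph graph
#'
#' @param network A `cerna_network`.
#' @return An undirected `igraph` graph with node attributes `class`,
#'   `direction`, `degree` and edge attribute `interaction`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  if (nrow(network$nodes) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  edges_df <- data.frame(from = network$edges$mirna_id,
                         to = network$edges$partner_id,
                         interaction = edge_interaction(network$edges$partner_class),
                         stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges_df, directed = FALSE,
                                vertices = network$nodes)
}

#' Read a SIF file back into an edge list
#'
#' @param path SIF file path.
#' @return `data.frame` with `source`, `interaction`, `target`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(source = character(0), interaction = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop_domain("malformed SIF line")
  data.frame(source = vapply(parts, `[`, "", 1),
             interaction = vapply(parts, `[`, "", 2),
             target = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE)
}
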