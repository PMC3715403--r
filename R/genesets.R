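# Pathway and protein-interaction tools over user-supplied gene-set and
# edge-list files. Gene matching is by symbol string after uppercasing; no
# alias resolution is attempted (aliasing is a data problem upstream of
# this package).

#' Read a gene-set catalog
#'
#' Two-column TSV, one `set_id<TAB>gene` pair per line.
#'
#' @param path File path.
#' @return data.frame with `set_id` and `gene` (uppercased), plus the file
#'   checksum as an attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) vardb_stop(sprintf("gene-set file not found: %s", path), "vardb_io_error")
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("set_id", "gene"), comment.char = "#",
                   quote = "")
  df$gene <- toupper(df$gene)
  df <- df[nzchar(df$set_id) & nzchar(df$gene), ]
  rownames(df) <- NULL
  attr(df, "checksum") <- unname(tools::md5sum(path))
  df
}

#' Read a protein-interaction edge list
#'
#' Two-column TSV of gene pairs; builds an undirected simple graph
#' (self-loops and duplicate edges dropped, symbols uppercased).
#'
#' @param path File path.
#' @return An igraph graph.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) vardb_stop(sprintf("interaction file not found: %s", path), "vardb_io_error")
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("gene_a", "gene_b"), comment.char = "#", quote = "")
  g <- igraph::graph_from_edgelist(as.matrix(cbind(toupper(df$gene_a),
                                                   toupper(df$gene_b))),
                                   directed = FALSE)
  igraph::simplify(g)
}

# variants at which `sample` carries >= 1 alternate allele and whose
# primary-impact gene meets the severity floor
qualifying_variants <- function(session, sample, min_severity) {
  if (!sample %in% names(session$sample_index)) {
    vardb_stop(sprintf("unknown sample '%s' (known: %s)", sample,
                       paste(names(session$sample_index), collapse = ", ")),
               "vardb_sample_error")
  }
  idx <- session$sample_index[[sample]]
  min_rank <- severity_rank(min_severity)
  rows <- fetch_variants(session)
  carrier <- vapply(rows$gt_types, function(g) {
    g[idx] %in% c(gt_type_codes[["HET"]], gt_type_codes[["HOM_ALT"]])
  }, logical(1))
  keep <- which(carrier & !is.na(rows$gene) & !is.na(rows$impact_severity) &
                  severity_rank(rows$impact_severity) >= min_rank)
  rows[keep, c("variant_id", "chrom", "start", "ref", "alt", "gene", "impact_severity")]
}

#' Map one sample's functional variants onto gene sets
#'
#' One row per (variant, set) where the sample carries at least one
#' alternate allele at a variant whose primary-impact gene belongs to the
#' set and whose severity is at least `min_severity`.
#'
#' @param session A `vardb_session` (or database path).
#' @param sample Sample name.
#' @param catalog data.frame from [read_gene_sets()].
#' @param min_severity Minimum primary-impact severity (default `"MED"`).
#' @return data.frame with `variant_id`, `gene`, `set_id` (plus
#'   coordinates).
#' @export
sample_pathways <- function(session, sample, catalog, min_severity = "MED") {
  session <- as_session(session)
  on.exit(release_session(session), add = TRUE)
  qv <- qualifying_variants(session, sample, min_severity)
  qv$gene_uc <- toupper(qv$gene)
  hit <- merge(qv, catalog, by.x = "gene_uc", by.y = "gene")
  hit <- hit[order(hit$variant_id, hit$set_id), ]
  out <- data.frame(variant_id = hit$variant_id, chrom = hit$chrom, start = hit$start,
                    gene = hit$gene, set_id = hit$set_id,
                    sample = rep(sample, nrow(hit)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Interaction-network neighborhoods of one sample's functional variants
#'
#' For every gene where the sample has a qualifying variant, reports the
#' genes at shortest-path distance 1..k in the interaction graph that also
#' harbor qualifying variants in the same sample.
#'
#' @inheritParams sample_pathways
#' @param graph igraph graph from [read_interactions()].
#' @param k Neighborhood radius (shortest-path distance), `k >= 1`.
#' @return data.frame with `seed_gene`, `order` (distance), `neighbor_gene`
#'   and the comma-joined `variants` in the neighbor gene. Symmetric: if
#'   `(g1, d, g2)` is reported, so is `(g2, d, g1)`.
#' @export
sample_interactions <- function(session, sample, graph, k = 1L, min_severity = "MED") {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1L) {
    vardb_stop("k must be an integer >= 1", "vardb_config_error")
  }
  session <- as_session(session)
  on.exit(release_session(session), add = TRUE)
  qv <- qualifying_variants(session, sample, min_severity)
  qv$gene_uc <- toupper(qv$gene)
  genes <- sort(unique(qv$gene_uc))
  present <- intersect(genes, igraph::V(graph)$name)
  out <- list()
  if (length(present) >= 2L) {
    d <- igraph::distances(graph, v = present, to = present)
    for (g1 in present) for (g2 in present) {
      dist <- d[g1, g2]
      if (g1 == g2 || !is.finite(dist) || dist > k) next
      vids <- sort(qv$variant_id[qv$gene_uc == g2])
      out[[length(out) + 1L]] <- data.frame(
        sample = sample, seed_gene = g1, order = as.integer(dist),
        neighbor_gene = g2, variants = paste(vids, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sample = character(0), seed_gene = character(0),
                      order = integer(0), neighbor_gene = character(0),
                      variants = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
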