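# Comparable Pearson-correlation (PCC) networks matched to a PMI network.
#
# Three constructions make a PCC network "comparable" to a given PMI network:
# type 1 matches its edge count, type 2 its node coverage, and type 3 asks,
# edge by edge, whether a third gene dominates the pair in absolute PCC.
# Edges present in the type-3 network but absent from the PMI network are the
# PCC-only edges.

#' Pairwise Pearson correlation matrix of an expression matrix
#'
#' @param expr numeric genes-by-samples matrix.
#' @return symmetric correlation matrix with unit diagonal. Zero-variance
#'   genes yield `NA` rows/columns and are flagged in the
#'   `"zero_variance"` attribute (with a warning).
#' @export
pcc_matrix <- function(expr) {
  stopifnot_named_matrix(expr, "expr")
  if (ncol(expr) < 2L) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(expr, 1L, stats::sd)
  zv <- rownames(expr)[sds == 0]
  if (length(zv)) {
    warning("zero-variance gene(s): ", paste(zv, collapse = ", "),
            call. = FALSE)
  }
  m <- suppressWarnings(stats::cor(t(expr)))
  diag(m) <- 1
  attr(m, "zero_variance") <- zv
  m
}

# All candidate pairs within the PMI gene set ranked by descending |PCC|,
# ties broken lexicographically by canonical pair name (deterministic).
ranked_pcc_pairs <- function(pcc, genes) {
  genes <- intersect(sort(genes), rownames(pcc))
  pairs <- all_pairs(genes)
  if (nrow(pairs) == 0) {
    pairs$abs_pcc <- numeric(0)
    return(pairs)
  }
  pairs$abs_pcc <- abs(pcc[cbind(pairs$gene_a, pairs$gene_b)])
  pairs <- pairs[!is.na(pairs$abs_pcc), , drop = FALSE]
  pairs[order(-pairs$abs_pcc, pairs$gene_a, pairs$gene_b), , drop = FALSE]
}

#' Comparable PCC networks (types 1-3) and PCC-only edges
#'
#' `pcc_type1()` takes gene pairs within the PMI gene set in descending
#' absolute Pearson correlation until it has the same number of edges as the
#' PMI network. `pcc_type2()` takes the shortest such prefix whose endpoints
#' cover every node of the PMI network. `pcc_type3()` considers each PMI edge
#' (G1, G2) separately: any third gene G3 of the PMI gene set whose absolute
#' correlations with both G1 and G2 exceed |PCC(G1, G2)| contributes the edges
#' (G3, G1) and (G3, G2); the returned network is the union of the contributed
#' edges and the PMI edge set. `pcc_only_edges()` extracts the type-3 edges
#' absent from the PMI network.
#'
#' Ties in |PCC| are broken lexicographically by canonical pair name so
#' repeated runs are identical. Zero-variance genes are excluded from
#' candidate sets with a warning (raised by [pcc_matrix()]).
#'
#' @param expr numeric genes-by-samples matrix covering the PMI genes.
#' @param pmi_net a PMI network from [pmi_network()].
#' @return a `"pminet_network"` with method tag `PCC1`, `PCC2` or `PCC3`;
#'   edge strengths are absolute Pearson correlations. For `pcc_type3()` each
#'   edge carries an `origin` column (`"both"` for PMI edges, `"pcc_only"`
#'   otherwise). `pcc_only_edges()` returns a data.frame of pairs.
#' @export
pcc_type1 <- function(expr, pmi_net) {
  pcc <- pcc_matrix(expr)
  check_pmi_genes(pmi_net, rownames(expr))
  ranked <- ranked_pcc_pairs(pcc, pmi_net$genes)
  k <- n_edges(pmi_net)
  top <- utils::head(ranked, k)
  new_network(pmi_net$genes,
              data.frame(gene_a = top$gene_a, gene_b = top$gene_b,
                         strength = top$abs_pcc, stringsAsFactors = FALSE),
              method = "PCC1")
}

#' @rdname pcc_type1
#' @export
pcc_type2 <- function(expr, pmi_net) {
  pcc <- pcc_matrix(expr)
  check_pmi_genes(pmi_net, rownames(expr))
  target <- network_nodes(pmi_net)
  ranked <- ranked_pcc_pairs(pcc, pmi_net$genes)
  n_take <- 0L
  if (length(target) > 0) {
    covered <- character(0)
    for (i in seq_len(nrow(ranked))) {
      covered <- union(covered, c(ranked$gene_a[i], ranked$gene_b[i]))
      if (all(target %in% covered)) { n_take <- i; break }
    }
    if (n_take == 0L) {
      stop("PCC ranking cannot cover the PMI nodes", call. = FALSE)
    }
  }
  top <- utils::head(ranked, n_take)
  new_network(pmi_net$genes,
              data.frame(gene_a = top$gene_a, gene_b = top$gene_b,
                         strength = top$abs_pcc, stringsAsFactors = FALSE),
              method = "PCC2")
}

#' @rdname pcc_type1
#' @export
pcc_type3 <- function(expr, pmi_net) {
  pcc <- pcc_matrix(expr)
  check_pmi_genes(pmi_net, rownames(expr))
  candidates <- setdiff(intersect(pmi_net$genes, rownames(pcc)),
                        attr(pcc, "zero_variance"))
  keys <- character(0)
  ga <- gb <- character(0)
  add_edge <- function(a, b) {
    k <- pair_key(a, b)
    if (!k %in% keys) {
      keys <<- c(keys, k)
      cp <- canonical_pair(a, b)
      ga <<- c(ga, cp[1L]); gb <<- c(gb, cp[2L])
    }
  }
  E <- pmi_net$edges
  for (e in seq_len(nrow(E))) {
    g1 <- E$gene_a[e]; g2 <- E$gene_b[e]
    base <- abs(pcc[g1, g2])
    for (g3 in setdiff(candidates, c(g1, g2))) {
      if (isTRUE(abs(pcc[g3, g1]) > base) &&
          isTRUE(abs(pcc[g3, g2]) > base)) {
        add_edge(g3, g1)
        add_edge(g3, g2)
      }
    }
    add_edge(g1, g2)   # the PMI edges themselves are part of the network
  }
  edges <- data.frame(gene_a = ga, gene_b = gb,
                      strength = if (length(ga)) abs(pcc[cbind(ga, gb)])
                                 else numeric(0),
                      stringsAsFactors = FALSE)
  edges$origin <- ifelse(pair_key(edges$gene_a, edges$gene_b) %in%
                           edge_keys(pmi_net), "both", "pcc_only")
  new_network(pmi_net$genes, edges, method = "PCC3")
}

#' @rdname pcc_type1
#' @param type3_net the type-3 comparable network from [pcc_type3()].
#' @export
pcc_only_edges <- function(type3_net, pmi_net) {
  keep <- !(edge_keys(type3_net) %in% edge_keys(pmi_net))
  out <- type3_net$edges[keep, c("gene_a", "gene_b", "strength"),
                         drop = FALSE]
  rownames(out) <- NULL
  out
}

check_pmi_genes <- function(pmi_net, expr_genes) {
  missing <- setdiff(pmi_net$genes, expr_genes)
  if (length(missing)) {
    stop("PMI genes absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}
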