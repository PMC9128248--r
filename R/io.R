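# Readers and writers for the pipeline's on-disk formats. TSV with a header
# row is the lingua franca; networks also export to Cytoscape SIF
# ("geneA pp geneB"); configuration and run manifests are JSON. Genome
# coordinates are 0-based half-open (BED dialect). Gene pairs are always
# written in canonical (sorted) order.

read_tsv_checked <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

read_gene_matrix <- function(path, what, integer_range = NULL) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) stop(what, ": need id column plus samples",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop(what, ": duplicate identifiers",
                               call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop(what, ": non-numeric cells", call. = FALSE)
  if (anyNA(m)) stop(what, ": missing values", call. = FALSE)
  rownames(m) <- ids
  if (!is.null(integer_range)) {
    if (!all(m %in% integer_range)) {
      stop(what, ": values outside ", paste(range(integer_range),
                                            collapse = ".."),
           call. = FALSE)
    }
    storage.mode(m) <- "integer"
  }
  m
}

write_gene_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write pipeline input tables
#'
#' TSV dialects: expression and CNV matrices have the identifier in the
#' first column (`gene`) and one column per sample; beta matrices use `cpg`;
#' coordinates are BED-like (`chrom`, `start`, `end`, `gene`, `score`,
#' `strand`; 0-based half-open, `start < end`); clinical tables need
#' `sample`, `time`, `event`. Duplicate identifiers, non-numeric cells and
#' malformed intervals are errors.
#'
#' @param path file path.
#' @return the typed object (matrix or data.frame); writers return the path
#'   invisibly.
#' @name pminet_io
NULL

#' @rdname pminet_io
#' @export
read_expression <- function(path) read_gene_matrix(path, "expression")

#' @rdname pminet_io
#' @param expr,cnv,beta matrix to write.
#' @export
write_expression <- function(expr, path) {
  write_gene_matrix(expr, path, "gene")
}

#' @rdname pminet_io
#' @export
read_cnv <- function(path) read_gene_matrix(path, "cnv",
                                            integer_range = -2:2)

#' @rdname pminet_io
#' @export
write_cnv <- function(cnv, path) write_gene_matrix(cnv, path, "gene")

#' @rdname pminet_io
#' @export
read_beta <- function(path) {
  m <- read_gene_matrix(path, "beta")
  if (any(m < 0 | m > 1)) stop("beta values outside [0, 1]", call. = FALSE)
  m
}

#' @rdname pminet_io
#' @export
write_beta <- function(beta, path) write_gene_matrix(beta, path, "cpg")

#' @rdname pminet_io
#' @param map CpG-to-gene mapping data.frame (`cpg`, `gene`).
#' @export
read_cpg_map <- function(path) {
  df <- read_tsv_checked(path)
  stopifnot(all(c("cpg", "gene") %in% names(df)))
  df
}

#' @rdname pminet_io
#' @export
write_cpg_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pminet_io
#' @export
read_coords <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("malformed BED: need 6 columns", call. = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "gene", "score", "strand")
  if (!is.numeric(df$start) || !is.numeric(df$end) ||
      any(df$start >= df$end)) {
    stop("malformed BED interval (need start < end)", call. = FALSE)
  }
  if (anyDuplicated(df$gene)) stop("duplicate gene names", call. = FALSE)
  df[, c("gene", "chrom", "start", "end", "strand")]
}

#' @rdname pminet_io
#' @param coords coordinate data.frame from [simulate_coords()] or
#'   [read_coords()].
#' @export
write_coords <- function(coords, path) {
  bed <- data.frame(coords$chrom, coords$start, coords$end, coords$gene,
                    0L, coords$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pminet_io
#' @export
read_clinical <- function(path) {
  df <- read_tsv_checked(path)
  check_clinical(df)
  df
}

#' @rdname pminet_io
#' @param clinical clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pminet_io
#' @export
read_pairs <- function(path) {
  df <- read_tsv_checked(path)
  stopifnot(all(c("gene_a", "gene_b") %in% names(df)))
  df
}

#' @rdname pminet_io
#' @export
read_tr <- function(path) {
  df <- read_tsv_checked(path)
  stopifnot(all(c("regulator", "class", "target") %in% names(df)))
  df
}

#' @rdname pminet_io
#' @export
read_ppi <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) stop("PPI table needs two columns", call. = FALSE)
  df
}

#' Write a network as TSV or Cytoscape SIF
#'
#' The TSV carries `gene_a`, `gene_b`, `strength`, `method`, `threshold`
#' (plus any extra edge columns such as the type-3 `origin`); the SIF uses
#' the `pp` interaction type.
#'
#' @param net a `"pminet_network"`.
#' @param path output path.
#' @param format `"tsv"` or `"sif"`.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s pp %s", net$edges$gene_a, net$edges$gene_b)
    writeLines(lines, path)
  } else {
    df <- net$edges
    df$method <- net$meta$method
    df$threshold <- net$meta$threshold
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- read_tsv_checked(path)
  stopifnot(all(c("gene_a", "gene_b", "strength") %in% names(df)))
  method <- if ("method" %in% names(df)) df$method[1L] else "PMI"
  threshold <- if ("threshold" %in% names(df)) df$threshold[1L] else
    NA_real_
  new_network(unique(c(df$gene_a, df$gene_b)),
              df[, c("gene_a", "gene_b", "strength")],
              method = method, threshold = threshold)
}

#' Write a correlation change network
#'
#' Produces an edge TSV (`gene_a`, `gene_b`, `pattern`), a node attribute
#' TSV (`gene`, `mean_stage`) and optionally a SIF with a stage color
#' attribute file: blue/green/yellow/red for edges confined to a single
#' stage 1-4, black for the always-present (`1-1-1-1`) and cancer-only
#' (`0-1-1-1`) patterns, grey otherwise.
#'
#' @param cn a `"change_network"` (filter first with
#'   [filter_inconsecutive()] if desired).
#' @param edge_path,node_path,sif_path output paths (`sif_path` optional).
#' @export
write_change_network <- function(cn, edge_path, node_path,
                                 sif_path = NULL) {
  utils::write.table(cn$edges[, c("gene_a", "gene_b", "pattern")],
                     edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  msv <- mean_stage_value(cn)
  utils::write.table(data.frame(gene = names(msv), mean_stage = msv),
                     node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sif_path)) {
    single <- c("1-0-0-0" = "blue", "0-1-0-0" = "green",
                "0-0-1-0" = "yellow", "0-0-0-1" = "red",
                "1-1-1-1" = "black", "0-1-1-1" = "black")
    color <- unname(single[cn$edges$pattern])
    color[is.na(color)] <- "grey"
    writeLines(sprintf("%s pp %s", cn$edges$gene_a, cn$edges$gene_b),
               sif_path)
    utils::write.table(data.frame(gene_a = cn$edges$gene_a,
                                  gene_b = cn$edges$gene_b,
                                  color = color),
                       paste0(sif_path, ".attrs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(edge_path)
}

#' Write a relationship table or a recall report
#'
#' `write_relationships()` emits the unified pair TSV (`gene_a`, `gene_b`,
#' `kind`, weight columns). `write_recall_report()` aggregates
#' `"recall_result"` objects into one table with a row per network/
#' relationship/weight-variant combination.
#'
#' @param rel a `"relationship_table"`.
#' @param results list of `"recall_result"` objects.
#' @param path output path.
#' @export
write_relationships <- function(rel, path) {
  df <- as.data.frame(rel)
  df$kind <- attr(rel, "kind")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_relationships
#' @export
write_recall_report <- function(results, path) {
  rows <- lapply(results, function(r) {
    data.frame(network = r$network, kind = r$kind,
               variant = names(r$zscores),
               n_edges = r$n_edges, recalled = r$recall_count,
               observed = r$observed, null_mean = r$null_mean,
               null_sd = r$null_sd, z = r$zscores,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records parameters, seeds and the package version so a pipeline run can
#' be reproduced from its manifest.
#'
#' @param params named list of run parameters.
#' @param path output path.
#' @export
write_manifest <- function(params, path) {
  params$pminet_version <-
    as.character(utils::packageVersion("pminet"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
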