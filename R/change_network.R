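# Correlation change network: the union of four single-stage networks along
# a disease progression. Each edge carries a 4-bit existence pattern (e.g.
# "0-1-1-1" = present in the three cancer stages but not in normal); each
# node a mean stage value, the average of the stage numbers (1-4) over its
# single-stage edge incidences.

#' Combine four single-stage networks into a correlation change network
#'
#' The stage order is normal, stage 1, stage 2, stage 3, with stage numbers
#' 1-4. The combined edge set is the union of the stage edge sets; bit i of
#' an edge's existence pattern is set iff the edge occurs in the stage-i
#' network.
#'
#' @param stage_nets list of exactly 4 `"pminet_network"` objects over the
#'   same gene universe, in progression order.
#' @param stage_labels labels for the four stages.
#' @return object of class `"change_network"`: list with `stages`, `genes`
#'   and `edges` (data.frame `gene_a`, `gene_b`, logical `s1..s4`, `pattern`
#'   string).
#' @examples
#' # an edge present only in the cancer stages gets pattern "0-1-1-1"
#' @export
combine_stages <- function(stage_nets,
                           stage_labels = c("normal", "s1", "s2", "s3")) {
  if (length(stage_nets) != 4L) {
    stop("exactly 4 stage networks are required", call. = FALSE)
  }
  genes <- stage_nets[[1L]]$genes
  for (net in stage_nets[-1L]) {
    if (!identical(net$genes, genes)) {
      stop("stage networks have mismatched gene universes", call. = FALSE)
    }
  }
  keysets <- lapply(stage_nets, edge_keys)
  all_keys <- sort(unique(unlist(keysets)))
  parts <- do.call(rbind, strsplit(all_keys, "|", fixed = TRUE))
  member <- vapply(keysets, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, ncol = 4L,
                   dimnames = list(NULL, paste0("s", 1:4)))
  edges <- data.frame(
    gene_a = if (length(all_keys)) parts[, 1L] else character(),
    gene_b = if (length(all_keys)) parts[, 2L] else character(),
    stringsAsFactors = FALSE)
  edges <- cbind(edges, as.data.frame(member))
  edges$pattern <- apply(member, 1L, function(b) {
    paste(as.integer(b), collapse = "-")
  })
  if (nrow(edges) == 0) edges$pattern <- character(0)
  structure(list(stages = stage_labels, genes = genes, edges = edges),
            class = "change_network")
}

#' Drop edges whose stage occurrences are not consecutive
#'
#' An edge whose set stages do not form one contiguous run (e.g. pattern
#' "1-0-1-0") is considered an unstable correlation and removed; contiguous
#' patterns such as "0-1-1-0" or "1-1-1-1" are kept. Idempotent.
#'
#' @param cn a `"change_network"`.
#' @return the filtered `"change_network"`.
#' @export
filter_inconsecutive <- function(cn) {
  stopifnot(inherits(cn, "change_network"))
  bits <- as.matrix(cn$edges[, paste0("s", 1:4)])
  keep <- apply(bits, 1L, function(b) {
    on <- which(b)
    length(on) > 0L && all(diff(on) == 1L)
  })
  cn$edges <- cn$edges[keep, , drop = FALSE]
  rownames(cn$edges) <- NULL
  cn
}

#' Mean stage value of genes in a change network
#'
#' For each gene, the average of the stage numbers (1-4) over every
#' (edge, stage) incidence of the gene: an edge with pattern "1-1-0-0"
#' contributes stage numbers 1 and 2 to both of its endpoints. Apply
#' [filter_inconsecutive()] first if inconsecutive edges are to be ignored.
#'
#' @param cn a `"change_network"`.
#' @param gene a single gene (must have at least one edge), or `NULL` for all
#'   genes with edges.
#' @return named numeric vector of mean stage values in `[1, 4]`.
#' @export
mean_stage_value <- function(cn, gene = NULL) {
  stopifnot(inherits(cn, "change_network"))
  bits <- as.matrix(cn$edges[, paste0("s", 1:4)])
  ga <- cn$edges$gene_a
  gb <- cn$edges$gene_b
  acc <- list()
  for (e in seq_len(nrow(bits))) {
    stages <- which(bits[e, ])
    acc[[ga[e]]] <- c(acc[[ga[e]]], stages)
    acc[[gb[e]]] <- c(acc[[gb[e]]], stages)
  }
  if (!is.null(gene)) {
    if (is.null(acc[[gene]])) {
      stop("gene has no edges in the change network: ", gene, call. = FALSE)
    }
    return(stats::setNames(mean(acc[[gene]]), gene))
  }
  vapply(acc[sort(names(acc))], mean, numeric(1))
}

#' @export
print.change_network <- function(x, ...) {
  cat(sprintf("<change network> %d genes, %d edges over stages %s\n",
              length(x$genes), nrow(x$edges),
              paste(x$stages, collapse = " -> ")))
  if (nrow(x$edges)) {
    tab <- sort(table(x$edges$pattern), decreasing = TRUE)
    cat("existence patterns:\n")
    print(tab)
  }
  invisible(x)
}
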