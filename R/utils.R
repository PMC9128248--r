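# Shared helpers: canonical gene-pair handling and small validators.

#' Canonicalize gene pairs
#'
#' Networks and relationship tables are undirected, so every gene pair is
#' stored with its two members in lexicographic order. `pair_key()` builds a
#' single string key used for set operations on pairs.
#'
#' @param a,b character vectors of gene identifiers (recycled to a common
#'   length).
#' @return `canonical_pair()` returns a two-column character matrix with the
#'   smaller identifier first; `pair_key()` returns a character vector of
#'   `"geneA|geneB"` keys.
#' @examples
#' pair_key(c("TP53", "BRCA1"), c("BRCA1", "TP53"))
#' @export
pair_key <- function(a, b) {
  cp <- canonical_pair(a, b)
  paste(cp[, 1L], cp[, 2L], sep = "|")
}

#' @rdname pair_key
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  cbind(gene_a = a, gene_b = b)
}

# All unordered pairs over a gene set, in lexicographic order.
all_pairs <- function(genes) {
  genes <- sort(unique(as.character(genes)))
  if (length(genes) < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(length(genes), 2L)
  data.frame(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]],
             stringsAsFactors = FALSE)
}

stopifnot_named_matrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop(what, " must have unique row names", call. = FALSE)
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    stop(what, " must have unique column names", call. = FALSE)
  }
  if (anyNA(m)) stop(what, " contains missing values", call. = FALSE)
  invisible(m)
}
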