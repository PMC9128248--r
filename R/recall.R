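# Matching network edges against omics-defined gene-pair relationships:
# recall counts, permutation-null Z-scores and weight comparisons.

#' Edges of a network recalled by a relationship table
#'
#' An edge is recalled when its unordered gene pair is a record of the
#' relationship table (matching is order-insensitive).
#'
#' @param net a `"pminet_network"`.
#' @param rel a `"relationship_table"`.
#' @return data.frame of the recalled pairs with the relationship's weight
#'   columns attached.
#' @export
recall_edges <- function(net, rel) {
  hit <- match(edge_keys(net), rel_keys(rel))
  out <- rel[stats::na.omit(hit), , drop = FALSE]
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Permutation Z-score for network-relationship recall
#'
#' Compares the observed number of recalled edges (and, where the
#' relationship carries weights, the summed weights of the recalled records)
#' against a permutation null: each of `n_perm` draws selects the same number
#' of gene pairs uniformly without replacement from all pairs of the
#' universe and recomputes the statistic. `Z = (observed - mean(null)) /
#' sd(null)`; a null with zero spread yields an `NA` sentinel with a warning.
#'
#' @inheritParams recall_edges
#' @param universe gene universe from which null pairs are drawn; defaults to
#'   the network's gene set.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed for the permutation generator.
#' @param weight_cols columns of `rel` to use as weighted recall variants
#'   (defaults to every numeric column).
#' @return object of class `"recall_result"`: list with the network/
#'   relationship tags, `recalled` pairs, `recall_count`, and per-variant
#'   `observed`, `null_mean`, `null_sd`, `zscores`, plus the seed used.
#' @export
recall_zscore <- function(net, rel, universe = NULL, n_perm = 100L,
                          seed = 1L, weight_cols = NULL) {
  if (n_edges(net) < 1L) stop("network has no edges", call. = FALSE)
  if (is.null(universe)) universe <- net$genes
  universe <- sort(unique(as.character(universe)))
  if (!all(net$genes %in% universe)) {
    stop("universe must contain the network genes", call. = FALSE)
  }
  if (is.null(weight_cols)) {
    weight_cols <- names(rel)[vapply(rel, is.numeric, logical(1))]
  }
  pairs <- all_pairs(universe)
  pkeys <- pair_key(pairs$gene_a, pairs$gene_b)
  rmatch <- match(pkeys, rel_keys(rel))
  in_rel <- !is.na(rmatch)
  wmat <- cbind(count = as.numeric(in_rel))
  for (cl in weight_cols) {
    w <- rep(0, length(pkeys))
    w[in_rel] <- rel[[cl]][rmatch[in_rel]]
    wmat <- cbind(wmat, w)
    colnames(wmat)[ncol(wmat)] <- cl
  }

  obs_idx <- which(pkeys %in% edge_keys(net))
  if (length(obs_idx) != n_edges(net)) {
    stop("network edges outside the pair universe", call. = FALSE)
  }
  observed <- colSums(wmat[obs_idx, , drop = FALSE])

  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  k <- length(obs_idx)
  null_stats <- matrix(0, nrow = n_perm, ncol = ncol(wmat),
                       dimnames = list(NULL, colnames(wmat)))
  for (b in seq_len(n_perm)) {
    draw <- sample.int(length(pkeys), k)
    null_stats[b, ] <- colSums(wmat[draw, , drop = FALSE])
  }
  null_mean <- colMeans(null_stats)
  null_sd <- apply(null_stats, 2L, stats::sd)
  z <- (observed - null_mean) / null_sd
  degenerate <- null_sd == 0
  if (any(degenerate)) {
    warning("zero-spread permutation null; Z undefined for: ",
            paste(names(z)[degenerate], collapse = ", "), call. = FALSE)
    z[degenerate] <- NA_real_
  }
  structure(list(network = net$meta$method, kind = attr(rel, "kind"),
                 recalled = recall_edges(net, rel),
                 recall_count = sum(in_rel[obs_idx]),
                 n_edges = length(obs_idx),
                 observed = observed, null_mean = null_mean,
                 null_sd = null_sd, zscores = z,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("<recall: %s network vs %s> %d of %d edges recalled\n",
              x$network, x$kind, x$recall_count, x$n_edges))
  df <- data.frame(variant = names(x$zscores), observed = x$observed,
                   null_mean = x$null_mean, null_sd = x$null_sd,
                   z = x$zscores)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare relationship weights of two recalled pair sets
#'
#' Tests whether the relationship weights of the pairs recalled by one
#' network differ from those recalled by another (e.g. PMI-recalled vs
#' PCC-recalled records), with a two-sided Mann-Whitney rank-sum test by
#' default (Welch t behind the `method` flag). Swapping the two sets flips
#' the direction of the reported medians.
#'
#' @param recall_a,recall_b data.frames of recalled pairs (as returned by
#'   [recall_edges()]), or character vectors of `"geneA|geneB"` keys.
#' @param rel the `"relationship_table"` supplying the weights.
#' @param weight_col weight column to compare (defaults to the first numeric
#'   column of `rel`).
#' @param method `"wilcox"` (default) or `"welch"`.
#' @return list with `statistic`, `p_value`, `median_a`, `median_b`,
#'   `n_a`, `n_b` and the method used.
#' @export
compare_weights <- function(recall_a, recall_b, rel, weight_col = NULL,
                            method = c("wilcox", "welch")) {
  method <- match.arg(method)
  if (is.null(weight_col)) {
    weight_col <- names(rel)[vapply(rel, is.numeric, logical(1))][1L]
  }
  keys_of <- function(r) {
    if (is.character(r)) r else pair_key(r$gene_a, r$gene_b)
  }
  wa <- rel[[weight_col]][match(keys_of(recall_a), rel_keys(rel))]
  wb <- rel[[weight_col]][match(keys_of(recall_b), rel_keys(rel))]
  if (anyNA(wa) || anyNA(wb)) {
    warning("pairs absent from the relationship table are dropped",
            call. = FALSE)
    wa <- wa[!is.na(wa)]; wb <- wb[!is.na(wb)]
  }
  if (!length(wa) || !length(wb)) {
    stop("empty recalled set after weight lookup", call. = FALSE)
  }
  tst <- if (method == "wilcox") {
    suppressWarnings(stats::wilcox.test(wa, wb, exact = FALSE))
  } else {
    stats::t.test(wa, wb)
  }
  # complete ties leave the normal approximation 0/0; that is the null center
  if (is.nan(tst$p.value)) tst$p.value <- 1
  list(statistic = unname(tst$statistic), p_value = tst$p.value,
       median_a = stats::median(wa), median_b = stats::median(wb),
       n_a = length(wa), n_b = length(wb), method = method,
       weight_col = weight_col)
}
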