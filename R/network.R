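# The pminet_network container and the PMI network fitting procedure.

new_network <- function(genes, edges, method, threshold = NA_real_,
                        order_reached = NA_integer_, n_bins = NA_integer_,
                        extra_class = NULL) {
  genes <- sort(unique(as.character(genes)))
  if (nrow(edges) > 0) {
    cp <- canonical_pair(edges$gene_a, edges$gene_b)
    edges$gene_a <- cp[, 1L]
    edges$gene_b <- cp[, 2L]
    if (any(edges$gene_a == edges$gene_b)) stop("self-edge", call. = FALSE)
    if (anyDuplicated(pair_key(edges$gene_a, edges$gene_b))) {
      stop("duplicate edge", call. = FALSE)
    }
    if (!all(c(edges$gene_a, edges$gene_b) %in% genes)) {
      stop("edge endpoint outside gene universe", call. = FALSE)
    }
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(genes = genes, edges = edges,
                 meta = list(method = method, threshold = threshold,
                             order_reached = order_reached, n_bins = n_bins)),
            class = c(extra_class, "pminet_network"))
}

edge_keys <- function(net) {
  if (nrow(net$edges) == 0) character() else
    pair_key(net$edges$gene_a, net$edges$gene_b)
}

#' Number of edges and node set of a network
#'
#' @param net a `"pminet_network"`.
#' @return `n_edges()` the edge count; `network_nodes()` the genes incident to
#'   at least one edge.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$edges$gene_a, net$edges$gene_b)))
}

#' @export
print.pminet_network <- function(x, ...) {
  cat(sprintf("<%s network> %d genes, %d edges", x$meta$method,
              length(x$genes), nrow(x$edges)))
  if (!is.na(x$meta$threshold)) {
    cat(sprintf(" (threshold %.4g)", x$meta$threshold))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.pminet_network <- function(object, ...) {
  deg <- table(factor(c(object$edges$gene_a, object$edges$gene_b),
                      levels = object$genes))
  out <- list(method = object$meta$method, n_genes = length(object$genes),
              n_edges = nrow(object$edges),
              threshold = object$meta$threshold,
              order_reached = object$meta$order_reached,
              degree = as.vector(deg),
              strength = object$edges$strength)
  class(out) <- "summary.pminet_network"
  out
}

#' @export
print.summary.pminet_network <- function(x, ...) {
  cat(sprintf("%s network: %d genes, %d edges\n", x$method, x$n_genes,
              x$n_edges))
  if (!is.na(x$threshold)) cat("threshold:", format(x$threshold), "\n")
  if (!is.na(x$order_reached)) {
    cat("conditioning order reached:", x$order_reached, "\n")
  }
  if (length(x$strength)) {
    cat("edge strength:\n")
    print(summary(x$strength))
  }
  cat("degree:\n")
  print(summary(x$degree))
  invisible(x)
}

#' @export
plot.pminet_network <- function(x, ...) {
  g <- x$genes
  n <- length(g)
  theta <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  px <- cos(theta); py <- sin(theta)
  graphics::plot(px, py, asp = 1, axes = FALSE, xlab = "", ylab = "",
                 pch = 19, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), ...)
  if (nrow(x$edges) > 0) {
    ia <- match(x$edges$gene_a, g)
    ib <- match(x$edges$gene_b, g)
    graphics::segments(px[ia], py[ia], px[ib], py[ib], col = "grey50")
  }
  graphics::text(px * 1.15, py * 1.15, g, cex = 0.7)
  graphics::title(sprintf("%s network (%d edges)", x$meta$method,
                          nrow(x$edges)))
  invisible(x)
}

# Estimation context shared across the elimination passes: under the
# gaussian scheme a single covariance matrix; under a binning scheme every
# gene discretized once.
pmi_context <- function(expr, n_bins, scheme) {
  genes <- rownames(expr)
  if (scheme == "gaussian") {
    list(scheme = scheme, genes = genes, S = stats::cov(t(expr)))
  } else {
    binned <- lapply(seq_len(nrow(expr)), function(i) {
      discretize(expr[i, ], n_bins = n_bins, scheme = scheme)
    })
    list(scheme = scheme, genes = genes, binned = binned)
  }
}

# Order-0 PMI (unconditioned) for every gene pair; symmetric matrix.
pairwise_pmi0 <- function(ctx) {
  genes <- ctx$genes
  n <- length(genes)
  m <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- if (ctx$scheme == "gaussian") {
        pmi_gaussian_cov(ctx$S, i, j)
      } else {
        pmi_from_bins(ctx$binned[[i]]$bins, ctx$binned[[i]]$n_bins,
                      ctx$binned[[j]]$bins, ctx$binned[[j]]$n_bins)
      }
    }
  }
  m
}

# Conditioned PMI of genes (a, b) given the genes in `zs` (indices).
cond_pmi <- function(ctx, ia, ib, zs) {
  if (ctx$scheme == "gaussian") {
    return(pmi_gaussian_cov(ctx$S, ia, ib, zs))
  }
  bi <- ctx$binned[[ia]]
  bj <- ctx$binned[[ib]]
  bz <- rep.int(1L, length(bi$bins))
  width <- 1L
  for (g in zs) {
    bz <- bz + (ctx$binned[[g]]$bins - 1L) * width
    width <- width * ctx$binned[[g]]$n_bins
  }
  u <- sort(unique(bz))
  pmi_from_bins(bi$bins, bi$n_bins, bj$bins, bj$n_bins,
                match(bz, u), length(u))
}

#' Fit a part-mutual-information co-expression network
#'
#' Starts from the fully connected network over the genes of `expr` and
#' eliminates edges by conditioned PMI. The order-0 pass removes every pair
#' whose unconditioned PMI falls below `threshold`. At each order
#' `k = 1, ..., max_order`, the conditioning candidates for a surviving edge
#' (X, Y) are the k-subsets of the common network neighbors of X and Y; the
#' edge's retained strength is the maximum PMI over those candidates ("top
#' one"), and the edge is removed when that maximum is below `threshold`.
#' Passes are synchronous (neighbor sets are frozen at the start of each
#' order) and candidate enumeration is lexicographic, so the result is fully
#' deterministic. The loop stops early when an order pass removes nothing.
#'
#' @param expr numeric genes-by-samples matrix with unique row (gene) and
#'   column (sample) names.
#' @param threshold PMI retention threshold in nats; edges below it are
#'   removed.
#' @param max_order largest conditioning-set size (default 1).
#' @param n_bins discretization bins per variable (default 3; unused by the
#'   gaussian scheme).
#' @param scheme PMI estimation scheme: `"gaussian"` (closed-form
#'   covariance-based estimate, the default — it conditions on continuous
#'   intermediaries without discretization leakage) or a discretization
#'   scheme (`"equal_frequency"`, `"equal_width"`), see [pmi()].
#' @return an object of classes `"pmi_network"` and `"pminet_network"`: list
#'   with `genes`, `edges` (data.frame `gene_a`, `gene_b`, `strength` in
#'   nats) and `meta` (threshold, conditioning order reached, method tag,
#'   bins).
#' @seealso [optimal_network_scan()] for choosing the threshold,
#'   [pcc_type1()] and friends for comparable correlation networks.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- x + rnorm(200, sd = 0.5); z <- y + rnorm(200, sd = 0.5)
#' expr <- rbind(g1 = x, g2 = y, g3 = z)
#' colnames(expr) <- paste0("s", 1:200)
#' pmi_network(expr, threshold = 0.15)
#' @export
pmi_network <- function(expr, threshold, max_order = 1L, n_bins = 3L,
                        scheme = c("gaussian", "equal_frequency",
                                   "equal_width")) {
  scheme <- match.arg(scheme)
  stopifnot_named_matrix(expr, "expr")
  if (nrow(expr) < 3L) stop("need at least 3 genes", call. = FALSE)
  if (ncol(expr) < max(10L, n_bins^2)) {
    stop("too few samples for reliable PMI estimation", call. = FALSE)
  }
  ctx <- pmi_context(expr, n_bins = n_bins, scheme = scheme)
  pmi_network_from_ctx(ctx, pairwise_pmi0(ctx), threshold,
                       max_order = max_order, n_bins = n_bins)
}

# Elimination given a context and a precomputed order-0 PMI matrix; shared
# by pmi_network() and the threshold scan.
pmi_network_from_ctx <- function(ctx, pmi0, threshold, max_order = 1L,
                                 n_bins = 3L) {
  genes <- ctx$genes
  pairs <- all_pairs(genes)
  ia <- match(pairs$gene_a, genes)
  ib <- match(pairs$gene_b, genes)
  strength <- pmi0[cbind(ia, ib)]
  keep <- strength >= threshold
  edges <- data.frame(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                      strength = strength[keep], stringsAsFactors = FALSE)
  order_reached <- 0L
  k <- 1L
  while (k <= max_order && nrow(edges) > 0) {
    adj <- split(c(edges$gene_b, edges$gene_a),
                 c(edges$gene_a, edges$gene_b))
    removed <- logical(nrow(edges))
    new_strength <- edges$strength
    for (e in seq_len(nrow(edges))) {
      a <- edges$gene_a[e]; b <- edges$gene_b[e]
      cn <- sort(setdiff(intersect(adj[[a]], adj[[b]]), c(a, b)))
      if (length(cn) < k) next   # no candidates at this order: edge retained
      combos <- utils::combn(cn, k, simplify = FALSE)
      best <- -Inf
      ia <- match(a, genes); ib <- match(b, genes)
      for (cmb in combos) {
        v <- cond_pmi(ctx, ia, ib, match(cmb, genes))
        if (v > best) best <- v
        if (is.infinite(best) && best > 0) break
      }
      new_strength[e] <- best
      if (best < threshold) removed[e] <- TRUE
    }
    order_reached <- k
    edges$strength <- new_strength
    if (!any(removed)) break
    edges <- edges[!removed, , drop = FALSE]
    k <- k + 1L
  }
  net <- new_network(genes, edges, method = "PMI", threshold = threshold,
                     order_reached = order_reached,
                     n_bins = as.integer(n_bins),
                     extra_class = "pmi_network")
  net$meta$scheme <- ctx$scheme
  net
}

jaccard_edges <- function(a, b) {
  ka <- edge_keys(a); kb <- edge_keys(b)
  u <- length(union(ka, kb))
  if (u == 0) return(1)          # two empty networks are identical
  length(intersect(ka, kb)) / u
}

#' Scan thresholds for a stable ("optimal") PMI network
#'
#' Builds one PMI network per threshold on an ascending grid and measures the
#' stability of the scan as the Jaccard similarity of consecutive edge sets.
#' The chosen network is the one at the first grid position whose edge set
#' agrees with the next threshold's at Jaccard `>= stability_tol`; if the scan
#' never stabilizes the last network is chosen with a warning.
#'
#' @inheritParams pmi_network
#' @param threshold_grid ascending numeric vector of thresholds to try.
#' @param stability_tol consecutive-Jaccard stability criterion (default
#'   0.95).
#' @return object of class `"pmi_scan"`: list with `thresholds`, `networks`,
#'   `stability` (length `length(thresholds) - 1`), `chosen_index` and
#'   `chosen` (the selected network).
#' @export
optimal_network_scan <- function(expr, threshold_grid, stability_tol = 0.95,
                                 max_order = 1L, n_bins = 3L,
                                 scheme = c("gaussian", "equal_frequency",
                                            "equal_width")) {
  scheme <- match.arg(scheme)
  if (length(threshold_grid) < 1L || is.unsorted(threshold_grid,
                                                 strictly = TRUE)) {
    stop("threshold_grid must be nonempty and strictly ascending",
         call. = FALSE)
  }
  stopifnot_named_matrix(expr, "expr")
  ctx <- pmi_context(expr, n_bins = n_bins, scheme = scheme)
  pmi0 <- pairwise_pmi0(ctx)
  nets <- lapply(threshold_grid, function(t) {
    pmi_network_from_ctx(ctx, pmi0, t, max_order = max_order,
                         n_bins = n_bins)
  })
  stab <- if (length(nets) > 1L) {
    vapply(seq_len(length(nets) - 1L), function(i) {
      jaccard_edges(nets[[i]], nets[[i + 1L]])
    }, numeric(1))
  } else numeric(0)
  hit <- which(stab >= stability_tol)
  if (length(hit)) {
    chosen <- hit[1L]
  } else {
    chosen <- length(nets)
    if (length(nets) > 1L) {
      warning("threshold scan did not stabilize; choosing last network",
              call. = FALSE)
    }
  }
  structure(list(thresholds = threshold_grid, networks = nets,
                 stability = stab, chosen_index = chosen,
                 chosen = nets[[chosen]]),
            class = "pmi_scan")
}

#' @export
print.pmi_scan <- function(x, ...) {
  cat("<PMI threshold scan>\n")
  df <- data.frame(threshold = x$thresholds,
                   edges = vapply(x$networks, n_edges, integer(1)),
                   jaccard_next = c(round(x$stability, 3), NA))
  print(df, row.names = FALSE)
  cat(sprintf("chosen: threshold %.4g (index %d)\n",
              x$thresholds[x$chosen_index], x$chosen_index))
  invisible(x)
}
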