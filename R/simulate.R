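# Synthetic-data generators: every pipeline input with known ground truth.
#
# Expression comes from a linear-Gaussian structural cascade on a directed
# acyclic graph, so direct edges and path-induced indirect correlations are
# planted and have closed-form population correlations. CNV matrices carry
# controllable co-gain/co-loss pair rates over a sparse mutation background;
# methylation betas come from per-gene low/mid/high mixtures; survival times
# are exponential with per-sample hazards multiplied by planted pair-status
# effects, so group medians have closed forms.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specify a directed acyclic cascade graph
#'
#' @param genes character vector of gene names.
#' @param edges data.frame with columns `from`, `to` and optionally `coef`
#'   (defaults to 1): directed regulatory influences.
#' @return object of class `"cascade_graph"`.
#' @export
cascade_graph <- function(genes, edges) {
  genes <- as.character(genes)
  stopifnot(!anyDuplicated(genes))
  if (is.null(edges$coef)) edges$coef <- rep_len(1, nrow(edges))
  stopifnot(all(c(edges$from, edges$to) %in% genes))
  if (any(edges$from == edges$to)) stop("self-loop", call. = FALSE)
  # Kahn topological sort; fails on cycles
  order <- character(0)
  remaining <- edges
  roots <- setdiff(genes, remaining$to)
  while (length(roots)) {
    order <- c(order, roots[1L])
    remaining <- remaining[remaining$from != roots[1L], , drop = FALSE]
    roots <- setdiff(setdiff(genes, order), remaining$to)
  }
  if (length(order) != length(genes)) stop("graph has a cycle",
                                           call. = FALSE)
  structure(list(genes = genes, edges = edges, topo_order = order),
            class = "cascade_graph")
}

#' Random directed acyclic graph over a gene set
#'
#' Samples `n_edges` distinct ordered pairs respecting a random topological
#' order; used to plant direct edges for network-recovery experiments.
#'
#' @param n_genes,n_edges graph size.
#' @param seed integer seed.
#' @param coef edge coefficient (default 1).
#' @return a `"cascade_graph"`.
#' @export
random_dag <- function(n_genes, n_edges, seed = 1L, coef = 1) {
  stopifnot(n_edges <= choose(n_genes, 2))
  genes <- sprintf("g%02d", seq_len(n_genes))
  with_seed(seed, {
    ord <- sample(genes)
    idx <- utils::combn(n_genes, 2L)
    pick <- sample.int(ncol(idx), n_edges)
    cascade_graph(genes,
                  data.frame(from = ord[idx[1L, pick]],
                             to = ord[idx[2L, pick]], coef = coef,
                             stringsAsFactors = FALSE))
  })
}

#' True direct edges of a cascade graph as canonical pairs
#'
#' @param graph a `"cascade_graph"`.
#' @return data.frame `gene_a`, `gene_b` (lexicographically canonical).
#' @export
true_edges <- function(graph) {
  cp <- canonical_pair(graph$edges$from, graph$edges$to)
  out <- unique(data.frame(gene_a = cp[, 1L], gene_b = cp[, 2L],
                           stringsAsFactors = FALSE))
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Simulate expression data from a cascade graph
#'
#' Samples in topological order: root genes are standard normal; every other
#' gene is the coefficient-weighted sum of its parents plus Gaussian noise
#' with standard deviation `noise_sd`. Indirect correlations therefore arise
#' only through directed paths. A quadratic link (`nonlinear = TRUE`)
#' replaces each parent contribution by a standardized `parent^2` term,
#' producing non-monotonic dependence invisible to Pearson correlation.
#'
#' @param graph a `"cascade_graph"`.
#' @param n_samples number of samples (columns).
#' @param noise_sd child noise standard deviation (default 0.5).
#' @param seed integer seed.
#' @param nonlinear use the quadratic link (default `FALSE`).
#' @return list with `expr` (genes-by-samples matrix) and `truth` (list with
#'   `true_direct_edges`, `graph`, `noise_sd`).
#' @export
simulate_expression <- function(graph, n_samples, noise_sd = 0.5, seed = 1L,
                                nonlinear = FALSE) {
  stopifnot(inherits(graph, "cascade_graph"))
  with_seed(seed, {
    expr <- matrix(0, nrow = length(graph$genes), ncol = n_samples,
                   dimnames = list(graph$genes,
                                   sprintf("s%04d", seq_len(n_samples))))
    for (g in graph$topo_order) {
      parents <- graph$edges[graph$edges$to == g, , drop = FALSE]
      if (nrow(parents) == 0) {
        expr[g, ] <- stats::rnorm(n_samples)
      } else {
        contrib <- rep(0, n_samples)
        for (pr in seq_len(nrow(parents))) {
          px <- expr[parents$from[pr], ]
          if (nonlinear) px <- (px^2 - 1) / sqrt(2)
          contrib <- contrib + parents$coef[pr] * px
        }
        expr[g, ] <- contrib + stats::rnorm(n_samples, sd = noise_sd)
      }
    }
    list(expr = expr,
         truth = list(true_direct_edges = true_edges(graph), graph = graph,
                      noise_sd = noise_sd, nonlinear = nonlinear))
  })
}

#' Simulate four progression stages from one base graph
#'
#' Stage i is generated from the base graph restricted to the edges enabled
#' by `stage_edge_masks[[i]]`; per-stage seeds are derived deterministically
#' from `seed`.
#'
#' @param base_graph a `"cascade_graph"`.
#' @param stage_edge_masks list of 4 logical vectors over
#'   `base_graph$edges` rows.
#' @param n_per_stage samples per stage.
#' @inheritParams simulate_expression
#' @return list of 4 elements as returned by [simulate_expression()].
#' @export
simulate_staged <- function(base_graph, stage_edge_masks, n_per_stage,
                            noise_sd = 0.5, seed = 1L) {
  stopifnot(length(stage_edge_masks) == 4L)
  lapply(seq_len(4L), function(i) {
    mask <- stage_edge_masks[[i]]
    stopifnot(length(mask) == nrow(base_graph$edges))
    g <- cascade_graph(base_graph$genes,
                       base_graph$edges[mask, , drop = FALSE])
    simulate_expression(g, n_per_stage, noise_sd = noise_sd,
                        seed = as.integer(seed) + i)
  })
}

#' Simulate a GISTIC-style gene-level CNV matrix
#'
#' Background mutations hit each gene-sample cell independently at
#' `background_rate` with a level drawn from {-2, -1, 1, 2}; on top,
#' designated pairs receive joint statuses (co-gain `GG`, co-loss `LL`, or
#' mixed `GL`/`LG`) in a random `rate` fraction of samples, overriding the
#' background for those two genes.
#'
#' @param genes gene names.
#' @param n_samples number of samples.
#' @param pair_spec data.frame with columns `gene_a`, `gene_b`, `type`
#'   (GG/LL/GL/LG, relative to the given gene order) and `rate`.
#' @param background_rate per-cell background mutation probability (default
#'   0.05).
#' @param seed integer seed.
#' @return list with `cnv` (integer genes-by-samples matrix in -2..2) and
#'   `truth` (the pair specification).
#' @export
simulate_cnv <- function(genes, n_samples, pair_spec = NULL,
                         background_rate = 0.05, seed = 1L) {
  genes <- as.character(genes)
  with_seed(seed, {
    cnv <- matrix(0L, nrow = length(genes), ncol = n_samples,
                  dimnames = list(genes, sprintf("s%04d",
                                                 seq_len(n_samples))))
    hit <- matrix(stats::runif(length(cnv)) < background_rate,
                  nrow = nrow(cnv))
    cnv[hit] <- sample(c(-2L, -1L, 1L, 2L), sum(hit), replace = TRUE)
    if (!is.null(pair_spec) && nrow(pair_spec) > 0) {
      for (p in seq_len(nrow(pair_spec))) {
        ga <- pair_spec$gene_a[p]; gb <- pair_spec$gene_b[p]
        ty <- pair_spec$type[p]
        sel <- stats::runif(n_samples) < pair_spec$rate[p]
        na <- sum(sel)
        if (na == 0) next
        lv <- function(sign) sign * sample(1:2, na, replace = TRUE)
        va <- switch(ty, GG = lv(1L), LL = lv(-1L), GL = lv(1L),
                     LG = lv(-1L), stop("bad pair type"))
        vb <- switch(ty, GG = lv(1L), LL = lv(-1L), GL = lv(-1L),
                     LG = lv(1L))
        cnv[ga, sel] <- va
        cnv[gb, sel] <- vb
      }
    }
    list(cnv = cnv, truth = list(pair_spec = pair_spec,
                                 background_rate = background_rate))
  })
}

#' Simulate a CpG-island methylation beta matrix
#'
#' Each gene owns `islands_per_gene` islands; each island-sample beta is
#' drawn from a three-component mixture (low ~ Beta(1.5, 15),
#' mid ~ Beta(10, 10), high ~ Beta(15, 1.5)) with per-gene component
#' weights. Per-gene weights default to random draws unless supplied.
#'
#' @param genes gene names.
#' @param islands_per_gene islands per gene (recycled).
#' @param n_samples number of samples.
#' @param gene_weights optional genes-by-3 matrix of mixture weights
#'   (columns low, mid, high; rows sum to 1).
#' @param seed integer seed.
#' @return list with `beta` (islands-by-samples matrix in `[0,1]`),
#'   `cpg_to_gene` mapping data.frame and `truth` (the weights).
#' @export
simulate_dm <- function(genes, islands_per_gene = 3L, n_samples,
                        gene_weights = NULL, seed = 1L) {
  genes <- as.character(genes)
  k <- rep_len(as.integer(islands_per_gene), length(genes))
  with_seed(seed, {
    if (is.null(gene_weights)) {
      w <- matrix(stats::rexp(3L * length(genes)), ncol = 3L)
      gene_weights <- w / rowSums(w)
      dimnames(gene_weights) <- list(genes, c("low", "mid", "high"))
    }
    shapes <- list(low = c(1.5, 15), mid = c(10, 10), high = c(15, 1.5))
    cpg <- unlist(lapply(seq_along(genes), function(i) {
      sprintf("%s_cpg%d", genes[i], seq_len(k[i]))
    }))
    map <- data.frame(cpg = cpg,
                      gene = rep(genes, k), stringsAsFactors = FALSE)
    beta <- matrix(0, nrow = length(cpg), ncol = n_samples,
                   dimnames = list(cpg, sprintf("s%04d",
                                                seq_len(n_samples))))
    for (r in seq_len(nrow(beta))) {
      g <- map$gene[r]
      comp <- sample(c("low", "mid", "high"), n_samples, replace = TRUE,
                     prob = gene_weights[g, ])
      for (cm in c("low", "mid", "high")) {
        nsel <- sum(comp == cm)
        if (nsel) {
          beta[r, comp == cm] <- stats::rbeta(nsel, shapes[[cm]][1L],
                                              shapes[[cm]][2L])
        }
      }
    }
    list(beta = beta, cpg_to_gene = map,
         truth = list(gene_weights = gene_weights))
  })
}

#' Simulate disease-specific survival with planted pair-status effects
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * prod(multipliers)`, one multiplier per planted pair
#' status the sample carries (a multiplier below 1 is protective: it scales
#' the median survival time up by its inverse). Censoring is independent
#' exponential calibrated so each sample is censored with probability
#' `censor_rate`.
#'
#' @param statuses named list: pair key to named per-sample status vector
#'   (as produced from a CNV matrix via [cocnv_status()]).
#' @param effect_spec named list: pair key to a named vector of hazard
#'   multipliers per status; missing statuses multiply by 1.
#' @param baseline_hazard events per unit time (default 0.01, i.e. median
#'   time ~ 69 time units).
#' @param censor_rate probability a sample is censored (default 0).
#' @param seed integer seed.
#' @return a clinical data.frame with columns `sample`, `time`, `event` and
#'   an attached `"hazard"` attribute with the per-sample hazards.
#' @export
simulate_survival <- function(statuses, effect_spec = list(),
                              baseline_hazard = 0.01, censor_rate = 0,
                              seed = 1L) {
  samples <- sort(unique(unlist(lapply(statuses, names))))
  hz <- stats::setNames(rep(baseline_hazard, length(samples)), samples)
  for (pair in names(effect_spec)) {
    st <- statuses[[pair]]
    mult <- effect_spec[[pair]]
    stopifnot(all(mult > 0))
    for (s in intersect(names(st), samples)) {
      m <- mult[st[[s]]]
      if (!is.na(m) && length(m)) hz[s] <- hz[s] * m
    }
  }
  with_seed(seed, {
    t_event <- stats::rexp(length(samples), rate = hz)
    if (censor_rate > 0) {
      c_rate <- hz * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(length(samples), rate = c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, length(samples))
    }
    out <- data.frame(sample = samples, time = time, event = event,
                      stringsAsFactors = FALSE)
    attr(out, "hazard") <- hz
    out
  })
}

#' Gene coordinates for a synthetic genome
#'
#' Places genes head to tail on a small number of chromosomes with random
#' strands; used to exercise the same-chromosome gene distance table.
#'
#' @param genes gene names.
#' @param n_chrom number of chromosomes (default 2).
#' @param gene_span gene length in bp (default 1000).
#' @param gap intergenic gap in bp (default 9000).
#' @param seed integer seed.
#' @return BED-style data.frame `gene`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
simulate_coords <- function(genes, n_chrom = 2L, gene_span = 1000L,
                            gap = 9000L, seed = 1L) {
  genes <- as.character(genes)
  with_seed(seed, {
    chrom <- paste0("chr", rep_len(seq_len(n_chrom), length(genes)))
    pos <- stats::ave(seq_along(genes), chrom, FUN = seq_along) - 1L
    start <- pos * (gene_span + gap)
    data.frame(gene = genes, chrom = chrom, start = start,
               end = start + gene_span,
               strand = sample(c("+", "-"), length(genes), replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
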