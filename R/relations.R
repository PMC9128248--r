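# Omics-defined gene-pair relationships: common transcriptional regulators
# (CoTR), protein-protein interactions (PPI), same-chromosome gene distance
# (SCGD), joint copy-number status (CoCNV) and joint CpG-island methylation
# profiles (CoDM). Every table stores unordered, canonicalized gene pairs
# with one or more nonnegative weights.

new_relationship_table <- function(records, kind) {
  if (nrow(records) > 0) {
    cp <- canonical_pair(records$gene_a, records$gene_b)
    swapped <- records$gene_a != cp[, 1L]
    records$gene_a <- cp[, 1L]
    records$gene_b <- cp[, 2L]
    if (any(records$gene_a == records$gene_b)) {
      stop("self-pair in relationship table", call. = FALSE)
    }
    records <- records[order(records$gene_a, records$gene_b), , drop = FALSE]
    rownames(records) <- NULL
    attr(records, "swapped") <- swapped
  }
  structure(records, class = c("relationship_table", "data.frame"),
            kind = kind)
}

#' Construct a relationship table from canonicalized gene-pair records
#'
#' Mostly used when reading relationship TSVs back; the specialized
#' constructors ([cotr_from_tr()], [scgd()], [cocnv_table()], ...) are the
#' usual entry points.
#'
#' @param records data.frame with `gene_a`, `gene_b` and weight columns.
#' @param kind relationship kind tag (e.g. `"PPI"`, `"CoCNV-GG"`).
#' @return a `"relationship_table"`.
#' @export
relationship_table <- function(records, kind) {
  new_relationship_table(as.data.frame(records), kind)
}

#' @export
print.relationship_table <- function(x, ...) {
  cat(sprintf("<relationship table: %s> %d gene pairs\n", attr(x, "kind"),
              nrow(x)))
  NextMethod()
}

rel_keys <- function(rel) {
  if (nrow(rel) == 0) character() else pair_key(rel$gene_a, rel$gene_b)
}

#' Common-regulator (CoTR) gene-pair table from transcription-regulation data
#'
#' Two genes are CoTR-related when at least one upstream regulator of the
#' stated class (transcription factor or miRNA) targets both; the pair's
#' weight is the number of such common regulators. TF- and miRNA-based tables
#' are always built separately.
#'
#' @param tr_edges data.frame with columns `regulator`, `class` (`"TF"` or
#'   `"miRNA"`) and `target`.
#' @param regulator_class which regulator class to use.
#' @return a `"relationship_table"` (kind `TFCoTR` or `miRCoTR`) with columns
#'   `gene_a`, `gene_b`, `n_regulators`.
#' @export
cotr_from_tr <- function(tr_edges, regulator_class = c("TF", "miRNA")) {
  regulator_class <- match.arg(regulator_class)
  stopifnot(all(c("regulator", "class", "target") %in% names(tr_edges)))
  sub <- tr_edges[tr_edges$class == regulator_class, , drop = FALSE]
  counts <- new.env(parent = emptyenv())
  for (reg in unique(sub$regulator)) {
    targets <- sort(unique(sub$target[sub$regulator == reg]))
    if (length(targets) < 2L) next
    idx <- utils::combn(length(targets), 2L)
    keys <- paste(targets[idx[1L, ]], targets[idx[2L, ]], sep = "|")
    for (k in keys) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  parts <- if (length(keys)) {
    do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  } else matrix(character(), ncol = 2L)
  new_relationship_table(
    data.frame(gene_a = parts[, 1L], gene_b = parts[, 2L],
               n_regulators = vapply(keys, function(k) counts[[k]],
                                     integer(1), USE.NAMES = FALSE),
               stringsAsFactors = FALSE),
    kind = paste0(if (regulator_class == "TF") "TF" else "miR", "CoTR"))
}

#' Direct regulator-target pairs as an unordered relationship table
#'
#' Networks are undirected, so a directed regulation record (regulator,
#' target) is matched as the unordered pair. Weight is the number of distinct
#' regulation records supporting the pair.
#'
#' @inheritParams cotr_from_tr
#' @return a `"relationship_table"` of kind `TR`.
#' @export
tr_pairs <- function(tr_edges) {
  keep <- tr_edges$regulator != tr_edges$target
  keys <- unique(pair_key(tr_edges$regulator[keep], tr_edges$target[keep]))
  parts <- if (length(keys)) {
    do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  } else matrix(character(), ncol = 2L)
  new_relationship_table(
    data.frame(gene_a = parts[, 1L], gene_b = parts[, 2L], weight = 1,
               stringsAsFactors = FALSE), kind = "TR")
}

#' Protein-protein interaction pairs as a relationship table
#'
#' @param ppi_edges data.frame with two columns of interacting gene
#'   identifiers.
#' @return a `"relationship_table"` of kind `PPI` (unit weights, duplicates
#'   and self-pairs dropped).
#' @export
ppi_pairs <- function(ppi_edges) {
  a <- as.character(ppi_edges[[1L]])
  b <- as.character(ppi_edges[[2L]])
  keep <- a != b
  keys <- unique(pair_key(a[keep], b[keep]))
  parts <- if (length(keys)) {
    do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  } else matrix(character(), ncol = 2L)
  new_relationship_table(
    data.frame(gene_a = parts[, 1L], gene_b = parts[, 2L], weight = 1,
               stringsAsFactors = FALSE), kind = "PPI")
}

#' Same-chromosome gene distance (SCGD) table
#'
#' For every pair of genes on the same chromosome, the weight is the distance
#' in base pairs between their transcription start sites. Coordinates are
#' 0-based half-open (BED dialect); the TSS is the interval start for `+`
#' strand genes and the interval end for `-` strand genes.
#'
#' @param coords data.frame with columns `gene`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`).
#' @return a `"relationship_table"` of kind `SCGD` with column `distance`.
#' @export
scgd <- function(coords) {
  stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in%
                  names(coords)))
  if (!all(coords$strand %in% c("+", "-"))) {
    stop("unknown strand value", call. = FALSE)
  }
  tss <- ifelse(coords$strand == "+", coords$start, coords$end)
  out <- list()
  for (chr in unique(coords$chrom)) {
    sel <- which(coords$chrom == chr)
    if (length(sel) < 2L) next
    idx <- utils::combn(length(sel), 2L)
    i <- sel[idx[1L, ]]; j <- sel[idx[2L, ]]
    out[[chr]] <- data.frame(gene_a = coords$gene[i], gene_b = coords$gene[j],
                             distance = abs(tss[i] - tss[j]),
                             stringsAsFactors = FALSE)
  }
  records <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_a = character(), gene_b = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  new_relationship_table(records, kind = "SCGD")
}

#' Joint copy-number (CoCNV) status of a gene pair in one sample
#'
#' Statuses follow GISTIC-style integer calls in -2..2: `GG` when both genes
#' are gained (> 0), `LL` when both lost, `GL`/`LG` for mixed signs (first
#' gene gained/lost respectively), and `NC` when either gene is unmutated
#' (0). The level product is `|cnv1 * cnv2|`, 0 for `NC`.
#'
#' @param cnv1,cnv2 integer copy-number calls (vectors are accepted and
#'   processed elementwise).
#' @return list with character `status` and integer `level_product`.
#' @examples
#' cocnv_status(2, 1)   # GG, level product 2
#' cocnv_status(-1, 0)  # NC
#' @export
cocnv_status <- function(cnv1, cnv2) {
  if (!all(cnv1 %in% -2:2) || !all(cnv2 %in% -2:2)) {
    stop("CNV calls must be integers in -2..2", call. = FALSE)
  }
  status <- rep("NC", length(cnv1))
  status[cnv1 > 0 & cnv2 > 0] <- "GG"
  status[cnv1 < 0 & cnv2 < 0] <- "LL"
  status[cnv1 > 0 & cnv2 < 0] <- "GL"
  status[cnv1 < 0 & cnv2 > 0] <- "LG"
  list(status = status, level_product = abs(as.integer(cnv1 * cnv2)))
}

#' CoCNV relationship tables for a list of gene pairs
#'
#' For each pair and each co-mutation type (GG, LL, GL, LG), records the
#' number of samples with that status (`n_samples`), the same count
#' normalized by the cohort size (`fraction`), and the level-product-weighted
#' count (`weighted`, the sum of `|cnv1 * cnv2|` over those samples). Pairs
#' never showing a type are absent from that type's table. GL/LG orientation
#' refers to the canonical (lexicographic) gene order of the pair.
#'
#' @param cnv_matrix integer genes-by-samples matrix of calls in -2..2.
#' @param pair_list data.frame with columns `gene_a`, `gene_b`.
#' @return named list of four `"relationship_table"`s (`GG`, `LL`, `GL`,
#'   `LG`), kinds `CoCNV-GG` etc.
#' @export
cocnv_table <- function(cnv_matrix, pair_list) {
  stopifnot_named_matrix(cnv_matrix, "cnv_matrix")
  n_samples <- ncol(cnv_matrix)
  cp <- canonical_pair(pair_list$gene_a, pair_list$gene_b)
  missing <- setdiff(unique(c(cp)), rownames(cnv_matrix))
  if (length(missing)) {
    stop("genes absent from CNV matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  types <- c("GG", "LL", "GL", "LG")
  acc <- stats::setNames(vector("list", 4L), types)
  for (p in seq_len(nrow(cp))) {
    st <- cocnv_status(cnv_matrix[cp[p, 1L], ], cnv_matrix[cp[p, 2L], ])
    for (ty in types) {
      hit <- st$status == ty
      cnt <- sum(hit)
      if (cnt == 0) next
      acc[[ty]][[length(acc[[ty]]) + 1L]] <-
        data.frame(gene_a = cp[p, 1L], gene_b = cp[p, 2L],
                   n_samples = cnt, fraction = cnt / n_samples,
                   weighted = sum(st$level_product[hit]),
                   stringsAsFactors = FALSE)
    }
  }
  out <- lapply(types, function(ty) {
    records <- if (length(acc[[ty]])) do.call(rbind, acc[[ty]]) else
      data.frame(gene_a = character(), gene_b = character(),
                 n_samples = integer(), fraction = numeric(),
                 weighted = numeric(), stringsAsFactors = FALSE)
    new_relationship_table(records, kind = paste0("CoCNV-", ty))
  })
  stats::setNames(out, types)
}

#' Per-gene counts of low/high methylation CpG islands
#'
#' Maps CpG islands to genes and counts, per gene and sample, the islands
#' whose beta value is below `low_thr` (L) or above `high_thr` (H);
#' intermediate islands count in neither. Genes with no mapped island are
#' absent, with a warning.
#'
#' @param beta numeric CpG-islands-by-samples matrix of beta values in
#'   `[0, 1]`.
#' @param cpg_to_gene data.frame with columns `cpg`, `gene`.
#' @param low_thr,high_thr hypo-/hyper-methylation thresholds (defaults 0.3
#'   and 0.7).
#' @return list with integer genes-by-samples matrices `L` and `H`.
#' @export
dm_gene_counts <- function(beta, cpg_to_gene, low_thr = 0.3, high_thr = 0.7) {
  stopifnot_named_matrix(beta, "beta")
  if (!(low_thr >= 0 && low_thr < high_thr && high_thr <= 1)) {
    stop("require 0 <= low_thr < high_thr <= 1", call. = FALSE)
  }
  stopifnot(all(c("cpg", "gene") %in% names(cpg_to_gene)))
  map <- cpg_to_gene[cpg_to_gene$cpg %in% rownames(beta), , drop = FALSE]
  unmapped <- setdiff(unique(cpg_to_gene$gene), unique(map$gene))
  if (length(unmapped)) {
    warning("gene(s) with no mapped CpG island: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  genes <- sort(unique(map$gene))
  L <- H <- matrix(0L, nrow = length(genes), ncol = ncol(beta),
                   dimnames = list(genes, colnames(beta)))
  for (g in genes) {
    islands <- map$cpg[map$gene == g]
    sub <- beta[islands, , drop = FALSE]
    L[g, ] <- colSums(sub < low_thr)
    H[g, ] <- colSums(sub > high_thr)
  }
  list(L = L, H = H)
}

#' CoDM profile of a gene pair in one sample
#'
#' The joint methylation profile of a gene pair is the four cross products of
#' the two genes' (L, H) island counts: `LL = L1*L2`, `HH = H1*H2`,
#' `LH = L1*H2`, `HL = H1*L2`. The identity `HH*LL == LH*HL` holds by
#' construction.
#'
#' @param counts1,counts2 lists or vectors with elements `L` and `H`
#'   (vectors are processed elementwise across samples).
#' @return data.frame with columns `LL`, `HH`, `LH`, `HL`.
#' @examples
#' codm_profile(c(L = 2, H = 3), c(L = 1, H = 4))
#' @export
codm_profile <- function(counts1, counts2) {
  c1 <- as.list(counts1); c2 <- as.list(counts2)
  data.frame(LL = c1$L * c2$L, HH = c1$H * c2$H,
             LH = c1$L * c2$H, HL = c1$H * c2$L)
}

#' CoDM relationship tables for a list of gene pairs
#'
#' For each pair and each CoDM value (LL, HH, LH, HL), records the number of
#' samples in which the value is positive (`n_samples`), the sum of the value
#' over samples (`weight_sum`) and that sum normalized by the cohort size
#'   (`weight_norm`). L/H orientation refers to the canonical gene order.
#'
#' @param dm_counts output of [dm_gene_counts()].
#' @param pair_list data.frame with columns `gene_a`, `gene_b`.
#' @return named list of four `"relationship_table"`s (`LL`, `HH`, `LH`,
#'   `HL`), kinds `CoDM-LL` etc.
#' @export
codm_table <- function(dm_counts, pair_list) {
  L <- dm_counts$L; H <- dm_counts$H
  n_samples <- ncol(L)
  cp <- canonical_pair(pair_list$gene_a, pair_list$gene_b)
  missing <- setdiff(unique(c(cp)), rownames(L))
  if (length(missing)) {
    stop("genes absent from methylation counts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  values <- c("LL", "HH", "LH", "HL")
  acc <- stats::setNames(vector("list", 4L), values)
  for (p in seq_len(nrow(cp))) {
    g1 <- cp[p, 1L]; g2 <- cp[p, 2L]
    prof <- codm_profile(list(L = L[g1, ], H = H[g1, ]),
                         list(L = L[g2, ], H = H[g2, ]))
    for (v in values) {
      vals <- prof[[v]]
      cnt <- sum(vals > 0)
      if (cnt == 0) next
      acc[[v]][[length(acc[[v]]) + 1L]] <-
        data.frame(gene_a = g1, gene_b = g2, n_samples = cnt,
                   weight_sum = sum(vals), weight_norm = sum(vals) / n_samples,
                   stringsAsFactors = FALSE)
    }
  }
  out <- lapply(values, function(v) {
    records <- if (length(acc[[v]])) do.call(rbind, acc[[v]]) else
      data.frame(gene_a = character(), gene_b = character(),
                 n_samples = integer(), weight_sum = numeric(),
                 weight_norm = numeric(), stringsAsFactors = FALSE)
    new_relationship_table(records, kind = paste0("CoDM-", v))
  })
  stats::setNames(out, values)
}
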