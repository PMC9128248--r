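# Survival-factor discovery on gene pairs and the I_gp patient score.
#
# A CoCNV survival factor "Gene1-Gene2 GG > NC" means patients whose pair
# status is GG survive significantly better than NC patients (two-group
# log-rank, p < alpha, both groups larger than min_n). A CoDM factor
# "HH-high > HH-low" splits patients at the cohort median of one CoDM value.
# Each factor-bearing pair contributes I_gp in {-1, 0, +1} to a patient:
# +1 when the patient's status/group sits only on the better side of the
# pair's factors, -1 only on the worse side, 0 otherwise. The patient Score
# is the sum of I_gp over pairs and is used to divide the cohort in three.

check_clinical <- function(clinical) {
  stopifnot(all(c("sample", "time", "event") %in% names(clinical)))
  if (anyDuplicated(clinical$sample)) stop("duplicate samples",
                                           call. = FALSE)
  if (any(clinical$time < 0)) stop("negative survival time", call. = FALSE)
  if (!all(clinical$event %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  invisible(clinical)
}

#' Partition patients by CoCNV status of one gene pair
#'
#' @param status named character vector: per-sample CoCNV status (`GG`,
#'   `LL`, `GL`, `LG`, `NC`) of one gene pair.
#' @return named list of sample-name vectors, one per status present.
#' @export
cocnv_patient_groups <- function(status) {
  split(names(status), factor(status))
}

# Kaplan-Meier survival curve as a step function; returns the restricted
# mean (area under the curve up to the last observed time) used to orient
# better/worse groups.
km_area <- function(time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time[event == 1])
  n <- length(time)
  s <- 1
  last_t <- 0
  area <- 0
  for (t in ut) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    area <- area + s * (t - last_t)
    s <- s * (1 - d / at_risk)
    last_t <- t
  }
  area + s * (max(time) - last_t)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square: at every distinct event time the
#' observed events in group A are compared with their hypergeometric
#' expectation under the pooled risk set; the statistic is
#' `(O - E)^2 / V` with one degree of freedom. Symmetric in the two groups.
#'
#' @param time_a,event_a survival times and 0/1 event indicators of group A.
#' @param time_b,event_b the same for group B.
#' @return list with `statistic` (chi-square), `p_value`, `observed` and
#'   `expected` events in group A.
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (sum(event_a) + sum(event_b) < 1) {
    stop("no events in either group", call. = FALSE)
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1L, 0L), c(length(time_a), length(time_b)))
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1L)
    O <- O + d1
    E <- E + d_t * n1 / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

new_survival_factors <- function(df) {
  structure(df, class = c("survival_factors", "data.frame"))
}

#' Discover CoCNV survival factors for gene pairs
#'
#' For each pair, patients are split into the five CoCNV groups; every
#' unordered group pair in which both groups exceed `min_n` samples is
#' compared by log-rank. Comparisons with `p < alpha` become survival
#' factors, oriented by the Kaplan-Meier restricted mean (larger area =
#' better survival), e.g. `"GG > NC"`.
#'
#' @param pair_statuses named list: pair key (`"geneA|geneB"`) to named
#'   per-sample CoCNV status vector.
#' @param clinical data.frame with columns `sample`, `time`, `event`.
#' @param min_n minimum group size; groups must be strictly larger (default
#'   20).
#' @param alpha significance level for the uncorrected log-rank p (default
#'   0.05).
#' @return a `"survival_factors"` data.frame with columns `pair`, `modality`,
#'   `better_type`, `worse_type`, `n_better`, `n_worse`, `statistic`,
#'   `p_value`.
#' @export
find_cocnv_factors <- function(pair_statuses, clinical, min_n = 20L,
                               alpha = 0.05) {
  check_clinical(clinical)
  tm <- stats::setNames(clinical$time, clinical$sample)
  ev <- stats::setNames(clinical$event, clinical$sample)
  rows <- list()
  for (pair in names(pair_statuses)) {
    status <- pair_statuses[[pair]]
    status <- status[names(status) %in% clinical$sample]
    groups <- cocnv_patient_groups(status)
    big <- names(groups)[vapply(groups, length, integer(1)) > min_n]
    if (length(big) < 2L) next
    for (idx in utils::combn(sort(big), 2L, simplify = FALSE)) {
      sa <- groups[[idx[1L]]]; sb <- groups[[idx[2L]]]
      lr <- logrank(tm[sa], ev[sa], tm[sb], ev[sb])
      if (lr$p_value >= alpha) next
      a_better <- km_area(tm[sa], ev[sa]) >= km_area(tm[sb], ev[sb])
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pair, modality = "CoCNV",
        better_type = if (a_better) idx[1L] else idx[2L],
        worse_type = if (a_better) idx[2L] else idx[1L],
        n_better = if (a_better) length(sa) else length(sb),
        n_worse = if (a_better) length(sb) else length(sa),
        statistic = lr$statistic, p_value = lr$p_value,
        stringsAsFactors = FALSE)
    }
  }
  new_survival_factors(if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(), modality = character(),
               better_type = character(), worse_type = character(),
               n_better = integer(), n_worse = integer(),
               statistic = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE))
}

#' Normalized mean absolute deviation
#'
#' `mean(|v - mean(v)|) / mean(v)` — the variability filter applied to CoDM
#' values before median-split survival testing.
#'
#' @param v nonnegative numeric vector.
#' @return the NMAD, or `NA` when `mean(v) == 0`.
#' @export
nmad <- function(v) {
  m <- mean(v)
  if (m == 0) return(NA_real_)
  mean(abs(v - m)) / m
}

#' Discover CoDM survival factors for gene pairs
#'
#' For each pair and each CoDM value (LL, HH, LH, HL), values with
#' normalized mean absolute deviation above `nmad_thr` across samples are
#' retained; patients are split at the cohort median of the value
#' (`> median` = high group, `<= median` = low group) and compared by
#' log-rank. Significant comparisons become factors such as
#' `"HH-high > HH-low"`, oriented by the Kaplan-Meier restricted mean.
#' Values with zero mean, a degenerate median split, or fewer than one event
#' are skipped with a warning.
#'
#' @param pair_profiles named list: pair key to a samples-by-4 data.frame (or
#'   matrix) of CoDM values with columns `LL`, `HH`, `LH`, `HL` and sample
#'   row names.
#' @inheritParams find_cocnv_factors
#' @param nmad_thr variability threshold (default 0.25).
#' @return a `"survival_factors"` data.frame with columns `pair`, `modality`,
#'   `value`, `better_type`, `worse_type`, `split_median`, `nmad`,
#'   `n_better`, `n_worse`, `statistic`, `p_value`.
#' @export
find_codm_factors <- function(pair_profiles, clinical, nmad_thr = 0.25,
                              alpha = 0.05) {
  check_clinical(clinical)
  tm <- stats::setNames(clinical$time, clinical$sample)
  ev <- stats::setNames(clinical$event, clinical$sample)
  rows <- list()
  for (pair in names(pair_profiles)) {
    prof <- as.data.frame(pair_profiles[[pair]])
    prof <- prof[rownames(prof) %in% clinical$sample, , drop = FALSE]
    for (value in intersect(c("LL", "HH", "LH", "HL"), names(prof))) {
      v <- prof[[value]]
      names(v) <- rownames(prof)
      nm <- nmad(v)
      if (is.na(nm)) {
        warning(sprintf("%s %s: zero mean, skipped", pair, value),
                call. = FALSE)
        next
      }
      if (nm <= nmad_thr) next
      med <- stats::median(v)
      hi <- names(v)[v > med]
      lo <- names(v)[v <= med]
      if (!length(hi) || !length(lo)) {
        warning(sprintf("%s %s: degenerate median split, skipped",
                        pair, value), call. = FALSE)
        next
      }
      lr <- logrank(tm[hi], ev[hi], tm[lo], ev[lo])
      if (lr$p_value >= alpha) next
      hi_better <- km_area(tm[hi], ev[hi]) >= km_area(tm[lo], ev[lo])
      lab_hi <- paste0(value, "-high"); lab_lo <- paste0(value, "-low")
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pair, modality = "CoDM", value = value,
        better_type = if (hi_better) lab_hi else lab_lo,
        worse_type = if (hi_better) lab_lo else lab_hi,
        split_median = med, nmad = nm,
        n_better = if (hi_better) length(hi) else length(lo),
        n_worse = if (hi_better) length(lo) else length(hi),
        statistic = lr$statistic, p_value = lr$p_value,
        stringsAsFactors = FALSE)
    }
  }
  new_survival_factors(if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(), modality = character(),
               value = character(), better_type = character(),
               worse_type = character(), split_median = numeric(),
               nmad = numeric(), n_better = integer(), n_worse = integer(),
               statistic = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE))
}

#' Per-pair score contribution I_gp
#'
#' Evaluates one gene pair's contribution to a patient's survival score from
#' the pair's survival factors: +1 when the patient's status (CoCNV) or
#' median-group membership (CoDM) appears only on the better side of the
#' pair's factors, -1 when only on the worse side, and 0 otherwise. The NC
#' status is always neutral: in a factor against NC only the mutated side
#' carries survival impact, so NC scores 0 even when it occurs on a factor
#' side. Any other status listed on both the better and the worse side
#' across the pair's factors is a contradiction and raises an error.
#'
#' @param pair_factors rows of a `"survival_factors"` table for one pair.
#' @param patient_status the patient's CoCNV status (e.g. `"GG"`) or CoDM
#'   group label(s) (e.g. `"HH-high"`; multiple labels allowed, one per CoDM
#'   value).
#' @return integer in `{-1, 0, 1}`.
#' @examples
#' f <- data.frame(pair = "A|B", modality = "CoCNV",
#'                 better_type = "GG", worse_type = "NC")
#' i_gp(f, "GG")  # +1
#' @export
i_gp <- function(pair_factors, patient_status) {
  if (nrow(pair_factors) == 0) return(0L)
  if (length(unique(pair_factors$pair)) > 1L) {
    stop("i_gp expects the factors of a single pair", call. = FALSE)
  }
  # NC never carries survival impact: in a factor against NC only the
  # mutated side orients ("GG > NC" scores GG as +1 and NC as 0), so NC is
  # excluded from both orientation sets before the conflict check.
  better <- setdiff(unique(pair_factors$better_type), "NC")
  worse <- setdiff(unique(pair_factors$worse_type), "NC")
  clash <- intersect(better, worse)
  if (length(clash)) {
    stop("conflicting factor orientations for status: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  in_better <- any(patient_status %in% better)
  in_worse <- any(patient_status %in% worse)
  as.integer(in_better) - as.integer(in_worse)
}

#' CoDM group labels for every patient
#'
#' Assigns, for each CoDM factor, the `"<value>-high"` or `"<value>-low"`
#' label of every patient using the factor's recorded median split, for use
#' with [i_gp()] and [score_patients()].
#'
#' @param factors a CoDM `"survival_factors"` table (needs `value` and
#'   `split_median` columns).
#' @param pair_profiles as in [find_codm_factors()].
#' @return named list: pair key to a named list of per-sample label vectors.
#' @export
codm_sample_labels <- function(factors, pair_profiles) {
  out <- list()
  for (pair in unique(factors$pair)) {
    rows <- factors[factors$pair == pair, , drop = FALSE]
    prof <- as.data.frame(pair_profiles[[pair]])
    labels <- stats::setNames(
      replicate(nrow(prof), character(0), simplify = FALSE),
      rownames(prof))
    for (r in seq_len(nrow(rows))) {
      v <- prof[[rows$value[r]]]
      lab <- ifelse(v > rows$split_median[r],
                    paste0(rows$value[r], "-high"),
                    paste0(rows$value[r], "-low"))
      for (s in seq_along(lab)) {
        labels[[s]] <- c(labels[[s]], lab[s])
      }
    }
    out[[pair]] <- labels
  }
  out
}

#' Sum I_gp into a patient survival score and divide the cohort
#'
#' `Score = sum over factor-bearing pairs of I_gp`; patients with a higher
#' score are expected to survive longer. The cohort is then divided into
#' three groups (low / mid / high) by score tertiles.
#'
#' @param factors a `"survival_factors"` table (CoCNV, CoDM, or both
#'   row-bound).
#' @param statuses named list: pair key to either a named per-sample status
#'   vector (CoCNV) or a named per-sample list of group labels (CoDM, see
#'   [codm_sample_labels()]).
#' @param samples sample identifiers to score (defaults to every sample seen
#'   in `statuses`).
#' @return object of class `"score_table"`: data.frame with `sample`,
#'   `score`, `group`.
#' @export
score_patients <- function(factors, statuses, samples = NULL) {
  if (is.null(samples)) {
    samples <- sort(unique(unlist(lapply(statuses, names))))
  }
  score <- stats::setNames(integer(length(samples)), samples)
  pairs <- intersect(unique(factors$pair), names(statuses))
  if (nrow(factors) == 0 || length(pairs) == 0) {
    warning("no survival factors: all scores are 0", call. = FALSE)
  }
  for (pair in pairs) {
    pf <- factors[factors$pair == pair, , drop = FALSE]
    st <- statuses[[pair]]
    for (s in samples) {
      lab <- if (is.list(st)) st[[s]] else unname(st[s])
      if (is.null(lab) || !length(lab) || anyNA(lab)) next
      score[s] <- score[s] + i_gp(pf, lab)
    }
  }
  out <- data.frame(sample = samples, score = as.integer(score),
                    group = divide_by_score(score),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("score_table", "data.frame"))
}

#' Divide patients into three groups by survival score
#'
#' Tertile cut with ties assigned to the lower group; a constant score vector
#' yields a single group with a warning.
#'
#' @param scores numeric vector of patient scores.
#' @return factor with levels `low`, `mid`, `high` (group sizes sum to
#'   `length(scores)`).
#' @export
divide_by_score <- function(scores) {
  if (length(unique(scores)) == 1L) {
    warning("all scores identical: single group", call. = FALSE)
    return(factor(rep("low", length(scores)),
                  levels = c("low", "mid", "high")))
  }
  q <- stats::quantile(scores, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  grp <- ifelse(scores <= q[1L], "low", ifelse(scores <= q[2L], "mid",
                                               "high"))
  factor(grp, levels = c("low", "mid", "high"))
}

#' Cox proportional-hazards fit of survival scores and clinical covariates
#'
#' Fits `Surv(time, event) ~ score(s) + covariates` with
#' [survival::coxph()]. Several score columns (e.g. a CoCNV score and a CoDM
#' score) may enter one model together.
#'
#' @param scores a `"score_table"`, a named numeric vector, or a data.frame
#'   with a `sample` column and one or more score columns.
#' @param clinical data.frame with `sample`, `time`, `event` and covariate
#'   columns (pathologic stage covariates simplified to integers 0-4).
#' @param covariates character vector of clinical covariate column names.
#' @return list with `fit` (the `coxph` object) and `table` (data.frame
#'   `term`, `coef`, `hr`, `se`, `z`, `p_value`).
#' @export
cox_multivariate <- function(scores, clinical, covariates = character()) {
  check_clinical(clinical)
  if (inherits(scores, "score_table")) {
    sdf <- data.frame(sample = scores$sample, score = scores$score,
                      stringsAsFactors = FALSE)
  } else if (is.numeric(scores) && !is.null(names(scores))) {
    sdf <- data.frame(sample = names(scores), score = unname(scores),
                      stringsAsFactors = FALSE)
  } else {
    sdf <- as.data.frame(scores)
    stopifnot("sample" %in% names(sdf))
  }
  dat <- merge(clinical, sdf, by = "sample")
  score_cols <- setdiff(names(sdf), "sample")
  terms <- c(score_cols, covariates)
  missing_cov <- setdiff(terms, names(dat))
  if (length(missing_cov)) {
    stop("missing covariate column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat)
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), coef = sm[, "coef"],
                    hr = sm[, "exp(coef)"], se = sm[, "se(coef)"],
                    z = sm[, "z"], p_value = sm[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(fit = fit, table = tab, n = nrow(dat))
}

#' Stability of Cox p-values under repeated 80% subsampling
#'
#' Refits the Cox model on `reps` random subsamples of fraction `frac` of
#' the cohort and summarizes the per-term p-values by their mean and
#' standard deviation.
#'
#' @inheritParams cox_multivariate
#' @param frac subsample fraction (default 0.8).
#' @param reps number of refits (default 100); with `reps = 1` the standard
#'   deviation is an `NA` sentinel.
#' @param seed integer seed.
#' @return data.frame with `term`, `p_mean`, `p_sd`, `n_fits`.
#' @export
subsample_stability <- function(scores, clinical, covariates = character(),
                                frac = 0.8, reps = 100L, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  pvals <- list()
  for (b in seq_len(reps)) {
    keep <- sort(sample.int(nrow(clinical), round(frac * nrow(clinical))))
    sub <- clinical[keep, , drop = FALSE]
    res <- cox_multivariate(scores, sub, covariates)
    pvals[[b]] <- stats::setNames(res$table$p_value, res$table$term)
  }
  terms <- names(pvals[[1L]])
  pm <- sapply(terms, function(t) {
    vapply(pvals, function(p) p[[t]], numeric(1))
  })
  pm <- matrix(pm, nrow = reps, dimnames = list(NULL, terms))
  data.frame(term = terms, p_mean = colMeans(pm),
             p_sd = if (reps > 1L) apply(pm, 2L, stats::sd)
                    else NA_real_,
             n_fits = reps, row.names = NULL, stringsAsFactors = FALSE)
}
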