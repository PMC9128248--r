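# Survival-factor discovery, I_gp scoring and Cox support.

clin <- function(time, event, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("p%03d", seq_along(time))
  data.frame(sample = samples, time = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("patient groups partition the cohort by status", {
  status <- setNames(c("GG", "GG", "NC", "LL", "NC"), sprintf("p%d", 1:5))
  groups <- cocnv_patient_groups(status)
  expect_setequal(names(groups), c("GG", "LL", "NC"))
  expect_equal(sum(lengths(groups)), 5L)
  expect_setequal(groups$GG, c("p1", "p2"))
  one <- cocnv_patient_groups(setNames(rep("NC", 4), sprintf("p%d", 1:4)))
  expect_equal(lengths(one), c(NC = 4L))
})

test_that("log-rank matches its closed properties and survdiff", {
  # identical groups: statistic 0, p = 1
  t0 <- c(1, 3, 5, 7, 9); e0 <- c(1, 1, 0, 1, 1)
  same <- logrank(t0, e0, t0, e0)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  # label symmetry
  set.seed(1)
  ta <- rexp(30); tb <- rexp(25, rate = 2)
  ea <- rbinom(30, 1, 0.8); eb <- rbinom(25, 1, 0.8)
  expect_equal(logrank(ta, ea, tb, eb)$statistic,
               logrank(tb, eb, ta, ea)$statistic, tolerance = 1e-12)
  # agreement with survival::survdiff on random cohorts
  for (s in 1:10) {
    set.seed(s)
    n1 <- sample(10:40, 1); n2 <- sample(10:40, 1)
    t1 <- rexp(n1); t2 <- rexp(n2, rate = runif(1, 0.5, 3))
    e1 <- rbinom(n1, 1, 0.9); e2 <- rbinom(n2, 1, 0.9)
    mine <- logrank(t1, e1, t2, e2)
    ref <- survival::survdiff(
      survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, c(n1, n2)))
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-8)
  }
  expect_error(logrank(1:3, c(0, 0, 0), 4:6, c(0, 0, 0)), "no events")
  expect_error(logrank(numeric(0), numeric(0), 1, 1), "nonempty")
})

test_that("log-rank p agrees with a permutation oracle", {
  for (s in 1:8) {
    set.seed(s + 40)
    n1 <- sample(8:15, 1); n2 <- sample(8:15, 1)
    t1 <- rexp(n1); t2 <- rexp(n2, rate = runif(1, 0.5, 2.5))
    e1 <- rep(1, n1); e2 <- rep(1, n2)
    p_asym <- logrank(t1, e1, t2, e2)$p_value
    p_perm <- logrank_permutation_p(t1, e1, t2, e2, n_perm = 400,
                                    seed = s)
    expect_lt(abs(p_asym - p_perm), 0.12)
  }
})

test_that("log-rank detects a hazard ratio of 3 reliably", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    ta <- rexp(100, rate = 1); tb <- rexp(100, rate = 3)
    if (logrank(ta, rep(1, 100), tb, rep(1, 100))$p_value < 0.01) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 50, 0.95)
})

test_that("CoCNV factor discovery enforces group sizes and counts tests", {
  set.seed(2)
  status <- setNames(c(rep("GG", 25), rep("LL", 25), rep("NC", 25),
                       rep("GL", 5), rep("LG", 5)), sprintf("p%03d", 1:85))
  cl <- clin(rexp(85), rep(1, 85), names(status))
  # alpha = 1 keeps every comparison: sizes {25,25,25,5,5} -> C(3,2) tests
  all_cmp <- find_cocnv_factors(list("A|B" = status), cl, min_n = 20,
                                alpha = 1)
  expect_equal(nrow(all_cmp), 3L)
  # all groups at or below min_n: nothing tested
  small <- find_cocnv_factors(list("A|B" = status[1:40]), cl, min_n = 20,
                              alpha = 1)
  expect_equal(nrow(small), 0L)
})

test_that("a planted protective CoCNV effect is recovered and oriented", {
  set.seed(3)
  n <- 200
  samples <- sprintf("p%03d", 1:n)
  status <- setNames(c(rep("GG", 60), rep("NC", 140)), samples)
  cl <- clin(c(rexp(60, rate = 0.5), rexp(140, rate = 2)), rep(1, n),
             samples)
  f <- find_cocnv_factors(list("A|B" = status), cl)
  expect_equal(nrow(f), 1L)
  expect_equal(f$better_type, "GG")
  expect_equal(f$worse_type, "NC")
  expect_lt(f$p_value, 0.05)
})

test_that("NMAD filters constant CoDM values and passes variable ones", {
  expect_equal(nmad(c(0, 0, 10, 10)), 1.0)
  expect_equal(nmad(rep(4, 10)), 0)
  expect_true(is.na(nmad(rep(0, 5))))
  set.seed(4)
  n <- 120
  samples <- sprintf("p%03d", 1:n)
  hh <- c(rep(0, 60), rep(8, 60))
  prof <- data.frame(LL = rep(3, n), HH = hh, LH = rep(0, n),
                     HL = rep(2, n), row.names = samples)
  cl <- clin(c(rexp(60, 2), rexp(60, 0.5)), rep(1, n), samples)
  expect_warning(
    f <- find_codm_factors(list("A|B" = prof), cl),
    "zero mean")                       # the all-zero LH value is skipped
  expect_equal(unique(f$value), "HH")  # constant LL/HL filtered by NMAD
  expect_equal(f$better_type, "HH-high")
  expect_equal(f$worse_type, "HH-low")
  expect_equal(f$split_median, median(hh))
})

test_that("I_gp reproduces the printed worked cases", {
  f1 <- data.frame(pair = "G1|G2", modality = "CoCNV",
                   better_type = "GG", worse_type = "NC",
                   stringsAsFactors = FALSE)
  expect_identical(i_gp(f1, "GG"), 1L)
  expect_identical(i_gp(f1, "NC"), 0L)
  f2 <- data.frame(pair = "G3|G4", modality = "CoCNV",
                   better_type = c("LL", "NC", "LL", "GL"),
                   worse_type = c("NC", "GG", "GG", "GG"),
                   stringsAsFactors = FALSE)
  expect_identical(i_gp(f2, "GG"), -1L)
  expect_identical(i_gp(f2, "LL"), 1L)
  expect_identical(i_gp(f2, "GL"), 1L)
  expect_identical(i_gp(f2, "NC"), 0L)
  f3 <- data.frame(pair = "G5|G6", modality = "CoDM",
                   better_type = "HH-high", worse_type = "HH-low",
                   stringsAsFactors = FALSE)
  expect_identical(i_gp(f3, "HH-high"), 1L)
  expect_identical(i_gp(f3, "HH-low"), -1L)
  # NC is neutral even when it sits on both sides of a factor set
  nc_both <- data.frame(pair = "A|B", modality = "CoCNV",
                        better_type = c("GG", "NC"),
                        worse_type = c("NC", "LL"), stringsAsFactors = FALSE)
  expect_identical(i_gp(nc_both, "NC"), 0L)
  expect_identical(i_gp(nc_both, "GG"), 1L)
  # a mutated status on both sides is a genuine contradiction
  bad <- data.frame(pair = "A|B", modality = "CoCNV",
                    better_type = c("GG", "LL"), worse_type = c("LL", "GG"),
                    stringsAsFactors = FALSE)
  expect_error(i_gp(bad, "GG"), "conflicting")
})

test_that("scores sum I_gp across pairs and divide into tertiles", {
  samples <- sprintf("p%02d", 1:6)
  factors <- rbind(
    data.frame(pair = "A|B", modality = "CoCNV", better_type = "GG",
               worse_type = "NC", stringsAsFactors = FALSE),
    data.frame(pair = "C|D", modality = "CoCNV", better_type = "NC",
               worse_type = "LL", stringsAsFactors = FALSE))
  statuses <- list(
    "A|B" = setNames(c("GG", "GG", "NC", "NC", "NC", "GG"), samples),
    "C|D" = setNames(c("LL", "NC", "LL", "NC", "LL", "NC"), samples))
  st <- score_patients(factors, statuses)
  expect_equal(st$score, c(0L, 1L, -1L, 0L, -1L, 1L))
  expect_true(all(table(st$group) > 0))
  expect_equal(sum(table(st$group)), 6L)
  # no factors: all scores zero with a warning (and a degenerate division)
  expect_warning(
    expect_warning(z <- score_patients(factors[0, ], statuses),
                   "no survival factors"),
    "identical")
  expect_true(all(z$score == 0L))
})

test_that("score tertiles put ties in the lower group", {
  scores <- c(rep(-1, 30), rep(0, 30), rep(1, 30))
  g <- divide_by_score(scores)
  expect_equal(as.vector(table(g)), c(30, 30, 30))
  expect_warning(divide_by_score(rep(2, 10)), "identical")
})

test_that("higher planted scores give longer survival in simulation", {
  set.seed(5)
  n <- 300
  samples <- sprintf("p%03d", 1:n)
  status <- setNames(sample(c("GG", "NC", "LL"), n, replace = TRUE,
                            prob = c(0.35, 0.4, 0.25)), samples)
  cl <- simulate_survival(list("A|B" = status),
                          effect_spec = list("A|B" = c(GG = 0.4, LL = 2.5)),
                          baseline_hazard = 0.02, seed = 5)
  f <- find_cocnv_factors(list("A|B" = status), cl)
  expect_gt(nrow(f), 0L)
  st <- score_patients(f, list("A|B" = status))
  med <- tapply(cl$time[match(st$sample, cl$sample)], st$group, median)
  expect_gt(med[["high"]], med[["low"]])
})

test_that("Cox recovery and covariate null behave as planned", {
  set.seed(6)
  n <- 500
  score <- sample(-2:2, n, replace = TRUE)
  junk <- rnorm(n)
  hz <- 0.01 * 2^score                    # HR 2 per unit of score
  cl <- clin(rexp(n, rate = hz), rep(1, n))
  cl$junk <- junk
  res <- cox_multivariate(setNames(score, cl$sample), cl,
                          covariates = "junk")
  cs <- res$table
  expect_equal(cs$coef[cs$term == "score"], log(2), tolerance = 0.3 * log(2))
  expect_gt(cs$p_value[cs$term == "junk"], 0.05)
  expect_lt(abs(cs$coef[cs$term == "junk"]), 0.15)
  # two score columns enter one model together
  two <- data.frame(sample = cl$sample, cocnv_score = score,
                    codm_score = sample(-1:1, n, TRUE))
  res2 <- cox_multivariate(two, cl)
  expect_setequal(res2$table$term, c("cocnv_score", "codm_score"))
})

test_that("subsample stability is seeded and handles reps = 1", {
  set.seed(7)
  n <- 150
  score <- rnorm(n)
  cl <- clin(rexp(n, rate = 0.01 * exp(0.8 * score)), rep(1, n))
  s1 <- subsample_stability(setNames(score, cl$sample), cl, reps = 20,
                            seed = 3)
  s2 <- subsample_stability(setNames(score, cl$sample), cl, reps = 20,
                            seed = 3)
  expect_identical(s1, s2)
  expect_lt(s1$p_mean[s1$term == "score"], 0.05)
  one <- subsample_stability(setNames(score, cl$sample), cl, reps = 1,
                             seed = 1)
  expect_true(is.na(one$p_sd))
})
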