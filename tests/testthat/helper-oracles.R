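# Independent oracles used across the suite. These re-derive quantities by
# direct summation / enumeration and never call the package's modular path.

# Brute-force PMI by direct summation of the defining formula over an
# explicit joint probability array p[x, y, z]. Written as one self-contained
# function, independent of estimate_joint/star_conditional/extended_kl.
pmi_brute_force <- function(p) {
  nx <- dim(p)[1L]; ny <- dim(p)[2L]; nz <- dim(p)[3L]
  px <- apply(p, 1L, sum); py <- apply(p, 2L, sum); pz <- apply(p, 3L, sum)
  pzy <- apply(p, c(3L, 2L), sum)   # p(z, y)
  pzx <- apply(p, c(3L, 1L), sum)   # p(z, x)
  sx <- matrix(0, nx, nz)
  for (x in 1:nx) for (z in 1:nz) {
    s <- 0
    for (y in 1:ny) if (pzy[z, y] > 0) s <- s + p[x, y, z] / pzy[z, y] * py[y]
    sx[x, z] <- s
  }
  sy <- matrix(0, ny, nz)
  for (y in 1:ny) for (z in 1:nz) {
    s <- 0
    for (x in 1:nx) if (pzx[z, x] > 0) s <- s + p[x, y, z] / pzx[z, x] * px[x]
    sy[y, z] <- s
  }
  total <- 0
  for (x in 1:nx) for (y in 1:ny) for (z in 1:nz) {
    if (p[x, y, z] > 0) {
      q <- sx[x, z] * sy[y, z] * pz[z]
      if (q == 0) return(Inf)
      total <- total + p[x, y, z] * log(p[x, y, z] / q)
    }
  }
  total
}

# Brute-force p*(x|z) by direct summation (oracle for star_conditional).
star_brute_force <- function(p, axis = "x") {
  if (axis == "y") p <- aperm(p, c(2L, 1L, 3L))
  nx <- dim(p)[1L]; ny <- dim(p)[2L]; nz <- dim(p)[3L]
  py <- apply(p, 2L, sum)
  pzy <- apply(p, c(3L, 2L), sum)
  out <- matrix(0, nx, nz)
  for (x in 1:nx) for (z in 1:nz) {
    s <- 0
    for (y in 1:ny) if (pzy[z, y] > 0) s <- s + p[x, y, z] / pzy[z, y] * py[y]
    out[x, z] <- s
  }
  out
}

# Expand a joint probability array with rational cell masses into sample
# vectors whose equal-width discretization reproduces the bins exactly
# (values are the bin indices scaled to [0, 1]).
expand_joint_to_samples <- function(p, n = NULL) {
  if (is.null(n)) n <- round(1 / min(p[p > 0]))
  counts <- round(p * n)
  stopifnot(sum(counts) == n)
  idx <- which(counts > 0, arr.ind = TRUE)
  x <- y <- z <- numeric(0)
  for (r in seq_len(nrow(idx))) {
    k <- counts[idx[r, 1L], idx[r, 2L], idx[r, 3L]]
    x <- c(x, rep((idx[r, 1L] - 1) / (dim(p)[1L] - 1), k))
    y <- c(y, rep((idx[r, 2L] - 1) / (dim(p)[2L] - 1), k))
    z <- c(z, rep((idx[r, 3L] - 1) / max(1, dim(p)[3L] - 1), k))
  }
  list(x = x, y = y, z = z)
}

# Exact hypergeometric null moments for recall counts: draw k pairs from N
# total of which K are relationship records.
hyper_moments <- function(N, K, k) {
  mean <- k * K / N
  var <- k * K * (N - K) * (N - k) / (N^2 * (N - 1))
  list(mean = mean, sd = sqrt(var))
}

# Permutation-test oracle for the two-group log-rank statistic: permute
# group labels, recompute, return the p-value of the observed statistic.
logrank_permutation_p <- function(time_a, event_a, time_b, event_b,
                                  n_perm = 500, seed = 1) {
  obs <- logrank(time_a, event_a, time_b, event_b)$statistic
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  na <- length(time_a)
  set.seed(seed)
  exceed <- 0
  for (b in seq_len(n_perm)) {
    pi <- sample.int(length(time))
    ia <- pi[seq_len(na)]
    s <- logrank(time[ia], event[ia], time[-ia], event[-ia])$statistic
    if (s >= obs) exceed <- exceed + 1
  }
  (exceed + 1) / (n_perm + 1)
}

# Small labelled expression matrix helper.
make_expr <- function(..., samples = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- if (is.null(samples)) sprintf("s%03d", seq_len(ncol(m)))
  else samples
  m
}

# Linear chain x1 -> x2 -> x3 with unit coefficients.
make_chain <- function(n, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, sd = noise_sd)
  x3 <- x2 + rnorm(n, sd = noise_sd)
  make_expr(g1 = x1, g2 = x2, g3 = x3)
}
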