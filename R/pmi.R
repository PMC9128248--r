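# Part mutual information (PMI) estimation from sample data.
#
# PMI(X;Y|Z) = D( p(x,y,z) || p*(x|z) p*(y|z) p(z) )
# with the partially conditioned marginals
#   p*(x|z) = sum_y p(x|z,y) p(y),   p*(y|z) = sum_x p(y|z,x) p(x)
# and the extended KL divergence D(p,q) = sum p log(p/q), where q need not be
# a normalized distribution. All values are in nats. Continuous variables are
# discretized before estimation (equal-frequency by default).

#' Discretize a numeric variable into bins
#'
#' Maps a continuous sample vector to integer bin indices, either by
#' equal-frequency (quantile) or equal-width binning. Equal-frequency is the
#' default throughout the package: it is robust for small samples and keeps
#' the discrete summation formulas exact.
#'
#' @param x numeric vector with at least two distinct values.
#' @param n_bins number of bins, at least 2.
#' @param scheme `"equal_frequency"` (quantile cutpoints) or `"equal_width"`.
#' @return list with `bins` (integer vector in `1..n_bins`; fewer bins may be
#'   occupied when quantile cutpoints coincide) and `edges` (numeric cut
#'   boundaries including both extremes).
#' @examples
#' discretize(c(1, 2, 3, 4), n_bins = 2)$bins
#' @export
discretize <- function(x, n_bins = 3L,
                       scheme = c("equal_frequency", "equal_width")) {
  scheme <- match.arg(scheme)
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values in input", call. = FALSE)
  if (length(unique(x)) < 2L) stop("degenerate variable", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  if (scheme == "equal_frequency") {
    edges <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                             names = FALSE)
    edges <- unique(edges)
  } else {
    edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  }
  bins <- cut(x, breaks = edges, include.lowest = TRUE, labels = FALSE)
  list(bins = as.integer(bins), edges = edges, n_bins = max(bins))
}

# Collapse one or more conditioning columns to a single integer bin index.
# `z` may be NULL (no conditioning: one constant bin), a vector, or a matrix
# whose columns are conditioning variables; the joint bin is the interaction
# of the per-column bins.
bin_conditioning <- function(z, n, n_bins, scheme = "equal_frequency") {
  if (is.null(z)) {
    return(list(bins = rep.int(1L, n), n_bins = 1L))
  }
  if (is.list(z) && !is.data.frame(z)) z <- do.call(cbind, z)
  z <- as.matrix(z)
  if (nrow(z) != n) stop("length mismatch between variables", call. = FALSE)
  idx <- rep.int(1L, n)
  width <- 1L
  for (j in seq_len(ncol(z))) {
    bj <- discretize(z[, j], n_bins = n_bins, scheme = scheme)
    idx <- idx + (bj$bins - 1L) * width
    width <- width * bj$n_bins
  }
  # compact to occupied joint bins only
  u <- sort(unique(idx))
  list(bins = match(idx, u), n_bins = length(u))
}

#' Estimate a discretized joint distribution
#'
#' Bins `x`, `y` and (optionally) `z` and tabulates empirical relative
#' frequencies of the bin triples into a 3-dimensional probability array. A
#' missing `z` is treated as a single constant bin, so the same machinery
#' computes unconditional quantities. `z` may also be a matrix, in which case
#' the conditioning bin is the joint (interaction) bin over its columns.
#'
#' @param x,y numeric vectors of equal length.
#' @param z optional conditioning variable(s): `NULL`, a numeric vector, or a
#'   matrix with one conditioning variable per column.
#' @param n_bins bins per variable (default 3).
#' @param scheme discretization scheme, see [discretize()].
#' @param alpha optional Laplace pseudocount added to every cell before
#'   normalization; 0 (the default) keeps small-sample estimates exactly equal
#'   to empirical relative frequencies.
#' @return object of class `"discrete_joint"`: a list with `p_xyz` (array
#'   `[x bin, y bin, z bin]` summing to 1), the bin index vectors and the bin
#'   edges of `x` and `y`.
#' @examples
#' j <- estimate_joint(c(0, 0, 1, 1), c(0, 0, 1, 1), n_bins = 2)
#' j$p_xyz[, , 1]
#' @export
estimate_joint <- function(x, y, z = NULL, n_bins = 3L,
                           scheme = "equal_frequency", alpha = 0) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch between variables", call. = FALSE)
  if (n < 1L) stop("empty input", call. = FALSE)
  bx <- discretize(x, n_bins = n_bins, scheme = scheme)
  by <- discretize(y, n_bins = n_bins, scheme = scheme)
  bz <- bin_conditioning(z, n, n_bins, scheme)
  joint_from_bins(bx$bins, by$bins, bz$bins,
                  nx = bx$n_bins, ny = by$n_bins, nz = bz$n_bins,
                  alpha = alpha,
                  edges = list(x = bx$edges, y = by$edges))
}

# Core tabulation on pre-binned data (also used by the network builder, which
# bins every gene once).
joint_from_bins <- function(bx, by, bz, nx, ny, nz, alpha = 0, edges = NULL) {
  idx <- bx + (by - 1L) * nx + (bz - 1L) * nx * ny
  counts <- tabulate(idx, nbins = nx * ny * nz) + alpha
  p <- array(counts / sum(counts), dim = c(nx, ny, nz))
  structure(list(p_xyz = p, values_x = bx, values_y = by, values_z = bz,
                 bin_edges = edges),
            class = "discrete_joint")
}

#' Partially conditioned marginal p*(x|z)
#'
#' Computes the modified marginal `p*(x|z) = sum_y p(x|z,y) p(y)` (or the
#' symmetric `p*(y|z)`) from a discretized joint. Terms where `p(z,y) = 0`
#' have an undefined conditional and contribute 0. The result is not a true
#' conditional distribution: columns need not sum to 1.
#'
#' @param joint a `"discrete_joint"` from [estimate_joint()].
#' @param axis `"x"` for `p*(x|z)`, `"y"` for `p*(y|z)`.
#' @return object of class `"star_conditional"`: list with `axis` and `table`,
#'   a matrix `[variable bin, z bin]`.
#' @export
star_conditional <- function(joint, axis = c("x", "y")) {
  axis <- match.arg(axis)
  p <- joint$p_xyz
  if (axis == "y") p <- aperm(p, c(2L, 1L, 3L))
  nx <- dim(p)[1L]; ny <- dim(p)[2L]; nz <- dim(p)[3L]
  p_other <- apply(p, 2L, sum)                      # p(y)
  p_zo <- apply(p, c(3L, 2L), sum)                  # p(z, y), [z, y]
  tab <- matrix(0, nrow = nx, ncol = nz)
  for (yi in seq_len(ny)) {
    pz <- p_zo[, yi]                                # p(z, y = yi) over z
    ok <- pz > 0
    if (!any(ok)) next
    # p(x | z, y) * p(y) for this y slice, zero where p(z,y) = 0
    slice <- p[, yi, ok, drop = FALSE]
    tab[, ok] <- tab[, ok] +
      sweep(matrix(slice, nrow = nx), 2L, pz[ok], "/") * p_other[yi]
  }
  structure(list(axis = axis, table = tab), class = "star_conditional")
}

#' Extended Kullback-Leibler divergence
#'
#' `sum(p * log(p / q))` over matching cells, with the conventions
#' `0 * log(0/q) = 0` and `p > 0, q = 0` yielding `+Inf`. `q` need not sum
#' to 1 — the PMI reference measure `p*(x|z) p*(y|z) p(z)` generally does not.
#'
#' @param p,q nonnegative numeric arrays of identical shape.
#' @return a single numeric value in nats (possibly `+Inf`).
#' @examples
#' extended_kl(c(1, 0), c(0.5, 0.5))  # log 2
#' @export
extended_kl <- function(p, q) {
  if (!identical(dim(p), dim(q)) || length(p) != length(q)) {
    stop("shape mismatch between p and q", call. = FALSE)
  }
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Part mutual information between two variables given conditioning variables
#'
#' Estimates `PMI(X;Y|Z) = D(p(x,y,z) || p*(x|z) p*(y|z) p(z))` from sample
#' data, where `D` is the extended KL divergence and `p*` the partially
#' conditioned marginals. With `z = NULL` this reduces to the mutual
#' information of the discretized variables. PMI is symmetric in `x` and `y`.
#' A `+Inf` return is a sentinel meaning some observed cell has zero reference
#' mass; the network elimination loop treats it as "retain edge".
#'
#' Two estimation schemes are available. The discretized scheme
#' (`"equal_frequency"`, `"equal_width"`) runs the full modular pipeline —
#' joint table, partially conditioned marginals, extended KL. The
#' `"gaussian"` scheme evaluates the same functional in closed form from the
#' sample covariance under a jointly Gaussian model; it has no
#' discretization leakage when conditioning on continuous variables and is
#' the default for network construction (see [pmi_network()]).
#'
#' @inheritParams estimate_joint
#' @return PMI estimate in nats.
#' @examples
#' x <- rep(c(0, 1), each = 10)
#' pmi(x, x, n_bins = 2)  # log 2: perfect dependence
#' @export
pmi <- function(x, y, z = NULL, n_bins = 3L,
                scheme = c("equal_frequency", "equal_width", "gaussian"),
                alpha = 0) {
  scheme <- match.arg(scheme)
  if (scheme == "gaussian") {
    return(pmi_gaussian(x, y, z))
  }
  joint <- estimate_joint(x, y, z, n_bins = n_bins, scheme = scheme,
                          alpha = alpha)
  pmi_from_joint(joint)
}

pmi_from_joint <- function(joint) {
  p <- joint$p_xyz
  sx <- star_conditional(joint, "x")$table          # [x, z]
  sy <- star_conditional(joint, "y")$table          # [y, z]
  pz <- apply(p, 3L, sum)
  nx <- dim(p)[1L]; ny <- dim(p)[2L]; nz <- dim(p)[3L]
  q <- array(0, dim = dim(p))
  for (zi in seq_len(nz)) {
    q[, , zi] <- outer(sx[, zi], sy[, zi]) * pz[zi]
  }
  extended_kl(p, q)
}

# PMI on pre-binned vectors; bz may be NULL for no conditioning.
pmi_from_bins <- function(bx, nx, by, ny, bz = NULL, nz = 1L) {
  if (is.null(bz)) {
    bz <- rep.int(1L, length(bx))
    nz <- 1L
  }
  pmi_from_joint(joint_from_bins(bx, by, bz, nx, ny, nz))
}

# Closed-form PMI under a jointly Gaussian model, from a covariance matrix.
# With conditioning set W, p(x|w,y) integrates against p(y) to another
# Gaussian, so p*(x|w) is Gaussian with mean beta_w' w and variance
# s_x^2 + beta_y^2 var(y); every expectation in
#   PMI = E log p(x,y,w) - E log p*(x|w) - E log p*(y|w) - E log p(w)
# is then a quadratic form in the covariance. Without conditioning this
# reduces to the Gaussian mutual information -0.5 log(1 - rho^2). Singular
# covariances return the +Inf sentinel. `S` is the covariance over all
# variables; `ix`, `iy`, `iw` index the pair and the conditioning set.
pmi_gaussian_cov <- function(S, ix, iy, iw = integer()) {
  if (length(iw) == 0L) {
    r2 <- S[ix, iy]^2 / (S[ix, ix] * S[iy, iy])
    if (r2 >= 1) return(Inf)
    return(-0.5 * log1p(-r2))
  }
  nw <- length(iw)
  d <- 2L + nw
  C <- S[c(ix, iy, iw), c(ix, iy, iw)]     # 1 = x, 2 = y, 3.. = w
  wi <- 3:d
  ld_full <- determinant(C, logarithm = TRUE)
  ld_w <- determinant(C[wi, wi, drop = FALSE], logarithm = TRUE)
  if (ld_full$sign <= 0 || ld_w$sign <= 0) return(Inf)
  e_lp_xyw <- -0.5 * (d * log(2 * pi) + as.numeric(ld_full$modulus) + d)
  e_lp_w <- -0.5 * (nw * log(2 * pi) + as.numeric(ld_w$modulus) + nw)
  star <- function(a, b) {            # E log p*(a|w), marginalizing over b
    q <- c(wi, b)
    beta <- tryCatch(solve(C[q, q], C[q, a]), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    s2 <- C[a, a] - sum(beta * C[q, a])
    v <- s2 + beta[nw + 1L]^2 * C[b, b]
    if (v <= 0) return(NULL)
    bw <- beta[seq_len(nw)]
    ew2 <- C[a, a] - 2 * sum(bw * C[wi, a]) +
      drop(crossprod(bw, C[wi, wi, drop = FALSE] %*% bw))
    -0.5 * log(2 * pi * v) - ew2 / (2 * v)
  }
  sx <- star(1L, 2L)
  sy <- star(2L, 1L)
  if (is.null(sx) || is.null(sy)) return(Inf)
  e_lp_xyw - sx - sy - e_lp_w
}

pmi_gaussian <- function(x, y, z = NULL) {
  dat <- cbind(x = x, y = y, z)
  S <- stats::cov(dat)
  pmi_gaussian_cov(S, 1L, 2L, iw = if (is.null(z)) integer() else
    3:ncol(dat))
}
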