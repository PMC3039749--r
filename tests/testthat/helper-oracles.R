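# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# calibrated default kernel, shared by many tests
tkernel <- default_kernel_params()

# discrete convolution y = (u * h) * dt, plain R loop-free construction
conv_oracle <- function(u, h, dt) {
  n <- length(u)
  stats::convolve(u, rev(h), type = "open")[seq_len(n)] * dt
}

# ordinary least squares through explicit normal equations
normal_eq_ls <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# ROC AUC as the pairwise Mann-Whitney construction (ties count one half)
mw_auc_oracle <- function(counts, state) {
  pos <- counts[state == 1]
  neg <- counts[state == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix),
# transformed for integration against a N(mu, sd^2) density
gauss_hermite <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

# expectation of f(theta) under independent normals, product GH rule;
# f takes a matrix (one row per quadrature point) and returns a vector
gh_expectation <- function(f, mean, sd, k = 8) {
  gh <- gauss_hermite(k)
  d <- length(mean)
  grids <- lapply(seq_len(d), function(j) {
    mean[j] + sqrt(2) * sd[j] * gh$nodes
  })
  pts <- as.matrix(expand.grid(grids))
  w <- as.matrix(expand.grid(rep(list(gh$weights), d)))
  sum(apply(w, 1, prod) * f(pts))
}

# tabulated response of one unit burst, built from exported primitives only
burst_response_oracle <- function(params, sigma = 0.3, t_max = 60,
                                  fine_rate = 100) {
  df <- 1 / fine_rate
  sg <- seq(-5 * sigma, 5 * sigma, by = df)
  g <- exp(-sg^2 / (2 * sigma^2))
  h <- impulse_response(params, t_max + 5 * sigma + df, fine_rate)
  b <- conv_oracle(c(g, numeric(length(h) - length(g))), h, df)
  approxfun(seq_along(b) * df - df - 5 * sigma, b, yleft = 0, yright = 0)
}
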