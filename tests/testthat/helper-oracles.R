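# Independent dense oracles.  These deliberately avoid the package's
# profiled/Woodbury code paths: everything is built from explicit design
# matrices and the textbook formulas.

# indicator matrix for a factor, one column per level
ind_mat <- function(f) {
  f <- factor(f)
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

# Restricted log-likelihood at (vu, ve) from the dense covariance:
# -1/2 [ log|V| + log|X'V^-1 X| + y'Py + (n-p) log 2pi ]
oracle_reml_loglik <- function(y, fixed, random, vu, ve, w = NULL) {
  X <- ind_mat(fixed)
  Z <- ind_mat(random)
  n <- length(y); p <- ncol(X)
  Winv <- if (is.null(w)) diag(n) else diag(1 / w)
  V <- vu * tcrossprod(Z) + ve * Winv
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  quad <- drop(crossprod(r, Vi %*% r))
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus + quad +
            (n - p) * log(2 * pi))
}

# GLS fixed estimates and conditional-mean (BLUP) random predictions
oracle_mme <- function(y, fixed, random, vu, ve) {
  X <- ind_mat(fixed)
  Z <- ind_mat(random)
  V <- vu * tcrossprod(Z) + ve * diag(length(y))
  Vi <- solve(V)
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  u <- vu * crossprod(Z, Vi %*% (y - X %*% beta))
  list(beta = drop(beta), u = drop(u),
       beta_names = colnames(X), u_names = colnames(Z))
}

# brute-force check-anchored binning, straight from the verbal rules
oracle_classify <- function(yields, tolerant, susceptible,
                            upper_anchor, lower_anchor) {
  top <- max(yields[tolerant])
  up <- yields[[upper_anchor]]
  lo <- yields[[lower_anchor]]
  vapply(yields, function(v) {
    if (v >= top) "high-yielding drought-tolerant"
    else if (v >= up) "moderately resistant"
    else if (v >= lo) "moderately susceptible"
    else "highly drought-susceptible"
  }, character(1))
}

# exhaustive best-subset by AIC over all subsets of candidates
oracle_best_subset <- function(y, X) {
  X <- as.data.frame(X)
  k <- ncol(X)
  best_aic <- Inf
  best <- character(0)
  for (mask in 0:(2^k - 1)) {
    sel <- names(X)[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    dat <- data.frame(y = y, X)
    f <- if (length(sel)) reformulate(sel, "y") else y ~ 1
    a <- AIC(lm(f, data = dat))
    if (a < best_aic - 1e-12) {
      best_aic <- a
      best <- sel
    }
  }
  list(selected = sort(best), aic = best_aic)
}

# small augmented-design generator for engine tests: nb blocks, checks in
# every block, unreplicated entries split across blocks
make_augmented <- function(n_entries = 8, n_checks = 2, nb = 2,
                           vg = 1, vb = 0.5, ve = 0.25, seed = 1) {
  set.seed(seed)
  checks <- paste0("chk", seq_len(n_checks))
  entries <- paste0("e", seq_len(n_entries))
  d <- rbind(
    expand.grid(genotype = checks, block = seq_len(nb),
                stringsAsFactors = FALSE),
    data.frame(genotype = entries,
               block = rep(seq_len(nb), length.out = n_entries)))
  g_eff <- rnorm(n_checks + n_entries, 0, sqrt(vg))
  names(g_eff) <- c(checks, entries)
  b_eff <- rnorm(nb, 0, sqrt(vb))
  d$y <- 10 + g_eff[d$genotype] + b_eff[d$block] + rnorm(nrow(d), 0, sqrt(ve))
  d$is_check <- d$genotype %in% checks
  d
}
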