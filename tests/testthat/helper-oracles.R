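# Independent oracles used across the suite. Each reimplements the quantity
# it checks by a different route than the package (quadrature, enumeration,
# explicit normal equations), so agreement is evidence, not tautology.

# Standard normal CDF by adaptive quadrature of the density; never calls
# pnorm. Accurate to well below 1e-12 absolute over [-8, 8].
phi_oracle <- function(z) {
  vapply(z, function(zz) {
    if (zz <= 0) {
      stats::integrate(stats::dnorm, -Inf, zz,
                       rel.tol = 1e-12, abs.tol = 1e-15)$value
    } else {
      1 - stats::integrate(stats::dnorm, zz, Inf,
                           rel.tol = 1e-12, abs.tol = 1e-15)$value
    }
  }, 0)
}

two_sided_p_oracle <- function(z) {
  vapply(z, function(zz) {
    if (zz < 0) 2 * phi_oracle(zz)
    else 2 * stats::integrate(stats::dnorm, zz, Inf,
                              rel.tol = 1e-12, abs.tol = 1e-15)$value
  }, 0)
}

# Pooled z by a different arithmetic path: the sqrt-difference is computed
# as (p1 - p2) / (sqrt(p1) + sqrt(p2)), which is algebraically identical
# but numerically distinct from the package's direct subtraction.
pooled_z_oracle <- function(x1, N1, x2, N2, variant = "sqrt") {
  p1 <- x1 / N1
  p2 <- x2 / N2
  num <- if (variant == "sqrt") {
    ifelse(p1 == p2, 0, (p1 - p2) / (sqrt(p1) + sqrt(p2)))
  } else {
    p1 - p2
  }
  num * sqrt(4 / (1 / N1 + 1 / N2))
}

# Exact hypergeometric upper tail P(|draw of size n from M, K marked| >= k)
# by full enumeration of all C(M, n) draws.
hyper_tail_enum <- function(k, n, K, M) {
  if (k <= 0) return(1)
  draws <- utils::combn(M, n)
  mean(colSums(draws <= K) >= k)
}

# Fixed-effects OLS oracle by explicit normal equations: returns LS means
# (equal weight over the other factors' levels), their SEs, and the
# marginal (drop-one) F test for each factor. Treatment-coded design built
# from scratch with model.matrix only as a dummy-expansion convenience.
ols_oracle <- function(data, response, factors) {
  for (f in factors) data[[f]] <- factor(data[[f]])
  y <- data[[response]]
  fml <- stats::reformulate(factors)
  X <- stats::model.matrix(fml, data)
  XtX_inv <- solve(crossprod(X))
  beta <- XtX_inv %*% crossprod(X, y)
  rss <- sum((y - X %*% beta)^2)
  df_res <- nrow(X) - ncol(X)
  s2 <- rss / df_res

  lsm <- lapply(factors, function(f) {
    grid <- expand.grid(lapply(factors, function(g) levels(data[[g]])),
                        KEEP.OUT.ATTRS = FALSE)
    names(grid) <- factors
    lv <- levels(data[[f]])
    means <- numeric(length(lv)); ses <- numeric(length(lv))
    for (i in seq_along(lv)) {
      rowsel <- grid[grid[[f]] == lv[i], , drop = FALSE]
      Xg <- stats::model.matrix(fml, rowsel)
      l <- colMeans(Xg)
      means[i] <- sum(l * beta)
      ses[i] <- sqrt(drop(t(l) %*% XtX_inv %*% l) * s2)
    }
    data.frame(level = lv, lsmean = means, se = ses, stringsAsFactors = FALSE)
  })
  names(lsm) <- factors

  ftests <- lapply(factors, function(f) {
    others <- setdiff(factors, f)
    X0 <- if (length(others)) stats::model.matrix(stats::reformulate(others), data)
          else matrix(1, nrow(data), 1)
    beta0 <- solve(crossprod(X0), crossprod(X0, y))
    rss0 <- sum((y - X0 %*% beta0)^2)
    df_f <- ncol(X) - ncol(X0)
    Fval <- ((rss0 - rss) / df_f) / s2
    data.frame(term = f, df = df_f, F = Fval,
               p = stats::pf(Fval, df_f, df_res, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  list(lsmeans = lsm, ftests = do.call(rbind, ftests),
       s2 = s2, df_res = df_res)
}

# Small ready-made calibration for toy tests: three aging days with
# symmetric means, consistent grade margins, one trait.
toy_calibration <- function() {
  list(
    grades = c("A", "B", "C"),
    aging_days = c(1L, 2L, 3L),
    shear = list(
      grade_means = list(A = 15, B = 20, C = 25),
      grade_sds = list(A = 1, B = 1, C = 1),
      aging_means = list(`1` = 10, `2` = 20, `3` = 30)
    ),
    traits = list(
      marbling = list(mean = list(A = 200, B = 300, C = 400),
                      sd = list(A = 10, B = 10, C = 10))
    )
  )
}

study_design <- function() design_spec()
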