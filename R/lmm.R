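## Linear mixed model with a single random intercept (participant), fitted by
## maximum likelihood. Marginal covariance per group g: sigma_e^2 (I + theta J),
## theta = sigma_u^2 / sigma_e^2. ML is used (not REML) so likelihood-ratio
## tests of fixed effects between nested models are valid. Wald p-values use
## a residual-degrees-of-freedom t reference (df = n - p - (G - 1)) with the
## matching scale correction of the ML variance estimate; at the extreme
## Bonferroni tails used by the screens the plain normal reference on ML
## standard errors is anti-conservative by several-fold.
##
## For the study design every participant carries the same set of condition
## rows, so the GLS estimate equals OLS (the group-sum direction lies in the
## span of the intercept) and the profiled likelihood in lambda = 1 + theta*m
## has a closed-form maximizer:
##   lambda_hat = max(1, (n - G) * SSB / (G * SSW))
## with SSB/SSW the between/within-participant sums of squares of the OLS
## residuals. This makes thousands of model fits (all metabolite pairs,
## replicated simulations) cheap. Unbalanced data fall back to a 1-D
## numerical profile likelihood; both paths are checked against lme4 in the
## test suite.

balanced_design <- function(X, g) {
  g <- as.factor(g)
  if (nlevels(g) < 2) return(FALSE)
  rows <- apply(X, 1, paste, collapse = ",")
  sp <- split(rows, g)
  sizes <- lengths(sp)
  if (length(unique(sizes)) != 1) return(FALSE)
  key <- vapply(sp, function(r) paste(sort(r), collapse = ";"), "")
  all(key == key[[1]])
}

## Closed-form ML for many outcomes sharing one balanced design.
## Y: n x K outcomes, X: n x p fixed-effect design (with intercept), g: groups.
fit_ri_lmm_multi <- function(Y, X, g) {
  Y <- as.matrix(Y)
  g <- as.factor(g)
  n <- nrow(Y); G <- nlevels(g); m <- n / G; K <- ncol(Y); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient fixed-effect design")
  beta <- qr.coef(qrX, Y)
  E <- qr.resid(qrX, Y)
  Tg <- rowsum(E, g)
  SSB <- colSums(Tg^2) / m
  SSE <- colSums(E^2)
  SSW <- pmax(SSE - SSB, 0)
  ok <- SSE > 1e-300 & SSW > 1e-300
  lambda <- ifelse(ok, pmax(1, (n - G) * SSB / (G * SSW)), NA_real_)
  sigma2 <- (SSW + SSB / lambda) / n
  ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1) - G / 2 * log(lambda)
  ## Wald SEs: X'V*inv X = X'X - (c/G) u u', u = colSums(X); Sherman-Morrison
  A <- crossprod(X)
  Ainv <- solve(A)
  u <- colSums(X)
  v <- drop(Ainv %*% u)
  q <- sum(u * v)
  cc <- (lambda - 1) / (m * lambda)          # c_g, per outcome
  w <- cc / G
  dA <- diag(Ainv)
  ## p x K matrix of diagonal entries of (X'V*inv X)^{-1}
  dinv <- outer(dA, rep(1, K)) + outer(v^2, w / (1 - w * q))
  se <- sqrt(sweep(dinv, 2, sigma2, `*`))
  z <- beta / se
  dfres <- max(n - p - (G - 1), 1)
  pval <- 2 * pt(-abs(z) * sqrt(dfres / n), df = dfres)
  dimnames(beta) <- dimnames(se) <- dimnames(pval) <-
    list(colnames(X), colnames(Y))
  list(beta = beta, se = se, p = pval, logLik = unname(ll),
       sigma2_e = unname(sigma2),
       sigma2_u = unname(sigma2 * (lambda - 1) / m),
       converged = unname(ok))
}

## Numerical profile-likelihood fit for one outcome, unbalanced groups allowed.
fit_ri_lmm_general <- function(y, X, g) {
  g <- as.factor(g)
  idx <- split(seq_along(y), g)
  ng <- lengths(idx)
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y^2)
  Xg1 <- t(matrix(vapply(idx, function(i) colSums(X[i, , drop = FALSE]),
                         numeric(ncol(X))), nrow = ncol(X)))   # G x p
  sg <- vapply(idx, function(i) sum(y[i]), 0) # G
  n <- length(y)
  prof <- function(theta) {
    cg <- theta / (1 + theta * ng)
    A <- XtX - crossprod(Xg1 * sqrt(cg))
    b <- Xty - drop(crossprod(Xg1, cg * sg))
    Syy <- yty - sum(cg * sg^2)
    beta <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(beta)) return(list(ll = -Inf))
    rss <- max(Syy - sum(beta * b), 1e-300)
    sigma2 <- rss / n
    ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1) -
      0.5 * sum(log1p(theta * ng))
    list(ll = ll, beta = beta, sigma2 = sigma2, A = A)
  }
  opt <- optimize(function(lt) -prof(exp(lt))$ll, c(-14, 14), tol = 1e-8)
  cand <- c(0, exp(opt$minimum))
  lls <- vapply(cand, function(th) prof(th)$ll, 0)
  theta <- cand[which.max(lls)]
  fit <- prof(theta)
  vc <- fit$sigma2 * solve(fit$A)
  se <- sqrt(diag(vc))
  z <- fit$beta / se
  dfres <- max(n - ncol(X) - (nlevels(g) - 1), 1)
  list(beta = setNames(fit$beta, colnames(X)),
       se = setNames(se, colnames(X)),
       p = setNames(2 * pt(-abs(z) * sqrt(dfres / n), df = dfres),
                    colnames(X)),
       logLik = fit$ll, sigma2_e = fit$sigma2, sigma2_u = fit$sigma2 * theta,
       converged = is.finite(fit$ll))
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Fits `y = X beta + u[group] + e` with `u ~ N(0, sigma_u^2)` and
#' `e ~ N(0, sigma_e^2)` by ML, profiling the variance ratio. A closed-form
#' path is used when every group shares the same design rows (the balanced
#' study layout); otherwise a one-dimensional profile likelihood is
#' maximized numerically. Wald p-values use a t reference with residual
#' degrees of freedom `n - p - (G - 1)`.
#'
#' @param y numeric outcome vector (rows with `NA` are dropped).
#' @param X fixed-effect design matrix including an intercept column.
#' @param group grouping factor (participant).
#' @return list with elements `beta`, `se`, `p` (per coefficient), `logLik`,
#'   `sigma2_e`, `sigma2_u`, `converged`.
#' @examples
#' set.seed(1)
#' g <- rep(1:6, each = 4)
#' x <- rep(c(0, 1, 2, 3), 6)
#' y <- 1 + 0.5 * x + rnorm(6)[g] + rnorm(24, sd = 0.3)
#' fit_ri_lmm(y, cbind(1, x), g)$beta
#' @export
fit_ri_lmm <- function(y, X, group) {
  X <- as.matrix(X)
  keep <- is.finite(y) & apply(is.finite(X), 1, all)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; group <- factor(group[keep])
  if (length(y) < ncol(X) + 2) stop("too few observations")
  if (sd(y) < 1e-12) {
    b <- rep(0, ncol(X)); b[1] <- mean(y)
    return(list(beta = setNames(b, colnames(X)),
                se = setNames(rep(NA_real_, ncol(X)), colnames(X)),
                p = setNames(rep(NA_real_, ncol(X)), colnames(X)),
                logLik = NA_real_, sigma2_e = 0, sigma2_u = 0,
                converged = FALSE))
  }
  if (balanced_design(X, group)) {
    f <- fit_ri_lmm_multi(matrix(y, ncol = 1), X, group)
    list(beta = setNames(drop(f$beta), colnames(X)),
         se = setNames(drop(f$se), colnames(X)),
         p = setNames(drop(f$p), colnames(X)),
         logLik = f$logLik, sigma2_e = f$sigma2_e, sigma2_u = f$sigma2_u,
         converged = f$converged)
  } else {
    fit_ri_lmm_general(y, X, group)
  }
}

## Likelihood-ratio p-value for nested ML fits; the statistic is clamped at 0.
lrt_pvalue <- function(ll_full, ll_null, df) {
  stat <- pmax(2 * (ll_full - ll_null), 0)
  pchisq(stat, df = df, lower.tail = FALSE)
}
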