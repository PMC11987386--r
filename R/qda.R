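# Quadratic discriminant analysis with a regularization knob.
#
# Each class is modeled as multivariate Gaussian with its own covariance;
# the discriminant is the maximum-a-posteriori score
#   g_i(x) = -1/2 (x-mu_i)' S_i^-1 (x-mu_i) - 1/2 log|S_i| + log p_i
# and posteriors follow by softmax over classes. reg blends the class
# covariance toward a scaled identity, S <- (1-reg) S + reg tr(S)/p I;
# at reg = 0 this coincides with classical QDA (cross-checked against
# MASS::qda in the test suite). A singular class covariance at reg = 0
# triggers a diagnostic fallback to reg = 1e-6 with a warning rather
# than a crash.

qda_fit <- function(x, y, reg = 0, tol = 1e-4) {
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  stopifnot(nlevels(y) >= 2)
  classes <- levels(y)
  fit_once <- function(reg) {
    comps <- lapply(classes, function(cl) {
      xi <- x[y == cl, , drop = FALSE]
      if (nrow(xi) < 2) stop("class '", cl, "' has fewer than 2 rows")
      mu <- colMeans(xi)
      s <- stats::cov(xi)
      if (reg > 0) {
        s <- (1 - reg) * s + reg * (sum(diag(s)) / ncol(s)) * diag(ncol(s))
      }
      r <- chol(s)  # errors on a singular covariance
      if (min(diag(r))^2 < tol * max(diag(r))^2 * .Machine$double.eps) {
        stop("effectively singular covariance for class '", cl, "'")
      }
      list(mu = mu, chol = r,
           logdet = 2 * sum(log(diag(r))),
           logprior = log(mean(y == cl)))
    })
    names(comps) <- classes
    comps
  }
  comps <- tryCatch(fit_once(reg), error = function(e) {
    if (reg > 0) stop(e)
    warning("singular class covariance with reg = 0; refitting with reg = 1e-6")
    fit_once(1e-6)
  })
  structure(list(classes = classes, comps = comps, p = ncol(x)),
            class = "liquidcascade_qda")
}

qda_discriminants <- function(fit, newx) {
  newx <- as.matrix(newx)
  g <- vapply(fit$classes, function(cl) {
    cm <- fit$comps[[cl]]
    centered <- sweep(newx, 2, cm$mu)
    z <- backsolve(cm$chol, t(centered), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * cm$logdet + cm$logprior
  }, numeric(nrow(newx)))
  matrix(g, nrow = nrow(newx), dimnames = list(NULL, fit$classes))
}

# posterior class probabilities by softmax over discriminants
predict_qda <- function(fit, newx) {
  g <- qda_discriminants(fit, newx)
  g <- g - apply(g, 1, max)
  e <- exp(g)
  e / rowSums(e)
}
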