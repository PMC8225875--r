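#' Train a ridge-regression BLUP (rrBLUP) genomic prediction model
#'
#' Solves the ridge system `(Z'Z + lambda I) u = Z'(y - ybar)` for marker
#' effects, with `Z` the column-centred allele-dosage matrix and
#' `lambda = sigma2_e / sigma2_u` the residual-to-marker variance ratio.
#' When `lambda` is not supplied it is estimated by REML through the
#' eigendecomposition of `ZZ'` (the standard spectral trick for the
#' equivalent kinship mixed model). Markers with zero variance in the
#' training set are dropped with a warning.
#'
#' @param geno allele-dosage matrix, individuals in rows, markers in
#'   columns.
#' @param pheno numeric phenotype vector.
#' @param lambda optional fixed ridge parameter; `NULL` to estimate by REML.
#' @param quiet suppress the zero-variance-marker warning (markers fixed in
#'   the training set are still dropped).
#' @return An object of class `rrblup_model`: marker `effects` (named by
#'   retained marker column), `intercept` (phenotype mean), column `means`
#'   used for centring, the markers kept, and `lambda`.
#' @export
rrblup_train <- function(geno, pheno, lambda = NULL, quiet = FALSE) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (n < 2 || length(pheno) != n)
    stop("need >= 2 training individuals with matching phenotypes")
  v <- apply(geno, 2, var)
  keep <- which(v > 0)
  if (length(keep) < ncol(geno) && !quiet)
    warning(sprintf("dropped %d zero-variance markers",
                    ncol(geno) - length(keep)))
  if (length(keep) == 0) stop("no segregating markers in training set")
  Z <- geno[, keep, drop = FALSE]
  mu <- mean(pheno)
  cm <- colMeans(Z)
  Z <- sweep(Z, 2, cm)
  yc <- pheno - mu

  if (is.null(lambda)) {
    K <- tcrossprod(Z)                     # n x n
    eig <- eigen(K, symmetric = TRUE)
    U <- eig$vectors
    d <- pmax(eig$values, 0)
    eta <- as.numeric(crossprod(U, yc))
    # REML log-likelihood of y = mu + g + e, g ~ N(0, s2u * K), profiled
    # over the total variance; optimize over the ratio lam = s2e / s2u.
    nll <- function(loglam) {
      lam <- exp(loglam)
      w <- d + lam                          # eigenvalues of K + lam I
      s2 <- sum(eta^2 / w) / (n - 1)        # profiled s2u (REML divisor)
      0.5 * ((n - 1) * log(s2) + sum(log(w)))
    }
    opt <- stats::optimize(nll, c(log(1e-8), log(1e8)))
    lambda <- exp(opt$minimum)
  }
  # effects via the n-dimensional system: u = Z'(ZZ' + lam I)^{-1} yc
  a <- solve(tcrossprod(Z) + lambda * diag(n), yc)
  u <- as.numeric(crossprod(Z, a))
  structure(list(effects = setNames(u, colnames(geno)[keep]),
                 intercept = mu, means = cm, markers = keep,
                 lambda = lambda, n_train = n),
            class = "rrblup_model")
}

#' @export
print.rrblup_model <- function(x, ...) {
  cat(sprintf(
    "rrBLUP model: %d markers, %d training individuals, lambda = %.4g\n",
    length(x$markers), x$n_train, x$lambda))
  invisible(x)
}

#' Genomic estimated breeding values
#'
#' Linear score `intercept + (dosage - training means) %*% effects`. To
#' emulate genotyping error the clean score can be perturbed with noise
#' calibrated so its squared correlation with the clean score equals
#' `h2_gebv` (0.95 by default when `noisy = TRUE`).
#'
#' @param model an `rrblup_model` from [rrblup_train()].
#' @param geno candidates: either a dosage matrix (individuals x markers,
#'   same marker columns as training) or an `hs_population`.
#' @param noisy add calibrated GEBV noise?
#' @param h2_gebv target squared correlation between noisy and clean scores.
#' @return Numeric vector of GEBVs.
#' @export
gebv <- function(model, geno, noisy = FALSE, h2_gebv = 0.95) {
  stopifnot(inherits(model, "rrblup_model"))
  if (inherits(geno, "hs_population")) {
    g <- model$intercept +
      .linear_score_cpp(geno$hap1, geno$hap2, model$markers - 1L,
                        unname(model$effects), unname(model$means))
  } else {
    Z <- as.matrix(geno)[, model$markers, drop = FALSE]
    Z <- sweep(Z, 2, model$means)
    g <- model$intercept + as.numeric(Z %*% model$effects)
  }
  if (noisy) {
    if (h2_gebv <= 0 || h2_gebv > 1) stop("'h2_gebv' must be in (0, 1]")
    vg <- var(g)
    if (vg > 0 && h2_gebv < 1)
      g <- g + rnorm(length(g), 0, sqrt(vg * (1 - h2_gebv) / h2_gebv))
  }
  g
}
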