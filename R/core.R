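#' Row-wise standardization to zero mean and unit sum of squares
#'
#' Centers each row and scales it to unit sum of squares.  Under this
#' convention, for standardized expression Z and genotypes X,
#' `Z %*% t(X)` is exactly the matrix of sample gene-SNP correlations, which
#' the correlation-screening step relies on.  The map is idempotent.
#'
#' @param m numeric matrix (rows are variables, columns are samples)
#' @return matrix of the same shape with zero-mean, unit sum-of-squares rows
#' @seealso [standardize()] for the method on the S4 containers
#' @examples
#' standardizeRows(matrix(c(0, 1, 2), 1, 3))
#' @export
standardizeRows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("standardization needs at least 2 samples")
  if (anyNA(m) || any(!is.finite(m))) stop("non-finite values in matrix")
  ctr <- m - rowMeans(m)
  ss <- sqrt(rowSums(ctr^2))
  bad <- ss <= sqrt(.Machine$double.eps) * pmax(1, sqrt(rowSums(m * m)))
  if (any(bad)) {
    lab <- rownames(m)[bad]
    if (is.null(lab)) lab <- which(bad)
    stop("zero variance in row(s): ", paste(utils::head(lab, 5L),
                                            collapse = ", "))
  }
  ctr / ss
}

#' Standardize a genotype or expression container
#'
#' Applies [standardizeRows()] to the underlying matrix and flags the object
#' as standardized.  Already-standardized objects are returned unchanged.
#'
#' @param x a [GenotypeMatrix-class] or [ExpressionMatrix-class]
#' @param ... unused
#' @return an object of the same class with standardized rows
#' @name standardize
NULL

#' @rdname standardize
setMethod("standardize", "GenotypeMatrix", function(x, ...) {
  if (x@standardized) return(x)
  new("GenotypeMatrix", values = standardizeRows(x@values),
      standardized = TRUE)
})

#' @rdname standardize
setMethod("standardize", "ExpressionMatrix", function(x, ...) {
  if (x@standardized) return(x)
  new("ExpressionMatrix", values = standardizeRows(x@values),
      standardized = TRUE)
})

#' @rdname standardize
setMethod("standardize", "matrix", function(x, ...) standardizeRows(x))

## Coerce a fitting input to a plain standardized matrix.
.stdValues <- function(x) {
  if (is(x, "GenotypeMatrix") || is(x, "ExpressionMatrix"))
    return(as.matrix(standardize(x)))
  standardizeRows(as.matrix(x))
}

#' Singular-value thresholding (proximal operator of the nuclear norm)
#'
#' Returns `U D_lam V^T` where `U D V^T` is the SVD of `O` and
#' `D_lam = diag((d_i - lam)_+)`: every singular value is reduced by `lam`
#' and floored at zero.  This is the unique minimizer of
#' `0.5 * ||O - S||_F^2 + lam * ||S||_*` (nuclear norm), the building block
#' of the low-rank confounder update.
#'
#' @param O numeric matrix
#' @param lam nonnegative shrinkage level
#' @return matrix of the same shape as `O`
#' @examples
#' svt(diag(c(3, 1)), 2)   # diag(1, 0)
#' @export
svt <- function(O, lam) {
  O <- as.matrix(O)
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0)
    stop("'lam' must be a single nonnegative number")
  if (any(!is.finite(O))) stop("non-finite values in 'O'")
  if (lam == 0) return(O)
  s <- svd(O)
  d <- pmax(s$d - lam, 0)
  keep <- d > 0
  out <- if (!any(keep)) {
    matrix(0, nrow(O), ncol(O))
  } else {
    s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
  }
  dimnames(out) <- dimnames(O)
  out
}

.nuclearNorm <- function(m) {
  if (all(m == 0)) return(0)
  sum(svd(m, nu = 0, nv = 0)$d)
}

#' Squared-residual loss of the decoupled association model
#'
#' Computes `||Z - L - (B %*% A + C) %*% X||_F^2`, the data-fit term shared
#' by all model variants.
#'
#' @param Z N x H expression matrix
#' @param L N x H confounder matrix
#' @param A M x K latent-factor loading on SNPs
#' @param B N x M gene loading on latent factors
#' @param C N x K individual-association matrix
#' @param X K x H genotype matrix
#' @return a nonnegative scalar
#' @export
geqtlLoss <- function(Z, L, A, B, C, X) {
  Z <- as.matrix(Z); X <- as.matrix(X)
  stopifnot(ncol(A) == nrow(X), nrow(B) == nrow(Z), ncol(B) == nrow(A),
            all(dim(C) == c(nrow(Z), nrow(X))), all(dim(L) == dim(Z)))
  R <- Z - L - (B %*% A + C) %*% X
  sum(R * R)
}

.penaltyC <- function(C, gamma, variant) {
  if (variant == "geqtl_ridge") gamma * sum(C * C) else gamma * sum(abs(C))
}

.objectiveValue <- function(Z, X, A, B, C, L, alpha, beta, gamma, rho,
                            variant = "geqtl") {
  geqtlLoss(Z, L, A, B, C, X) + rho * .nuclearNorm(L) +
    alpha * sum(abs(A)) + beta * sum(abs(B)) + .penaltyC(C, gamma, variant)
}

#' Penalized objective of a fitted model
#'
#' The loss [geqtlLoss()] plus `rho ||L||_* + alpha ||A||_1 + beta ||B||_1`
#' and `gamma ||C||_1` (or `gamma ||C||_2^2` for the ridge variant).
#'
#' @param object a [GeQTLModel-class]
#' @param X genotype input (standardized internally if needed)
#' @param Z expression input (standardized internally if needed)
#' @param ... unused
#' @return a nonnegative scalar
#' @name geqtlObjective
NULL

#' @rdname geqtlObjective
setMethod("geqtlObjective", "GeQTLModel", function(object, X, Z, ...) {
  hp <- object@hyperparams
  .objectiveValue(.stdValues(Z), .stdValues(X), object@A, object@B,
                  object@C, object@L, hp$alpha, hp$beta, hp$gamma, hp$rho,
                  object@variant)
})
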