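#' @import methods
NULL

.checkLabelledMatrix <- function(values, what) {
  msg <- NULL
  if (!is.matrix(values) || !is.numeric(values))
    msg <- c(msg, sprintf("%s 'values' must be a numeric matrix", what))
  else {
    if (is.null(rownames(values)) || is.null(colnames(values)))
      msg <- c(msg, sprintf("%s must carry row and column identifiers", what))
    else {
      if (anyDuplicated(rownames(values)))
        msg <- c(msg, sprintf("duplicate row identifiers in %s", what))
      if (anyDuplicated(colnames(values)))
        msg <- c(msg, sprintf("duplicate sample identifiers in %s", what))
    }
    if (anyNA(values))
      msg <- c(msg, sprintf("%s contains missing values", what))
  }
  msg
}

#' GenotypeMatrix: SNPs-by-samples genotype data
#'
#' Container for a K x H genotype matrix with SNPs as rows and samples as
#' columns.  Raw genotypes are minor-allele counts coded 0/1/2; after
#' [standardize()] each row has zero mean and unit sum of squares, the
#' convention under which `Z %*% t(X)` is exactly the matrix of sample
#' gene-SNP correlations.
#'
#' @slot values numeric K x H matrix with SNP ids as rownames and sample ids
#'   as colnames.
#' @slot standardized logical; `FALSE` while entries are raw 0/1/2 codes.
#' @export
setClass("GenotypeMatrix",
  representation(values = "matrix", standardized = "logical"),
  validity = function(object) {
    msg <- .checkLabelledMatrix(object@values, "GenotypeMatrix")
    if (is.null(msg) && !object@standardized &&
        !all(object@values %in% c(0, 1, 2)))
      msg <- c(msg, "raw genotype entries must be 0, 1 or 2")
    if (is.null(msg)) TRUE else msg
  })

#' ExpressionMatrix: genes-by-samples expression data
#'
#' Container for an N x H matrix of continuous expression traits, genes as
#' rows and samples as columns, sample order matching the paired
#' [GenotypeMatrix-class].
#'
#' @slot values numeric N x H matrix with gene ids as rownames and sample ids
#'   as colnames.
#' @slot standardized logical; `TRUE` once rows are zero-mean, unit
#'   sum-of-squares.
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", standardized = "logical"),
  validity = function(object) {
    msg <- .checkLabelledMatrix(object@values, "ExpressionMatrix")
    if (is.null(msg)) TRUE else msg
  })

#' ScreeningMask: which individual associations may be nonzero
#'
#' Binary N x K indicator matrix R from marginal-correlation screening:
#' `R[i, j] = 1` iff `|cor(gene i, SNP j)| > thresholdR`.  Only masked-in
#' entries of the individual-association matrix C are optimized by the
#' screened model variants.
#'
#' @slot R numeric 0/1 matrix, genes x SNPs.
#' @slot thresholdR correlation threshold in `[0, 1]` implied by `pvalue`.
#' @slot pvalue two-sided significance level the threshold was derived from.
#' @export
setClass("ScreeningMask",
  representation(R = "matrix", thresholdR = "numeric", pvalue = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(object@R %in% c(0, 1)))
      msg <- c(msg, "mask entries must be 0 or 1")
    if (length(object@thresholdR) != 1L || object@thresholdR < 0 ||
        object@thresholdR > 1)
      msg <- c(msg, "thresholdR must be a single value in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' GeQTLModel: a fitted sparse group-wise + individual association model
#'
#' Holds the fitted quadruple (A, B, C, L) of the model
#' `Z = L + (B %*% A + C) %*% X + E`: A (M x K) maps SNPs to M latent group
#' factors, B (N x M) maps factors to genes, C (N x K) carries individual
#' SNP-gene effects and L (N x H) absorbs low-rank confounding variation.
#' The total association matrix is `B %*% A + C` (see [assocMatrix()]).
#'
#' @slot A,B,C,L fitted coefficient matrices (see description).
#' @slot M integer, number of group-wise associations (latent factors).
#' @slot variant one of `"geqtl"`, `"geqtl_plus"`, `"geqtl_ridge"`.
#' @slot hyperparams named list with elements alpha, beta, gamma, rho.
#' @slot mask `ScreeningMask` or `NULL`; required for the screened variants.
#' @slot objectiveTrace numeric, objective after every block update (named by
#'   block); the first element is the objective at initialization.
#' @slot sweeps integer, number of completed coordinate sweeps.
#' @slot converged logical, whether the relative-change tolerance was met.
#' @export
setClass("GeQTLModel",
  representation(A = "matrix", B = "matrix", C = "matrix", L = "matrix",
                 M = "integer", variant = "character",
                 hyperparams = "list", mask = "ANY",
                 objectiveTrace = "numeric", sweeps = "integer",
                 converged = "logical"),
  validity = function(object) {
    msg <- NULL
    M <- object@M
    K <- ncol(object@A); N <- nrow(object@B)
    if (nrow(object@A) != M || ncol(object@B) != M)
      msg <- c(msg, "A must be M x K and B must be N x M")
    if (!identical(dim(object@C), c(N, K)))
      msg <- c(msg, "C must be N x K")
    if (nrow(object@L) != N)
      msg <- c(msg, "L must have one row per gene")
    if (!object@variant %in% c("geqtl", "geqtl_plus", "geqtl_ridge"))
      msg <- c(msg, "unknown variant")
    if (object@variant != "geqtl" && !is(object@mask, "ScreeningMask"))
      msg <- c(msg, "screened variants require a ScreeningMask")
    if (is(object@mask, "ScreeningMask") &&
        any(object@C[object@mask@R == 0] != 0))
      msg <- c(msg, "C has nonzero entries outside the screening mask")
    if (is.null(msg)) TRUE else msg
  })

#' BaselineModel: Lasso or low-rank-plus-sparse (LORS-style) baseline
#'
#' @slot W N x K association coefficient matrix.
#' @slot L N x H low-rank confounder matrix, or `NULL` for plain Lasso.
#' @slot variant `"lasso"` or `"lors"`.
#' @slot hyperparams named list (eta, and rho for `"lors"`).
#' @slot objectiveTrace numeric objective values across updates.
#' @slot converged logical.
#' @export
setClass("BaselineModel",
  representation(W = "matrix", L = "ANY", variant = "character",
                 hyperparams = "list", objectiveTrace = "numeric",
                 converged = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!object@variant %in% c("lasso", "lors"))
      msg <- c(msg, "variant must be 'lasso' or 'lors'")
    if (object@variant == "lasso" && !is.null(object@L))
      msg <- c(msg, "lasso baseline must not carry an L matrix")
    if (object@variant == "lors" &&
        (!is.matrix(object@L) || nrow(object@L) != nrow(object@W)))
      msg <- c(msg, "lors baseline requires an N x H matrix L")
    if (is.null(msg)) TRUE else msg
  })

#' SimTruth: ground truth of a simulated eQTL dataset
#'
#' Records the true coefficient matrix beta (group blocks plus cis diagonal),
#' the confounder loadings and realized confounder/noise components of
#' `Z = beta %*% X + Xi + E`.
#'
#' @slot beta N x K true coefficients.
#' @slot blocks list of group blocks, each `list(snps =, genes =)` index sets.
#' @slot F H x J confounder loading matrix (Lambda = F F^T).
#' @slot Xi N x H realized confounder effect, rows ~ N(0, tau * F F^T).
#' @slot E N x H realized Gaussian noise, entries ~ N(0, phi).
#' @export
setClass("SimTruth",
  representation(beta = "matrix", blocks = "list", F = "matrix",
                 Xi = "matrix", E = "matrix"))

#' SimulatedEQTL: a full simulated dataset with ground truth
#'
#' @slot X raw [GenotypeMatrix-class].
#' @slot Z [ExpressionMatrix-class] generated as `beta X + Xi + E`.
#' @slot truth [SimTruth-class].
#' @slot config named list of all generator parameters including the seed.
#' @export
setClass("SimulatedEQTL",
  representation(X = "GenotypeMatrix", Z = "ExpressionMatrix",
                 truth = "SimTruth", config = "list"))

#' RankDiagnostics: singular-value diagnostics for selecting M
#'
#' @slot singularValues descending singular values of the least-squares
#'   group-association estimate `(Z - L - C X) X^T (X X^T)^{-1}`.
#' @slot gapRatios successive ratios `s_k / s_{k+1}` considered by the gap
#'   rule.
#' @slot chosenM selected number of group-wise associations.
#' @slot iterations outer refinement iterations performed (0 for a single
#'   inference).
#' @slot stable logical; `FALSE` when no dominant gap was found or the outer
#'   refinement oscillated.
#' @export
setClass("RankDiagnostics",
  representation(singularValues = "numeric", gapRatios = "numeric",
                 chosenM = "integer", iterations = "integer",
                 stable = "logical"))

#' RocResult: a partial ROC curve against simulation truth
#'
#' @slot fpr,tpr operating points (ascending fpr), including (0, 0).
#' @slot partialAuc trapezoidal area under the curve on `[0, fprCap]`.
#' @slot fprCap upper limit of the false-positive-rate range of interest.
#' @export
setClass("RocResult",
  representation(fpr = "numeric", tpr = "numeric", partialAuc = "numeric",
                 fprCap = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (is.unsorted(object@fpr)) msg <- c(msg, "fpr must be ascending")
    if (is.unsorted(object@tpr, strictly = FALSE))
      msg <- c(msg, "tpr must be non-decreasing")
    if (object@partialAuc < -1e-12 ||
        object@partialAuc > object@fprCap + 1e-12)
      msg <- c(msg, "partialAuc must lie in [0, fprCap]")
    if (is.null(msg)) TRUE else msg
  })
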