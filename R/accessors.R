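#' Construct a GenotypeMatrix
#'
#' @param values numeric K x H matrix of genotypes coded 0/1/2 (SNPs as rows,
#'   samples as columns).  Row/column names are used as SNP and sample ids;
#'   defaults (`snp1..snpK`, `s1..sH`) are filled in when absent.
#' @param standardized logical; set `TRUE` only if `values` are already
#'   zero-mean, unit sum-of-squares rows.
#' @return a [GenotypeMatrix-class]
#' @examples
#' X <- GenotypeMatrix(matrix(rbinom(20, 2, 0.4), 4, 5))
#' snpIds(X)
#' @export
GenotypeMatrix <- function(values, standardized = FALSE) {
  values <- .labelMatrix(as.matrix(values), "snp", "s")
  new("GenotypeMatrix", values = values, standardized = standardized)
}

#' Construct an ExpressionMatrix
#'
#' @param values numeric N x H matrix of expression traits (genes as rows,
#'   samples as columns).  Row/column names are used as gene and sample ids;
#'   defaults (`gene1..geneN`, `s1..sH`) are filled in when absent.
#' @param standardized logical; set `TRUE` only if rows are already zero-mean
#'   with unit sum of squares.
#' @return an [ExpressionMatrix-class]
#' @export
ExpressionMatrix <- function(values, standardized = FALSE) {
  values <- .labelMatrix(as.matrix(values), "gene", "s")
  new("ExpressionMatrix", values = values, standardized = standardized)
}

.labelMatrix <- function(m, rowPrefix, colPrefix) {
  storage.mode(m) <- "double"
  if (is.null(rownames(m)))
    rownames(m) <- paste0(rowPrefix, seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- paste0(colPrefix, seq_len(ncol(m)))
  m
}

#' Identifier and state accessors
#'
#' @param x a [GenotypeMatrix-class] or [ExpressionMatrix-class]
#' @name accessors
#' @aliases snpIds geneIds sampleIds isStandardized
NULL

#' @rdname accessors
setMethod("snpIds", "GenotypeMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("isStandardized", "GenotypeMatrix", function(x) x@standardized)
#' @rdname accessors
setMethod("isStandardized", "ExpressionMatrix", function(x) x@standardized)

#' @export
setMethod("as.matrix", "GenotypeMatrix", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "ExpressionMatrix", function(x, ...) x@values)
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@values))
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' Fitted-model accessors
#'
#' `assocMatrix()` returns the total association matrix `B %*% A + C`;
#' `groupAssoc()` the rank-M group-wise part `B %*% A`; `indivAssoc()` the
#' individual part C; `confounders()` the low-rank matrix L; and
#' `objectiveTrace()` the objective value after every block update.
#'
#' @param object a fitted [GeQTLModel-class] (or [BaselineModel-class] where
#'   applicable)
#' @name assocMatrix
NULL

#' @rdname assocMatrix
setMethod("assocMatrix", "GeQTLModel", function(object)
  object@B %*% object@A + object@C)
#' @rdname assocMatrix
setMethod("assocMatrix", "BaselineModel", function(object) object@W)
#' @rdname assocMatrix
setMethod("groupAssoc", "GeQTLModel", function(object) object@B %*% object@A)
#' @rdname assocMatrix
setMethod("indivAssoc", "GeQTLModel", function(object) object@C)
#' @rdname assocMatrix
setMethod("confounders", "GeQTLModel", function(object) object@L)
#' @rdname assocMatrix
setMethod("confounders", "BaselineModel", function(object) object@L)
#' @rdname assocMatrix
setMethod("objectiveTrace", "GeQTLModel", function(object)
  object@objectiveTrace)
#' @rdname assocMatrix
setMethod("objectiveTrace", "BaselineModel", function(object)
  object@objectiveTrace)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d samples (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@standardized) "standardized" else "raw 0/1/2"))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@standardized) "standardized" else "raw"))
})

setMethod("show", "GeQTLModel", function(object) {
  hp <- object@hyperparams
  cat(sprintf("GeQTLModel (variant '%s')\n", object@variant))
  cat(sprintf("  %d genes x %d SNPs, M = %d group-wise associations\n",
              nrow(object@B), ncol(object@A), object@M))
  cat(sprintf("  penalties: alpha=%.3g beta=%.3g gamma=%.3g rho=%.3g\n",
              hp$alpha, hp$beta, hp$gamma, hp$rho))
  cat(sprintf("  nonzero: A %d, B %d, C %d; rank(L) = %d\n",
              sum(object@A != 0), sum(object@B != 0), sum(object@C != 0),
              qr(object@L)$rank))
  cat(sprintf("  %d sweeps, objective %.6g (%s)\n", object@sweeps,
              utils::tail(object@objectiveTrace, 1L),
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "BaselineModel", function(object) {
  cat(sprintf("BaselineModel (variant '%s'): %d x %d, %d nonzero W\n",
              object@variant, nrow(object@W), ncol(object@W),
              sum(object@W != 0)))
})

setMethod("show", "ScreeningMask", function(object) {
  cat(sprintf(
    "ScreeningMask: %d x %d, density %.3f (|r| > %.4f at p = %g)\n",
    nrow(object@R), ncol(object@R), mean(object@R), object@thresholdR,
    object@pvalue))
})

setMethod("show", "RankDiagnostics", function(object) {
  cat(sprintf("RankDiagnostics: chosen M = %d (%s, %d iterations)\n",
              object@chosenM,
              if (object@stable) "stable" else "unstable",
              object@iterations))
  cat("  leading singular values:",
      paste(signif(utils::head(object@singularValues, 8L), 4),
            collapse = " "), "\n")
})

setMethod("show", "SimulatedEQTL", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SimulatedEQTL: %d SNPs x %d genes x %d samples, %d group blocks%s\n",
    cfg$K, cfg$N, cfg$H, length(object@truth@blocks),
    if (isTRUE(cfg$cisDiagonal)) " + cis diagonal" else ""))
  cat(sprintf("  phi=%g tau=%g J=%d, realized SNR = %.4g\n",
              cfg$phi, cfg$tau, cfg$J, snr(object)))
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: %d points, partial AUC %.5f on FPR in [0, %g]\n",
              length(object@fpr), object@partialAuc, object@fprCap))
})
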