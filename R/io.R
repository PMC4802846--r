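#' Read a labelled matrix from TSV
#'
#' Expects one header row of sample ids and one leading id column (SNP or
#' gene ids), with a numeric body.  Duplicate identifiers, ragged rows and
#' missing/non-numeric cells are rejected with the offending row/column
#' named.
#'
#' @param path path to a tab-separated file
#' @return numeric matrix with row and column names
#' @export
readMatrixTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("expected an id column plus at least one sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at row '%s', column '%s'",
                 ids[bad[1L]], samples[bad[2L]]))
  }
  dimnames(vals) <- list(ids, samples)
  vals
}

#' Write a labelled matrix as TSV
#'
#' Values are written with 10 significant digits so that re-reading
#' reproduces them at full printed precision and diffs are stable.
#'
#' @param m numeric matrix with row and column names (or a
#'   [GenotypeMatrix-class] / [ExpressionMatrix-class])
#' @param path output path
#' @param idHeader name of the leading identifier column
#' @return `path`, invisibly
#' @export
writeMatrixTSV <- function(m, path, idHeader = "id") {
  if (is(m, "GenotypeMatrix") || is(m, "ExpressionMatrix"))
    m <- as.matrix(m)
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  body <- apply(m, 2L, function(col) formatC(col, digits = 10, format = "g"))
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(m))
  lines <- c(paste(c(idHeader, colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write the ranked association table of a model
#'
#' @param object a fitted [GeQTLModel-class] or [BaselineModel-class]
#' @param path output TSV path
#' @param topN optional cap on the number of pairs written
#' @return `path`, invisibly
#' @export
writeAssociations <- function(object, path, topN = NULL) {
  df <- associationTable(object, topN = topN)
  for (cn in c("weight_total", "weight_individual", "weight_groupwise"))
    df[[cn]] <- formatC(df[[cn]], digits = 10, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Writes `X.tsv` (raw genotypes), `Z.tsv` (expression), `beta.tsv` (ground
#' truth coefficients) and a `config.json`-style sidecar recording every
#' generator parameter including the seed.
#'
#' @param sim a [SimulatedEQTL-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixTSV(sim@X, file.path(dir, "X.tsv"), idHeader = "snp_id")
  writeMatrixTSV(sim@Z, file.path(dir, "Z.tsv"), idHeader = "gene_id")
  beta <- sim@truth@beta
  dimnames(beta) <- list(rownames(as.matrix(sim@Z)),
                         rownames(as.matrix(sim@X)))
  writeMatrixTSV(beta, file.path(dir, "beta.tsv"), idHeader = "gene_id")
  cfg <- sim@config
  cfg$realizedSnr <- snr(sim)
  cfgLines <- vapply(names(cfg), function(nm)
    paste0(nm, "\t", paste(format(cfg[[nm]], digits = 10), collapse = ",")),
    character(1))
  writeLines(cfgLines, file.path(dir, "config.tsv"))
  invisible(dir)
}
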