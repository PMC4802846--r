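#' Partial ROC curve of association weights against ground truth
#'
#' Sweeps a threshold over `|weights|`; every cell whose truth label is
#' nonzero counts as a positive (group blocks and the cis diagonal alike).
#' Cells with tied `|weight|` enter the positive call set together, giving a
#' step curve with one operating point per distinct value.  The partial AUC
#' is the trapezoidal area under the curve restricted to
#' `fpr <= fprCap` (with linear interpolation at the cap); for the
#' degenerate all-constant weight matrix the single operating point yields
#' `partialAuc = fprCap * tpr`.
#'
#' @param weights numeric N x K association weights (e.g.
#'   `abs(assocMatrix(fit))`)
#' @param truth logical/binary N x K ground-truth support, or a
#'   [SimTruth-class] / [SimulatedEQTL-class]
#' @param fprCap upper false-positive-rate limit of interest (default 0.1,
#'   the customary range for eQTL benchmarks)
#' @return a [RocResult-class]
#' @export
rocCurve <- function(weights, truth, fprCap = 0.1) {
  if (is(truth, "SimulatedEQTL") || is(truth, "SimTruth"))
    truth <- truthSupport(truth)
  weights <- abs(as.matrix(weights))
  lab <- as.vector(truth != 0)
  stopifnot(length(lab) == length(weights), fprCap > 0, fprCap <= 1)
  P <- sum(lab); Ng <- sum(!lab)
  if (P == 0L || Ng == 0L)
    stop("truth must contain at least one positive and one negative cell")
  w <- as.vector(weights)
  ord <- order(w, decreasing = TRUE)
  wS <- w[ord]; labS <- lab[ord]
  ## group ties: one operating point after each distinct weight value
  grpEnd <- which(diff(wS) != 0)
  grpEnd <- c(grpEnd, length(wS))
  tp <- cumsum(labS)[grpEnd]
  fp <- grpEnd - tp
  tpr <- tp / P
  fpr <- fp / Ng
  if (length(grpEnd) == 1L) {
    pauc <- fprCap * tpr
  } else {
    fprA <- c(0, fpr); tprA <- c(0, tpr)
    pauc <- .trapezoidCapped(fprA, tprA, fprCap)
    fpr <- fprA; tpr <- tprA
  }
  new("RocResult", fpr = fpr, tpr = tpr, partialAuc = pauc,
      fprCap = fprCap)
}

.trapezoidCapped <- function(fpr, tpr, cap) {
  area <- 0
  for (i in seq_len(length(fpr) - 1L)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1L]
    if (x0 >= cap) break
    y0 <- tpr[i]; y1 <- tpr[i + 1L]
    if (x1 > cap) {
      y1 <- if (x1 > x0) y0 + (y1 - y0) * (cap - x0) / (x1 - x0) else y1
      x1 <- cap
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

#' Ranked association table of a fitted model
#'
#' Flattens the association weights into a (gene, SNP) table sorted by
#' decreasing `|weight_total|` with ties broken by gene then SNP id order
#' (stable), reporting the total, individual (C) and group-wise (B A)
#' components.
#'
#' @param object a [GeQTLModel-class] or [BaselineModel-class]
#' @param topN optionally keep only the strongest `topN` pairs
#' @return data.frame with columns gene_id, snp_id, weight_total,
#'   weight_individual, weight_groupwise
#' @export
associationTable <- function(object, topN = NULL) {
  W <- assocMatrix(object)
  if (is(object, "GeQTLModel")) {
    Ci <- indivAssoc(object); G <- groupAssoc(object)
  } else {
    Ci <- W; G <- W * 0
  }
  genes <- rownames(W); snps <- colnames(W)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(W)))
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(W)))
  df <- data.frame(
    gene_id = rep(genes, times = ncol(W)),
    snp_id = rep(snps, each = nrow(W)),
    weight_total = as.vector(W),
    weight_individual = as.vector(Ci),
    weight_groupwise = as.vector(G),
    stringsAsFactors = FALSE)
  df <- df[order(-abs(df$weight_total), df$gene_id, df$snp_id), ]
  rownames(df) <- NULL
  if (!is.null(topN)) df <- utils::head(df, topN)
  df
}

.pairKeys <- function(x) {
  if (is.data.frame(x)) {
    gi <- if ("gene_id" %in% names(x)) x$gene_id else x[[1L]]
    si <- if ("snp_id" %in% names(x)) x$snp_id else x[[2L]]
    paste(gi, si, sep = "\r")
  } else as.character(x)
}

#' Reproducibility of top-ranked associations between two studies
#'
#' Fraction of (gene, SNP) pairs shared between the top `T` entries of two
#' ranked association lists: `|L1^T  intersect  L2^T| / T`.
#'
#' @param list1,list2 ranked association lists: data.frames with gene/snp id
#'   columns in rank order (e.g. from [associationTable()]), or character
#'   vectors of pair keys
#' @param T depth of the comparison, `1 <= T <= min(lengths)`
#' @return overlap fraction in `[0, 1]`
#' @export
topAssocOverlap <- function(list1, list2, T) {
  k1 <- .pairKeys(list1); k2 <- .pairKeys(list2)
  T <- as.integer(T)
  if (T < 1L || T > min(length(k1), length(k2)))
    stop("'T' must be between 1 and the length of the shorter list")
  length(intersect(k1[seq_len(T)], k2[seq_len(T)])) / T
}

.hotspotRank <- function(assoc, snpIds) {
  si <- if (is.data.frame(assoc)) {
    if ("snp_id" %in% names(assoc)) assoc$snp_id else assoc[[2L]]
  } else as.character(assoc)
  deg <- table(factor(si, levels = snpIds))
  ## sort by degree descending, ties resolved by stable SNP-id order
  names(deg)[order(-as.vector(deg), seq_along(deg))]
}

#' Reproducibility of regulatory hotspots between two studies
#'
#' Each SNP's regulatory degree is the number of genes it is associated
#' with in the given (already significance-filtered) association set.  SNPs
#' are sorted by decreasing degree -- ties crossing the depth-T boundary are
#' resolved by stable SNP-id order -- and the fraction of SNPs shared
#' between the two top-T lists, `|S1^T intersect S2^T| / T`, is returned.
#'
#' @param assoc1,assoc2 significant association sets: data.frames with a
#'   `snp_id` column (one row per significant gene-SNP pair)
#' @param T depth of the hotspot comparison
#' @param snpIds optional character vector fixing the SNP universe and the
#'   tie-break order; defaults to the sorted union of SNPs present
#' @return overlap fraction in `[0, 1]`
#' @export
hotspotOverlap <- function(assoc1, assoc2, T, snpIds = NULL) {
  getSnps <- function(a) {
    if (is.data.frame(a)) {
      if ("snp_id" %in% names(a)) a$snp_id else a[[2L]]
    } else as.character(a)
  }
  if (is.null(snpIds))
    snpIds <- sort(unique(c(getSnps(assoc1), getSnps(assoc2))))
  T <- as.integer(T)
  if (T < 1L || T > length(snpIds))
    stop("'T' must be between 1 and the number of SNPs")
  s1 <- .hotspotRank(assoc1, snpIds)[seq_len(T)]
  s2 <- .hotspotRank(assoc2, snpIds)[seq_len(T)]
  length(intersect(s1, s2)) / T
}
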