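#' Eight-point staining signature
#'
#' Reduces the 2 x 4 grid of treatments (untreated/heat-treated x unstained,
#' FDA, CMFDA, FDA+CMFDA) to a signature of mean log10 fluorescence values,
#' each normalized to the overall mean of the eight. Normalization removes
#' per-cell brightness (biovolume) so replicate experiments can be compared
#' on staining pattern alone.
#'
#' @param mean_logs numeric vector of 8 mean log10 fluorescence values,
#'   ordered (untreated, heat_treated) x (none, FDA, CMFDA, FDA_CMFDA);
#'   names are attached if absent.
#' @return A `signature` object (class `c("signature8", "signature")`) whose
#'   values average exactly 1.
#' @export
staining_signature <- function(mean_logs) {
  if (length(mean_logs) != 8 || any(!is.finite(mean_logs)))
    stop("incomplete grid: need 8 finite treatment means")
  m <- mean(mean_logs)
  if (abs(m) < 1e-9) stop("degenerate signature: mean of treatment means is ~0")
  v <- mean_logs / m
  if (is.null(names(v)))
    names(v) <- paste(rep(c("untreated", "heat_treated"), each = 4),
                      rep(c("none", "FDA", "CMFDA", "FDA_CMFDA"), 2),
                      sep = ".")
  structure(v, class = c("signature8", "signature"))
}

#' Three-point separation signature
#'
#' The live-vs-dead separation statistic for each stain (FDA, CMFDA,
#' FDA+CMFDA), normalized to the mean of the three values. Separation can be
#' negative (dead cells staining brighter than live), so these signatures
#' are compared with Euclidean distance, not Bray-Curtis.
#'
#' @param separations numeric vector of 3 separation statistics, ordered
#'   (FDA, CMFDA, FDA_CMFDA).
#' @return A `signature` object (class `c("signature3", "signature")`).
#' @export
separation_signature <- function(separations) {
  if (length(separations) != 3 || any(!is.finite(separations)))
    stop("need 3 finite separation values")
  m <- mean(separations)
  if (abs(m) < 1e-9)
    stop("degenerate signature: mean separation is ~0, cannot normalize")
  v <- separations / m
  if (is.null(names(v))) names(v) <- c("FDA", "CMFDA", "FDA_CMFDA")
  structure(v, class = c("signature3", "signature"))
}

#' Bray-Curtis similarity between two signatures
#'
#' `100 * (1 - sum|a - b| / sum(a + b))`, in percent. Defined only for
#' non-negative signatures, which restricts it to the 8-point staining
#' signatures; 3-point separation signatures can carry negative values and
#' are compared with Euclidean distance instead.
#'
#' @param a,b numeric vectors of equal length with non-negative entries.
#' @return similarity in percent (100 iff identical).
#' @export
bray_curtis_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("signatures must have equal length")
  if (any(a < 0) || any(b < 0))
    stop("Bray-Curtis is undefined for negative entries")
  tot <- sum(a + b)
  if (tot == 0) return(100)
  100 * (1 - sum(abs(a - b)) / tot)
}

#' Replicate consistency by mean pairwise Bray-Curtis similarity
#'
#' A species stains consistently when the mean pairwise Bray-Curtis
#' similarity between its replicate 8-point staining signatures is at least
#' 95% (boundary inclusive).
#'
#' @param replicate_signatures list of >= 2 signatures (>= 3 expected for a
#'   full experiment).
#' @param cutoff similarity cutoff in percent (default 95).
#' @return list with `consistent` (logical), `mean_similarity`, and the
#'   vector of `pairwise` similarities.
#' @export
consistency_classification <- function(replicate_signatures, cutoff = 95) {
  k <- length(replicate_signatures)
  if (k < 2) stop("insufficient replicates: need at least 2 signatures")
  pairs <- utils::combn(k, 2)
  sims <- apply(pairs, 2, function(ij)
    bray_curtis_similarity(replicate_signatures[[ij[1]]],
                           replicate_signatures[[ij[2]]]))
  list(consistent = mean(sims) >= cutoff,
       mean_similarity = mean(sims), pairwise = sims)
}

#' Hierarchical clustering of separation signatures
#'
#' Agglomerative clustering (group-average/UPGMA linkage by default) on the
#' Euclidean distances between 3-point separation signatures, with flat
#' clusters obtained by cutting the tree at a fixed height. A cut height of
#' 2 is the study-level default; singleton clusters are permitted.
#'
#' @param signatures a list of `signature3` objects or a numeric matrix with
#'   one signature per row.
#' @param cut_distance tree-cut height on the Euclidean distance scale.
#' @param method linkage method passed to [stats::hclust()].
#' @return list with `labels` (integer cluster ids, in input order),
#'   `n_clusters`, `cut_distance`, and the `hclust` tree.
#' @export
cluster_separation_signatures <- function(signatures, cut_distance = 2,
                                          method = "average") {
  mat <- if (is.matrix(signatures)) signatures
         else do.call(rbind, lapply(signatures, as.numeric))
  if (nrow(mat) < 2) stop("need at least 2 signatures to cluster")
  tree <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = method)
  labels <- stats::cutree(tree, h = cut_distance)
  list(labels = unname(labels), n_clusters = length(unique(labels)),
       cut_distance = cut_distance, tree = tree)
}
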