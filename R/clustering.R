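#' Uncentered (optionally absolute) Pearson distance between samples
#'
#' Distance d = 1 - r_u (or 1 - |r_u|) with the uncentered correlation
#' r_u = sum(x y) / sqrt(sum(x^2) sum(y^2)) — cosine similarity without
#' mean-centering. The absolute variant treats anti-correlated samples as
#' similar.
#'
#' @param mat numeric matrix, transcripts x samples; distance is computed
#'   between columns (samples).
#' @param absolute take |r_u| (default TRUE).
#' @return a `dist` object over samples.
#' @export
uncentered_pearson_dist <- function(mat, absolute = TRUE) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  norms <- sqrt(colSums(mat^2))
  if (any(norms == 0))
    stop("zero-norm sample vector; uncentered correlation undefined",
         call. = FALSE)
  ru <- crossprod(mat) / tcrossprod(norms)
  if (absolute) ru <- abs(ru)
  d <- 1 - ru
  d[d < 0] <- 0  # numeric fuzz
  stats::as.dist(d)
}

#' Hierarchical clustering of samples with Ward linkage
#'
#' Agglomerates samples under the uncentered (absolute) Pearson distance
#' using Ward's minimum-variance rule. The default applies the
#' Lance-Williams Ward update to squared dissimilarities (`"ward.D2"`);
#' `"ward.D"` applies it to the dissimilarities as given. Typically run on
#' the transcripts retained by an [anova_oneway()] filter.
#'
#' @param mat numeric matrix, transcripts x samples (e.g. log2 scale,
#'   ANOVA-filtered).
#' @param absolute absolute uncentered correlation (default TRUE).
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return an `hclust` object over the samples.
#' @export
ward_cluster <- function(mat, absolute = TRUE,
                         method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  d <- uncentered_pearson_dist(mat, absolute = absolute)
  stats::hclust(d, method = method)
}

#' Export a dendrogram to Newick
#'
#' Branch lengths are the increments in merge height from a node to its
#' parent, so root-to-leaf path lengths reproduce the merge heights.
#'
#' @param hc an `hclust` object.
#' @param path optional file path; when given, the tree is written there.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  # as.phylo() places leaves at depth height/2; rescale so root-to-leaf
  # path lengths equal the merge heights
  phy$edge.length <- phy$edge.length * 2
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' ANOVA-filtered clustering of an expression experiment
#'
#' Convenience wrapper for the clustering leg of the workflow: quantile
#' normalization, log2, one-way ANOVA across groups, transcript filter at
#' `p_filter`, then Ward clustering of samples.
#'
#' @param mat linear-scale matrix, transcripts x samples.
#' @param groups group labels.
#' @param p_filter ANOVA p-value cut for transcripts entering the
#'   clustering (default 0.05).
#' @param absolute,method passed to [ward_cluster()].
#' @param normalize quantile-normalize first (default TRUE).
#' @return list with `hclust`, `n_transcripts_used`, `anova` (the
#'   per-transcript filter table).
#' @export
cluster_samples <- function(mat, groups, p_filter = 0.05,
                            absolute = TRUE, method = "ward.D2",
                            normalize = TRUE) {
  groups <- resolve_groups(mat, groups)
  norm <- if (normalize) quantile_normalize(mat) else mat
  lmat <- log2(norm)
  an <- anova_oneway(lmat, groups)
  keep <- an$p <= p_filter
  if (sum(keep) < 2)
    stop("fewer than 2 transcripts pass the ANOVA filter", call. = FALSE)
  hc <- ward_cluster(lmat[keep, , drop = FALSE],
                     absolute = absolute, method = method)
  list(hclust = hc, n_transcripts_used = sum(keep), anova = an)
}
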