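#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' across-sample means of the order statistics. Ties within a column
#' receive the mean of the normalized values they span. Idempotent.
#'
#' @param mat numeric matrix, transcripts x samples, complete and positive.
#' @return matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) stop("matrix must be complete", call. = FALSE)
  if (any(mat <= 0)) stop("intensities must be > 0", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

## ---- empirical-Bayes variance moderation ---------------------------------

## Inverse of trigamma() by Newton iteration on 1/trigamma (which is nearly
## linear), as used in empirical-Bayes variance-prior estimation.
trigamma_inverse <- function(x) {
  sapply(x, function(xi) {
    if (!is.finite(xi)) return(NA_real_)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  })
}

#' Estimate the variance prior (d0, s0^2) from per-gene sample variances
#'
#' Fits the scaled inverse-chi-square prior sigma2_g ~ d0 s0^2 / chisq(d0)
#' by moment matching on log variances: with e_g = log s2_g -
#' digamma(df/2) + log(df/2), the model gives E e_g = log s0^2 +
#' digamma(d0/2) - log(d0/2) and Var e_g = trigamma(df/2) +
#' trigamma(d0/2), so d0 comes from the trigamma inverse of the excess
#' variance and s0^2 from the mean. When the observed spread of log
#' variances does not exceed its sampling expectation, d0 is infinite and
#' s0^2 is the common variance.
#'
#' @param s2 per-gene sample variances (>= 0; zeros are dropped with a
#'   warning unless all are zero, which is an error).
#' @param df residual degrees of freedom of each s2 (scalar or vector).
#' @return list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  stopifnot(length(s2) > 1)
  df <- rep_len(df, length(s2))
  ok <- s2 > 0 & is.finite(s2)
  if (!any(ok))
    stop("all sample variances are zero; moderation undefined",
         call. = FALSE)
  if (!all(ok)) {
    warning(sprintf("dropping %d zero/non-finite variances from prior fit",
                    sum(!ok)))
    s2 <- s2[ok]; df <- df[ok]
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  excess <- mean((e - ebar)^2) * n / (n - 1) - mean(trigamma(df / 2))
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond sampling noise: common variance
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-sample t-test between two groups
#'
#' Empirical-Bayes moderated t on log2 intensities: per transcript the
#' pooled sample variance s2_g (df = n_a + n_b - 2) is shrunk toward a
#' prior, s2_post = (d0 s0^2 + df s2_g) / (d0 + df), and
#' t = (mean_a - mean_b) / (s_post sqrt(1/n_a + 1/n_b)) is referred to a
#' t distribution with d0 + df degrees of freedom (standard normal when
#' d0 = Inf — the asymptotic case). By default the prior (d0, s0^2) is
#' estimated from the data with [fit_variance_prior()]; `d0 = 0` turns
#' moderation off (ordinary pooled t), `d0 = Inf` fixes every posterior
#' variance at s0^2.
#'
#' @param log2_mat numeric matrix of log2 intensities, transcripts x
#'   samples.
#' @param groups named vector mapping colnames of `log2_mat` to group
#'   labels (or a vector of labels in column order).
#' @param group_a,group_b labels of the two groups to compare (`group_a`
#'   minus `group_b`; use the test group as `group_a` and the reference as
#'   `group_b`).
#' @param prior optional list with `d0` and `s0_sq` to override estimation.
#' @return data.frame `transcript_id`, `mean_a`, `mean_b`, `log2fc`
#'   (mean_a - mean_b), `s2`, `s2_post`, `t`, `df_total`, `p`; with the
#'   fitted prior in attributes `d0` and `s0_sq`.
#' @export
moderated_t <- function(log2_mat, groups, group_a, group_b, prior = NULL) {
  stopifnot(is.matrix(log2_mat))
  groups <- resolve_groups(log2_mat, groups)
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  na_ <- length(ia); nb <- length(ib)
  if (na_ < 2 || nb < 2)
    stop("both groups need >= 2 samples", call. = FALSE)
  A <- log2_mat[, ia, drop = FALSE]
  B <- log2_mat[, ib, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  df <- na_ + nb - 2
  ss <- rowSums((A - ma)^2) + rowSums((B - mb)^2)
  s2 <- ss / df
  if (is.null(prior)) prior <- fit_variance_prior(s2, df)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- rep(d0 + df, length(s2))
  }
  tstat <- (ma - mb) / sqrt(s2_post * (1 / na_ + 1 / nb))
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(tstat)),
              2 * stats::pt(-abs(tstat), df_total))
  out <- data.frame(
    transcript_id = rownames(log2_mat) %||% as.character(seq_len(nrow(log2_mat))),
    mean_a = ma, mean_b = mb, log2fc = ma - mb,
    s2 = s2, s2_post = s2_post, t = tstat, df_total = df_total, p = p,
    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_groups <- function(mat, groups) {
  if (!is.null(names(groups)) && !is.null(colnames(mat))) {
    if (!all(colnames(mat) %in% names(groups)))
      stop("every sample needs a group label", call. = FALSE)
    return(as.character(groups[colnames(mat)]))
  }
  if (length(groups) != ncol(mat))
    stop("groups must match the number of samples", call. = FALSE)
  as.character(groups)
}

#' Linear fold change between group means
#'
#' Ratio of linear-scale group means folded to >= 1 with an up/down flag:
#' "up" means higher in the test group than in the reference.
#'
#' @param mat linear-scale matrix, transcripts x samples.
#' @param groups group labels (named by sample or in column order).
#' @param group_test,group_ref labels of test and reference group.
#' @return data.frame `transcript_id`, `fc` (>= 1), `direction`
#'   (`"up"`/`"down"`; equal means give `fc = 1`, direction `"up"`).
#' @export
fold_change <- function(mat, groups, group_test, group_ref) {
  stopifnot(is.matrix(mat))
  groups <- resolve_groups(mat, groups)
  mt <- rowMeans(mat[, groups == group_test, drop = FALSE])
  mr <- rowMeans(mat[, groups == group_ref, drop = FALSE])
  if (any(mt <= 0) || any(mr <= 0))
    stop("group means must be > 0 for fold changes", call. = FALSE)
  ratio <- mt / mr
  data.frame(
    transcript_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    fc = pmax(ratio, 1 / ratio),
    direction = ifelse(ratio >= 1, "up", "down"),
    row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment controlling the false discovery rate.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (q-values), same order as input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Bin significant fold changes and count up/down regulation
#'
#' Cumulative counts of significant transcripts at fold-change thresholds
#' (each bin includes the stricter ones) plus the up/down split at the
#' loosest threshold.
#'
#' @param fc fold changes (>= 1, magnitude) of the significant transcripts.
#' @param direction `"up"`/`"down"` flags matching `fc`.
#' @param breaks fold-change thresholds (default 1.5, 2, 3, 5).
#' @return list with `bins` (named cumulative counts `FC>=x`), `up`,
#'   `down`.
#' @export
classify_fc_bins <- function(fc, direction,
                             breaks = c(1.5, 2, 3, 5)) {
  stopifnot(length(fc) == length(direction))
  keep <- fc >= breaks[1]
  counts <- vapply(breaks, function(b) sum(fc >= b), integer(1))
  names(counts) <- sprintf("FC>=%g", breaks)
  list(bins = counts,
       up = sum(direction[keep] == "up"),
       down = sum(direction[keep] == "down"))
}

#' Venn decomposition of 2-3 differentially-expressed gene sets
#'
#' Exact region sizes by membership tally: per-set totals, per-set
#' "specific" counts (members of that set only), all pairwise overlaps
#' (both including and excluding the triple region) and the triple
#' overlap, plus the union size.
#'
#' @param sets named list of 2 or 3 character vectors (id sets).
#' @return list with `total` (named per-set sizes), `specific`,
#'   `pair_total` (|A intersect B|), `pair_only` (pairwise minus triple),
#'   `triple` (NA for two sets), `union_size`.
#' @export
venn_decompose <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L),
            !is.null(names(sets)))
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets))
  memb <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) memb <- matrix(memb, nrow = 1,
                                       dimnames = list(NULL, names(sets)))
  nmemb <- rowSums(memb)
  total <- colSums(memb)
  specific <- colSums(memb & nmemb == 1)
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  pair_total <- vapply(pairs, function(pr)
    sum(memb[, pr[1]] & memb[, pr[2]]), numeric(1))
  names(pair_total) <- vapply(pairs, paste, "", collapse = "&")
  triple <- if (length(sets) == 3) sum(nmemb == 3) else NA_integer_
  pair_only <- if (length(sets) == 3) pair_total - triple else pair_total
  list(total = total, specific = specific,
       pair_total = pair_total, pair_only = pair_only,
       triple = triple, union_size = length(ids))
}

#' One-way ANOVA across groups, per transcript
#'
#' Classical F statistic of group-mean differences per transcript on log2
#' intensities, computed with vectorized sums of squares; used to
#' pre-filter transcripts before hierarchical clustering. Transcripts with
#' zero within-group variance but distinct group means get p = 0 (flagged
#' via `zero_within`).
#'
#' @param log2_mat log2 matrix, transcripts x samples.
#' @param groups group labels (>= 2 groups, each >= 2 samples).
#' @return data.frame `transcript_id`, `F`, `p`, `zero_within`.
#' @export
anova_oneway <- function(log2_mat, groups) {
  stopifnot(is.matrix(log2_mat))
  groups <- resolve_groups(log2_mat, groups)
  g <- factor(groups)
  k <- nlevels(g)
  n <- ncol(log2_mat)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs >= 2 samples",
                              call. = FALSE)
  grand <- rowMeans(log2_mat)
  ss_between <- 0
  ss_within <- 0
  for (lev in levels(g)) {
    sub <- log2_mat[, g == lev, drop = FALSE]
    m <- rowMeans(sub)
    ss_between <- ss_between + ncol(sub) * (m - grand)^2
    ss_within <- ss_within + rowSums((sub - m)^2)
  }
  df1 <- k - 1
  df2 <- n - k
  Fstat <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  zero <- ss_within == 0
  p[zero & ss_between > 0] <- 0
  Fstat[zero & ss_between > 0] <- Inf
  data.frame(
    transcript_id = rownames(log2_mat) %||%
      as.character(seq_len(nrow(log2_mat))),
    F = Fstat, p = p, zero_within = zero, row.names = NULL)
}

#' Run the full differential-expression contrast chain
#'
#' Orchestrates the culture-age workflow: quantile normalization, log2
#' transform, one moderated t-test per test group against the reference,
#' BH adjustment, linear fold changes, significance flags, fold-change
#' bins and the Venn decomposition of the significant sets. Deterministic
#' given its input.
#'
#' @param mat linear-scale matrix, transcripts x samples.
#' @param groups group labels (named by sample or in column order).
#' @param reference_group label of the reference (e.g. the day-6 culture).
#' @param test_groups labels to contrast against the reference (default:
#'   all other groups, in first-appearance order).
#' @param fc_cut,p_cut significance gates (defaults 1.5-fold, 0.05).
#' @param fdr_cut optional additional gate on the BH-adjusted p
#'   (`NULL` = report FDR but do not gate on it).
#' @param normalize quantile-normalize first (default TRUE).
#' @return object of class `de_contrasts`: list with `results` (named list
#'   of per-contrast data.frames: `transcript_id`, `fc`, `direction`,
#'   `log2fc`, `t`, `p`, `fdr`, `significant`), `bins`, `venn` (when 2-3
#'   contrasts), `prior` (per-contrast fitted d0/s0_sq), `cutoffs`.
#' @export
run_de_contrasts <- function(mat, groups, reference_group,
                             test_groups = NULL,
                             fc_cut = 1.5, p_cut = 0.05, fdr_cut = NULL,
                             normalize = TRUE) {
  stopifnot(is.matrix(mat))
  groups <- resolve_groups(mat, groups)
  if (!reference_group %in% groups)
    stop("reference group not present", call. = FALSE)
  if (is.null(test_groups))
    test_groups <- setdiff(unique(groups), reference_group)
  norm <- if (normalize) quantile_normalize(mat) else mat
  lmat <- log2(norm)
  results <- list()
  priors <- list()
  for (tg in test_groups) {
    tt <- moderated_t(lmat, groups, tg, reference_group)
    fc <- fold_change(norm, groups, tg, reference_group)
    fdr <- bh_adjust(tt$p)
    sig <- fc$fc >= fc_cut & tt$p <= p_cut
    if (!is.null(fdr_cut)) sig <- sig & fdr <= fdr_cut
    results[[tg]] <- data.frame(
      transcript_id = tt$transcript_id,
      fc = fc$fc, direction = fc$direction, log2fc = tt$log2fc,
      t = tt$t, p = tt$p, fdr = fdr, significant = sig,
      row.names = NULL)
    priors[[tg]] <- list(d0 = attr(tt, "d0"), s0_sq = attr(tt, "s0_sq"))
  }
  bins <- lapply(results, function(r) {
    s <- r[r$significant, ]
    classify_fc_bins(s$fc, s$direction)
  })
  sig_sets <- lapply(results, function(r)
    r$transcript_id[r$significant])
  venn <- if (length(sig_sets) %in% c(2L, 3L))
    venn_decompose(sig_sets) else NULL
  out <- list(results = results, bins = bins, venn = venn,
              prior = priors,
              cutoffs = list(fc = fc_cut, p = p_cut, fdr = fdr_cut))
  class(out) <- "de_contrasts"
  out
}
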