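#' Configuration for the synthetic expression-matrix generator
#'
#' Defaults emulate the culture-age experiment the downstream statistics
#' assume: four age groups (days 5, 6, 9, 11 of a batch culture; day 6 is
#' the reference), four independent replicates each, and an 8x60K-array
#' scale of 20,396 transcripts. Intensities are log-normal; per-gene
#' variances follow a scaled inverse-chi-square prior so that
#' empirical-Bayes variance moderation has a recoverable truth.
#'
#' @param n_transcripts number of transcripts.
#' @param groups character vector of group labels; first is the reference.
#' @param n_reps replicates per group (>= 2; the moderated t is undefined
#'   below that).
#' @param baseline_log_mean,baseline_log_sd mean and SD of per-transcript
#'   baseline log2 intensity.
#' @param de_fraction fraction of transcripts differentially expressed in
#'   each non-reference group, in `[0, 1]`.
#' @param logfc_min,logfc_max planted |log2 fold change| range; the default
#'   minimum is log2(1.5), the smallest fold change the pipeline calls.
#' @param d0,s0_sq variance-prior degrees of freedom and scale: per-gene
#'   variance sigma2_g ~ d0 * s0_sq / chisq(d0).
#' @param seed RNG seed.
#' @return validated list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_transcripts = 20396,
                            groups = c("6d", "5d", "9d", "11d"),
                            n_reps = 4,
                            baseline_log_mean = 8,
                            baseline_log_sd = 1.5,
                            de_fraction = 0.1,
                            logfc_min = log2(1.5),
                            logfc_max = 2,
                            d0 = 4,
                            s0_sq = 0.05,
                            seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              groups = as.character(groups), n_reps = as.integer(n_reps),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              de_fraction = de_fraction,
              logfc_min = logfc_min, logfc_max = logfc_max,
              d0 = d0, s0_sq = s0_sq, seed = as.integer(seed))
  if (cfg$n_reps < 2)
    stop("n_reps must be >= 2 (moderated t undefined)", call. = FALSE)
  if (cfg$d0 <= 0 || cfg$s0_sq <= 0)
    stop("d0 and s0_sq must be > 0", call. = FALSE)
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$logfc_min < 0 || cfg$logfc_max < cfg$logfc_min)
    stop("need 0 <= logfc_min <= logfc_max", call. = FALSE)
  if (anyDuplicated(cfg$groups))
    stop("group labels must be unique", call. = FALSE)
  if (cfg$n_transcripts < 1) stop("n_transcripts must be >= 1",
                                  call. = FALSE)
  class(cfg) <- "expr_sim_config"
  cfg
}

#' Simulate a linear-scale expression matrix with planted fold changes
#'
#' Per transcript g: baseline log2 intensity mu_g ~ Normal(
#' `baseline_log_mean`, `baseline_log_sd`), residual variance sigma2_g ~
#' `d0 * s0_sq / chisq(d0)` (scaled inverse-chi-square). In each
#' non-reference group a `de_fraction` subset of transcripts receives an
#' additive log2 shift of random sign and magnitude uniform in
#' `[logfc_min, logfc_max]`. Observed log2 values are
#' mu_g + shift + Normal(0, sigma_g); the matrix is returned on the linear
#' scale (2^log2), strictly positive.
#'
#' @param config an [expr_sim_config()].
#' @return list with `matrix` (transcripts x samples, linear scale; rownames
#'   are transcript ids, colnames `<group>_<rep>`), `groups` (named
#'   character vector mapping sample -> group label), and `truth`
#'   (data.frame `transcript_id`, `group`, `true_log2fc`, `is_de`, one row
#'   per transcript x non-reference group; plus attribute-free columns
#'   only).
#' @export
simulate_expression <- function(config = expr_sim_config()) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(config$seed)
  G <- config$n_transcripts
  grp <- config$groups
  reps <- config$n_reps
  samples <- paste(rep(grp, each = reps), rep(seq_len(reps), length(grp)),
                   sep = "_")
  group_of <- stats::setNames(rep(grp, each = reps), samples)

  ids <- sprintf("T%05d", seq_len(G))
  mu <- stats::rnorm(G, config$baseline_log_mean, config$baseline_log_sd)
  sigma2 <- config$d0 * config$s0_sq / stats::rchisq(G, config$d0)

  shift <- matrix(0, G, length(grp), dimnames = list(ids, grp))
  truth <- vector("list", length(grp) - 1L)
  nonref <- grp[-1L]
  n_de <- round(config$de_fraction * G)
  for (j in seq_along(nonref)) {
    de_idx <- if (n_de > 0) sample.int(G, n_de) else integer(0)
    lfc <- numeric(G)
    if (n_de > 0) {
      mag <- stats::runif(n_de, config$logfc_min, config$logfc_max)
      sgn <- sample(c(-1, 1), n_de, replace = TRUE)
      lfc[de_idx] <- mag * sgn
    }
    shift[, nonref[j]] <- lfc
    truth[[j]] <- data.frame(transcript_id = ids, group = nonref[j],
                             true_log2fc = lfc,
                             is_de = seq_len(G) %in% de_idx)
  }

  log2mat <- matrix(NA_real_, G, length(samples),
                    dimnames = list(ids, samples))
  for (s in seq_along(samples)) {
    g <- group_of[[s]]
    log2mat[, s] <- mu + shift[, g] + stats::rnorm(G, 0, sqrt(sigma2))
  }
  list(matrix = 2^log2mat, groups = group_of,
       truth = do.call(rbind, truth))
}

#' Simulate a transcript-to-GO annotation map with planted overlaps
#'
#' Builds a flat multi-map from transcripts to terms. Each term gets the
#' requested number of members; a planted term additionally contains a
#' prescribed number of members drawn from `deg_ids` (so its
#' overrepresentation, and its coverage percentage, are known by
#' construction); the remaining members are drawn from outside `deg_ids`.
#'
#' @param transcript_ids character vector: the annotation universe.
#' @param term_sizes named integer vector: term id -> term size.
#' @param planted_overlap named integer vector (subset of the term names):
#'   how many of that term's members must come from `deg_ids`.
#' @param deg_ids character vector of "truly changed" transcript ids
#'   (required when `planted_overlap` is non-empty).
#' @param seed RNG seed.
#' @return data.frame `transcript_id`, `term_id` (one row per membership).
#' @export
simulate_annotation <- function(transcript_ids, term_sizes,
                                planted_overlap = integer(0),
                                deg_ids = character(0), seed = 1L) {
  stopifnot(!is.null(names(term_sizes)) || length(term_sizes) == 0)
  if (any(term_sizes > length(transcript_ids)))
    stop("term size exceeds number of transcripts", call. = FALSE)
  if (length(planted_overlap)) {
    if (is.null(names(planted_overlap)) ||
        !all(names(planted_overlap) %in% names(term_sizes)))
      stop("planted_overlap names must be term ids", call. = FALSE)
    if (any(planted_overlap > term_sizes[names(planted_overlap)]))
      stop("planted overlap exceeds term size", call. = FALSE)
    if (any(planted_overlap > length(deg_ids)))
      stop("planted overlap exceeds DEG set size", call. = FALSE)
    stopifnot(all(deg_ids %in% transcript_ids))
  }
  set.seed(seed)
  non_deg <- setdiff(transcript_ids, deg_ids)
  rows <- vector("list", length(term_sizes))
  for (i in seq_along(term_sizes)) {
    term <- names(term_sizes)[i]
    size <- term_sizes[[i]]
    k <- if (term %in% names(planted_overlap))
      planted_overlap[[term]] else NA_integer_
    members <- if (is.na(k)) {
      sample(transcript_ids, size)
    } else {
      if (size - k > length(non_deg))
        stop("not enough non-DEG transcripts to fill term", call. = FALSE)
      c(sample(deg_ids, k), sample(non_deg, size - k))
    }
    rows[[i]] <- data.frame(transcript_id = members, term_id = term)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(transcript_id = character(0),
                               term_id = character(0)) else out
}
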