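#' Build an annotation universe from a flat transcript-to-term map
#'
#' @param annotation data.frame with columns `transcript_id`, `term_id`
#'   and optionally `term_name` (one row per membership; a transcript may
#'   belong to many terms). No term-hierarchy propagation is applied: term
#'   membership is taken as the flat counts given.
#' @param transcripts optional character vector enlarging the universe
#'   beyond the annotated transcripts (e.g. all transcripts on the array).
#' @return object of class `annotation_universe`: list with `transcripts`
#'   (character), `term_members` (named list of character vectors),
#'   `term_names` (named character).
#' @export
annotation_universe <- function(annotation, transcripts = NULL) {
  stopifnot(all(c("transcript_id", "term_id") %in% names(annotation)))
  term_members <- lapply(
    split(annotation$transcript_id, annotation$term_id), unique)
  if (any(lengths(term_members) < 1))
    stop("term sizes must be >= 1", call. = FALSE)
  universe <- unique(c(annotation$transcript_id, transcripts))
  term_names <- if ("term_name" %in% names(annotation)) {
    nm <- tapply(annotation$term_name, annotation$term_id,
                 function(x) x[1])
    stats::setNames(as.character(nm), names(nm))
  } else stats::setNames(names(term_members), names(term_members))
  out <- list(transcripts = universe, term_members = term_members,
              term_names = term_names)
  class(out) <- "annotation_universe"
  out
}

#' Coverage percentage of a GO term
#'
#' 100 * k / n: the share of a term's annotated transcripts that are
#' differentially expressed. Rounded half-up (so 35.485 -> 35.49), default
#' 2 decimals with a 1-decimal display option.
#'
#' @param k differentially expressed members of the term.
#' @param n total term size (> 0).
#' @param digits decimals to round to (default 2).
#' @return percentage in `[0, 100]`.
#' @examples
#' coverage_percent(33, 93)  # 35.48
#' coverage_percent(5, 355)  # 1.41
#' @export
coverage_percent <- function(k, n, digits = 2) {
  if (any(n <= 0)) stop("term size must be > 0", call. = FALSE)
  if (any(k < 0) || any(k > n))
    stop("need 0 <= k <= n", call. = FALSE)
  round_half_up(100 * k / n, digits)
}

#' GO-term overrepresentation of a DEG set
#'
#' One-sided hypergeometric test per term: with N transcripts in the
#' universe, K of them differentially expressed and a term of size n
#' containing k DEG members, p = P(X >= k) for X hypergeometric(N, K, n).
#' Terms smaller than `min_set_size` are excluded before testing; BH
#' adjustment runs across the tested terms; a term is flagged enriched
#' when it passes both the nominal p and the FDR cut. Coverage percentages
#' are attached to every row.
#'
#' @param deg_ids character vector of differentially expressed transcript
#'   ids (must be a subset of the universe).
#' @param universe an [annotation_universe()].
#' @param min_set_size smallest testable term size (default 5).
#' @param p_cut nominal p cut (default 0.05).
#' @param fdr_cut FDR cut (default 0.25).
#' @return data.frame with one row per tested term: `term_id`,
#'   `term_name`, `k`, `n`, `K`, `N`, `coverage_pct`, `p`, `fdr`,
#'   `enriched`; sorted by `term_id`.
#' @export
enrich <- function(deg_ids, universe, min_set_size = 5,
                   p_cut = 0.05, fdr_cut = 0.25) {
  stopifnot(inherits(universe, "annotation_universe"))
  N <- length(universe$transcripts)
  if (N == 0) stop("empty universe", call. = FALSE)
  deg_ids <- unique(deg_ids)
  if (!all(deg_ids %in% universe$transcripts))
    stop("deg_ids must be a subset of the universe", call. = FALSE)
  K <- length(deg_ids)
  sizes <- lengths(universe$term_members)
  test_terms <- names(sizes)[sizes >= min_set_size]
  if (length(test_terms) == 0)
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), coverage_pct = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      enriched = logical(0)))
  test_terms <- sort(test_terms)
  k <- vapply(test_terms, function(tm)
    sum(universe$term_members[[tm]] %in% deg_ids), integer(1))
  n <- sizes[test_terms]
  p <- if (K == 0) rep(1, length(test_terms)) else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fdr <- bh_adjust(p)
  data.frame(
    term_id = test_terms,
    term_name = unname(universe$term_names[test_terms]),
    k = unname(k), n = unname(as.integer(n)), K = K, N = N,
    coverage_pct = coverage_percent(unname(k), unname(n)),
    p = unname(p), fdr = unname(fdr),
    enriched = unname(p <= p_cut & fdr <= fdr_cut),
    row.names = NULL)
}

#' Per-contrast enrichment report
#'
#' Runs [enrich()] on the significant transcript set of every contrast of
#' a [run_de_contrasts()] result and returns one table per contrast
#' (sorted by term id), keeping only enriched terms by default.
#'
#' @param de a `de_contrasts` object (or a named list of character DEG
#'   sets).
#' @param universe an [annotation_universe()].
#' @param enriched_only keep only rows flagged enriched (default TRUE).
#' @param ... passed to [enrich()] (`min_set_size`, `p_cut`, `fdr_cut`).
#' @return named list of data.frames, one per contrast.
#' @export
enrichment_report <- function(de, universe, enriched_only = TRUE, ...) {
  sets <- if (inherits(de, "de_contrasts")) {
    lapply(de$results, function(r) r$transcript_id[r$significant])
  } else de
  stopifnot(is.list(sets), !is.null(names(sets)))
  lapply(sets, function(ids) {
    tab <- enrich(ids, universe, ...)
    if (enriched_only) tab[tab$enriched, , drop = FALSE] else tab
  })
}
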