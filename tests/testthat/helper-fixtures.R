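# Shared fixtures, all generated in code.

# a filled disk of the given pixel radius on a blank image
disk_image <- function(nrow, ncol, cx, cy, radius, value = 1) {
  img <- matrix(0, nrow, ncol)
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      if ((c - 0.5 - cx)^2 + (r - 0.5 - cy)^2 <= radius^2)
        img[r, c] <- value
    }
  }
  img
}

# straight single-cell trajectory as a per-frame object list
straight_frames <- function(n_frames, x0, y0, dx, dy,
                            area = 100, perimeter = 40) {
  lapply(seq_len(n_frames), function(t) {
    data.frame(x = x0 + (t - 1) * dx, y = y0 + (t - 1) * dy,
               area = area, perimeter = perimeter)
  })
}

# small two-group linear-scale expression matrix with planted shifts
tiny_expr <- function(n = 200, n_reps = 4, de_idx = integer(0),
                      log2fc = 1, sigma = 0.2, seed = 42) {
  set.seed(seed)
  mu <- rnorm(n, 8, 1)
  groups <- rep(c("ref", "test"), each = n_reps)
  m <- sapply(seq_along(groups), function(j) {
    shift <- if (groups[j] == "test")
      ifelse(seq_len(n) %in% de_idx, log2fc, 0) else 0
    2^(mu + shift + rnorm(n, 0, sigma))
  })
  rownames(m) <- sprintf("g%03d", seq_len(n))
  colnames(m) <- paste(groups, rep(seq_len(n_reps), 2), sep = "_")
  list(matrix = m, groups = setNames(groups, colnames(m)))
}

# independent step-up BH oracle (direct definition, no p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive hypergeometric oracle: enumerate all K-subsets of an
# N-universe and count those overlapping the term in >= k members
hyper_oracle <- function(k, K, n, N) {
  term <- seq_len(n)
  combos <- combn(N, K)
  mean(apply(combos, 2, function(s) sum(s %in% term) >= k))
}
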