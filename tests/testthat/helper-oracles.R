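# Independent oracles used against the package implementations.

# Brute-force connected components of the closed-ball adjacency graph:
# all-pairs distances, then BFS. Returns an integer component label per spot.
brute_force_components <- function(x, y, radius) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= radius
    }
  }
  comp <- rep(NA_integer_, n)
  label <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    label <- label + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- label
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Same partition regardless of label numbering?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Monte-Carlo oracle for chance juxtaposition: probability that any
# cross-color pair among points placed i.i.d. uniformly in the unit disk
# lies within distance r. `colors` gives the color of each point.
mc_juxtaposition_oracle <- function(colors, r, n_rep = 1e5, seed = 123) {
  set.seed(seed)
  n <- length(colors)
  cross <- outer(colors, colors, "!=") & upper.tri(matrix(TRUE, n, n))
  hits <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    rad <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    px <- rad * cos(th); py <- rad * sin(th)
    d2 <- outer(px, px, "-")^2 + outer(py, py, "-")^2
    hits[k] <- any(d2[cross] < r^2)
  }
  mean(hits)
}

# Direct-search oracle for the one-sided exact binomial upper bound: the
# smallest p such that P(X <= x | n, p) <= 1 - conf, found by bisection on
# the binomial CDF.
binomial_upper_oracle <- function(x, n, conf) {
  f <- function(p) pbinom(x, n, p) - (1 - conf)
  if (x >= n) return(1)
  uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-10)$root
}

# Construct an icp_cell_pattern with given per-color counts and fusion
# color-sets, bypassing geometry (for caller-level tests).
make_pattern <- function(counts = c(), fusions = list(), cell_id = 1L) {
  cc <- stats::setNames(rep(0L, length(ICP_COLORS)), ICP_COLORS)
  cc[names(counts)] <- as.integer(counts)
  structure(
    list(cell_id = cell_id, color_counts = cc,
         fusions = lapply(fusions, sort),
         clusters = data.frame(cluster = integer(0), x = numeric(0),
                               y = numeric(0), colors = character(0))),
    class = "icp_cell_pattern"
  )
}

# n cells with identical counts, k of which also carry a fusion of `pair`.
make_cohort <- function(n, counts, k_fused = 0L, pair = c("YELLOW", "GREEN")) {
  lapply(seq_len(n), function(i) {
    make_pattern(counts,
                 fusions = if (i <= k_fused) list(pair) else list(),
                 cell_id = i)
  })
}
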