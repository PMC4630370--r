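# Independent oracles used to check the implementation by a different route.

# Upper-tail hypergeometric probability by direct summation of binomial
# coefficients (exact for small N).
oracle_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exhaustive tryptic-digest oracle: every substring that starts after a
# cleavage site (or at the N-terminus), ends at one (or the C-terminus),
# and carries at most max_missed internal sites.
oracle_digest <- function(sequence, max_missed = 0) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  is_site <- function(i) i >= 1 && i < n && aa[i] %in% c("K", "R") && aa[i + 1] != "P"
  out <- character()
  for (s in 1:n) {
    if (!(s == 1 || is_site(s - 1))) next
    for (e in s:n) {
      if (!(e == n || is_site(e))) next
      internal <- if (e > s) sum(vapply(s:(e - 1), is_site, TRUE)) else 0
      if (internal <= max_missed) out <- c(out, paste(aa[s:e], collapse = ""))
    }
  }
  sort(out)
}

# Brute-force subnetwork perturbation score using only the raw edge list.
oracle_s_net <- function(nodes, edge_list, affinities) {
  total <- 0; touching <- 0
  for (t in names(affinities)) {
    if (t %in% nodes) {
      total <- total + affinities[[t]]
      touching <- touching + 1
      next
    }
    deg <- 0; e_in <- 0
    for (r in seq_len(nrow(edge_list))) {
      a <- edge_list[r, 1]; b <- edge_list[r, 2]
      if (a == t) { deg <- deg + 1; if (b %in% nodes) e_in <- e_in + 1 }
      if (b == t) { deg <- deg + 1; if (a %in% nodes) e_in <- e_in + 1 }
    }
    if (deg > 0 && e_in > 0) {
      total <- total + affinities[[t]] * e_in / deg
      touching <- touching + 1
    }
  }
  list(s_net = total / length(nodes), n_targets = touching)
}

# Grid-search least-squares oracle for a 2-template mixture (non-negative
# coefficients on a fine grid).
oracle_grid_fit <- function(y, t1, t2, upper = 5, step = 0.01) {
  best <- c(NA, NA); best_rss <- Inf
  for (a in seq(0, upper, step)) {
    for (b in seq(0, upper, step)) {
      rss <- sum((y - a * t1 - b * t2)^2)
      if (rss < best_rss) { best_rss <- rss; best <- c(a, b) }
    }
  }
  best
}
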