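# Deliberately naive O(n^2) pairwise-comparison oracles, kept independent of
# the package's histogram path.

# class size of each individual's equivalence class
oracle_class_sizes <- function(keys) {
  vapply(seq_along(keys), function(i) sum(keys == keys[[i]]), integer(1))
}

# histogram of class sizes as a plain data.frame
oracle_histogram <- function(keys) {
  u <- unique(keys)
  sizes <- vapply(u, function(k) sum(keys == k), integer(1))
  distinct_sizes <- sort(unique(sizes))
  data.frame(
    class_size = as.integer(distinct_sizes),
    num_bins = vapply(
      distinct_sizes, function(s) sum(sizes == s), integer(1)
    )
  )
}

# h(g) as a direct count of individuals whose own class size is <= g
oracle_h <- function(keys, g) {
  sum(oracle_class_sizes(keys) <= g)
}

random_key_set <- function(n, n_tuples, seed) {
  withr::with_seed(seed, sprintf("key%04d", sample.int(n_tuples, n, TRUE)))
}

# Pearson correlation of ranks: independent route to Spearman's rho
oracle_rank_correlation <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}
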