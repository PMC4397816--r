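# Independent oracles shared across test files.

# Brute-force compact-letter-display oracle: maximal cliques of the
# non-significance relation, by subset enumeration (feasible for <= 8
# levels).
clique_oracle <- function(nonsig) {
  k <- nrow(nonsig)
  lv <- rownames(nonsig)
  cliques <- list()
  for (bits in 1:(2^k - 1)) {
    members <- lv[bitwAnd(bits, 2^(seq_len(k) - 1)) > 0]
    if (all(nonsig[members, members])) cliques <- c(cliques, list(members))
  }
  maximal <- Filter(function(a) !any(vapply(cliques, function(b)
    length(b) > length(a) && all(a %in% b), logical(1))), cliques)
  unique(lapply(maximal, sort))
}

letters_to_sets <- function(grouping) {
  lett <- strsplit(grouping$letters, "")
  all_letters <- sort(unique(unlist(lett)))
  lapply(setNames(all_letters, all_letters), function(L)
    sort(grouping$level[vapply(lett, function(x) L %in% x, logical(1))]))
}
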