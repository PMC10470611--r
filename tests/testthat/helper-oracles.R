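# independent oracles shared across test files

all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# brute-force oracle for the contribution curve: explicit double loop over
# sample pairs, prefix numerator over full-pair denominator
contribution_oracle <- function(t, ranked) {
  comp <- sweep(unclass(t), 2, colSums(unclass(t)), "/")[ranked, ,
                                                         drop = FALSE]
  n <- ncol(comp)
  K <- nrow(comp)
  curve <- numeric(K)
  for (k in seq_len(K)) {
    vals <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        num_k <- sum(abs(comp[seq_len(k), i] - comp[seq_len(k), j]))
        num_full <- sum(abs(comp[, i] - comp[, j]))
        if (num_full > 0) vals <- c(vals, num_k / num_full)
      }
    }
    curve[k] <- mean(vals)
  }
  curve
}

# independent double-loop oracle for weighted endemism
weighted_oracle <- function(t, e) {
  m <- unclass(t)
  comp <- sweep(m, 2, colSums(m), "/")
  W <- numeric(ncol(m))
  for (s in seq_len(ncol(m))) {
    for (i in names(e)) {
      W[s] <- W[s] + comp[i, s] * e[[i]]
    }
  }
  W
}

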