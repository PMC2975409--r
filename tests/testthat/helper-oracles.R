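# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths.

# KS statistic by direct ECDF scan against a normal reference
oracle_ks_D <- function(values, mean, sd) {
  v <- sort(values)
  n <- length(v)
  f <- pnorm(v, mean, sd)
  max(abs(seq_len(n) / n - f), abs((seq_len(n) - 1) / n - f))
}

# scalar statistics computed independently (t.test / plain means)
oracle_stat <- function(case, control, kind) {
  switch(kind,
    mean_difference = mean(case) - mean(control),
    pooled_t = unname(t.test(case, control, var.equal = TRUE)$statistic),
    welch_t = unname(t.test(case, control, var.equal = FALSE)$statistic)
  )
}

# exhaustive permutation p-values by direct enumeration of group splits
oracle_exhaustive_p <- function(x, n_case, kind) {
  n <- ncol(x)
  splits <- combn(n, n_case)
  apply(x, 1, function(row) {
    obs <- abs(oracle_stat(row[seq_len(n_case)], row[-seq_len(n_case)], kind))
    perm <- apply(splits, 2, function(idx) {
      abs(oracle_stat(row[idx], row[-idx], kind))
    })
    mean(perm >= obs - 1e-9 * (1 + obs))
  })
}

# hypergeometric upper-tail by explicit sum of choose() terms
oracle_hyper_tail <- function(overlap, pathway_size, universe_size, list_size) {
  ks <- overlap:min(pathway_size, list_size)
  sum(choose(pathway_size, ks) *
        choose(universe_size - pathway_size, list_size - ks)) /
    choose(universe_size, list_size)
}

# Pearson correlation from its definition
oracle_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# small ready-made study for reuse
tiny_design <- function(...) {
  args <- modifyList(
    list(n_case = 6, n_control = 6, n_proteins = 30,
         peptides_per_protein = c(1, 3), n_differential = 5,
         effect_size = 2, seed = 42),
    list(...)
  )
  do.call(study_design, args)
}
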