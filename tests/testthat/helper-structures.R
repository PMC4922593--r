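## Shared fixtures: tiny trials and random structures built in code.

trial_of <- function(...) {
  recall_trial(lapply(list(...), recall_sequence))
}

subset_keys <- function(subsets) {
  sort(vapply(subsets, function(s) paste(sort(s), collapse = ""), ""))
}

## Random ground-truth structure with >= 2 groups and sub-map sizes >= 2.
random_structure <- function(B, seed) {
  set.seed(seed)
  ids <- sprintf("b%02d", seq_len(B))
  repeat {
    ngroups <- sample(2:min(4L, B - 1L), 1L)
    z <- sample(rep(seq_len(ngroups), length.out = B))
    sizes <- tabulate(z, ngroups)
    groups <- split(ids, z)
    submaps <- groups[sizes >= 2L]
    singles <- unlist(groups[sizes == 1L])
    if (length(submaps) + length(singles) >= 2L) break
  }
  map_structure(unname(submaps), excluded = singles)
}

## Random partition of ids into 1..K groups (any sizes), as a membership
## vector -- used by the Rand-index oracle tests.
random_partition <- function(ids, seed) {
  set.seed(seed)
  k <- sample.int(length(ids), 1L)
  stats::setNames(sample.int(k, length(ids), replace = TRUE), ids)
}

partition_to_structure <- function(z) {
  groups <- split(names(z), z)
  sizes <- vapply(groups, length, 1L)
  map_structure(unname(groups[sizes >= 2L]),
                excluded = character(),
                singleton_clusters = unname(groups[sizes == 1L]))
}

## Independent pair-enumeration Rand index over explicit memberships.
rand_oracle <- function(za, zb) {
  ids <- names(za)
  agree <- 0L; total <- 0L
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      total <- total + 1L
      if ((za[i] == za[j]) == (zb[i] == zb[j])) agree <- agree + 1L
    }
  }
  agree / total
}

## Log-density of a multivariate normal, written independently of the
## package internals (determinant + solve, no Cholesky shortcut).
dmvnorm_log <- function(x, mu, Sigma) {
  d <- length(mu)
  xm <- as.numeric(x - mu)
  -0.5 * (d * log(2 * pi) + log(det(Sigma)) +
            as.numeric(t(xm) %*% solve(Sigma) %*% xm))
}
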