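# independent oracles, deliberately implemented by different routes than
# the package code they check

# Wright path-counting kinship: phi(i,j) = sum over common ancestors A and
# pairs of ancestral paths meeting only at A of (1/2)^(n1+n2+1) (1+F_A)
oracle_kinship <- function(ped) {
  ids <- ped$id
  fa <- stats::setNames(ped$father, ids)
  mo <- stats::setNames(ped$mother, ids)
  path_cache <- new.env(parent = emptyenv())
  paths_up <- function(i) {
    if (!is.null(path_cache[[i]])) return(path_cache[[i]])
    out <- list(c(i))
    if (!is.na(fa[[i]])) {
      for (p in paths_up(fa[[i]])) out <- c(out, list(c(i, p)))
      for (p in paths_up(mo[[i]])) out <- c(out, list(c(i, p)))
    }
    path_cache[[i]] <- out
    out
  }
  inbreeding <- function(i) {
    if (is.na(fa[[i]])) return(0)
    phi_pair(fa[[i]], mo[[i]])
  }
  phi_pair <- function(i, j) {
    if (i == j) return(0.5 * (1 + inbreeding(i)))
    tot <- 0
    for (a in paths_up(i)) {
      for (b in paths_up(j)) {
        A <- a[length(a)]
        if (A == b[length(b)]) {
          shared <- intersect(a, b)
          if (length(shared) == 1 && shared == A)
            tot <- tot + 0.5^(length(a) + length(b) - 1) *
              (1 + inbreeding(A))
        }
      }
    }
    tot
  }
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n))
    for (j in i:n)
      K[i, j] <- K[j, i] <- phi_pair(ids[i], ids[j])
  K
}

# all permutations of a vector, by direct recursion
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (k in seq_along(v))
    for (p in perms_of(v[-k]))
      out <- c(out, list(c(v[k], p)))
  out
}

# one-factor PERMANOVA pseudo-F straight from the pairwise distances,
# via the within-group sum-of-squared-distances identity
oracle_onefactor_F <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  a <- length(unique(groups))
  ss_tot <- sum(D[upper.tri(D)]^2) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- D[idx, idx]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
  }
  ss_b <- ss_tot - ss_w
  (ss_b / (a - 1)) / (ss_w / (n - a))
}

# exact one-factor permutation p by exhaustive label permutation
oracle_onefactor_exact_p <- function(D, groups) {
  Fobs <- oracle_onefactor_F(D, groups)
  allp <- perms_of(seq_along(groups))
  Fs <- vapply(allp, function(p) oracle_onefactor_F(D, groups[p]),
               numeric(1))
  mean(Fs >= Fobs - 1e-10)
}

# exact Mantel p by exhaustive permutation of the second matrix
oracle_mantel_exact <- function(m1, m2) {
  ut <- upper.tri(m1)
  robs <- stats::cor(m1[ut], m2[ut])
  allp <- perms_of(seq_len(nrow(m1)))
  rs <- vapply(allp, function(p) stats::cor(m1[ut], m2[p, p][ut]),
               numeric(1))
  list(r = robs, p = mean(rs >= robs - 1e-12))
}

# 99% binomial band around an exact permutation p for a sampled estimate
binom_band <- function(p_exact, n_perm) {
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  c(p_exact - 2.576 * se, p_exact + 2.576 * se)
}
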