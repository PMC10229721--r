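# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive (loops, enumeration) so it cannot
# share a code path with the implementation it checks.

# brute-force MPD: explicit loop over ordered pairs
oracle_mpd <- function(p, D, weighted) {
  pres <- which(p > 0)
  num <- den <- 0
  for (i in pres) for (j in pres) {
    if (i == j) next
    w <- if (weighted) p[i] * p[j] else 1
    num <- num + w * D[i, j]
    den <- den + w
  }
  unname(num / den)
}

# brute-force MNTD: explicit nearest-neighbour scan
oracle_mntd <- function(p, D, weighted) {
  pres <- which(p > 0)
  ntd <- vapply(pres, function(i) {
    best <- Inf
    for (j in pres) if (j != i && D[i, j] < best) best <- D[i, j]
    best
  }, numeric(1))
  unname(if (weighted) sum(p[pres] / sum(p[pres]) * ntd) else mean(ntd))
}

# all permutations of 1..n (used for the exhaustive null oracle): insert n
# at every position of every permutation of 1..n-1
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# brute-force patristic distance: walk tip-to-root paths and sum edges
oracle_patristic <- function(tree, a, b) {
  root <- ape::Ntip(tree) + 1L
  path_to_root <- function(tip) {
    node <- which(tree$tip.label == tip)
    path <- node
    while (node != root) {
      node <- tree$edge[tree$edge[, 2] == node, 1]
      path <- c(path, node)
    }
    path
  }
  pa <- path_to_root(a); pb <- path_to_root(b)
  mrca <- intersect(pa, pb)[1]
  edge_len <- function(child) tree$edge.length[tree$edge[, 2] == child]
  sum(vapply(pa[seq_len(which(pa == mrca) - 1L)], edge_len, numeric(1))) +
    sum(vapply(pb[seq_len(which(pb == mrca) - 1L)], edge_len, numeric(1)))
}

# random community instance over a random tree
rand_instance <- function(n_species, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_species)
  D <- patristic_matrix(tr)
  p <- stats::setNames(numeric(n_species), rownames(D))
  k <- sample(2:n_species, 1)
  idx <- sample(n_species, k)
  g <- stats::rgamma(k, 1)
  p[idx] <- g / sum(g)
  list(tree = tr, D = D, p = p)
}

# closed-form OLS oracle via normal equations
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  list(beta = as.numeric(beta), se = as.numeric(se), t = as.numeric(tval),
       p = as.numeric(pval), r2 = r2,
       adj_r2 = 1 - (1 - r2) * (length(y) - 1) / df)
}

# data frame for a random interaction-model instance (n x 4 predictors)
rand_design_df <- function(n, seed) {
  set.seed(seed)
  data.frame(site = paste0("s", seq_len(n)),
             veg_data = rbinom(n, 1, 0.4),
             ses_mpd = rnorm(n),
             cwm = rnorm(n, 25, 5),
             rao = runif(n),
             y = rnorm(n))
}
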