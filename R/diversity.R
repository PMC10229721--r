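#' Mean pairwise phylogenetic distance (MPD / Abu.mpd)
#'
#' Unweighted MPD is the mean of pairwise distances over all unordered pairs
#' of distinct species present in the community. The abundance-weighted
#' variant (Abu.mpd) is the expected distance between two individuals of
#' distinct species: `sum_{i != j} p_i p_j d_ij / sum_{i != j} p_i p_j`.
#' Conspecific pairs are excluded in both variants.
#'
#' @param p named numeric abundance vector (relative abundances); species with
#'   `p > 0` are "present".
#' @param D patristic distance matrix covering at least the present species.
#' @param weighted logical; abundance-weighted variant?
#' @return distance in the units of `D` (Myr), or `NA_real_` with a warning
#'   when fewer than two species are present.
#' @export
mpd <- function(p, D, weighted = TRUE) {
  p <- align_abundance(p, D)
  pres <- which(p > 0)
  if (length(pres) < 2L) {
    warning("MPD undefined for fewer than 2 present species", call. = FALSE)
    return(NA_real_)
  }
  d <- D[pres, pres, drop = FALSE]
  if (weighted) {
    w <- outer(p[pres], p[pres])
    diag(w) <- 0
    sum(w * d) / sum(w)
  } else {
    sum(d[upper.tri(d)]) / choose(length(pres), 2)
  }
}

#' Mean nearest taxon distance (MNTD / Abu.mntd)
#'
#' For each present species i, `ntd_i` is the distance to its nearest
#' co-occurring heterospecific. Unweighted MNTD is the mean of the `ntd_i`;
#' the abundance-weighted variant is `sum_i p_i * ntd_i` (with `p`
#' renormalized over present species).
#'
#' @inheritParams mpd
#' @return distance in the units of `D` (Myr), or `NA_real_` when fewer than
#'   two species are present.
#' @export
mntd <- function(p, D, weighted = TRUE) {
  p <- align_abundance(p, D)
  pres <- which(p > 0)
  if (length(pres) < 2L) {
    warning("MNTD undefined for fewer than 2 present species", call. = FALSE)
    return(NA_real_)
  }
  d <- D[pres, pres, drop = FALSE]
  diag(d) <- Inf
  ntd <- apply(d, 1L, min)
  if (weighted) {
    w <- p[pres] / sum(p[pres])
    sum(w * ntd)
  } else {
    mean(ntd)
  }
}

align_abundance <- function(p, D) {
  if (!is.null(names(p))) {
    extra <- setdiff(names(p)[p > 0], rownames(D))
    if (length(extra) > 0)
      pf_stop("pf_lookup_error", "distance matrix missing species: %s",
              paste(extra, collapse = ", "))
    q <- stats::setNames(numeric(nrow(D)), rownames(D))
    q[names(p)[names(p) %in% rownames(D)]] <-
      p[names(p) %in% rownames(D)]
    q
  } else {
    stopifnot(length(p) == nrow(D))
    p
  }
}

#' Standardized effect size
#'
#' `SES = (observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation. Positive values indicate over-dispersion relative to the null,
#' negative values clustering.
#'
#' @param obs observed metric value(s), one per site.
#' @param nulls matrix of null draws, replicates in rows, sites in columns
#'   (or a vector for one site).
#' @return numeric vector of SES values; `NA` with a warning where the null
#'   SD is zero.
#' @export
ses <- function(obs, nulls) {
  if (is.vector(nulls)) nulls <- matrix(nulls, ncol = 1L)
  stopifnot(length(obs) == ncol(nulls))
  mu <- colMeans(nulls)
  sd0 <- apply(nulls, 2L, stats::sd)
  out <- (obs - mu) / sd0
  if (any(sd0 == 0, na.rm = TRUE)) {
    warning("null SD is zero for ", sum(sd0 == 0), " site(s); SES undefined",
            call. = FALSE)
    out[sd0 == 0] <- NA_real_
  }
  out
}

# --- vectorized all-site metric engines (used by the null model) ----------

# weighted / unweighted MPD for every row of a community matrix at once;
# P is sites x species aligned to D
mpd_all <- function(P, D, weighted = TRUE) {
  if (weighted) {
    num <- rowSums((P %*% D) * P)
    den <- rowSums(P)^2 - rowSums(P^2)
    out <- num / den
  } else {
    B <- (P > 0) + 0
    r <- rowSums(B)
    num <- rowSums((B %*% D) * B)
    out <- num / (r * (r - 1))
  }
  out[rowSums(P > 0) < 2] <- NA_real_
  out
}

mntd_all <- function(P, D, weighted = TRUE) {
  vapply(seq_len(nrow(P)), function(i) {
    pres <- which(P[i, ] > 0)
    if (length(pres) < 2L) return(NA_real_)
    d <- D[pres, pres, drop = FALSE]
    diag(d) <- Inf
    ntd <- apply(d, 1L, min)
    if (weighted) sum(P[i, pres] / sum(P[i, pres]) * ntd) else mean(ntd)
  }, numeric(1))
}

#' Null-model draws by reshuffling species identities
#'
#' Each replicate permutes the species labels of the distance matrix across
#' the full observed species pool ("taxa shuffle"), leaving every site's
#' abundance vector untouched, and recomputes the metric for every site.
#' This holds species richness and the abundance structure fixed while
#' randomizing phylogenetic (or trait) relationships.
#'
#' @param metric `"mpd"` or `"mntd"`.
#' @param community sites x species relative-abundance matrix (column names
#'   matching `D`).
#' @param D distance matrix over the species pool.
#' @param replicates number of null replicates (default 999).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param weighted abundance-weighted metric inside the null?
#' @return matrix of null metric values, `replicates` rows x sites columns.
#' @export
run_null <- function(metric = c("mpd", "mntd"), community, D,
                     replicates = 999L, seed = 1L, weighted = TRUE) {
  metric <- match.arg(metric)
  stopifnot(replicates >= 1L)
  S <- ncol(community)
  if (S < 2L) pf_stop("pf_validation_error", "species pool smaller than 2")
  if (!is.null(colnames(community)))
    D <- D[colnames(community), colnames(community), drop = FALSE]
  fun <- if (metric == "mpd") mpd_all else mntd_all
  with_seed(seed, {
    out <- matrix(NA_real_, replicates, nrow(community))
    for (r in seq_len(replicates)) {
      perm <- sample.int(S)
      out[r, ] <- fun(community, D[perm, perm, drop = FALSE], weighted)
    }
    colnames(out) <- rownames(community)
    out
  })
}

#' Rao's quadratic entropy for a single trait
#'
#' `Rao = sum_{i,j} p_i p_j d_ij`, the expected trait dissimilarity between
#' two randomly drawn individuals. With the trait scaled to [0, 1] and
#' `d_ij = |x'_i - x'_j|`, Rao lies in [0, 1]. Species with a missing trait
#' are dropped and `p` renormalized over the remainder.
#'
#' @param p named relative-abundance vector.
#' @param trait named vector of [0, 1]-scaled trait values (`NA` = missing),
#'   or a precomputed dissimilarity matrix via `d`.
#' @param d optional pairwise dissimilarity matrix overriding `trait`.
#' @return list with `rao` (numeric) and `n_dropped` (species with missing
#'   trait among the present species).
#' @export
rao <- function(p, trait = NULL, d = NULL) {
  pres <- names(p)[p > 0]
  if (is.null(d)) {
    stopifnot(!is.null(trait))
    x <- trait[pres]
    keep <- pres[is.finite(x)]
  } else {
    keep <- intersect(pres, rownames(d))
  }
  n_dropped <- length(pres) - length(keep)
  if (length(keep) == 0)
    return(list(rao = NA_real_, n_dropped = n_dropped))
  q <- p[keep] / sum(p[keep])
  dm <- if (is.null(d)) abs(outer(trait[keep], trait[keep], `-`))
        else d[keep, keep, drop = FALSE]
  list(rao = as.numeric(q %*% dm %*% q), n_dropped = n_dropped)
}

#' Community-weighted mean of a trait
#'
#' `CWM = sum_i p_i x_i`, with `p` renormalized over species that have the
#' trait.
#'
#' @param p named relative-abundance vector.
#' @param trait named trait vector in original trait units (`NA` = missing).
#' @return CWM in trait units, or `NA_real_` when no present species has the
#'   trait.
#' @export
cwm <- function(p, trait) {
  pres <- names(p)[p > 0]
  x <- trait[pres]
  keep <- is.finite(x)
  if (!any(keep)) return(NA_real_)
  q <- p[pres][keep] / sum(p[pres][keep])
  sum(q * x[keep])
}

#' Per-site diversity summary
#'
#' Computes, for every site of a community matrix: observed weighted MPD and
#' MNTD, their SES under the species-reshuffling null, Rao's Q and the CWM
#' for each trait.
#'
#' @param community sites x species relative-abundance matrix.
#' @param D patristic distance matrix over the pool (Myr).
#' @param traits data frame with a `species` column and one column per trait
#'   (raw units); traits are min-max scaled over the pool for Rao.
#' @param replicates,seed,weighted passed to [run_null()].
#' @param metrics which SES metrics to compute (`"mpd"`, `"mntd"`);
#'   dropping one skips its null model (a compute knob only — the other
#'   metric's draws are unchanged).
#' @return data frame, one row per site, with columns `site`, `mpd_obs`,
#'   `mntd_obs`, `ses_mpd`, `ses_mntd`, and `rao_<trait>` / `cwm_<trait>`
#'   per trait.
#' @export
community_diversity <- function(community, D, traits = NULL,
                                replicates = 999L, seed = 1L,
                                weighted = TRUE,
                                metrics = c("mpd", "mntd")) {
  sp <- colnames(community)
  D <- D[sp, sp, drop = FALSE]
  obs_mpd <- mpd_all(community, D, weighted)
  obs_mntd <- mntd_all(community, D, weighted)
  out <- data.frame(site = rownames(community) %||%
                      as.character(seq_len(nrow(community))),
                    mpd_obs = obs_mpd, mntd_obs = obs_mntd,
                    stringsAsFactors = FALSE)
  if ("mpd" %in% metrics) {
    null_mpd <- run_null("mpd", community, D, replicates,
                         derive_seed(seed, 1L), weighted)
    out$ses_mpd <- ses(obs_mpd, null_mpd)
  }
  if ("mntd" %in% metrics) {
    null_mntd <- run_null("mntd", community, D, replicates,
                          derive_seed(seed, 2L), weighted)
    out$ses_mntd <- ses(obs_mntd, null_mntd)
  }
  if (!is.null(traits)) {
    for (tr in setdiff(names(traits), "species")) {
      raw <- stats::setNames(traits[[tr]], traits$species)[sp]
      names(raw) <- sp
      scl <- tryCatch(scale_trait(raw), phylofauna_error = function(e) raw)
      out[[paste0("rao_", tr)]] <- vapply(seq_len(nrow(community)),
        function(i) rao(community[i, ], scl)$rao, numeric(1))
      out[[paste0("cwm_", tr)]] <- vapply(seq_len(nrow(community)),
        function(i) cwm(community[i, ], raw), numeric(1))
    }
  }
  rownames(out) <- NULL
  out
}
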