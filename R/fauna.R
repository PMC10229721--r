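#' Controlled vocabularies for soil-fauna group annotations
#'
#' Earthworm ecological categories, springtail vertical strata, mite
#' suborders and nematode guild labels accepted by [group_abundance()] and
#' [structure_index()].
#' @export
fauna_vocabularies <- function() {
  list(
    earthworm = c("epigeic", "anecic", "endogeic"),
    springtail = c("epigeic", "hemiedaphic", "euedaphic"),
    mite = c("actinedid", "gamasid", "other"),
    nematode = c("Ba1", "Ba2", "Ba3", "Ba4", "Fu2", "Fu3", "Fu4",
                 "Pl2", "Pl3", "Ca3", "Ca4", "Ca5", "Om4", "Om5")
  )
}

#' Default guild weights for the nematode Structure Index
#'
#' Structure guilds are the coloniser-persister (c-p) classes 3-5 with
#' weights 1.8, 3.2 and 5.0; basal guilds are bacterivores and fungivores of
#' c-p class 2 (Ba2, Fu2) with weight 0.8. Alternative weightings can be
#' passed to [structure_index()].
#'
#' @return data frame with columns `cp` (c-p class) and `weight`.
#' @export
default_guild_weights <- function() {
  data.frame(cp = c(2L, 3L, 4L, 5L), weight = c(0.8, 1.8, 3.2, 5.0))
}

# c-p class encoded as the trailing digit of the guild label (e.g. "Ca4")
guild_cp <- function(guild) as.integer(sub("^[A-Za-z]+", "", guild))
guild_role <- function(guild) sub("[0-9]+$", "", guild)

#' Aggregate fauna counts by site and ecological group
#'
#' @param table data frame with columns `site`, `taxon`, `count` and an
#'   annotation column named by `grouping` (e.g. `earthworm_group`).
#' @param grouping name of the annotation column to aggregate by.
#' @param vocabulary allowed annotation values; defaults to the matching
#'   entry of [fauna_vocabularies()] when recognizable from `grouping`.
#' @return data frame site x group of summed counts (groups with no records
#'   get 0).
#' @export
group_abundance <- function(table, grouping, vocabulary = NULL) {
  stopifnot(all(c("site", "count", grouping) %in% names(table)))
  if (any(table$count < 0) || any(table$count != round(table$count)))
    pf_stop("pf_validation_error", "counts must be non-negative integers")
  g <- table[[grouping]]
  if (is.null(vocabulary)) {
    key <- sub("_.*$", "", grouping)
    vocabulary <- fauna_vocabularies()[[key]]
  }
  if (!is.null(vocabulary) && !all(g %in% vocabulary))
    pf_stop("pf_vocabulary_error", "unknown %s value(s): %s", grouping,
            paste(unique(g[!g %in% vocabulary]), collapse = ", "))
  groups <- vocabulary %||% sort(unique(g))
  sites <- unique(table$site)
  out <- matrix(0, length(sites), length(groups),
                dimnames = list(as.character(sites), groups))
  agg <- stats::aggregate(count ~ site + grp,
                          data = data.frame(site = table$site, grp = g,
                                            count = table$count),
                          FUN = sum)
  out[cbind(as.character(agg$site), agg$grp)] <- agg$count
  data.frame(site = sites, out, check.names = FALSE, row.names = NULL)
}

#' Log-transform an abundance count
#'
#' `log10(count + 1)`: monotone, maps 0 to 0, accommodates zero counts. The
#' base is immaterial to t and p statistics of linear models (an affine
#' rescaling of the response).
#'
#' @param count non-negative count(s).
#' @return transformed value(s).
#' @export
log_abundance <- function(count) {
  if (any(count < 0, na.rm = TRUE))
    pf_stop("pf_validation_error", "counts must be non-negative")
  log10(count + 1)
}

#' Simpson diversity (1 - D)
#'
#' `1 - sum(p_i^2)`: the probability that two randomly drawn individuals
#' belong to different species; 0 = no diversity.
#'
#' @param x counts or relative abundances (normalized internally).
#' @return value in [0, 1], or `NA_real_` for an empty community.
#' @export
simpson <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) == 0) return(NA_real_)
  p <- x / sum(x)
  1 - sum(p^2)
}

#' Nematode Structure Index
#'
#' `SI = 100 * s / (s + b)` where `s` sums weighted abundances of structure
#' guilds (c-p classes 3-5) and `b` sums weighted abundances of the basal
#' guilds Ba2 and Fu2. High SI indicates a structured, undisturbed food web
#' dominated by long-lived, higher-trophic-level taxa.
#'
#' @param counts named numeric vector: guild label (e.g. `"Ba2"`, `"Ca4"`)
#'   to summed count.
#' @param weights guild-weight table as from [default_guild_weights()].
#' @return SI in [0, 100], or `NA_real_` when no structure or basal guilds
#'   are present.
#' @export
structure_index <- function(counts, weights = default_guild_weights()) {
  if (any(counts < 0, na.rm = TRUE))
    pf_stop("pf_validation_error", "counts must be non-negative")
  guilds <- names(counts)
  if (is.null(guilds))
    pf_stop("pf_validation_error", "counts must be named by guild label")
  cp <- guild_cp(guilds)
  role <- guild_role(guilds)
  w <- stats::setNames(weights$weight, weights$cp)
  is_structure <- cp >= 3L & cp <= 5L
  is_basal <- cp == 2L & role %in% c("Ba", "Fu")
  s <- sum(w[as.character(cp[is_structure])] * counts[is_structure])
  b <- sum(w["2"] * counts[is_basal])
  if (s + b == 0) return(NA_real_)
  100 * s / (s + b)
}

#' Per-site fauna summary
#'
#' For a long-format fauna table, computes per site: total counts and
#' log-abundance per major group, Simpson diversity per major group, and the
#' nematode Structure Index.
#'
#' @param table data frame with columns `site`, `taxon`, `group` (major
#'   group: earthworm, springtail, mite, nematode), `subgroup` (annotation
#'   within group; nematode guild labels for nematodes) and `count`.
#' @param weights guild weights for the Structure Index.
#' @return data frame, one row per site.
#' @export
fauna_summary <- function(table, weights = default_guild_weights()) {
  stopifnot(all(c("site", "taxon", "group", "subgroup", "count") %in%
                  names(table)))
  sites <- unique(table$site)
  rows <- lapply(sites, function(s) {
    tb <- table[table$site == s, , drop = FALSE]
    row <- list(site = s)
    for (g in c("earthworm", "springtail", "mite", "nematode")) {
      sub <- tb[tb$group == g, , drop = FALSE]
      row[[paste0("abund_", g)]] <- sum(sub$count)
      row[[paste0("logabund_", g)]] <- log_abundance(sum(sub$count))
      cnt <- tapply(sub$count, sub$taxon, sum)
      row[[paste0("simpson_", g)]] <-
        if (g == "mite") NA_real_ else simpson(cnt) # mites not id'd to species
      for (sg in unique(sub$subgroup)) {
        row[[paste0("logabund_", g, "_", sg)]] <-
          log_abundance(sum(sub$count[sub$subgroup == sg]))
      }
    }
    nem <- tb[tb$group == "nematode", , drop = FALSE]
    si <- if (nrow(nem) > 0)
      structure_index(tapply(nem$count, nem$subgroup, sum), weights)
    else NA_real_
    row$structure_index <- si
    row
  })
  cols <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA_real_
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
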