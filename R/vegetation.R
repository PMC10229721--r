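#' Point-centred-quarter density score for one species at one site
#'
#' Grassland surveys record, at each of the four corners of a square plot,
#' the distance (m, up to 3.5 m) to the nearest individual of each species.
#' The density score is `(1 / dbar^2) * f`, where `dbar` is the mean distance
#' over the corners where the species was found and `f` is the fraction of
#' the four corners where it was found. Absence at a corner contributes only
#' through `f`, never through `dbar`. A mean distance of exactly zero (plant
#' at the point) is substituted by 0.01 m (one cm).
#'
#' Scores are proportional to density; they are only ever used after
#' within-site normalization (see [relative_abundance()]), which also makes
#' a 0-4 count convention for the frequency term equivalent to this 0-1
#' fraction.
#'
#' @param distances numeric vector of length `n_corners`; `NA` = species
#'   absent at that corner.
#' @param n_corners number of observation corners (4 in the field design).
#' @return a non-negative density score; 0 when absent everywhere.
#' @examples
#' pcq_density(c(2, 2, 2, 2))      # 0.25
#' pcq_density(c(1, NA, NA, NA))   # 0.25
#' @export
pcq_density <- function(distances, n_corners = 4L) {
  stopifnot(length(distances) == n_corners)
  present <- !is.na(distances)
  if (!any(present)) return(0)
  d <- distances[present]
  if (any(d < 0 | d > 3.5))
    pf_stop("pf_validation_error",
            "corner distances must lie in [0, 3.5] m; got %s",
            paste(format(d[d < 0 | d > 3.5]), collapse = ", "))
  dbar <- mean(d)
  if (dbar == 0) dbar <- 0.01
  (1 / dbar^2) * (sum(present) / n_corners)
}

#' Relative abundances for one site from survey records
#'
#' Converts per-species density scores (PCQ method) or cover fractions
#' (cover method) into a relative-abundance vector summing to one.
#'
#' @param records a data frame for a single site with columns `species`,
#'   `method` (`"pcq"` or `"cover"`), distance columns `d1..d4` (PCQ,
#'   blank/NA = absent at that corner) and/or `cover`.
#' @return named numeric vector of relative abundances (sums to 1).
#' @export
relative_abundance <- function(records) {
  stopifnot(is.data.frame(records), "species" %in% names(records))
  method <- unique(records$method)
  if (length(method) != 1L)
    pf_stop("pf_validation_error", "mixed survey methods within one site")
  if (method == "pcq") {
    dcols <- grep("^d[0-9]+$", names(records), value = TRUE)
    dens <- apply(as.matrix(records[, dcols, drop = FALSE]), 1L,
                  pcq_density, n_corners = length(dcols))
  } else if (method == "cover") {
    dens <- records$cover
    if (any(is.na(dens)) || any(dens < 0 | dens > 1))
      pf_stop("pf_validation_error", "cover values must lie in [0, 1]")
  } else {
    pf_stop("pf_validation_error", "unknown survey method '%s'", method)
  }
  names(dens) <- records$species
  dens <- c(tapply(dens, names(dens), sum)) # merge duplicate species rows
  total <- sum(dens)
  if (total <= 0)
    pf_stop("pf_empty_community_error", "no species with positive abundance")
  dens / total
}

#' Build a community matrix (sites x species, rows sum to 1)
#'
#' @param survey a data frame of survey records with a `site` column plus the
#'   columns [relative_abundance()] expects.
#' @param species optional full species pool fixing column order; defaults to
#'   all species observed.
#' @return numeric matrix, sites as rows, relative abundances as entries.
#' @export
community_matrix <- function(survey, species = NULL) {
  stopifnot(is.data.frame(survey), all(c("site", "species") %in% names(survey)))
  sites <- unique(survey$site)
  species <- species %||% sort(unique(survey$species))
  M <- matrix(0, length(sites), length(species),
              dimnames = list(as.character(sites), species))
  for (s in sites) {
    p <- relative_abundance(survey[survey$site == s, , drop = FALSE])
    M[as.character(s), names(p)] <- p
  }
  M
}

#' Aggregate repeated trait measurements to one value per species
#'
#' Databases often hold several measurements per species; the species value
#' is their median (mid-point of the two central order statistics for an
#' even count). Species with no finite value get `NA` and are excluded from
#' that trait's analyses.
#'
#' @param values numeric vector of measurements for one species.
#' @return a single numeric value, or `NA_real_` when none is available.
#' @export
aggregate_trait <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) return(NA_real_)
  stats::median(v)
}

#' Scale a trait to [0, 1] over the whole species pool
#'
#' `x' = (x - min) / (max - min)`, computed once over the global pool so that
#' Rao's Q values are comparable across sites. Missing values stay missing.
#'
#' @param x numeric trait values over the species pool.
#' @return vector on [0, 1], same length and names as `x`.
#' @export
scale_trait <- function(x) {
  v <- x[is.finite(x)]
  if (length(unique(v)) < 2L)
    pf_stop("pf_degenerate_scaling_error",
            "trait is constant over the pool; all distances would be zero")
  (x - min(v)) / (max(v) - min(v))
}

#' Read a survey table from delimited text
#'
#' Expected columns: `site`, `species`, `method`, `d1..d4` (blank = absent)
#' and/or `cover`.
#'
#' @param file path to a delimited text file.
#' @param sep field separator.
#' @return a data frame of survey records.
#' @export
read_survey <- function(file, sep = "\t") {
  utils::read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Read a species trait table (columns species, sla, ldmc) and aggregate
#' duplicate species rows by the median.
#'
#' @inheritParams read_survey
#' @return data frame with one row per species.
#' @export
read_traits <- function(file, sep = "\t") {
  tt <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopifnot("species" %in% names(tt))
  traits <- setdiff(names(tt), "species")
  out <- data.frame(species = unique(tt$species), stringsAsFactors = FALSE)
  for (tr in traits) {
    agg <- tapply(tt[[tr]], tt$species, aggregate_trait)
    out[[tr]] <- as.numeric(agg[out$species])
  }
  out
}
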