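#' z-scale a numeric vector (mean 0, SD 1)
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return scaled vector (sample SD, n-1 denominator).
#' @export
zscale <- function(x) {
  v <- x[is.finite(x)]
  if (length(unique(v)) < 2L)
    pf_stop("pf_degenerate_scaling_error", "cannot z-scale a constant vector")
  (x - mean(v)) / stats::sd(v)
}

#' Fit the diversity-interaction regression for one response
#'
#' Ordinary least squares of a (typically log-transformed) soil-fauna
#' response on: a binary data-source factor (`VegData`), the standardized
#' phylogenetic diversity (`PhylDiv`, SES of Abu.mpd), the community-weighted
#' mean of the focal trait (`meanFunTrait`), the single-trait Rao diversity
#' (`FunTraitDiv`) and the `PhylDiv x FunTraitDiv` interaction. Continuous
#' predictors are z-scaled before fitting (the binary factor is left 0/1);
#' the interaction is the product of the two scaled diversity terms. Up to
#' `max_outliers` points with externally studentized residual above
#' `outlier_threshold` are removed iteratively (largest first), refitting
#' after each removal.
#'
#' @param data data frame containing `response` and the predictor columns.
#' @param response name of the response column.
#' @param predictors named list mapping the canonical term names `VegData`,
#'   `PhylDiv`, `meanFunTrait`, `FunTraitDiv` to columns of `data`; any term
#'   may be omitted. The interaction `PhylDiv:FunTraitDiv` is always added
#'   when both parents are present.
#' @param scale_predictors z-scale continuous predictors? (default TRUE, as
#'   in the field convention of reporting comparable effect sizes).
#' @param max_outliers cap on removed points (default 3).
#' @param outlier_threshold |externally studentized residual| above which a
#'   point is an outlier (default 3).
#' @return an object of class `pf_model`: list with `coefficients` (term,
#'   estimate, se, t, p), `r_squared`, `adj_r_squared`, `vif`, `excluded`
#'   (site ids or row indices removed), `n_used`, `fit` (the final `lm`).
#' @export
fit_interaction_model <- function(data, response,
                                  predictors = list(
                                    VegData = "veg_data",
                                    PhylDiv = "ses_mpd",
                                    meanFunTrait = "cwm",
                                    FunTraitDiv = "rao"),
                                  scale_predictors = TRUE,
                                  max_outliers = 3L,
                                  outlier_threshold = 3) {
  stopifnot(response %in% names(data))
  cols <- unlist(predictors)
  stopifnot(all(cols %in% names(data)))
  df <- data[, c(response, cols), drop = FALSE]
  site_id <- if ("site" %in% names(data)) data$site else seq_len(nrow(data))
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  site_id <- site_id[keep]
  names(df) <- c(".y", names(predictors))

  binary <- vapply(names(predictors), function(nm)
    nm == "VegData" || length(unique(df[[nm]])) <= 2L, logical(1))
  if (scale_predictors)
    for (nm in names(predictors)[!binary]) df[[nm]] <- zscale(df[[nm]])

  terms <- names(predictors)
  if (all(c("PhylDiv", "FunTraitDiv") %in% terms))
    terms <- c(terms, "PhylDiv:FunTraitDiv")
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))

  if (nrow(df) <= length(terms) + 1L)
    pf_stop("pf_validation_error",
            "n (%d) too small for %d terms", nrow(df), length(terms))

  excluded <- site_id[0]
  repeat {
    fit <- stats::lm(fml, data = df)
    if (fit$rank < length(stats::coef(fit))) {
      aliased <- names(which(is.na(stats::coef(fit))))
      pf_stop("pf_rank_deficiency_error", "singular design; aliased: %s",
              paste(aliased, collapse = ", "))
    }
    if (length(excluded) >= max_outliers) break
    rs <- stats::rstudent(fit)
    worst <- which.max(abs(rs))
    if (!is.finite(rs[worst]) || abs(rs[worst]) <= outlier_threshold) break
    if (nrow(df) - 1L <= length(terms) + 1L) {
      warning("outlier remains but removal would exhaust residual df",
              call. = FALSE)
      break
    }
    excluded <- c(excluded, site_id[worst])
    df <- df[-worst, , drop = FALSE]
    site_id <- site_id[-worst]
  }
  if (max_outliers > 0L && length(excluded) == max_outliers &&
      any(abs(stats::rstudent(fit)) > outlier_threshold, na.rm = TRUE))
    warning("outlier cap (", max_outliers, ") reached; further outliers kept",
            call. = FALSE)

  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                      t = ct[, 3], p = ct[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  X <- stats::model.matrix(fit)[, -1, drop = FALSE]
  vifs <- if (ncol(X) >= 2L) vif(X) else stats::setNames(1, colnames(X))
  structure(list(coefficients = coefs,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 vif = vifs,
                 excluded = excluded,
                 n_used = nrow(df),
                 response = response,
                 formula = deparse(fml),
                 fit = fit),
            class = "pf_model")
}

#' @export
print.pf_model <- function(x, ...) {
  cat("Interaction model:", x$formula, "\n")
  cat("n =", x$n_used, " excluded:",
      if (length(x$excluded)) paste(x$excluded, collapse = ", ") else "none",
      "\n")
  print(transform(x$coefficients, t = round(t, 2), p = round(p, 4),
                  estimate = signif(estimate, 4), se = signif(se, 4)))
  cat(sprintf("R2 = %.3f  adj R2 = %.3f\n", x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is from regressing predictor k on
#' all other predictors (intercept included).
#'
#' @param X numeric predictor matrix (no intercept column), >= 2 columns.
#' @return named vector of VIFs; `Inf` flags perfect collinearity.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2L)
  vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(X))
}

#' Pearson correlation screen
#'
#' Pairwise Pearson correlations with two-sided p-values (t approximation,
#' n-2 df), pairwise-complete observations.
#'
#' @param data data frame or matrix of numeric variables (columns).
#' @return list with matrices `r`, `p` and `n` (complete pairs per cell).
#' @export
pearson_screen <- function(data) {
  X <- as.matrix(data)
  k <- ncol(X)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(colnames(X),
                                                        colnames(X)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(X[, i], X[, j])
    n[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (n[i, j] < 3 || stats::sd(X[ok, i]) == 0 || stats::sd(X[ok, j]) == 0) {
      next # undefined r left NA
    }
    rij <- stats::cor(X[ok, i], X[ok, j])
    r[i, j] <- rij
    tt <- rij * sqrt((n[i, j] - 2) / (1 - rij^2))
    p[i, j] <- 2 * stats::pt(abs(tt), n[i, j] - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' First two principal-component scores of a community matrix
#'
#' Summarizes plant community composition as the scores of each site on the
#' first two principal components of the centred sites x species matrix.
#' The sign of each component is fixed so the species with the largest
#' absolute loading loads positively.
#'
#' @param community sites x species matrix.
#' @return matrix sites x 2 (`PC1`, `PC2`) plus attribute
#'   `var_explained`; reduced to fewer columns with a warning when the
#'   matrix has fewer than 2 non-degenerate components.
#' @export
vegetation_factors <- function(community) {
  M <- as.matrix(community)
  if (nrow(M) < 3L || ncol(M) < 2L)
    pf_stop("pf_validation_error", "need >= 3 sites and >= 2 species")
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  nz <- sum(pc$sdev > 1e-10)
  k <- min(2L, nz)
  if (k < 2L)
    warning("fewer than 2 non-degenerate components; returning ", k,
            call. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) scores[, j] <- -scores[, j]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(scores, var_explained = ve[seq_len(k)])
}

#' Split sites at the median of a diversity measure
#'
#' @param x numeric vector (e.g. SES of Abu.mpd per site).
#' @return factor with levels `below`/`above`; ties at the median go to
#'   `below`. The threshold is attached as attribute `threshold`.
#' @export
median_split <- function(x) {
  stopifnot(length(x) >= 2L)
  m <- stats::median(x, na.rm = TRUE)
  g <- factor(ifelse(x <= m, "below", "above"), levels = c("below", "above"))
  if (all(g == "below", na.rm = TRUE))
    warning("all values at or below the median; degenerate split",
            call. = FALSE)
  attr(g, "threshold") <- m
  g
}

#' Assemble a publication-style model report table
#'
#' One row per fitted model (trait x fauna response): n sites used, per-term
#' `t (p)` strings, R2 and adjusted R2. p < 0.05 is marked `*`,
#' 0.05 <= p < 0.1 marked `.` (a boundary p = 0.05 is marginal, not
#' significant). No multiple-testing correction is applied; interpretation
#' rests on consistency across taxa and traits.
#'
#' @param results named list of `pf_model` objects; names like
#'   `"SLA|Earthworms"` become the trait / group columns.
#' @return data frame report table.
#' @export
build_report <- function(results) {
  stopifnot(length(results) >= 1L)
  fmt <- function(t, p) {
    mark <- if (p < 0.05) "*" else if (p < 0.1) "." else ""
    sprintf("%.2f (%.2f)%s", t, p, mark)
  }
  terms <- unique(unlist(lapply(results, function(m)
    setdiff(m$coefficients$term, "(Intercept)"))))
  rows <- lapply(names(results), function(nm) {
    m <- results[[nm]]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    row <- list(trait = parts[1],
                response = if (length(parts) > 1) parts[2] else m$response,
                n_sites = m$n_used)
    for (tm in terms) {
      i <- match(tm, m$coefficients$term)
      row[[tm]] <- if (is.na(i)) "" else
        fmt(m$coefficients$t[i], m$coefficients$p[i])
    }
    row$R2 <- round(m$r_squared, 2)
    row$adj_R2 <- round(m$adj_r_squared, 2)
    as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
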