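test_that("zscale standardizes with the n-1 SD", {
  expect_equal(zscale(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  expect_equal(zscale(x), (x - 5) / sd(x))
  set.seed(2)
  y <- rnorm(40, 10, 3)
  expect_equal(mean(zscale(y)), 0, tolerance = 1e-12)
  expect_equal(sd(zscale(y)), 1, tolerance = 1e-12)
  expect_error(zscale(rep(1, 5)), class = "pf_degenerate_scaling_error")
})

test_that("fit_interaction_model matches the normal-equations oracle", {
  df <- rand_design_df(19, seed = 31)
  m <- fit_interaction_model(df, "y", max_outliers = 0L)
  zP <- zscale(df$ses_mpd); zM <- zscale(df$cwm); zF <- zscale(df$rao)
  X <- cbind(1, df$veg_data, zP, zM, zF, zP * zF)
  o <- oracle_ols(X, df$y)
  expect_equal(m$coefficients$estimate, o$beta, tolerance = 1e-8)
  expect_equal(m$coefficients$se, o$se, tolerance = 1e-8)
  expect_equal(m$coefficients$t, o$t, tolerance = 1e-8)
  expect_equal(m$coefficients$p, o$p, tolerance = 1e-8)
  expect_equal(m$r_squared, o$r2, tolerance = 1e-8)
  expect_equal(m$adj_r_squared, o$adj_r2, tolerance = 1e-8)
  expect_lte(m$adj_r_squared, m$r_squared)
})

test_that("perfect fits and singular designs are handled", {
  df <- rand_design_df(19, seed = 7)
  df$y <- 2 + 3 * zscale(df$ses_mpd)
  m <- fit_interaction_model(df, "y", max_outliers = 0L)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  expect_gt(abs(m$coefficients$t[m$coefficients$term == "PhylDiv"]), 1e6)

  dup <- rand_design_df(19, seed = 8)
  dup$rao <- dup$ses_mpd # duplicated predictor -> aliased interaction
  expect_error(fit_interaction_model(dup, "y", max_outliers = 0L),
               class = "pf_rank_deficiency_error")
})

test_that("t and p are invariant to affine rescaling of raw predictors", {
  df <- rand_design_df(19, seed = 12)
  m1 <- fit_interaction_model(df, "y", max_outliers = 0L)
  df2 <- df
  df2$ses_mpd <- 100 * df$ses_mpd - 7
  df2$rao <- 0.001 * df$rao + 5
  m2 <- fit_interaction_model(df2, "y", max_outliers = 0L)
  expect_equal(m1$coefficients$t, m2$coefficients$t, tolerance = 1e-9)
  expect_equal(m1$coefficients$p, m2$coefficients$p, tolerance = 1e-9)
})

test_that("outlier exclusion removes planted outliers, capped at three", {
  make <- function(n, k_outliers, seed) {
    df <- rand_design_df(n, seed = seed)
    df$y <- 0.5 * zscale(df$ses_mpd) + 0.3 * zscale(df$rao) + rnorm(n, 0, 1)
    if (k_outliers > 0) df$y[seq_len(k_outliers)] <-
      df$y[seq_len(k_outliers)] + 10
    df
  }
  set.seed(41)
  clean <- make(30, 0, 41)
  expect_length(fit_interaction_model(clean, "y")$excluded, 0)

  set.seed(42)
  one <- make(30, 1, 42)
  m1 <- fit_interaction_model(one, "y")
  expect_identical(m1$excluded, "s1")

  set.seed(43)
  four <- make(40, 4, 43)
  expect_warning(m4 <- fit_interaction_model(four, "y"), "cap")
  expect_length(m4$excluded, 3)
  expect_true(all(m4$excluded %in% paste0("s", 1:4)))

  # idempotence: refitting the cleaned data excludes nothing more
  kept <- one[!(one$site %in% m1$excluded), ]
  expect_length(fit_interaction_model(kept, "y")$excluded, 0)
})

test_that("vif matches closed forms", {
  # exactly orthogonal centred predictors
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(X)), c(1, 1))
  expect_true(any(is.infinite(vif(cbind(X, a2 = X[, "a"])))))
  # correlation exactly 0.6 by construction
  u <- scale(c(1, 2, 3, 4, 5, 6))[, 1]
  v <- scale(c(1, -1, 1, -1, 1, -1) - mean(c(1, -1, 1, -1, 1, -1)))[, 1]
  v <- v - u * sum(u * v) / sum(u^2) # orthogonalize
  v <- v / sd(v)
  y <- 0.6 * u + sqrt(1 - 0.36) * v
  expect_equal(cor(u, y), 0.6, tolerance = 1e-12)
  expect_equal(unname(vif(cbind(u, y))), c(1.5625, 1.5625), tolerance = 1e-9)
})

test_that("pearson_screen reproduces hand correlations and p-values", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8),
                  z = c(2, 1, 4, 3))
  ps <- pearson_screen(d)
  expect_equal(ps$r["x", "y"], 1)
  expect_equal(ps$r["x", "z"], 0.6)
  expect_equal(diag(ps$r), c(x = 1, y = 1, z = 1))
  ct <- cor.test(d$x, d$z)
  expect_equal(ps$p["x", "z"], ct$p.value, tolerance = 1e-10)
  d$neg <- -d$x
  expect_equal(pearson_screen(d)$r["x", "neg"], -1)
  d$const <- 5
  expect_true(is.na(pearson_screen(d)$r["x", "const"]))
})

test_that("vegetation_factors matches an SVD oracle up to sign", {
  set.seed(17)
  M <- matrix(runif(60), 10, 6, dimnames = list(paste0("s", 1:10),
                                                paste0("sp", 1:6)))
  M <- M / rowSums(M)
  vf <- vegetation_factors(M)
  C <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(C)
  for (j in 1:2) {
    ref <- sv$u[, j] * sv$d[j]
    expect_true(min(max(abs(vf[, j] - ref)), max(abs(vf[, j] + ref))) < 1e-8)
  }
  # permuting species columns leaves scores unchanged
  vf2 <- vegetation_factors(M[, c(3, 1, 6, 2, 5, 4)])
  expect_equal(unclass(vf), unclass(vf2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # rank-1 gradient (two perfectly trading-off species): PC1 explains all
  p <- seq(0.2, 0.8, length.out = 8)
  expect_warning(vf1 <- vegetation_factors(cbind(a = p, b = 1 - p)),
                 "non-degenerate")
  expect_gt(attr(vf1, "var_explained")[1], 0.999)
})

test_that("median_split labels with ties going below", {
  g <- median_split(c(-2, -1, 0, 1))
  expect_equal(as.character(g), c("below", "below", "above", "above"))
  expect_equal(attr(g, "threshold"), -0.5)
  g2 <- median_split(c(-1.9, -0.8, 0.3))
  expect_equal(attr(g2, "threshold"), -0.8)
  expect_equal(as.character(g2)[2], "below")
  expect_warning(g3 <- median_split(rep(1, 4)), "degenerate")
  expect_true(all(g3 == "below"))
})

test_that("build_report formats rows with significance marks", {
  df <- rand_design_df(19, seed = 55)
  m <- fit_interaction_model(df, "y", max_outliers = 0L)
  rep1 <- build_report(list("SLA|Earthworms" = m))
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$trait, "SLA")
  expect_equal(rep1$response, "Earthworms")

  m_sig <- m; m_marg <- m
  m_sig$coefficients$p[] <- 0.049
  m_marg$coefficients$p[] <- 0.07
  expect_true(grepl("\\*$",
    build_report(list("SLA|x" = m_sig))$PhylDiv))
  expect_true(grepl("\\.$",
    build_report(list("SLA|x" = m_marg))$PhylDiv))
  # boundary p = 0.05 is marginal, not significant
  m_b <- m; m_b$coefficients$p[] <- 0.05
  expect_true(grepl("\\.$", build_report(list("SLA|x" = m_b))$PhylDiv))

  multi <- build_report(list("SLA|a" = m, "SLA|b" = m, "LDMC|a" = m,
                             "LDMC|b" = m))
  expect_equal(nrow(multi), 4)
})
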