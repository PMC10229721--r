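test_that("simulate_tree produces valid, deterministic pure-birth trees", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2L)
  a <- simulate_tree(30, seed = 5)
  b <- simulate_tree(30, seed = 5)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_false(identical(ape::write.tree(a),
                         ape::write.tree(simulate_tree(30, seed = 6))))
  expect_true(all(grepl("^Genus[0-9]+_species[0-9]+$", a$tip.label)))
  expect_error(simulate_tree(1, seed = 1), class = "pf_validation_error")
})

test_that("pure-birth depths scale inversely with the birth rate", {
  depth <- function(rate, seed) {
    tr <- simulate_tree(20, birth_rate = rate, seed = seed)
    max(ape::node.depth.edgelength(tr))
  }
  d_slow <- vapply(1:150, function(s) depth(0.05, s), numeric(1))
  d_fast <- vapply(1:150, function(s) depth(0.10, 1000 + s), numeric(1))
  expect_gt(mean(d_slow) / mean(d_fast), 1.7)
  expect_lt(mean(d_slow) / mean(d_fast), 2.3)
})

test_that("full trait signal makes zero-branch sisters identical", {
  expect_warning(tr <- parse_newick("((A:0,B:0):1,C:2);"), "zero-length")
  tt <- simulate_traits(tr, trait_signal = 1, seed = 3)
  expect_equal(tt$sla[tt$species == "A"], tt$sla[tt$species == "B"],
               tolerance = 1e-8)
  expect_equal(tt$ldmc[tt$species == "A"], tt$ldmc[tt$species == "B"],
               tolerance = 1e-8)
})

test_that("trait signal controls the trait-distance relationship", {
  tr <- simulate_tree(40, seed = 9)
  D <- patristic_matrix(tr)
  dv <- D[upper.tri(D)]
  cor_by_signal <- function(lambda, nrep, seed0) {
    vapply(seq_len(nrep), function(r) {
      tt <- simulate_traits(tr, trait_signal = lambda, seed = seed0 + r)
      z <- log(tt$sla / 25) / 0.25 # invert the log-normal map
      names(z) <- tt$species
      dz <- abs(outer(z[rownames(D)], z[rownames(D)], `-`))
      cor(dv, dz[upper.tri(dz)])
    }, numeric(1))
  }
  # signal-free: no association between trait and phylogenetic distance
  expect_lt(abs(mean(cor_by_signal(0, 50, 100))), 0.1)
  # conserved: squared trait differences grow linearly in patristic distance
  depth <- max(ape::vcv(tr))
  sq <- matrix(0, 40, 40)
  for (r in 1:300) {
    tt <- simulate_traits(tr, trait_signal = 1, trait_sd = 1,
                          seed = 5000 + r)
    z <- setNames(log(tt$sla / 25) / 0.25, tt$species)[rownames(D)]
    sq <- sq + outer(z, z, `-`)^2 / 300
  }
  slope <- coef(lm(sq[upper.tri(sq)] ~ dv))[2]
  expect_equal(unname(slope), 1 / depth, tolerance = 0.15)
})

test_that("the two traits carry the configured correlation", {
  tr <- simulate_tree(60, seed = 2)
  cors <- vapply(1:40, function(r) {
    tt <- simulate_traits(tr, trait_signal = 0.5, trait_cor = -0.5,
                          seed = 300 + r)
    cor(log(tt$sla / 25) / 0.25, log(tt$ldmc / 250) / 0.20)
  }, numeric(1))
  expect_equal(mean(cors), -0.5, tolerance = 0.1)
})

test_that("assemble_communities rows sum to one and respect the filters", {
  tr <- simulate_tree(40, seed = 21)
  tt <- simulate_traits(tr, seed = 22)
  D <- patristic_matrix(tr)

  narrow <- assemble_communities(tr, tt, tau_phylo = 2, tau_trait = 1e6,
                                 n_sites = 40, richness_range = c(5, 10),
                                 seed = 23)
  expect_equal(unname(rowSums(narrow)), rep(1, 40), tolerance = 1e-9)
  wide <- assemble_communities(tr, tt, tau_phylo = Inf, tau_trait = Inf,
                               n_sites = 200, richness_range = c(5, 10),
                               seed = 24)
  expect_equal(unname(rowSums(wide)), rep(1, 200), tolerance = 1e-9)

  ses_narrow <- community_diversity(narrow, D, replicates = 199, seed = 25,
                                    metrics = "mpd")$ses_mpd
  ses_wide <- community_diversity(wide, D, replicates = 199, seed = 26,
                                  metrics = "mpd")$ses_mpd
  # tight phylogenetic filter -> clustered communities, strongly negative SES
  expect_lt(mean(ses_narrow), -0.5)
  # no filtering reproduces the null: mean SES near zero
  expect_lt(abs(mean(ses_wide)), 0.2)
  expect_lt(mean(ses_narrow), mean(ses_wide))
})

test_that("simulate_fauna is deterministic and respects the null model", {
  set.seed(31)
  div <- data.frame(site = paste0("s", 1:12), ses_mpd = rnorm(12),
                    rao_sla = runif(12), cwm_sla = runif(12, 20, 30))
  beta <- list(b0 = 2, bP = 0.2, bF = 0.3, bint = 0.5, bM = 0.2)
  f1 <- simulate_fauna(div, beta, sigma = 0.4, seed = 8)
  f2 <- simulate_fauna(div, beta, sigma = 0.4, seed = 8)
  expect_identical(f1, f2)
  expect_true(all(f1$count >= 0))
  expect_true(all(f1$count == round(f1$count)))

  # all-zero coefficients and vanishing noise: near-constant log abundance
  b0 <- list(b0 = 2, bP = 0, bF = 0, bint = 0, bM = 0)
  f0 <- simulate_fauna(div, b0, sigma = 1e-9, seed = 9)
  per_taxon_sd <- tapply(f0$count, f0$taxon, sd)
  expect_true(all(per_taxon_sd == 0))
})

test_that("generate_study echoes the configured scale deterministically", {
  cfg <- synth_config(n_sites = 8, n_species = 25, null_replicates = 49,
                      seed = 77)
  st <- generate_study(cfg)
  expect_equal(nrow(st$community), 8)
  expect_equal(ncol(st$community), 25)
  expect_equal(ape::Ntip(st$tree), 25)
  expect_equal(sort(unique(st$fauna$site)), sort(st$diversity$site))
  expect_equal(st$truth$beta$bint, 0.5)

  st2 <- generate_study(cfg)
  j1 <- jsonlite::toJSON(st$diversity, digits = NA)
  j2 <- jsonlite::toJSON(st2$diversity, digits = NA)
  expect_identical(j1, j2)
  expect_identical(st$fauna, st2$fauna)

  # default config matches the emulated field scale
  dflt <- synth_config()
  expect_equal(dflt$n_sites, 19L)
  expect_equal(dflt$n_species, 91L)
})

test_that("write_study emits the plain-text bundle", {
  cfg <- synth_config(n_sites = 4, n_species = 12, null_replicates = 19,
                      seed = 3)
  st <- generate_study(cfg)
  out <- file.path(tempdir(), "pf_study_test")
  write_study(st, out)
  expect_true(all(file.exists(file.path(out,
    c("tree.nwk", "traits.tsv", "community.tsv", "fauna.tsv",
      "diversity.tsv", "truth.json")))))
  comm <- read.table(file.path(out, "community.tsv"), header = TRUE,
                     sep = "\t", check.names = FALSE)
  expect_equal(unname(rowSums(comm[, -1])), rep(1, 4), tolerance = 1e-6)
  unlink(out, recursive = TRUE)
})
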