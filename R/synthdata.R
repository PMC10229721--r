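#' Configuration for a synthetic study
#'
#' Defaults emulate the scale of the motivating field system: a pool of 91
#' meadow plant species observed over 19 sites, per-site richness between 5
#' and 25, a pure-birth phylogeny, two leaf traits (SLA, LDMC) evolving with
#' intermediate phylogenetic signal and the leaf-economics negative
#' correlation, communities assembled by joint phylogenetic and trait
#' filters, and fauna whose log10 abundance responds linearly to
#' phylogenetic diversity (SES of Abu.mpd), trait diversity (Rao), their
#' interaction, and the community-weighted trait mean.
#'
#' @param n_species species-pool size.
#' @param n_sites number of sites.
#' @param richness_range per-site species richness, drawn uniformly.
#' @param birth_rate pure-birth speciation rate (per Myr-like unit).
#' @param trait_signal Pagel-lambda-style phylogenetic signal in [0, 1]
#'   (1 = Brownian motion, 0 = signal-free).
#' @param trait_sd Brownian-motion SD at the tree depth scale.
#' @param trait_cor correlation between the two simulated traits.
#' @param tau_phylo phylogenetic filter width (Myr); small = sites dominated
#'   by close relatives; `Inf` = no phylogenetic filtering. A length-2
#'   vector gives a per-site log-uniform range, so sites span a gradient
#'   from clustered to unfiltered — the between-site diversity variation the
#'   emulated study observed. A scalar fixes one width for all sites.
#' @param tau_trait trait filter width on the [0, 1]-scaled trait; `Inf` =
#'   no trait filtering; scalar or length-2 range as for `tau_phylo`.
#' @param dirichlet_alpha symmetric Dirichlet concentration for abundances.
#' @param beta generative fauna coefficients: `b0` (baseline log10
#'   abundance), `bP` (SES), `bF` (Rao), `bint` (SES x Rao, applied to
#'   exposed sub-groups only), `bM` (CWM of the scaled trait).
#' @param sigma residual SD on the log10-abundance scale.
#' @param null_replicates replicates for the SES null model.
#' @param ses_metrics which SES metrics the study computes; restricting to
#'   `"mpd"` skips the MNTD null (compute only; other draws unchanged).
#' @param seed master seed; every stage derives its own sub-seed.
#' @return a `pf_synth_config` list.
#' @export
synth_config <- function(n_species = 91L, n_sites = 19L,
                         richness_range = c(5L, 25L),
                         birth_rate = 0.05,
                         trait_signal = 0.5, trait_sd = 1, trait_cor = -0.5,
                         tau_phylo = c(60, 500), tau_trait = c(0.05, 2),
                         dirichlet_alpha = 1,
                         beta = list(b0 = 2, bP = 0.2, bF = 0.3,
                                     bint = 0.5, bM = 0.2),
                         sigma = 0.5,
                         null_replicates = 999L,
                         ses_metrics = c("mpd", "mntd"),
                         seed = 1L) {
  stopifnot(n_species >= 2L, n_sites >= 1L,
            richness_range[1] >= 2L, richness_range[2] >= richness_range[1],
            birth_rate > 0, trait_signal >= 0, trait_signal <= 1,
            trait_sd > 0, abs(trait_cor) <= 1,
            all(tau_phylo > 0), all(tau_trait > 0),
            length(tau_phylo) <= 2L, length(tau_trait) <= 2L,
            dirichlet_alpha > 0, sigma > 0,
            null_replicates >= 1L)
  structure(as.list(environment()), class = "pf_synth_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Tip labels are binomial-like (`GenusXX speciesYYY`) with species assigned
#' to genera at random (about one genus per three species), so genus-level
#' substitution can be exercised on synthetic pools.
#'
#' @param n number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @return a `phylo` object with branch lengths in Myr-like units.
#' @export
simulate_tree <- function(n, birth_rate = 0.05, seed = 1L) {
  if (n < 2L) pf_stop("pf_validation_error", "need at least 2 tips")
  with_seed(seed, {
    tr <- ape::rphylo(n, birth = birth_rate, death = 0)
    genus <- sample.int(max(2L, ceiling(n / 3)), n, replace = TRUE)
    # underscores, not spaces: Newick round-trips them unchanged
    tr$tip.label <- sprintf("Genus%02d_species%03d", genus, seq_len(n))
    tr
  })
}

#' Simulate two correlated traits on a tree with tunable phylogenetic signal
#'
#' Traits follow Brownian motion on a lambda-transformed tree: the
#' between-tip covariance (shared path length) is multiplied by
#' `trait_signal`, leaving tip variances unchanged. `trait_signal = 1` is
#' plain Brownian motion; `trait_signal = 0` gives independent draws.
#' The two latent variables are given correlation `trait_cor` and mapped to
#' positive trait scales: SLA (mm2/mg) around 25 and LDMC (mg/g) around 250
#' via log-normal transforms.
#'
#' @param tree a `phylo` object.
#' @param trait_signal signal in [0, 1].
#' @param trait_sd Brownian SD scale.
#' @param trait_cor correlation between the two traits.
#' @param seed integer seed.
#' @return data frame `species`, `sla`, `ldmc`.
#' @export
simulate_traits <- function(tree, trait_signal = 0.5, trait_sd = 1,
                            trait_cor = -0.5, seed = 1L) {
  V <- ape::vcv(tree)
  depth <- max(diag(V))
  V <- V / depth # unit tip variance before trait_sd
  L <- trait_signal * V
  diag(L) <- diag(V)
  # eigen route tolerates the singular covariances that arise with
  # zero-length terminal branches at trait_signal = 1
  ev <- eigen(L, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(L))
  n <- ape::Ntip(tree)
  with_seed(seed, {
    z1 <- as.numeric(A %*% stats::rnorm(n)) * trait_sd
    z2r <- as.numeric(A %*% stats::rnorm(n)) * trait_sd
    z2 <- trait_cor * z1 + sqrt(1 - trait_cor^2) * z2r
    data.frame(species = rownames(V),
               sla = 25 * exp(0.25 * z1),
               ldmc = 250 * exp(0.20 * z2),
               stringsAsFactors = FALSE)
  })
}

#' Assemble site communities under joint phylogenetic and trait filters
#'
#' Each site draws a focal species; every pool species k gets sampling
#' weight `exp(-d_phylo(focal, k) / tau_phylo) * exp(-|x_k - x_focal| /
#' tau_trait)` (x = [0, 1]-scaled SLA). Site richness is uniform on
#' `richness_range`; that many species are sampled without replacement by
#' weight, and abundances come from a symmetric Dirichlet. Small
#' `tau_phylo` with large `tau_trait` yields clades of close relatives with
#' divergent traits, and vice versa; both filters wide recovers random
#' (null-like) assembly. When a filter width is a length-2 range, each site
#' draws its own width log-uniformly from it, creating the between-site
#' gradient from clustered to dispersed communities that gives diversity
#' regressions their leverage.
#'
#' @param tree a `phylo` object over the pool.
#' @param traits trait data frame from [simulate_traits()].
#' @param tau_phylo,tau_trait filter widths (Myr; scaled-trait units);
#'   scalar (fixed) or length-2 (per-site log-uniform range).
#' @param n_sites,richness_range,dirichlet_alpha see [synth_config()].
#' @param seed integer seed.
#' @return sites x species relative-abundance matrix.
#' @export
assemble_communities <- function(tree, traits, tau_phylo = c(60, 500),
                                 tau_trait = c(0.05, 2), n_sites = 19L,
                                 richness_range = c(5L, 25L),
                                 dirichlet_alpha = 1, seed = 1L) {
  D <- patristic_matrix(tree)
  sp <- tree$tip.label
  x <- scale_trait(stats::setNames(traits$sla, traits$species)[sp])
  draw_tau <- function(tau) {
    if (length(tau) == 1L) return(tau)
    exp(stats::runif(1, log(tau[1]), log(tau[2])))
  }
  with_seed(seed, {
    M <- matrix(0, n_sites, length(sp),
                dimnames = list(paste0("site", seq_len(n_sites)), sp))
    for (s in seq_len(n_sites)) {
      focal <- sample(sp, 1L)
      tp <- draw_tau(tau_phylo)
      tt <- draw_tau(tau_trait)
      w <- exp(-D[focal, ] / tp) * exp(-abs(x - x[focal]) / tt)
      k <- sample(seq.int(richness_range[1], richness_range[2]), 1L)
      k <- min(k, length(sp))
      chosen <- sample(sp, k, prob = w)
      g <- stats::rgamma(k, shape = dirichlet_alpha)
      M[s, chosen] <- g / sum(g)
    }
    M
  })
}

#' Default soil-fauna taxa template
#'
#' A small, fixed roster of taxa mirroring the field system's groups and
#' exposure contrasts: earthworms (epigeic exposed vs endogeic unexposed,
#' anecic counted but outside the contrast), springtails (hemiedaphic vs
#' euedaphic), mites (actinedid plant-feeders vs gamasid carnivores) and
#' nematode guilds (plant feeders and structure guilds exposed through diet
#' or longevity, basal guilds unexposed).
#'
#' @return data frame `taxon`, `group`, `subgroup`, `exposed` (logical),
#'   `b0_offset` (taxon-level baseline offset on the log10 scale).
#' @export
default_fauna_taxa <- function() {
  tx <- rbind(
    data.frame(taxon = paste0("earthworm_epi", 1:2), group = "earthworm",
               subgroup = "epigeic", exposed = TRUE),
    data.frame(taxon = "earthworm_ane1", group = "earthworm",
               subgroup = "anecic", exposed = FALSE),
    data.frame(taxon = paste0("earthworm_end", 1:3), group = "earthworm",
               subgroup = "endogeic", exposed = FALSE),
    data.frame(taxon = paste0("springtail_hem", 1:3), group = "springtail",
               subgroup = "hemiedaphic", exposed = TRUE),
    data.frame(taxon = paste0("springtail_eu", 1:3), group = "springtail",
               subgroup = "euedaphic", exposed = FALSE),
    data.frame(taxon = paste0("springtail_epi", 1:2), group = "springtail",
               subgroup = "epigeic", exposed = TRUE),
    data.frame(taxon = "mite_act1", group = "mite",
               subgroup = "actinedid", exposed = TRUE),
    data.frame(taxon = "mite_gam1", group = "mite",
               subgroup = "gamasid", exposed = FALSE),
    data.frame(taxon = c("nem_Ba1a", "nem_Ba2a", "nem_Ba2b", "nem_Fu2a"),
               group = "nematode", subgroup = c("Ba1", "Ba2", "Ba2", "Fu2"),
               exposed = FALSE),
    data.frame(taxon = c("nem_Pl2a", "nem_Pl3a"), group = "nematode",
               subgroup = c("Pl2", "Pl3"), exposed = TRUE),
    data.frame(taxon = c("nem_Ca3a", "nem_Ca4a", "nem_Om4a", "nem_Om5a"),
               group = "nematode", subgroup = c("Ca3", "Ca4", "Om4", "Om5"),
               exposed = TRUE)
  )
  # stable per-taxon baseline spread so taxa differ in commonness
  tx$b0_offset <- round(sin(seq_len(nrow(tx))) * 0.4, 3)
  tx
}

#' Simulate soil-fauna counts responding to plant diversity
#'
#' For each taxon and site, `log10(count + 1) = b0 + b0_offset + bP * SES +
#' bF * Rao + bint * SES * Rao + bM * CWMs + noise`, with `bint` applied
#' only to exposed taxa (unexposed taxa get 0), `CWMs` the pool-scaled CWM,
#' and noise ~ Normal(0, sigma^2). Counts are `round(10^eta - 1)` floored
#' at zero.
#'
#' @param div per-site diversity table with columns `site`, `ses_mpd`,
#'   `rao_sla` (or `rao`), `cwm_sla` (or `cwm`).
#' @param beta coefficient list (`b0`, `bP`, `bF`, `bint`, `bM`).
#' @param sigma residual SD (log10 scale).
#' @param seed integer seed.
#' @param taxa taxa template, see [default_fauna_taxa()].
#' @return long data frame `site`, `taxon`, `group`, `subgroup`, `count`.
#' @export
simulate_fauna <- function(div, beta, sigma = 0.5, seed = 1L,
                           taxa = default_fauna_taxa()) {
  stopifnot(sigma > 0)
  ses_v <- div$ses_mpd
  rao_v <- div$rao_sla %||% div$rao
  cwm_v <- div$cwm_sla %||% div$cwm
  cwm_s <- (cwm_v - mean(cwm_v)) / max(stats::sd(cwm_v), 1e-12)
  n <- nrow(div)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(taxa)), function(i) {
      bi <- if (taxa$exposed[i]) beta$bint else 0
      eta <- beta$b0 + taxa$b0_offset[i] + beta$bP * ses_v +
        beta$bF * rao_v + bi * ses_v * rao_v + beta$bM * cwm_s +
        stats::rnorm(n, 0, sigma)
      data.frame(site = div$site, taxon = taxa$taxon[i],
                 group = taxa$group[i], subgroup = taxa$subgroup[i],
                 count = pmax(0, round(10^eta - 1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic study
#'
#' Runs the full generative chain — phylogeny, traits, communities,
#' diversity metrics (including SES under the reshuffling null), a binary
#' data-source factor, and fauna counts — and records the true coefficients
#' for parameter-recovery tests.
#'
#' @param config a [synth_config()] list.
#' @return a `pf_synth_study` list: `tree`, `traits`, `community`, `D`,
#'   `diversity` (with `veg_data` column), `fauna`, `truth`, `config`.
#' @export
generate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "pf_synth_config"))
  sd0 <- config$seed
  tree <- simulate_tree(config$n_species, config$birth_rate,
                        derive_seed(sd0, 10L))
  traits <- simulate_traits(tree, config$trait_signal, config$trait_sd,
                            config$trait_cor, derive_seed(sd0, 20L))
  community <- assemble_communities(tree, traits, config$tau_phylo,
                                    config$tau_trait, config$n_sites,
                                    config$richness_range,
                                    config$dirichlet_alpha,
                                    derive_seed(sd0, 30L))
  D <- patristic_matrix(tree)
  div <- community_diversity(community, D, traits,
                             replicates = config$null_replicates,
                             seed = derive_seed(sd0, 40L),
                             metrics = config$ses_metrics)
  div$veg_data <- with_seed(derive_seed(sd0, 50L),
                            stats::rbinom(nrow(div), 1L, 1/3))
  fauna <- simulate_fauna(div, config$beta, config$sigma,
                          derive_seed(sd0, 60L))
  structure(list(tree = tree, traits = traits, community = community,
                 D = D, diversity = div, fauna = fauna,
                 truth = list(beta = config$beta, sigma = config$sigma),
                 config = config),
            class = "pf_synth_study")
}

#' Write a synthetic study to plain-text files
#'
#' Writes `tree.nwk`, `traits.tsv`, `community.tsv`, `fauna.tsv`,
#' `diversity.tsv` and `truth.json` under `outdir`.
#'
#' @param study a `pf_synth_study`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(study$tree, file.path(outdir, "tree.nwk"))
  utils::write.table(study$traits, file.path(outdir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comm <- data.frame(site = rownames(study$community), study$community,
                     check.names = FALSE)
  utils::write.table(comm, file.path(outdir, "community.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$fauna, file.path(outdir, "fauna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$diversity, file.path(outdir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
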