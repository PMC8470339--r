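#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every knob of the generator. Defaults describe a
#' desk-scale stand-in for a multi-wetland floristic survey: a 200-species
#' regional pool on an ultrametric pure-birth (Yule) tree, 28 sites with
#' richness 5-50, a life-form mix dominated by perennial herbs, and dominant/
#' invasive flag rates matching the roughly 11% and 5% of species such
#' surveys report.
#'
#' @param n_tips Species in the regional pool (>= 2). Default 200.
#' @param n_sites Number of sites. Default 28.
#' @param richness_range Integer range (min, max) of per-site richness,
#'   drawn uniformly. Default `c(5, 50)`.
#' @param assembly `"neutral"`, `"clustered"` or `"overdispersed"`.
#' @param tau Clustering length scale in branch-length units (> 0); under
#'   `"clustered"` a random focal species recruits others with weight
#'   `exp(-d/tau)`, under `"overdispersed"` with weight `1 - exp(-d/tau)`,
#'   where d is patristic distance to the focal species. Default 1.
#' @param lifeform_mix Named proportions over annual/perennial/woody/other
#'   (must sum to 1). Default `c(annual = .30, perennial = .60, woody = .07,
#'   other = .03)`.
#' @param dominant_rate,invasive_rate Expected fraction of species flagged.
#'   Defaults 0.11 and 0.05.
#' @param flag_mode `"random"` (independent Bernoulli flags) or `"clade"`
#'   (flags concentrated in one clade of about the target size, emulating
#'   phylogenetically clustered dominant/invasive sets).
#' @param seed Integer seed; all generated artifacts are reproducible from
#'   it. Default 1.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_tips = 200, n_sites = 28, richness_range = c(5, 50),
                         assembly = c("neutral", "clustered", "overdispersed"),
                         tau = 1,
                         lifeform_mix = c(annual = 0.30, perennial = 0.60,
                                          woody = 0.07, other = 0.03),
                         dominant_rate = 0.11, invasive_rate = 0.05,
                         flag_mode = c("random", "clade"), seed = 1) {
  assembly <- match.arg(assembly)
  flag_mode <- match.arg(flag_mode)
  n_tips <- as.integer(n_tips); n_sites <- as.integer(n_sites)
  richness_range <- as.integer(richness_range)
  stopifnot(n_tips >= 2L, n_sites >= 1L, length(richness_range) == 2L,
            richness_range[1] >= 1L, richness_range[1] <= richness_range[2],
            tau > 0, dominant_rate >= 0, dominant_rate <= 1,
            invasive_rate >= 0, invasive_rate <= 1)
  if (richness_range[2] > n_tips) {
    stop("maximum richness exceeds the number of tips", call. = FALSE)
  }
  if (!setequal(names(lifeform_mix), lifeform_levels()) ||
      abs(sum(lifeform_mix) - 1) > 1e-8 || any(lifeform_mix < 0)) {
    stop("lifeform_mix must be named proportions over ",
         paste(lifeform_levels(), collapse = "/"), " summing to 1", call. = FALSE)
  }
  structure(list(n_tips = n_tips, n_sites = n_sites,
                 richness_range = richness_range, assembly = assembly,
                 tau = tau, lifeform_mix = lifeform_mix[lifeform_levels()],
                 dominant_rate = dominant_rate, invasive_rate = invasive_rate,
                 flag_mode = flag_mode, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with unit speciation rate conditioned on the configured
#' number of tips, relabeled `sp001`, `sp002`, ... Root-to-tip distance is
#' equal across tips by construction.
#'
#' @param cfg A [synth_config()].
#' @return A `"phylo"` object.
#' @export
generate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  tr <- ape::rphylo(cfg$n_tips, birth = 1, death = 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(cfg$n_tips))
  validate_phylo(tr)
  tr
}

#' Simulate site-by-species incidence with controlled assembly
#'
#' Per-site richness is drawn uniformly from the configured range; species
#' are then sampled without replacement from the tree's tips:
#' \describe{
#'   \item{neutral}{uniform weights — the same process as the analysis null
#'     model, so standardized effect sizes are centred on 0;}
#'   \item{clustered}{a random focal species is chosen and species i is
#'     weighted `exp(-d(focal, i)/tau)` — assemblages of close relatives
#'     (environmental-filtering caricature), driving NTI positive;}
#'   \item{overdispersed}{sequential nearest-member repulsion: the assemblage
#'     is seeded with a random focal species and grown one species at a time,
#'     each candidate i weighted `1 - exp(-d_nn(i)/tau)` where `d_nn` is its
#'     distance to the nearest already-chosen member (competitive-exclusion
#'     caricature), driving NTI negative. Repulsion must act against the
#'     whole growing set — repulsion from a single focal species leaves the
#'     remaining taxa mutually random and produces no overdispersion signal.}
#' }
#' Weighted sampling without replacement draws sequentially with
#' renormalization (R's `sample(prob = )` semantics); exact draws therefore
#' depend on that convention, which is stated here because it affects
#' bit-level reproducibility across implementations.
#'
#' @param tree A `"phylo"` object (typically from [generate_tree()]).
#' @param cfg A [synth_config()].
#' @return Community incidence matrix with sites `site01`, `site02`, ...
#' @export
generate_communities <- function(tree, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  validate_phylo(tree)
  tips <- tree$tip.label
  n <- length(tips)
  if (cfg$richness_range[2] > n) stop("richness infeasible for this tree", call. = FALSE)
  d <- if (cfg$assembly != "neutral") cophenetic_matrix(tree) else NULL
  set.seed(cfg$seed + 1L)
  m <- matrix(0L, cfg$n_sites, n,
              dimnames = list(sprintf("site%02d", seq_len(cfg$n_sites)), tips))
  # all richness values are drawn up front so that matched configurations
  # (same seed, different assembly mode) share the same richness sequence
  richness <- sample.int(cfg$richness_range[2] - cfg$richness_range[1] + 1L,
                         cfg$n_sites, replace = TRUE) + cfg$richness_range[1] - 1L
  for (i in seq_len(cfg$n_sites)) {
    r <- richness[i]
    chosen <- if (cfg$assembly == "neutral") {
      sample.int(n, r)
    } else if (cfg$assembly == "clustered") {
      focal <- sample.int(n, 1L)
      w <- pmax(exp(-d[focal, ] / cfg$tau), 1e-12)  # keep all species reachable
      sample.int(n, r, prob = w)
    } else {
      # overdispersed: sequential nearest-member repulsion. Weighting against
      # a single focal cannot space the drawn taxa out from EACH OTHER, so the
      # repulsion kernel is applied to the growing assemblage instead: each
      # new member is drawn with weight 1 - exp(-d_nn/tau), d_nn its distance
      # to the nearest already-chosen member.
      focal <- sample.int(n, 1L)
      sel <- focal
      dn <- d[, focal]
      while (length(sel) < r) {
        w <- pmax(1 - exp(-dn / cfg$tau), 1e-12)
        w[sel] <- 0
        nxt <- sample.int(n, 1L, prob = w)
        sel <- c(sel, nxt)
        dn <- pmin(dn, d[, nxt])
      }
      sel
    }
    m[i, chosen] <- 1L
  }
  community_matrix(m)
}

#' Simulate species attributes (life form, dominant/invasive flags)
#'
#' Life forms are i.i.d. draws from the configured mix. Under
#' `flag_mode = "random"` the dominant and invasive flags are independent
#' Bernoulli draws at the configured rates; under `"clade"` each flag marks
#' all tips of the clade whose size is closest to the target count (two
#' different clades for the two flags), emulating phylogenetically clustered
#' dominant/invasive species sets.
#'
#' @param tree A `"phylo"` object.
#' @param cfg A [synth_config()].
#' @return A species-attribute data.frame (see [read_species_attributes()]).
#' @export
generate_attributes <- function(tree, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  validate_phylo(tree)
  tips <- tree$tip.label
  n <- length(tips)
  set.seed(cfg$seed + 2L)
  lf <- sample(lifeform_levels(), n, replace = TRUE, prob = cfg$lifeform_mix)
  if (cfg$flag_mode == "random") {
    dominant <- stats::runif(n) < cfg$dominant_rate
    invasive <- stats::runif(n) < cfg$invasive_rate
  } else {
    dominant <- clade_flag(tree, cfg$dominant_rate)
    invasive <- clade_flag(tree, cfg$invasive_rate, avoid = dominant)
  }
  data.frame(species = tips, life_form = factor(lf, levels = lifeform_levels()),
             dominant = dominant, invasive = invasive, stringsAsFactors = FALSE)
}

# flag the tips of the internal clade whose size is closest to rate * n_tips
# (ties broken toward the first in node order); `avoid` discourages reusing
# the clade already taken by another flag
clade_flag <- function(tree, rate, avoid = NULL) {
  n <- length(tree$tip.label)
  target <- max(2L, round(rate * n))
  if (rate <= 0) return(rep(FALSE, n))
  cache <- pd_cache(tree)  # inc: tips x edges, column e = tips below edge e
  sizes <- colSums(cache$inc)
  score <- abs(sizes - target)
  if (!is.null(avoid)) {
    overlap <- colSums(cache$inc[avoid, , drop = FALSE])
    score <- score + overlap * n  # any overlap dominates the size mismatch
  }
  best <- which.min(score)
  cache$inc[, best] > 0
}

#' Write a complete synthetic fixture to disk
#'
#' Generates tree, communities, attributes and site metadata from one config
#' and writes them in the same formats the pipeline reads: `tree.nwk`,
#' `community.csv`, `attributes.csv`, `sites.csv`. Wetland types are assigned
#' in proportions mirroring a mixed survey (12:7:3:3:3
#' lake/marsh/coastal/river/human-made, rescaled to the configured site
#' count).
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [synth_config()].
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_synth_fixture <- function(dir, cfg = synth_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- generate_tree(cfg)
  comm <- generate_communities(tr, cfg)
  attrs <- generate_attributes(tr, cfg)
  meta <- data.frame(site = rownames(comm),
                     wetland_type = assign_wetland_types(cfg$n_sites),
                     stringsAsFactors = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             community = file.path(dir, "community.csv"),
             attributes = file.path(dir, "attributes.csv"),
             metadata = file.path(dir, "sites.csv"))
  write_newick(tr, paths[["tree"]])
  utils::write.csv(data.frame(site = rownames(comm), comm, check.names = FALSE),
                   paths[["community"]], row.names = FALSE, quote = FALSE, eol = "\n")
  a_out <- attrs
  a_out$dominant <- as.integer(a_out$dominant)
  a_out$invasive <- as.integer(a_out$invasive)
  utils::write.csv(a_out, paths[["attributes"]], row.names = FALSE, quote = FALSE, eol = "\n")
  utils::write.csv(meta, paths[["metadata"]], row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(paths)
}

assign_wetland_types <- function(n_sites) {
  base <- c(lake = 12, marsh = 7, coastal = 3, river = 3, `human-made` = 3)
  counts <- setNames(pmax(1L, round(base / sum(base) * n_sites)), names(base))
  # adjust the largest class so counts sum exactly to n_sites
  counts[1] <- counts[1] + n_sites - sum(counts)
  if (counts[1] < 1) return(rep(names(base), length.out = n_sites))
  rep(names(counts), counts)[seq_len(n_sites)]
}
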