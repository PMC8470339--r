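#' Life-form proportions per site and per wetland type
#'
#' Per-site proportions of annual herbs, perennial herbs, woody species and
#' other life forms among the species present (rows sum to 1). When site
#' metadata are supplied, a per-wetland-type table of min-max ranges across
#' that type's sites is attached as the `"type_ranges"` attribute and in the
#' returned list.
#'
#' @param table Community incidence matrix.
#' @param attrs Species attributes (see [read_species_attributes()]); every
#'   table species must be present.
#' @param meta Optional site metadata (see [read_site_metadata()]).
#' @return A list with `site` (data.frame, one row per site, columns `site`,
#'   `richness`, `annual`, `perennial`, `woody`, `other`) and `type_ranges`
#'   (data.frame or `NULL`).
#' @export
lifeform_proportions <- function(table, attrs, meta = NULL) {
  table <- community_matrix(table)
  missing <- setdiff(colnames(table), attrs$species)
  if (length(missing)) {
    stop("species without attributes: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  lf <- attrs$life_form[match(colnames(table), attrs$species)]
  lv <- lifeform_levels()
  counts <- sapply(lv, function(f) rowSums(table[, lf == f, drop = FALSE]))
  counts <- matrix(counts, nrow = nrow(table), dimnames = list(rownames(table), lv))
  props <- counts / rowSums(table)
  site_df <- data.frame(site = rownames(table), richness = as.integer(rowSums(table)),
                        props, stringsAsFactors = FALSE, row.names = NULL)
  ranges <- NULL
  if (!is.null(meta)) {
    missing_sites <- setdiff(rownames(table), meta$site)
    if (length(missing_sites)) {
      stop("sites without metadata: ", paste(missing_sites, collapse = ", "), call. = FALSE)
    }
    wt <- meta$wetland_type[match(rownames(table), meta$site)]
    ranges <- do.call(rbind, lapply(split(seq_len(nrow(table)), wt), function(ix) {
      if (!length(ix)) return(NULL)
      p <- props[ix, , drop = FALSE]
      data.frame(wetland_type = as.character(wt[ix[1]]), n_sites = length(ix),
                 t(setNames(as.vector(rbind(apply(p, 2, min), apply(p, 2, max))),
                            paste0(rep(lv, each = 2), c("_min", "_max")))),
                 stringsAsFactors = FALSE)
    }))
    rownames(ranges) <- NULL
  }
  structure(list(site = site_df, type_ranges = ranges), type_ranges = ranges)
}

#' NTI of a species group against a pool null
#'
#' Treats a designated species group (e.g. the dominant species, or the alien
#' invasive species, pooled over all sites) as a single assemblage and
#' computes its nearest taxon index against `reps` richness-preserving null
#' draws from the pool — the same machinery as the per-site analysis. A
#' positive value means the group's members are each other's close relatives
#' more than expected (phylogenetic clustering).
#'
#' @param tree A `"phylo"` object.
#' @param group Character vector of group species (>= 2, all in `pool`).
#' @param pool Character vector of pool species (all on the tree).
#' @param reps Null replicates (default 999).
#' @param seed Integer seed (default 1).
#' @return A one-row data.frame: `n_group`, `mntd_obs`, `null_mean`,
#'   `null_sd`, `nti`, `note` (`nti` is `NA` with a reason when the null sd
#'   is 0, e.g. group = pool).
#' @export
group_nti <- function(tree, group, pool, reps = 999, seed = 1) {
  group <- unique(as.character(group))
  pool <- unique(as.character(pool))
  if (length(group) < 2L) stop("group must contain at least 2 species", call. = FALSE)
  if (length(setdiff(group, pool))) {
    stop("group species outside the pool: ",
         paste(setdiff(group, pool), collapse = ", "), call. = FALSE)
  }
  validate_phylo(tree)
  if (length(setdiff(pool, tree$tip.label))) {
    stop("pool species absent from tree: ",
         paste(setdiff(pool, tree$tip.label), collapse = ", "), call. = FALSE)
  }
  d <- cophenetic_matrix(tree)[pool, pool, drop = FALSE]
  obs <- mntd_within(d, group)
  k <- length(group)
  set.seed(as.integer(seed))
  nulls <- vapply(seq_len(reps), function(r) {
    mntd_within(d, pool[sample.int(length(pool), k)])
  }, numeric(1))
  note <- ""
  nti <- tryCatch(ses(obs, nulls, negate = TRUE),
                  commphylo_undefined_ses = function(e) {
                    note <<- "nti: null sd is 0"; NA_real_
                  })
  data.frame(n_group = k, mntd_obs = obs, null_mean = mean(nulls),
             null_sd = stats::sd(nulls), nti = nti, note = note,
             stringsAsFactors = FALSE)
}

#' Phylogenetic separation between a group and its complement
#'
#' Between-group mean nearest-taxon distance ([mntd_between()]) — e.g. how
#' far, on average, each dominant species is from its nearest non-dominant
#' relative and vice versa. Because "large" has no absolute scale, an optional
#' permutation reference shuffles the group labels over `group` and
#' `complement` (keeping group sizes) and reports where the observed value
#' falls in that distribution.
#'
#' @param dist Patristic distance matrix covering both sets.
#' @param group,complement Character vectors of species labels (non-empty).
#' @param perm Number of label permutations for the reference distribution
#'   (0 = none; default 999).
#' @param seed Integer seed for the permutations (default 1).
#' @return A one-row data.frame: `mntd_between_obs`, and when `perm > 0`,
#'   `perm_mean`, `perm_sd`, `perm_quantile` (fraction of permuted values
#'   below the observed, mid-ranked for ties).
#' @export
group_separation <- function(dist, group, complement, perm = 999, seed = 1) {
  group <- unique(as.character(group))
  complement <- unique(as.character(complement))
  obs <- mntd_between(dist, group, complement)
  out <- data.frame(mntd_between_obs = obs, stringsAsFactors = FALSE)
  all_sp <- unique(c(group, complement))
  ng <- length(group)
  if (perm > 0 && length(all_sp) > ng) {
    set.seed(as.integer(seed))
    pv <- vapply(seq_len(perm), function(p) {
      g <- sample(all_sp, ng)
      mntd_between(dist, g, setdiff(all_sp, g))
    }, numeric(1))
    out$perm_mean <- mean(pv)
    out$perm_sd <- stats::sd(pv)
    out$perm_quantile <- (sum(pv < obs) + 0.5 * sum(pv == obs)) / perm
  }
  out
}
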