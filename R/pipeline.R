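#' Pearson correlation with two-tailed p-value
#'
#' Computes r from the covariance formula and the two-tailed p-value from the
#' t-transform `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of
#' freedom. Pairs with a missing value in either vector are dropped and the
#' count reported in the result.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return A list with `r`, `p`, `n` (complete pairs used) and `n_dropped`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  sx <- x - mean(x); sy <- y - mean(y)
  vx <- sum(sx^2); vy <- sum(sy^2)
  if (vx == 0 || vy == 0) {
    stop("correlation undefined: zero variance in ",
         if (vx == 0) "x" else "y", call. = FALSE)
  }
  r <- sum(sx * sy) / sqrt(vx * vy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, n_dropped = n_dropped)
}

study_config_defaults <- function() {
  list(tree = "tree.nwk", community = "community.csv",
       attributes = "attributes.csv", metadata = "sites.csv",
       reps = 999L, seed = 1L, include_root = TRUE,
       pool = "union", align_policy = "strict",
       pcoa_metric = "mntd", pcoa_correction = "none",
       rank_stat = "mean", out = "commphylo_out")
}

#' Read a flat key = value study configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Every key has a
#' default (see the package vignette); unknown keys are errors. Relative file
#' paths are resolved against the config file's directory.
#'
#' @param path Path to the config file.
#' @return A named list of settings.
#' @export
read_study_config <- function(path) {
  cfg <- study_config_defaults()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("config line without '=': ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
    cfg[[key]] <- val
  }
  cfg$reps <- as.integer(cfg$reps)
  cfg$seed <- as.integer(cfg$seed)
  cfg$include_root <- as.logical(toupper(as.character(cfg$include_root)))
  if (is.na(cfg$reps) || is.na(cfg$seed) || is.na(cfg$include_root)) {
    stop("invalid reps/seed/include_root in config", call. = FALSE)
  }
  if (!cfg$pool %in% c("union", "weighted")) stop("pool must be union or weighted", call. = FALSE)
  if (!cfg$rank_stat %in% c("mean", "median")) stop("rank_stat must be mean or median", call. = FALSE)
  base <- dirname(normalizePath(path))
  for (k in c("tree", "community", "attributes", "metadata", "out")) {
    if (!grepl("^(/|[A-Za-z]:)", cfg[[k]])) cfg[[k]] <- file.path(base, cfg[[k]])
  }
  cfg
}

#' Run the full community-phylogenetics study
#'
#' End-to-end reproduction of the analysis pipeline on one set of inputs:
#' ingest and validation, per-site PDI/NTI under the richness-preserving
#' null, per-wetland-type summaries with rank order, Pearson correlations
#' (PDI-NTI, richness-PDI, richness-NTI), NTI sign tally, PCoA of the
#' between-site phylogenetic distance matrix, group statistics for dominant
#' and invasive species, and life-form proportion tables. All outputs are
#' written as CSV plus a run-metadata file recording the seed, replicate
#' count, package version and every setting in effect (no timestamps, so
#' identical config and seed give byte-identical output). Any stage error
#' aborts the run, removes partial outputs, and names the failing stage.
#'
#' @param config Path to a config file (see [read_study_config()]) or a named
#'   list of settings overriding the defaults.
#' @return A list of class `"study_report"` with elements `diversity`,
#'   `type_summary`, `correlations`, `nti_tally`, `pcoa`, `groups`,
#'   `lifeforms`, `settings`, `files`.
#' @export
run_study <- function(config) {
  cfg <- if (is.character(config)) read_study_config(config)
         else utils::modifyList(study_config_defaults(), config)
  out_dir <- cfg$out
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "ingest"
  result <- tryCatch({
    tree <- read_newick(cfg$tree)
    comm <- read_community(cfg$community)
    attrs <- read_species_attributes(cfg$attributes)
    meta <- read_site_metadata(cfg$metadata)
    comm <- align_to_tree(comm, tree, policy = cfg$align_policy)
    miss_meta <- setdiff(rownames(comm), meta$site)
    if (length(miss_meta)) stop("sites without metadata: ", paste(miss_meta, collapse = ", "))

    stage <- "diversity"
    div <- pdi_nti_report(tree, comm, reps = cfg$reps, seed = cfg$seed,
                          include_root = cfg$include_root,
                          weighted = (cfg$pool == "weighted"))
    f <- file.path(out_dir, "diversity.csv")
    write_diversity_report(div, f); written <- c(written, f)

    stage <- "type summary"
    wt <- meta$wetland_type[match(div$site, meta$site)]
    agg <- if (cfg$rank_stat == "median") stats::median else mean
    by_type <- Filter(length, split(seq_len(nrow(div)), wt))
    ts <- do.call(rbind, lapply(by_type, function(ix) {
      data.frame(wetland_type = as.character(wt[ix[1]]), n_sites = length(ix),
                 richness = agg(div$richness[ix]),
                 pdi = agg(div$pdi[ix], na.rm = TRUE),
                 nti = agg(div$nti[ix], na.rm = TRUE), stringsAsFactors = FALSE)
    }))
    ts <- ts[!is.na(ts$wetland_type), , drop = FALSE]
    ts$richness_rank <- rank(ts$richness, ties.method = "min")
    ts$pdi_rank <- rank(ts$pdi, ties.method = "min")
    ts$nti_rank <- rank(ts$nti, ties.method = "min")
    rownames(ts) <- NULL
    f <- file.path(out_dir, "type_summary.csv")
    utils::write.csv(ts, f, row.names = FALSE, quote = FALSE, eol = "\n")
    written <- c(written, f)

    stage <- "correlations"
    pairs <- list(c("pdi", "nti"), c("richness", "pdi"), c("richness", "nti"))
    cors <- do.call(rbind, lapply(pairs, function(p) {
      ct <- pearson_cor(as.numeric(div[[p[1]]]), as.numeric(div[[p[2]]]))
      data.frame(x = p[1], y = p[2], r = ct$r, p_value = ct$p, n = ct$n,
                 n_dropped = ct$n_dropped, stringsAsFactors = FALSE)
    }))
    f <- file.path(out_dir, "correlations.csv")
    utils::write.csv(cors, f, row.names = FALSE, quote = FALSE, eol = "\n")
    written <- c(written, f)
    tally <- c(positive = sum(div$nti > 0, na.rm = TRUE),
               negative = sum(div$nti < 0, na.rm = TRUE),
               zero = sum(div$nti == 0, na.rm = TRUE),
               missing = sum(is.na(div$nti)))

    stage <- "ordination"
    sd_mat <- site_distance_matrix(tree, comm, metric = cfg$pcoa_metric)
    ord <- pcoa_ord(sd_mat, correction = cfg$pcoa_correction)
    co <- data.frame(site = rownames(ord$coordinates),
                     wetland_type = as.character(meta$wetland_type[match(rownames(ord$coordinates), meta$site)]),
                     ord$coordinates, check.names = FALSE, stringsAsFactors = FALSE)
    f <- file.path(out_dir, "pcoa_coordinates.csv")
    utils::write.csv(co, f, row.names = FALSE, quote = FALSE, eol = "\n")
    written <- c(written, f)
    ei <- data.frame(axis = seq_along(ord$eigenvalues), eigenvalue = ord$eigenvalues,
                     variance_explained = c(ord$variance_explained,
                                            rep(NA, length(ord$eigenvalues) - length(ord$variance_explained))))
    f <- file.path(out_dir, "pcoa_eigenvalues.csv")
    utils::write.csv(ei, f, row.names = FALSE, quote = FALSE, eol = "\n")
    written <- c(written, f)

    stage <- "group statistics"
    pool <- colnames(comm)[colSums(comm) > 0L]
    dmat <- cophenetic_matrix(tree)[pool, pool]
    groups <- do.call(rbind, lapply(c("dominant", "invasive"), function(flag) {
      g <- intersect(attrs$species[attrs[[flag]]], pool)
      if (length(g) < 2L) {
        return(data.frame(group = flag, n_group = length(g), mntd_obs = NA,
                          null_mean = NA, null_sd = NA, nti = NA,
                          mntd_between_obs = NA, perm_mean = NA, perm_sd = NA,
                          perm_quantile = NA,
                          note = "fewer than 2 flagged species in pool",
                          stringsAsFactors = FALSE))
      }
      gn <- group_nti(tree, g, pool, reps = cfg$reps, seed = cfg$seed)
      sep <- group_separation(dmat, g, setdiff(pool, g), perm = cfg$reps, seed = cfg$seed)
      cbind(data.frame(group = flag, stringsAsFactors = FALSE),
            gn[, c("n_group", "mntd_obs", "null_mean", "null_sd", "nti")],
            sep, data.frame(note = gn$note, stringsAsFactors = FALSE))
    }))
    f <- file.path(out_dir, "group_statistics.csv")
    utils::write.csv(groups, f, row.names = FALSE, quote = FALSE, eol = "\n")
    written <- c(written, f)

    stage <- "life forms"
    lf <- lifeform_proportions(comm, attrs, meta)
    f <- file.path(out_dir, "lifeform_site.csv")
    utils::write.csv(lf$site, f, row.names = FALSE, quote = FALSE, eol = "\n")
    written <- c(written, f)
    if (!is.null(lf$type_ranges)) {
      f <- file.path(out_dir, "lifeform_type_ranges.csv")
      utils::write.csv(lf$type_ranges, f, row.names = FALSE, quote = FALSE, eol = "\n")
      written <- c(written, f)
    }

    stage <- "metadata"
    f <- file.path(out_dir, "run_metadata.txt")
    meta_lines <- c(
      paste0("commphylo_version = ", as.character(utils::packageVersion("commphylo"))),
      paste0("r_version = ", R.version.string),
      paste0("seed = ", cfg$seed),
      paste0("reps = ", cfg$reps),
      paste0("include_root = ", cfg$include_root),
      paste0("pool = ", cfg$pool),
      paste0("align_policy = ", cfg$align_policy),
      paste0("pcoa_metric = ", cfg$pcoa_metric),
      paste0("pcoa_correction = ", cfg$pcoa_correction),
      paste0("rank_stat = ", cfg$rank_stat),
      paste0("n_sites = ", nrow(comm)),
      paste0("n_species_pool = ", length(pool)),
      paste0("nti_tally = ", paste(names(tally), tally, sep = ":", collapse = " ")))
    writeLines(meta_lines, f); written <- c(written, f)

    structure(list(diversity = div, type_summary = ts, correlations = cors,
                   nti_tally = tally, pcoa = ord, groups = groups,
                   lifeforms = lf, settings = cfg, files = written),
              class = "study_report")
  }, error = function(e) {
    unlink(written)
    if (created) unlink(out_dir, recursive = TRUE)
    stop("study failed at stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
  result
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n")
  cat(sprintf("  sites: %d   null replicates: %d   seed: %s\n",
              nrow(x$diversity), x$settings$reps, format(x$settings$seed)))
  cat(sprintf("  NTI tally: %d positive / %d negative / %d missing\n",
              x$nti_tally[["positive"]], x$nti_tally[["negative"]],
              x$nti_tally[["missing"]]))
  r <- x$correlations
  cat(sprintf("  PDI-NTI: r = %.3f (p = %.3g); richness-PDI: r = %.3f; richness-NTI: r = %.3f\n",
              r$r[1], r$p_value[1], r$r[2], r$r[3]))
  k <- min(5L, length(x$pcoa$variance_explained))
  cat(sprintf("  PCoA (%s): first %d axes explain %.1f%% of variance\n",
              x$settings$pcoa_metric, k,
              100 * sum(x$pcoa$variance_explained[seq_len(k)])))
  cat("  outputs:", length(x$files), "files in", dirname(x$files[1]), "\n")
  invisible(x)
}
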