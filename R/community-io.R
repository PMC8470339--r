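#' Read a site-by-species incidence table
#'
#' The file must have a header row of species labels and a first column of
#' site labels; all cells are 0/1 presence/absence. The delimiter (comma or
#' tab) is auto-detected from the header line. Labels are trimmed of
#' surrounding whitespace and internal spaces in species names are mapped to
#' underscores, matching the usual Newick tip-label convention.
#'
#' @param path Path to a CSV/TSV file (UTF-8).
#' @return An integer matrix (sites x species) of 0/1 entries with site and
#'   species labels as dimnames, validated by [community_matrix()].
#' @export
read_community <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL,
                          colClasses = "character", encoding = "UTF-8",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("community table needs a site column plus >= 1 species column", call. = FALSE)
  sites <- clean_label(df[[1L]])
  species <- clean_species(colnames(df)[-1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-binary cell '%s' at site '%s' (row %d), species '%s' (column %d)",
                 m[bad[1L, 1L], bad[1L, 2L]], sites[bad[1L, 1L]], bad[1L, 1L],
                 species[bad[1L, 2L]], bad[1L, 2L]), call. = FALSE)
  }
  out <- matrix(as.integer(num), nrow(m), ncol(m),
                dimnames = list(sites, species))
  community_matrix(out)
}

#' Validate a community incidence matrix
#'
#' Checks the package's community-table invariants: binary entries, unique
#' non-empty site and species labels, and richness of at least 1 at every
#' site. Species that occur at no site are allowed but flagged with a message
#' (they are excluded from the default null-model pool).
#'
#' @param x A matrix of 0/1 entries with sites as rows and species as columns;
#'   dimnames are required.
#' @return The validated integer matrix.
#' @export
community_matrix <- function(x) {
  if (!is.matrix(x)) stop("community table must be a matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("community matrix requires site rownames and species colnames", call. = FALSE)
  }
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    bad <- which(is.na(x) | !(x %in% c(0L, 1L)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary entry at site '%s', species '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]), call. = FALSE)
  }
  dup_s <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_s)) stop("duplicate site label(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  dup_c <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_c)) stop("duplicate species label(s): ", paste(dup_c, collapse = ", "), call. = FALSE)
  if (any(!nzchar(rownames(x))) || any(!nzchar(colnames(x)))) {
    stop("empty site or species label", call. = FALSE)
  }
  rich <- rowSums(x)
  if (any(rich < 1L)) {
    stop("site(s) with richness 0: ",
         paste(rownames(x)[rich < 1L], collapse = ", "), call. = FALSE)
  }
  empty <- colSums(x) == 0L
  if (any(empty)) {
    message(sum(empty), " species occur at no site and are excluded from the default pool")
  }
  storage.mode(x) <- "integer"
  x
}

#' Read a species-attribute table
#'
#' Expects columns `species`, `life_form`, and optionally `dominant` and
#' `invasive` (0/1 or TRUE/FALSE; absent columns default to all-FALSE).
#' Life forms are normalized to `annual`, `perennial`, `woody`, `other`;
#' biennials are folded into perennials on ingest, following the convention
#' of treating the few biennial wetland plants as perennials.
#'
#' @param path Path to a CSV/TSV file.
#' @return A data.frame with columns `species`, `life_form` (factor with the
#'   four canonical levels), `dominant`, `invasive` (logical).
#' @export
read_species_attributes <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  names(df) <- tolower(trimws(names(df)))
  req <- c("species", "life_form")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("attribute table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  species <- clean_species(df$species)
  if (anyDuplicated(species)) {
    stop("duplicate species in attribute table: ",
         paste(unique(species[duplicated(species)]), collapse = ", "), call. = FALSE)
  }
  lf <- tolower(trimws(df$life_form))
  lf[lf %in% c("biennial", "biennial herb")] <- "perennial"
  lf[lf == "annual herb"] <- "annual"
  lf[lf == "perennial herb"] <- "perennial"
  bad <- setdiff(unique(lf), lifeform_levels())
  if (length(bad)) {
    stop("unknown life form(s): ", paste(bad, collapse = ", "),
         " (expected annual/perennial/woody/other; biennial accepted as perennial)",
         call. = FALSE)
  }
  out <- data.frame(
    species = species,
    life_form = factor(lf, levels = lifeform_levels()),
    dominant = parse_flag(df[["dominant"]], length(species), "dominant"),
    invasive = parse_flag(df[["invasive"]], length(species), "invasive"),
    stringsAsFactors = FALSE
  )
  out
}

#' Read site metadata (wetland types)
#'
#' Expects columns `site` and `wetland_type` with types among lake, marsh,
#' coastal, river, human-made.
#'
#' @param path Path to a CSV/TSV file.
#' @return A data.frame with columns `site` and `wetland_type` (factor).
#' @export
read_site_metadata <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  names(df) <- tolower(trimws(names(df)))
  miss <- setdiff(c("site", "wetland_type"), names(df))
  if (length(miss)) stop("site metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  site <- clean_label(df$site)
  if (anyDuplicated(site)) {
    stop("duplicate site(s) in metadata: ",
         paste(unique(site[duplicated(site)]), collapse = ", "), call. = FALSE)
  }
  wt <- tolower(trimws(df$wetland_type))
  wt[wt %in% c("human_made", "humanmade", "human made")] <- "human-made"
  bad <- setdiff(unique(wt), wetland_type_levels())
  if (length(bad)) {
    stop("unknown wetland type(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(wetland_type_levels(), collapse = "/"), ")", call. = FALSE)
  }
  data.frame(site = site,
             wetland_type = factor(wt, levels = wetland_type_levels()),
             stringsAsFactors = FALSE)
}

#' Align a community table to a phylogeny
#'
#' Under the default `strict` policy any table species absent from the tree is
#' an error (inputs are assumed name-standardized, so missing species signal
#' data problems). Under `drop`, such species are removed and the count is
#' reported via a message.
#'
#' @param table Community incidence matrix (see [community_matrix()]).
#' @param tree A `"phylo"` object.
#' @param policy `"strict"` (default) or `"drop"`.
#' @return The (possibly column-reduced) community matrix.
#' @export
align_to_tree <- function(table, tree, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  table <- community_matrix(table)
  validate_phylo(tree)
  absent <- setdiff(colnames(table), tree$tip.label)
  if (!length(absent)) return(table)
  if (policy == "strict") {
    stop("species absent from tree: ", paste(absent, collapse = ", "),
         " (use policy = \"drop\" to remove them)", call. = FALSE)
  }
  message("dropping ", length(absent), " species absent from the tree")
  community_matrix(table[, setdiff(colnames(table), absent), drop = FALSE])
}

lifeform_levels <- function() c("annual", "perennial", "woody", "other")
wetland_type_levels <- function() c("lake", "marsh", "coastal", "river", "human-made")

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

clean_label <- function(x) trimws(as.character(x))
clean_species <- function(x) gsub(" ", "_", trimws(as.character(x)), fixed = TRUE)

parse_flag <- function(x, n, what) {
  if (is.null(x)) return(rep(FALSE, n))
  if (is.logical(x)) {
    if (anyNA(x)) stop("missing values in '", what, "' flag", call. = FALSE)
    return(x)
  }
  v <- suppressWarnings(as.numeric(as.character(x)))
  if (anyNA(v) || !all(v %in% c(0, 1))) {
    stop("'", what, "' flag must be 0/1 or TRUE/FALSE", call. = FALSE)
  }
  v == 1
}
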