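#' Between-site phylogenetic distance matrix
#'
#' Builds the square sites x sites matrix of between-community MNTD
#' ([mntd_between()], comdistnt-style) or MPD ([mpd_between()],
#' comdist-style). The diagonal is set to 0 by convention for ordination (for
#' MNTD this is exact, since every taxon finds itself at distance 0; for MPD
#' the within-site mean pairwise distance is replaced by 0).
#'
#' @param tree A `"phylo"` object.
#' @param table Community incidence matrix aligned to the tree.
#' @param metric `"mntd"` (default) or `"mpd"`.
#' @return Symmetric numeric matrix with site labels as dimnames.
#' @export
site_distance_matrix <- function(tree, table, metric = c("mntd", "mpd")) {
  metric <- match.arg(metric)
  table <- community_matrix(table)
  validate_phylo(tree)
  absent <- setdiff(colnames(table), tree$tip.label)
  if (length(absent)) {
    stop("table not aligned to tree; missing species: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  d <- cophenetic_matrix(tree)
  n <- nrow(table)
  sp <- lapply(seq_len(n), function(i) colnames(table)[table[i, ] == 1L])
  fun <- if (metric == "mntd") mntd_between else mpd_between
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      out[i, j] <- out[j, i] <- fun(d, sp[[i]], sp[[j]])
    }
  }
  out
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of the squared distance matrix followed by
#' eigendecomposition. Coordinates are returned for axes with positive
#' eigenvalues, scaled by the square root of the eigenvalue; negative
#' eigenvalues (non-Euclidean input) are reported, never silently dropped.
#' With `correction = "none"` the variance explained by each axis uses the
#' sum of positive eigenvalues as the denominator; the Lingoes and Cailliez
#' corrections make the matrix Euclidean before decomposition.
#'
#' Axis signs are fixed by making the largest-magnitude coordinate on each
#' axis positive, so results are reproducible across platforms.
#'
#' @param dist Symmetric numeric matrix with zero diagonal.
#' @param correction `"none"` (default), `"lingoes"` or `"cailliez"`.
#' @return An object of class `"pcoa_result"`: a list with `coordinates`
#'   (points x axes, columns `Axis.1`, ...), `eigenvalues` (all, decreasing),
#'   `variance_explained` (per positive axis), `correction`, and
#'   `correction_constant`.
#' @export
pcoa_ord <- function(dist, correction = c("none", "lingoes", "cailliez")) {
  correction <- match.arg(correction)
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist) || max(abs(dist - t(dist))) > 1e-8) {
    stop("distance matrix must be square and symmetric", call. = FALSE)
  }
  if (max(abs(diag(dist))) > 1e-12) stop("distance matrix must have zero diagonal", call. = FALSE)
  n <- nrow(dist)
  cc <- 0
  if (correction != "none") {
    cc <- correction_constant(dist, correction)
    if (cc > 1e-12) {
      off <- 1 - diag(n)
      dist <- if (correction == "lingoes") sqrt(dist^2 + 2 * cc * off)
              else dist + cc * off
    } else cc <- 0
  }
  g <- gower_center(dist)
  eig <- eigen(g, symmetric = TRUE)
  vals <- eig$values
  # numerically-zero eigenvalues are clamped so a flat configuration reports none
  vals[abs(vals) < max(1, abs(vals[1])) * 1e-12] <- 0
  pos <- which(vals > 0)
  coords <- if (length(pos)) {
    co <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), length(pos))
    co <- fix_axis_signs(co)
    dimnames(co) <- list(rownames(dist), paste0("Axis.", seq_along(pos)))
    co
  } else {
    matrix(numeric(0), n, 0, dimnames = list(rownames(dist), NULL))
  }
  ve <- if (length(pos)) vals[pos] / sum(vals[pos]) else numeric(0)
  structure(list(coordinates = coords, eigenvalues = vals,
                 variance_explained = ve, correction = correction,
                 correction_constant = cc),
            class = "pcoa_result")
}

gower_center <- function(dist) {
  a <- -0.5 * dist^2
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, rm) + gm
}

correction_constant <- function(dist, correction) {
  n <- nrow(dist)
  if (correction == "lingoes") {
    ev <- eigen(gower_center(dist), symmetric = TRUE, only.values = TRUE)$values
    max(0, -min(ev))
  } else {
    # Cailliez: largest eigenvalue of the companion 2n x 2n block matrix
    d1 <- gower_center(dist)
    d2 <- gower_center_raw(-0.5 * dist)  # centered -d/2 matrix
    zero <- matrix(0, n, n)
    big <- rbind(cbind(zero, 2 * d1), cbind(-diag(n), -4 * d2))
    ev <- eigen(big, only.values = TRUE)$values
    max(0, max(Re(ev[abs(Im(ev)) < 1e-8])))
  }
}

gower_center_raw <- function(a) {
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, rm) + gm
}

fix_axis_signs <- function(co) {
  for (j in seq_len(ncol(co))) {
    i <- which.max(abs(co[, j]))
    if (co[i, j] < 0) co[, j] <- -co[, j]
  }
  co
}

#' Cumulative variance explained by the first k PCoA axes
#'
#' @param result A `"pcoa_result"` from [pcoa_ord()].
#' @param k Number of leading axes (1 <= k <= number of positive axes).
#' @return Proportion in `[0, 1]`, non-decreasing in `k`.
#' @export
variance_explained <- function(result, k) {
  stopifnot(inherits(result, "pcoa_result"))
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  ve <- result$variance_explained
  if (k > length(ve)) stop("k exceeds the number of reported axes (", length(ve), ")", call. = FALSE)
  sum(ve[seq_len(k)])
}

#' @export
print.pcoa_result <- function(x, ...) {
  np <- length(x$variance_explained)
  cat(sprintf("PCoA: %d points, %d positive axes (correction: %s)\n",
              nrow(x$coordinates), np, x$correction))
  if (np) {
    k <- min(5L, np)
    cat(sprintf("First %d axes explain %.1f%% of the variance\n",
                k, 100 * sum(x$variance_explained[seq_len(k)])))
  }
  neg <- sum(x$eigenvalues < 0)
  if (neg) cat(neg, "negative eigenvalues (non-Euclidean input)\n")
  invisible(x)
}

#' Scatter plot of the first two PCoA axes
#'
#' @param x A `"pcoa_result"`.
#' @param groups Optional factor (e.g. wetland type) used for point colour.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pcoa_result <- function(x, groups = NULL, ...) {
  if (ncol(x$coordinates) < 2L) stop("fewer than 2 positive axes to plot", call. = FALSE)
  co <- x$coordinates[, 1:2]
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  ve <- 100 * x$variance_explained[1:2]
  graphics::plot(co, col = col, pch = 19,
                 xlab = sprintf("Axis 1 (%.1f%%)", ve[1]),
                 ylab = sprintf("Axis 2 (%.1f%%)", ve[2]), ...)
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 19, cex = 0.8)
  }
  invisible(x)
}
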