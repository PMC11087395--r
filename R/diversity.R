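# Parent-level genetic relationship summaries: mismatch distance, UPGMA
# clustering with Newick output, and principal-component coordinates.

#' Pairwise genotype mismatch distance
#'
#' `d(i, j)` is the proportion of mismatching genotype calls over the sites
#' where both samples are called. Pairs sharing no called site get `NA`.
#'
#' @param table A variant table.
#' @return A symmetric matrix with zero diagonal, entries in \[0, 1\].
#' @export
genotype_distance <- function(table) {
  validate_variant_table(table)
  samples <- variant_samples(table)
  if (length(samples) < 2) {
    stop_kaspanel("need at least 2 samples", "kaspanel_validation_error")
  }
  gt <- as.matrix(table[samples])
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ok <- !is.na(gt[, i]) & !is.na(gt[, j])
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(gt[ok, i] != gt[ok, j]) else NA_real_
    }
  }
  d
}

#' UPGMA clustering
#'
#' Agglomerates the distance matrix with arithmetic-mean (average) linkage:
#' at each step the pair at minimal distance is merged at a node of height
#' half that distance, and distances to the merged cluster are the
#' size-weighted means of the members' distances. Ties are broken by
#' lexicographic label order, making the tree deterministic. The result is
#' rooted and ultrametric; branch lengths carry height units (distance/2
#' per merge).
#'
#' @param d A symmetric distance matrix with labelled rows/columns (or a
#'   `dist`).
#' @return An [ape::as.phylo] tree; write Newick with [ape::write.tree()].
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  labs <- rownames(d)
  if (is.null(labs) || any(d < 0, na.rm = TRUE) ||
      !isTRUE(all.equal(d, t(d)))) {
    stop_kaspanel("need a labelled symmetric non-negative matrix",
                  "kaspanel_validation_error")
  }
  ord <- order(labs)
  d <- d[ord, ord, drop = FALSE]
  labs <- labs[ord]
  n <- length(labs)
  if (n < 2) stop_kaspanel("need >= 2 taxa", "kaspanel_validation_error")

  # active clusters: list of (members, height, newick)
  cl <- purrr::map(seq_len(n), function(i)
    list(members = i, size = 1L, height = 0, label = labs[i]))
  dm <- d
  rownames(dm) <- colnames(dm) <- purrr::map_chr(cl, "label")
  while (length(cl) > 1) {
    m <- length(cl)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        dij <- dm[i, j]
        if (dij < bestd - 1e-15) { bestd <- dij; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    h <- bestd / 2
    bi <- h - cl[[i]]$height
    bj <- h - cl[[j]]$height
    lab <- sprintf("(%s:%.15g,%s:%.15g)", cl[[i]]$label, bi,
                   cl[[j]]$label, bj)
    new <- list(members = c(cl[[i]]$members, cl[[j]]$members),
                size = cl[[i]]$size + cl[[j]]$size, height = h, label = lab)
    keep <- setdiff(seq_len(m), c(i, j))
    newd <- vapply(keep, function(k) {
      (cl[[i]]$size * dm[i, k] + cl[[j]]$size * dm[j, k]) /
        (cl[[i]]$size + cl[[j]]$size)
    }, numeric(1))
    dm <- dm[keep, keep, drop = FALSE]
    dm <- rbind(cbind(dm, newd), c(newd, 0))
    cl <- c(cl[keep], list(new))
    rownames(dm) <- colnames(dm) <- purrr::map_chr(cl, "label")
  }
  ape::read.tree(text = paste0(cl[[1]]$label, ";"))
}

#' Write a tree as Newick text
#'
#' @param tree An `ape` phylo object.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Principal-component coordinates of genotype profiles
#'
#' Codes genotypes additively (0/1/2, missing imputed to the site mean),
#' drops zero-variance sites, column-centres, and eigendecomposes the
#' sample covariance (via `prcomp`).
#'
#' @param table A variant table.
#' @param n_components Number of leading components to return.
#' @return A list with `scores` (tibble: `sample_id` + `PC1`, `PC2`, ...)
#'   and `explained_variance` (fractions).
#' @export
pca_coordinates <- function(table, n_components = 2L) {
  validate_variant_table(table)
  samples <- variant_samples(table)
  gt <- as.matrix(table[samples])
  x <- matrix(c(0, 1, 2)[match(gt, c("0/0", "0/1", "1/1"))],
              nrow = nrow(gt))
  # samples in rows
  x <- t(x)
  for (j in seq_len(ncol(x))) {
    m <- mean(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- m
  }
  keep <- apply(x, 2, var) > 0
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) {
    stop_kaspanel("no variable sites for PCA", "kaspanel_validation_error")
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  scores <- as_tibble(p$x[, seq_len(k), drop = FALSE])
  scores <- bind_cols(tibble(sample_id = samples), scores)
  list(scores = scores,
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)])
}
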