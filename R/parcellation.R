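# Hierarchical synthetic parcellations.
#
# A parcellation here is a partition of n_fine "finest units" (stand-ins for
# voxels) into regions, with 3D centroids in mm. Several granularities cut
# from one clustering tree give nested levels, emulating how finer atlas
# granularity yields smaller brain regions.

new_parcellation <- function(level_id, region_sizes, centroids, parent_map) {
  structure(
    list(
      level_id = level_id,
      n_regions = length(region_sizes),
      region_sizes = as.integer(region_sizes),
      centroids = centroids,
      parent_map = as.integer(parent_map)
    ),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "<parcellation '%s': %d regions over %d fine units, sizes %d-%d>\n",
    x$level_id, x$n_regions, length(x$parent_map),
    min(x$region_sizes), max(x$region_sizes)
  ))
  invisible(x)
}

#' Build a nested hierarchy of synthetic parcellations
#'
#' Draws `n_fine` fine-unit centroids uniformly in a brain-sized
#' 140 x 180 x 120 mm box, clusters them with Ward linkage, and cuts the
#' tree at each requested granularity. Because all levels are cuts of one
#' tree, coarser regions are exact unions of finer regions (nesting holds
#' by construction). Region centroids are size-weighted means of member
#' fine-unit centroids; at the finest possible level every region has
#' size 1.
#'
#' @param n_fine Number of finest-level units.
#' @param granularities Integer vector of region counts, one per level;
#'   each must lie in `[1, n_fine]`. Levels are returned sorted from fine
#'   to coarse.
#' @param seed Integer seed controlling the centroid draw.
#' @return A list of `parcellation` objects, finest first.
#' @export
#' @examples
#' hier <- make_parcellation_hierarchy(60, c(20, 10), seed = 1)
#' hier[[1]]
make_parcellation_hierarchy <- function(n_fine, granularities, seed = 1L) {
  if (n_fine < 1) stop("`n_fine` must be at least 1", call. = FALSE)
  granularities <- as.integer(granularities)
  if (any(granularities < 1L | granularities > n_fine)) {
    stop("every granularity must lie in [1, n_fine]", call. = FALSE)
  }
  granularities <- sort(unique(granularities), decreasing = TRUE)

  box <- c(140, 180, 120)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fine_xyz <- cbind(
    runif(n_fine, 0, box[1]),
    runif(n_fine, 0, box[2]),
    runif(n_fine, 0, box[3])
  )
  colnames(fine_xyz) <- c("x", "y", "z")

  tree <- if (n_fine > 1) stats::hclust(stats::dist(fine_xyz), method = "ward.D2")

  lapply(granularities, function(g) {
    raw <- if (g == n_fine || n_fine == 1) {
      seq_len(n_fine)
    } else if (g == 1L) {
      rep(1L, n_fine)
    } else {
      stats::cutree(tree, k = g)
    }
    # relabel by first appearance for a stable, order-independent labelling
    labels <- match(raw, unique(raw))
    sizes <- tabulate(labels, nbins = g)
    cents <- t(vapply(
      seq_len(g),
      function(r) colMeans(fine_xyz[labels == r, , drop = FALSE]),
      numeric(3)
    ))
    colnames(cents) <- c("x", "y", "z")
    new_parcellation(
      level_id = sprintf("g%d", g),
      region_sizes = sizes,
      centroids = cents,
      parent_map = labels
    )
  })
}

# map each region of `fine` to its containing region of `coarse`
# (both must come from the same hierarchy)
region_membership <- function(fine, coarse) {
  # representative fine unit of each fine region
  rep_unit <- match(seq_len(fine$n_regions), fine$parent_map)
  member <- coarse$parent_map[rep_unit]
  # verify nesting: all units of a fine region share one coarse region
  for (r in seq_len(fine$n_regions)) {
    units <- which(fine$parent_map == r)
    if (length(unique(coarse$parent_map[units])) != 1L) {
      stop("target parcellation is not a nested ancestor of the source level",
        call. = FALSE
      )
    }
  }
  member
}

# save/restore .Random.seed so generators don't disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
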