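#' Generate per-window gene trees with a controlled topology mix
#'
#' Emulates the per-window gene trees a sliding-window phylogenetic
#' analysis would produce over a genomic region: each window's tree is
#' generated under one of the supplied taxon-level topologies (chosen
#' with the stated probabilities), with every group's tips attached as
#' a clade of random internal topology. A `scatter` parameter then
#' detaches each tip with that probability and regrafts it on a random
#' edge, degrading group monophyly the way incomplete lineage sorting
#' does.
#'
#' Tips are labelled `group_index` (e.g. `hapA_2`) so that
#' [groups_from_labels()] recovers the grouping. All edges have length
#' 1; topology-weighting ignores branch lengths.
#'
#' @param n_windows Number of trees to generate.
#' @param group_sizes Named integer vector: tips per group (at least
#'   one tip per group, at least 2 groups).
#' @param topology_mix Named numeric vector: names are newick strings
#'   over the group names (e.g. `"((hapA,hapB),out);"`), values are
#'   window proportions (normalised to sum to 1).
#' @param scatter Per-tip regrafting probability in `[0, 1]`
#'   (default 0).
#' @param seed Optional seed.
#' @return An `ape::multiPhylo` list of `n_windows` trees; the
#'   generating topology of each window is stored in the
#'   `"true_topology"` attribute.
#' @export
generate_window_trees <- function(n_windows, group_sizes, topology_mix,
                                  scatter = 0, seed = NULL) {
  stopifnot(n_windows >= 1, length(group_sizes) >= 2,
            all(group_sizes >= 1), !is.null(names(group_sizes)),
            length(topology_mix) >= 1, !is.null(names(topology_mix)),
            scatter >= 0, scatter <= 1)
  if (!is.null(seed)) set.seed(seed)
  probs <- topology_mix / sum(topology_mix)
  backbones <- lapply(names(probs), function(nw) {
    tr <- ape::read.tree(text = nw)
    if (!setequal(tr$tip.label, names(group_sizes)))
      stop("topology tips must match the group names: ", nw)
    tr$edge.length <- rep(1, nrow(tr$edge))
    tr
  })
  assign <- sample.int(length(probs), n_windows, replace = TRUE,
                       prob = probs)
  trees <- lapply(assign, function(i)
    build_window_tree(backbones[[i]], group_sizes, scatter))
  class(trees) <- "multiPhylo"
  attr(trees, "true_topology") <- names(probs)[assign]
  trees
}

build_window_tree <- function(backbone, group_sizes, scatter) {
  tree <- backbone
  for (g in names(group_sizes)) {
    k <- group_sizes[[g]]
    labs <- paste0(g, "_", seq_len(k))
    if (k == 1) {
      tree$tip.label[tree$tip.label == g] <- labs
    } else {
      clade <- ape::rtree(k, tip.label = sample(labs))
      clade$edge.length <- rep(1, nrow(clade$edge))
      clade$root.edge <- 1
      tree <- ape::bind.tree(tree, clade,
                             where = which(tree$tip.label == g))
    }
  }
  if (scatter > 0) {
    for (tip in tree$tip.label) {
      if (stats::runif(1) < scatter && length(tree$tip.label) > 3) {
        pruned <- ape::drop.tip(tree, tip)
        e <- sample.int(nrow(pruned$edge), 1)
        tree <- phytools::bind.tip(pruned, tip, edge.length = 1,
                                   where = pruned$edge[e, 2],
                                   position = stats::runif(1) *
                                     pruned$edge.length[e])
      }
    }
  }
  tree
}

#' Write window trees to a newick file
#'
#' One newick string per line, one line per window.
#'
#' @param trees `multiPhylo` from [generate_window_trees()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_trees <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}
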