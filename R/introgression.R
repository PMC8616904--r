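#' ABBA-BABA D statistic from allele frequencies
#'
#' Frequency-based (population) D for the four-taxon tree
#' (((P1,P2),P3),P4):
#' `D = sum(abba - baba) / sum(abba + baba)` with per-site
#' `abba = (1-p1) p2 p3 (1-p4) + p1 (1-p2) (1-p3) p4` and
#' `baba = p1 (1-p2) p3 (1-p4) + (1-p1) p2 (1-p3) p4`,
#' where `p_i` is the alt-allele frequency in population i. Both
#' allele polarisations are counted, so D does not depend on which
#' allele is labelled alt (when the outgroup P4 is fixed ancestral the
#' second terms vanish and this is the familiar polarised form).
#' Positive D indicates excess allele sharing between P2 and P3.
#'
#' @param p1,p2,p3,p4 Equal-length allele-frequency vectors; sites with
#'   any `NA` are dropped.
#' @return List with `D`, `n_sites`, and the per-site `numerator` /
#'   `denominator` vectors (inputs to [block_jackknife()]).
#' @export
d_statistic <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(p4))
  ok <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(p4))
  if (!any(ok)) stop("no site with all four frequencies defined")
  p1 <- p1[ok]; p2 <- p2[ok]; p3 <- p3[ok]; p4 <- p4[ok]
  abba <- (1 - p1) * p2 * p3 * (1 - p4) + p1 * (1 - p2) * (1 - p3) * p4
  baba <- p1 * (1 - p2) * p3 * (1 - p4) + (1 - p1) * p2 * (1 - p3) * p4
  num <- abba - baba
  den <- abba + baba
  if (sum(den) == 0) stop("D undefined: no ABBA or BABA signal at any site")
  list(D = sum(num) / sum(den), n_sites = length(num),
       numerator = num, denominator = den)
}

#' Block-jackknife significance for the D statistic
#'
#' Delete-one-block jackknife over contiguous site blocks, robust to
#' local linkage. Blocks may be unequal (the last block is short); the
#' weighted-jackknife variance of Busing et al. (1999) is used, as is
#' standard for genome-scale D tests. `Z = D / SE` and
#' `p = 2 * pnorm(-|Z|)`.
#'
#' @param numerator,denominator Per-site ABBA-BABA terms from
#'   [d_statistic()] in genomic order.
#' @param block_size Sites per block (default 100).
#' @return List with `D`, `se`, `z`, `p`, `n_blocks`, `block_d`
#'   (delete-one-block estimates).
#' @export
block_jackknife <- function(numerator, denominator, block_size = 100) {
  n <- length(numerator)
  stopifnot(n == length(denominator), block_size >= 1)
  block <- (seq_len(n) - 1) %/% block_size + 1
  g <- max(block)
  if (g < 10)
    stop("fewer than 10 blocks; use a smaller block_size")
  sn <- sum(numerator); sd_ <- sum(denominator)
  d_hat <- sn / sd_
  bn <- tapply(numerator, block, sum)
  bd <- tapply(denominator, block, sum)
  m <- tabulate(block)
  block_d <- (sn - bn) / (sd_ - bd)
  h <- n / m
  # Busing et al. (1999) delete-m_j jackknife for unequal blocks
  theta_j <- g * d_hat - sum((1 - m / n) * block_d)
  tau <- h * d_hat - (h - 1) * block_d
  var_j <- sum((tau - theta_j)^2 / (h - 1)) / g
  se <- sqrt(var_j)
  if (se <= 1e-12 * (abs(d_hat) + 1)) {
    warning("jackknife SE is zero (identical blocks); p set to floor")
    return(list(D = d_hat, se = 0, z = Inf * sign(d_hat),
                p = .Machine$double.xmin, n_blocks = g,
                block_d = as.numeric(block_d)))
  }
  z <- d_hat / se
  list(D = d_hat, se = se, z = z, p = max(2 * stats::pnorm(-abs(z)),
                                          .Machine$double.xmin),
       n_blocks = g, block_d = as.numeric(block_d))
}

#' D statistic with block-jackknife test
#'
#' Convenience wrapper: [d_statistic()] followed by
#' [block_jackknife()].
#'
#' @inheritParams d_statistic
#' @inheritParams block_jackknife
#' @return List combining both outputs.
#' @export
d_test <- function(p1, p2, p3, p4, block_size = 100) {
  ds <- d_statistic(p1, p2, p3, p4)
  jk <- block_jackknife(ds$numerator, ds$denominator, block_size)
  c(list(n_sites = ds$n_sites), jk)
}

## ---- taxon-level topology machinery -------------------------------------

# Nested rooted-binary topology enumeration. A rooted topology is a
# character leaf or a list(left, right). Unrooted topologies on g labels
# correspond to rooted topologies on g - 1 labels with the remaining
# label (the "handle") attached at the root.
rooted_topologies <- function(labels) {
  if (length(labels) == 1) return(list(labels[[1]]))
  sub <- rooted_topologies(labels[-length(labels)])
  leaf <- labels[[length(labels)]]
  unlist(lapply(sub, insert_leaf_everywhere, leaf = leaf),
         recursive = FALSE)
}

insert_leaf_everywhere <- function(tree, leaf) {
  out <- list(list(tree, leaf))           # above the current (sub)root
  if (is.list(tree)) {
    for (l in insert_leaf_everywhere(tree[[1]], leaf))
      out <- c(out, list(list(l, tree[[2]])))
    for (r in insert_leaf_everywhere(tree[[2]], leaf))
      out <- c(out, list(list(tree[[1]], r)))
  }
  out
}

nested_leaves <- function(tree) {
  if (!is.list(tree)) return(tree)
  c(nested_leaves(tree[[1]]), nested_leaves(tree[[2]]))
}

# All internal clades (leaf sets) of a nested rooted topology
nested_clades <- function(tree) {
  if (!is.list(tree)) return(list())
  c(list(sort(nested_leaves(tree))),
    nested_clades(tree[[1]]), nested_clades(tree[[2]]))
}

nested_newick <- function(tree) {
  if (!is.list(tree)) return(tree)
  parts <- sort(c(nested_newick(tree[[1]]), nested_newick(tree[[2]])))
  paste0("(", paste(parts, collapse = ","), ")")
}

# Canonical key of an unrooted topology = sorted non-trivial splits,
# each written as the sorted side not containing the reference label.
splits_key <- function(sides) paste(sort(unique(sides)), collapse = ";")

#' Enumerate unrooted taxon-level topologies
#'
#' All distinct unrooted binary tree topologies with one leaf per
#' group. The count is the double factorial `(2g - 5)!!`.
#'
#' @param group_names Character vector of 3 to 7 group names.
#' @return Data frame with columns `newick` (canonical newick, no
#'   branch lengths) and `key` (canonical split-set key); attribute
#'   `"groups"` holds the sorted group names.
#' @export
enumerate_topologies <- function(group_names) {
  g <- length(unique(group_names))
  if (g < 3 || g > 7) stop("between 3 and 7 groups are supported")
  groups <- sort(unique(group_names))
  handle <- groups[1]
  rts <- rooted_topologies(as.list(groups[-1]))
  newicks <- vapply(rts, function(t) {
    parts <- sort(c(handle, nested_newick(t[[1]]), nested_newick(t[[2]])))
    paste0("(", paste(parts, collapse = ","), ");")
  }, character(1))
  keys <- vapply(rts, function(t) {
    cl <- nested_clades(t)
    cl <- Filter(function(s) length(s) >= 2 && length(s) <= g - 2, cl)
    splits_key(vapply(cl, paste, character(1), collapse = ","))
  }, character(1))
  keep <- !duplicated(newicks)
  out <- data.frame(newick = newicks[keep], key = keys[keep],
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- groups
  out
}

#' Does a topology contain a given sister (cherry) pair?
#'
#' @param catalog Output of [enumerate_topologies()].
#' @param pair Character vector of two group names.
#' @return Logical vector over the catalog rows.
#' @export
has_sister_pair <- function(catalog, pair) {
  groups <- attr(catalog, "groups")
  stopifnot(length(pair) == 2, all(pair %in% groups))
  pair_s <- paste(sort(pair), collapse = ",")
  comp_s <- paste(sort(setdiff(groups, pair)), collapse = ",")
  vapply(catalog$key, function(k) {
    sides <- strsplit(k, ";", fixed = TRUE)[[1]]
    any(sides == pair_s) || any(sides == comp_s)
  }, logical(1), USE.NAMES = FALSE)
}

#' Topology weights of a gene tree
#'
#' The weight of a taxon-level topology T is the fraction of
#' one-tip-per-group subsamples of the tree whose induced unrooted
#' topology equals T (the Twisst quantity). `mode = "exact"` enumerates
#' all `prod(group sizes)` combinations; `"montecarlo"` samples
#' `n_subsamples` of them; `"auto"` picks exact when the product is at
#' most 10000.
#'
#' @param tree An `ape::phylo` gene tree (binary; branch lengths
#'   ignored).
#' @param tip_to_group Named character vector mapping tip label to
#'   group. If `NULL`, groups are parsed from labels of the form
#'   `group_index`.
#' @param mode One of "auto", "exact", "montecarlo".
#' @param n_subsamples Monte-Carlo subsample count.
#' @param seed Optional seed for Monte-Carlo mode.
#' @param catalog Optional precomputed [enumerate_topologies()] output.
#' @return Named numeric weight vector (names = canonical newick);
#'   sums to 1. Attributes: `"catalog"`, `"mode"`, `"n_subsamples"`.
#' @export
topology_weights <- function(tree, tip_to_group = NULL,
                             mode = c("auto", "exact", "montecarlo"),
                             n_subsamples = 10000, seed = NULL,
                             catalog = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tip_to_group)) tip_to_group <- groups_from_labels(tree)
  tg <- tip_to_group[tree$tip.label]
  if (anyNA(tg)) stop("tip(s) missing from tip_to_group mapping")
  groups <- sort(unique(unname(tg)))
  g <- length(groups)
  if (is.null(catalog)) catalog <- enumerate_topologies(groups)
  tips_by_group <- lapply(groups, function(x) which(tg == x))
  sizes <- lengths(tips_by_group)
  if (any(sizes == 0))
    stop("group with zero tips: ", groups[which(sizes == 0)[1]])
  total <- prod(sizes)
  exact <- switch(mode, exact = TRUE, montecarlo = FALSE,
                  auto = total <= 10000)

  # clade membership matrix over tips (one row per internal node)
  pp <- ape::prop.part(tree)
  ntip <- length(tree$tip.label)
  M <- do.call(rbind, lapply(pp, function(cl) {
    v <- logical(ntip); v[cl] <- TRUE; v
  }))
  M <- M[rowSums(M) < ntip, , drop = FALSE]  # drop trivial all-tips clade

  if (exact) {
    combos <- as.matrix(expand.grid(tips_by_group))
  } else {
    if (!is.null(seed)) set.seed(seed)
    combos <- vapply(tips_by_group, function(tp)
      tp[sample.int(length(tp), n_subsamples, replace = TRUE)],
      integer(n_subsamples))
  }
  ref <- groups[1]
  keys <- apply(combos, 1, function(idx) {
    S <- M[, idx, drop = FALSE]
    cnt <- rowSums(S)
    rows <- which(cnt >= 2 & cnt <= g - 2)
    sides <- vapply(rows, function(r) {
      side <- groups[S[r, ]]
      if (ref %in% side) side <- setdiff(groups, side)
      paste(sort(side), collapse = ",")
    }, character(1))
    splits_key(sides)
  })
  tab <- table(factor(keys, levels = catalog$key))
  if (sum(tab) != length(keys))
    stop("subsample induced a topology outside the catalog; ",
         "is the tree binary?")
  w <- as.numeric(tab) / length(keys)
  names(w) <- catalog$newick
  attr(w, "catalog") <- catalog
  attr(w, "mode") <- if (exact) "exact" else "montecarlo"
  attr(w, "n_subsamples") <- length(keys)
  w
}

#' Parse group names from `group_index` tip labels
#'
#' @param tree An `ape::phylo` object.
#' @return Named character vector mapping tip label to group.
#' @export
groups_from_labels <- function(tree) {
  labs <- tree$tip.label
  stats::setNames(sub("_[^_]+$", "", labs), labs)
}

#' Average topology weights and aggregate a sister relationship
#'
#' Computes the per-topology mean weight across windows and sums the
#' means over the topologies in which `sister_pair` forms a cherry —
#' the aggregate used to ask whether two haplotype groups are sister.
#'
#' @param weight_tables List of [topology_weights()] vectors (one per
#'   window) on a common catalog, or a matrix windows x topologies.
#' @param sister_pair Character vector of the two group names.
#' @return List with `mean_weights` (named), `sister_topologies`
#'   (newick strings), and `aggregate` (summed mean weight).
#' @export
summarize_weights <- function(weight_tables, sister_pair) {
  if (is.list(weight_tables)) {
    stopifnot(length(weight_tables) >= 1)
    catalog <- attr(weight_tables[[1]], "catalog")
    W <- do.call(rbind, weight_tables)
  } else {
    W <- weight_tables
    catalog <- attr(weight_tables, "catalog")
  }
  if (is.null(catalog))
    stop("weight tables carry no topology catalog")
  mw <- colMeans(W)
  sel <- has_sister_pair(catalog, sister_pair)
  if (!any(sel)) stop("sister pair not found in any catalog topology")
  list(mean_weights = mw, sister_topologies = catalog$newick[sel],
       aggregate = sum(mw[sel]))
}
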