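#' Read and write phylogenetic trees as newick
#'
#' Thin wrappers around ape's newick parser adding the invariants this
#' package relies on: unique leaf names and non-negative branch lengths.
#' Unrooted trees are midpoint-rooted with a message.
#'
#' @param text Newick string or path to a newick file (for `read_newick`).
#' @param tree An ape `phylo` object (for `write_newick`).
#' @param path Optional output file; if `NULL`, the newick string is
#'   returned.
#' @return `read_newick()` returns an ape `phylo`; `write_newick()` a
#'   newick string (invisibly, if written to a file).
#' @export
read_newick <- function(text) {
  tree <- tryCatch(suppressWarnings({
    if (length(text) == 1L && !grepl("(", text, fixed = TRUE) &&
        file.exists(text))
      ape::read.tree(file = text)
    else ape::read.tree(text = text)
  }), error = function(e) NULL)
  if (is.null(tree))
    stop_parse("malformed newick: could not be parsed")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  if (!ape::is.rooted(tree)) {
    message("tree is unrooted; midpoint-rooting")
    tree <- phangorn_midpoint(tree)
  }
  tree
}

# midpoint rooting without importing phangorn wholesale
phangorn_midpoint <- function(tree) {
  if (requireNamespace("phangorn", quietly = TRUE))
    return(phangorn::midpoint(tree))
  # fallback: root on the longest tip-to-tip path's midpoint edge endpoint
  d <- ape::cophenetic.phylo(tree)
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  ape::root(tree, outgroup = rownames(d)[ij[1]], resolve.root = TRUE)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' Species name to newick leaf name
#'
#' Newick leaf labels cannot contain spaces; species names are mapped to
#' leaf names by replacing spaces with underscores.
#'
#' @param species Character vector of species names.
#' @return Character vector of leaf names.
#' @export
leaf_name <- function(species) gsub(" ", "_", species)

#' Leaf set of trait-positive species on a tree
#'
#' Positive species not present as tree leaves are dropped with a warning
#' (trees rarely cover a whole corpus). Species in the training split are
#' excluded: trait trees display what the classifier predicted for species
#' it was not trained on, so training species are never highlighted even if
#' they have the trait.
#'
#' @param positive Character vector of trait-positive species names (from
#'   labels or predictions).
#' @param tree An ape `phylo`.
#' @param exclude Species names to exclude (the training split).
#' @return Character vector of leaf names.
#' @export
trait_leaf_set <- function(positive, tree, exclude = character()) {
  stopifnot(inherits(tree, "phylo"))
  positive <- unique(as.character(positive))
  absent <- setdiff(positive, tree$tip.label)
  if (length(absent))
    warning(length(absent), " positive species not in tree; dropped",
            call. = FALSE)
  setdiff(intersect(positive, tree$tip.label), exclude)
}

#' Unweighted UniFrac distance between two leaf sets
#'
#' Treats each leaf set as a presence/absence sample on the shared tree.
#' Every branch is classified by the leaves descending from it: *shared* if
#' they include members of both sets, *unique* if members of exactly one,
#' unused otherwise. The distance is the total unique branch length divided
#' by the total branch length shared or unique — 0 when both sets span the
#' same branches, 1 when they descend through disjoint parts of the tree.
#'
#' @param tree An ape `phylo` with branch lengths.
#' @param set_a,set_b Non-empty character vectors of leaf names.
#' @return A distance in \[0,1\].
#' @export
unifrac <- function(tree, set_a, set_b) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("both leaf sets must be non-empty", call. = FALSE)
  bad <- setdiff(c(set_a, set_b), tree$tip.label)
  if (length(bad))
    stop("not tree leaves: ", paste(bad, collapse = ", "), call. = FALSE)

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  in_a <- in_b <- logical(n_node)
  in_a[match(set_a, tree$tip.label)] <- TRUE
  in_b[match(set_b, tree$tip.label)] <- TRUE

  tree_po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tree_po$edge))) {   # children precede parents
    p <- tree_po$edge[e, 1]; ch <- tree_po$edge[e, 2]
    in_a[p] <- in_a[p] || in_a[ch]
    in_b[p] <- in_b[p] || in_b[ch]
  }

  child <- tree_po$edge[, 2]
  len <- tree_po$edge.length
  shared <- in_a[child] & in_b[child]
  uniq <- xor(in_a[child], in_b[child])
  denom <- sum(len[shared | uniq])
  if (denom == 0) return(0)
  sum(len[uniq]) / denom
}

#' Random-subset null distribution for a trait tree
#'
#' Draws uniform random leaf subsets of the same size as the predicted
#' trait set (so random and predicted trait trees span the same number of
#' leaves) and computes the UniFrac distance of each draw to the observed
#' set. Training-split leaves are ineligible, matching the exclusion
#' applied to the predicted set.
#'
#' @param tree An ape `phylo`.
#' @param observed Character vector: observed trait-positive leaves.
#' @param k Subset size (the predicted set's size).
#' @param n_draws Number of null draws.
#' @param seed Integer seed.
#' @param exclude Leaves ineligible for drawing (the training split).
#' @return Numeric vector of `n_draws` UniFrac distances.
#' @export
random_null <- function(tree, observed, k, n_draws = 100L, seed = 1L,
                        exclude = character()) {
  eligible <- setdiff(tree$tip.label, exclude)
  if (k > length(eligible))
    stop("`k` exceeds the number of eligible leaves", call. = FALSE)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  vapply(seq_len(n_draws), function(i) {
    unifrac(tree, sample(eligible, k), observed)
  }, numeric(1))
}

#' Compare replicate predicted-tree distances against the null
#'
#' Welch's two-sample t-test between the replicate-level
#' predicted-vs-observed distances and random-vs-observed distances. When
#' both groups are constant, the p-value is 1 if their means agree and 0
#' otherwise.
#'
#' @param predicted_d Numeric vector (>= 2) of predicted-tree distances,
#'   one per replicate training.
#' @param null_d Numeric vector (>= 2) of random-tree distances.
#' @return List with `statistic`, `p_value`, `mean_predicted`, `mean_null`.
#' @export
compare_replicates <- function(predicted_d, null_d) {
  stopifnot(length(predicted_d) >= 2L, length(null_d) >= 2L)
  if (stats::sd(predicted_d) == 0 && stats::sd(null_d) == 0) {
    same <- isTRUE(all.equal(mean(predicted_d), mean(null_d)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                mean_predicted = mean(predicted_d),
                mean_null = mean(null_d)))
  }
  tt <- stats::t.test(predicted_d, null_d)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_predicted = mean(predicted_d), mean_null = mean(null_d))
}

#' Full predicted-vs-observed trait-tree comparison
#'
#' Maps predicted and observed positive species to the tree (minus the
#' training split), computes their UniFrac distance, and situates it in the
#' random-subset null.
#'
#' @param tree An ape `phylo`.
#' @param predicted_positive,observed_positive Character vectors of species
#'   names.
#' @param exclude Training-split species names.
#' @param n_draws Null draws.
#' @param seed Integer seed for the null.
#' @return List of class `trait_tree_comparison`: `unifrac_distance`,
#'   `null` (distances), `null_mean`, `null_sd`, `null_q05`, `empirical_p`
#'   (fraction of null draws at or below the predicted distance), plus the
#'   two leaf sets.
#' @export
trait_tree_comparison <- function(tree, predicted_positive,
                                  observed_positive,
                                  exclude = character(),
                                  n_draws = 100L, seed = 1L) {
  pred <- trait_leaf_set(predicted_positive, tree, exclude)
  obs <- trait_leaf_set(observed_positive, tree, exclude)
  if (length(pred) == 0L || length(obs) == 0L)
    stop("predicted or observed leaf set is empty after exclusion",
         call. = FALSE)
  d <- unifrac(tree, pred, obs)
  null_d <- random_null(tree, obs, k = length(pred), n_draws = n_draws,
                        seed = seed, exclude = exclude)
  structure(list(unifrac_distance = d, null = null_d,
                 null_mean = mean(null_d), null_sd = stats::sd(null_d),
                 null_q05 = unname(stats::quantile(null_d, 0.05)),
                 empirical_p = mean(null_d <= d),
                 predicted_leaves = pred, observed_leaves = obs),
            class = "trait_tree_comparison")
}

#' @export
print.trait_tree_comparison <- function(x, ...) {
  cat(sprintf(paste0("<trait_tree_comparison> UniFrac %.4f ",
                     "(null %.4f +/- %.4f, 5th pct %.4f, empirical p %.3f)\n"),
              x$unifrac_distance, x$null_mean, x$null_sd, x$null_q05,
              x$empirical_p))
  invisible(x)
}
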