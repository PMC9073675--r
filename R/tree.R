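#' Haplotype tree with phenotype annotations
#'
#' Couples a phylogenetic tree (an `ape` `"phylo"` object or a Newick
#' file/string) with a partial tip -> Mrt-class map. Unphenotyped tips stay
#' in the tree — they shape the topology and path lengths — but are never
#' eligible as nearest phenotyped neighbours. Pairwise tip distances are
#' precomputed: patristic (sum of branch lengths on the connecting path) by
#' default, or topological (`"hops"`, every edge counted as length 1).
#'
#' @param tree A `"phylo"` object, or a path to / string of a Newick tree
#'   (read with [ape::read.tree()]); polytomies are allowed.
#' @param classes Tip phenotype map: a named character vector (names are
#'   tip labels), or a data frame whose first two columns are tip and
#'   class.
#' @param method `"patristic"` (default) or `"hops"`.
#' @return Object of class `"pheno_tree"`: list with `tree`, `classes`
#'   (named character), `dist` (tip distance matrix), `method`.
#' @examples
#' pt <- pheno_tree("((A:1,B:1):1,C:3);",
#'                  c(A = "strong", B = "wild_type", C = "wild_type"))
#' nearest_phenotyped_neighbor(pt, "A")
#' @export
pheno_tree <- function(tree, classes, method = c("patristic", "hops")) {
  method <- match.arg(method)
  if (is.character(tree) && length(tree) == 1L) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
    if (is.null(tree)) stop("could not parse Newick tree")
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (is.data.frame(classes)) {
    cl <- as.character(classes[[2]])
    names(cl) <- as.character(classes[[1]])
    classes <- cl
  }
  if (is.null(names(classes))) stop("classes must be named by tip label")
  unknown <- setdiff(names(classes), tree$tip.label)
  if (length(unknown)) {
    stop("phenotyped tips absent from the tree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  bad <- !classes %in% mrt_classes
  if (any(bad)) {
    stop("unknown Mrt class(es): ",
         paste(unique(classes[bad]), collapse = ", "))
  }
  tr <- tree
  if (method == "hops") tr$edge.length <- rep(1, nrow(tr$edge))
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths; use method = \"hops\" for a ",
         "topology-only distance")
  }
  if (any(tr$edge.length < 0)) stop("branch lengths must be non-negative")
  d <- stats::cophenetic(tr)
  structure(list(tree = tree, classes = classes, dist = d, method = method),
            class = "pheno_tree")
}

#' @export
print.pheno_tree <- function(x, ...) {
  cat(sprintf("Phenotype-annotated tree: %d tips, %d phenotyped (%s distances)\n",
              length(x$tree$tip.label), length(x$classes), x$method))
  print(table(factor(x$classes, levels = mrt_classes)))
  invisible(x)
}

#' Nearest phenotyped neighbour of a tip
#'
#' Among all phenotyped tips other than the query, returns the one at the
#' smallest tree distance. Exact distance ties are broken by lexicographic
#' tip label, so the result is deterministic.
#'
#' @param x A [pheno_tree()].
#' @param tip Tip label to query (need not itself be phenotyped).
#' @return List with `neighbor` (tip label), `class`, and `distance`.
#' @examples
#' pt <- pheno_tree("((A:1,B:1):1,C:3);",
#'                  c(A = "strong", B = "wild_type", C = "wild_type"))
#' nearest_phenotyped_neighbor(pt, "A")  # B at patristic distance 2
#' @export
nearest_phenotyped_neighbor <- function(x, tip) {
  stopifnot(inherits(x, "pheno_tree"))
  if (!tip %in% x$tree$tip.label) stop("tip '", tip, "' not in the tree")
  cand <- setdiff(names(x$classes), tip)
  if (!length(cand)) stop("no other phenotyped tip in the tree")
  cand <- sort(cand)
  d <- x$dist[tip, cand]
  dmin <- min(d)
  # tolerance absorbs float noise from re-rooting, preserving exact ties
  nb <- cand[d <= dmin + 1e-9 * (1 + dmin)][1]
  list(neighbor = nb, class = unname(x$classes[nb]),
       distance = unname(x$dist[tip, nb]))
}

# Nearest phenotyped neighbour of every phenotyped tip; independent of the
# class labels themselves, so permutation tests compute it once.
nn_of_phenotyped <- function(x) {
  tips <- sort(names(x$classes))
  vapply(tips, function(tp) {
    cand <- setdiff(tips, tp)
    d <- x$dist[tp, cand]
    dmin <- min(d)
    cand[d <= dmin + 1e-9 * (1 + dmin)][1]
  }, character(1))
}

#' Phylogenetic scattering statistic for a phenotype class
#'
#' Counts how many tips of the focal class have a wild-type nearest
#' phenotyped neighbour. Under mutation-selection balance a deleterious
#' phenotype recurs by mutation and is quickly purged, so carriers should
#' sit on scattered tip branches surrounded by wild type (large statistic);
#' under balancing selection carriers cluster in deeper clades (small
#' statistic).
#'
#' @param x A [pheno_tree()].
#' @param focal_class Class whose dispersion is measured (default
#'   `"strong"`).
#' @param reference_class Class counted as the "background" neighbour
#'   (default `"wild_type"`).
#' @return Integer in `[0, n_focal]`.
#' @export
scatter_statistic <- function(x, focal_class = "strong",
                              reference_class = "wild_type") {
  stopifnot(inherits(x, "pheno_tree"))
  focal <- names(x$classes)[x$classes == focal_class]
  if (!length(focal)) stop("no tip of class '", focal_class, "'")
  if (length(x$classes) < 2L) stop("need at least two phenotyped tips")
  nn <- nn_of_phenotyped(x)
  sum(x$classes[nn[focal]] == reference_class)
}

#' Permutation test for phylogenetic scattering of a phenotype
#'
#' Permutes the class labels over the phenotyped tips (tree and set of
#' phenotyped tips held fixed) and compares the observed
#' [scatter_statistic()] to its permutation distribution. With
#' `alternative = "scattered"` the p-value is the (+1-smoothed) fraction of
#' permutations with a statistic at least as large as observed — evidence
#' that focal-class tips are surrounded by wild type more often than label
#' exchange predicts; `"clustered"` tests the opposite direction.
#'
#' @inheritParams scatter_statistic
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Optional RNG seed.
#' @param alternative `"scattered"` (statistic >= observed) or
#'   `"clustered"` (statistic <= observed).
#' @return Object of class `"htest"` with the observed `statistic` and the
#'   permutation `p.value` (never exactly 0, by the +1 smoothing).
#' @export
scatter_permutation_test <- function(x, focal_class = "strong",
                                     reference_class = "wild_type",
                                     n_permutations = 999, seed = NULL,
                                     alternative = c("scattered",
                                                     "clustered")) {
  stopifnot(inherits(x, "pheno_tree"))
  alternative <- match.arg(alternative)
  if (!is_count(n_permutations)) {
    stop("n_permutations must be a positive integer")
  }
  nn <- nn_of_phenotyped(x)
  tips <- names(nn)
  labels <- x$classes[tips]
  stat_of <- function(lab) {
    names(lab) <- tips
    sum(lab[nn[tips[lab == focal_class]]] == reference_class)
  }
  obs <- stat_of(labels)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) stat_of(sample(labels)),
           numeric(1))
  })
  p <- if (alternative == "scattered") {
    (1 + sum(perm >= obs)) / (n_permutations + 1)
  } else {
    (1 + sum(perm <= obs)) / (n_permutations + 1)
  }
  structure(list(
    statistic = c("focal tips with wild-type nearest neighbour" = obs),
    p.value = p,
    alternative = paste0("focal class more ", alternative,
                         " than random label placement"),
    method = sprintf(
      "Nearest phenotyped-neighbour permutation test (%d permutations)",
      n_permutations),
    data.name = sprintf("%d phenotyped tips, focal class '%s'",
                        length(tips), focal_class)
  ), class = "htest")
}
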