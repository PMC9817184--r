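#' Read a forest of Newick gene trees
#'
#' Accepts a multi-tree Newick file (one tree per line) or a directory of
#' Newick files. Leaf names are preserved verbatim.
#'
#' @param path file or directory.
#' @return list of `phylo` objects.
#' @export
read_newick_forest <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(nwk|tre|tree|treefile|txt)$",
               full.names = TRUE)
  } else {
    if (!file.exists(path)) stop("no such file or directory: ", path)
    path
  }
  if (length(files) == 0) stop("no Newick files found in ", path)
  trees <- list()
  for (f in files) {
    lines <- trimws(readLines(f, warn = FALSE))
    lines <- lines[nzchar(lines)]
    for (li in seq_along(lines)) {
      tr <- suppressWarnings(
        tryCatch(ape::read.tree(text = lines[li]), error = function(e) NULL))
      if (is.null(tr))
        stop("malformed Newick in ", f, " at line ", li)
      trees[[length(trees) + 1L]] <- tr
    }
  }
  trees
}

#' Write a forest as a one-tree-per-line Newick file
#'
#' @param forest list of `phylo` objects or character vector of Newick strings.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick_forest <- function(forest, path) {
  lines <- if (is.character(forest)) forest else
    vapply(forest, ape::write.tree, "")
  writeLines(lines, path)
  invisible(path)
}

#' Root a gene tree on its outgroup
#'
#' Places the root on the edge subtending the outgroup leaf; the topology is
#' otherwise unchanged. A tree lacking the outgroup cannot be rooted and is
#' reported as such (NULL) rather than raising an error, so a census can
#' tally it.
#'
#' @param tree a `phylo`.
#' @param outgroup_name outgroup leaf label.
#' @return rooted `phylo`, or NULL when the outgroup is absent.
#' @export
root_at_outgroup <- function(tree, outgroup_name) {
  if (!outgroup_name %in% tree$tip.label) return(NULL)
  tryCatch(ape::root(tree, outgroup = outgroup_name, resolve.root = TRUE),
           error = function(e) NULL)
}

# leaf labels under a node of a phylo
node_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, node_tips, tree = tree))
}

#' Sister leaf set of a focal tip
#'
#' In a rooted tree, the sister group of the focal tip is the union of the
#' leaves of all other children of the focal tip's parent node (so a
#' multifurcating parent yields a non-singleton sister set).
#'
#' @param tree a rooted `phylo`.
#' @param focal_name focal leaf label.
#' @return character vector of sister leaf labels.
#' @export
sister_of <- function(tree, focal_name) {
  i <- match(focal_name, tree$tip.label)
  if (is.na(i)) stop("focal tip '", focal_name, "' absent from tree")
  parent <- tree$edge[tree$edge[, 2] == i, 1]
  siblings <- tree$edge[tree$edge[, 1] == parent & tree$edge[, 2] != i, 2]
  sort(unique(unlist(lapply(siblings, node_tips, tree = tree))))
}

#' Sister-taxon census over a gene-tree forest
#'
#' Roots each tree on the outgroup, extracts the focal tip's sister group,
#' and counts trees whose sister is a single leaf (the singleton-sister
#' filter), per species. Multi-leaf sisters and unrootable trees are tallied
#' separately and excluded from the proportion denominator.
#'
#' @param forest list of `phylo` objects or character vector of Newick strings.
#' @param focal_name focal (hybrid) tip label.
#' @param outgroup_name outgroup leaf label used for rooting.
#' @param species optional fixed census rows.
#' @return a `sister_census`: per-species singleton counts and proportions,
#'   `n_trees_total`, `n_singleton`, `n_multi_sister`, `n_unrootable`.
#' @export
sister_census <- function(forest, focal_name, outgroup_name, species = NULL) {
  if (is.character(forest))
    forest <- lapply(forest, function(s) ape::read.tree(text = s))
  sisters <- character(0)
  n_multi <- 0L
  n_unroot <- 0L
  for (tr in forest) {
    rooted <- root_at_outgroup(tr, outgroup_name)
    if (is.null(rooted)) {
      n_unroot <- n_unroot + 1L
      next
    }
    sis <- sister_of(rooted, focal_name)
    if (length(sis) == 1L) sisters <- c(sisters, sis) else n_multi <- n_multi + 1L
  }
  lev <- species %||% sort(unique(sisters))
  counts <- table(factor(sisters, levels = lev))
  counts <- setNames(as.integer(counts), lev)
  n_single <- sum(counts)
  structure(list(
    counts = counts,
    proportions = if (n_single > 0) counts / n_single else
      setNames(rep(NA_real_, length(lev)), lev),
    n_trees_total = length(forest),
    n_singleton = n_single,
    n_multi_sister = n_multi,
    n_unrootable = n_unroot
  ), class = "sister_census")
}

#' @export
print.sister_census <- function(x, ...) {
  cat(sprintf(
    "sister_census: %d trees | %d singleton-sister, %d multi-leaf, %d unrootable\n",
    x$n_trees_total, x$n_singleton, x$n_multi_sister, x$n_unrootable))
  if (x$n_singleton > 0) {
    tab <- data.frame(species = names(x$counts), count = x$counts,
                      proportion = round(x$proportions, 4))
    rownames(tab) <- NULL
    print(tab[order(-tab$count), ], row.names = FALSE)
  }
  invisible(x)
}
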