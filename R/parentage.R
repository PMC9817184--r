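#' Identify the two parent species from a nuclear best-hit census
#'
#' The two species with the highest unique-best-hit counts. Ties at the
#' second place are broken lexicographically with a warning.
#'
#' @param nuclear a `hit_census`.
#' @return character vector of two species names, highest count first.
#' @export
identify_parents <- function(nuclear) {
  stopifnot(inherits(nuclear, "hit_census"))
  cnt <- nuclear$counts[nuclear$counts > 0]
  if (length(cnt) < 2)
    stop("need at least two species with nonzero best-hit counts")
  ord <- order(-cnt, names(cnt)) # lexicographic tie-break
  sorted <- cnt[ord]
  if (length(sorted) > 2 && sorted[2] == sorted[3])
    warning("tie for second parent broken lexicographically: ",
            names(sorted)[2], " over ", names(sorted)[3])
  names(sorted)[1:2]
}

#' Assign the dam from the mitochondrial census
#'
#' The dam is the mito census' top species, provided its proportion of
#' mito-assigned reads reaches `threshold` and it is one of the two nuclear
#' parents; anything else is ambiguous.
#'
#' @param mito a `hit_census` from [mito_census()].
#' @param parents the two parent species ([identify_parents()]).
#' @param threshold minimum top-species proportion (default 0.99).
#' @return list with `dam` (species name or NA), `proportion`, `reason`.
#' @export
assign_dam <- function(mito, parents, threshold = 0.99) {
  stopifnot(inherits(mito, "hit_census"))
  if (mito$n_assigned == 0) {
    warning("empty mitochondrial census; dam ambiguous")
    return(list(dam = NA_character_, proportion = NA_real_,
                reason = "no mitochondrial assignments"))
  }
  top <- names(which.max(mito$proportions))
  p <- unname(mito$proportions[top])
  if (p < threshold)
    return(list(dam = NA_character_, proportion = p,
                reason = sprintf("top mito species %s below threshold (%.3f < %.2f)",
                                 top, p, threshold)))
  if (!top %in% parents)
    return(list(dam = NA_character_, proportion = p,
                reason = sprintf("top mito species %s is not a nuclear parent", top)))
  list(dam = top, proportion = p, reason = "ok")
}

#' Classify a hybrid as F1 or first-generation backcross
#'
#' Exact two-sided binomial tests of the first parent's share of
#' parent-assigned reads against the F1 expectation (p = 0.5) and the two
#' BC1 expectations (p = 0.75 toward parent 1, p = 0.25 toward parent 2).
#' The call is F1 when only the 0.5 model is retained at level `alpha`,
#' BC1 toward a parent when only that 0.75/0.25 model is retained, and
#' ambiguous otherwise (all models rejected, or several retained).
#'
#' Reads are not fully independent draws (overlapping reads, linked sites),
#' so the nominal binomial n overstates the effective sample size;
#' `downsample` caps the total count used in the tests while preserving the
#' observed proportion.
#'
#' @param c1,c2 parent-assigned read counts (by convention `c1` is the dam's
#'   parent when the dam is known).
#' @param alpha significance level of each exact test (default 0.001).
#' @param downsample optional cap on `c1 + c2` for the tests.
#' @return list with `generation` (`"F1"`, `"BC1_toward_1"`,
#'   `"BC1_toward_2"`, `"ambiguous"`), `p_hat`, `c1`, `c2`, `n`, and
#'   p-values `p_F1`, `p_BC1_1`, `p_BC1_2`.
#' @export
classify_generation <- function(c1, c2, alpha = 0.001, downsample = NULL) {
  stopifnot(c1 >= 0, c2 >= 0, c1 + c2 > 0)
  c1_t <- c1
  c2_t <- c2
  if (!is.null(downsample) && downsample < c1 + c2) {
    c1_t <- round(c1 / (c1 + c2) * downsample)
    c2_t <- downsample - c1_t
  }
  n <- c1_t + c2_t
  p_f1 <- binom.test(c1_t, n, p = 0.5)$p.value
  p_bc1 <- binom.test(c1_t, n, p = 0.75)$p.value
  p_bc2 <- binom.test(c1_t, n, p = 0.25)$p.value
  retained <- c(F1 = p_f1 >= alpha, BC1_1 = p_bc1 >= alpha, BC1_2 = p_bc2 >= alpha)
  generation <- if (sum(retained) == 1) {
    switch(names(which(retained)),
           F1 = "F1", BC1_1 = "BC1_toward_1", BC1_2 = "BC1_toward_2")
  } else {
    "ambiguous"
  }
  list(generation = generation, p_hat = c1 / (c1 + c2),
       c1 = c1, c2 = c2, n = n,
       p_F1 = p_f1, p_BC1_1 = p_bc1, p_BC1_2 = p_bc2,
       alpha = alpha)
}

#' Full parentage call from the three censuses
#'
#' Combines the nuclear best-hit census (parent pair), the mitochondrial
#' census (dam), the F1/BC1 binomial classification on parent-assigned
#' counts, and, when a gene-tree sister census is supplied, a concordance
#' flag checking that the trees' top sister species are the same two parents.
#'
#' @param nuclear nuclear `hit_census`.
#' @param mito mitochondrial `hit_census`, or NULL.
#' @param trees `sister_census`, or NULL.
#' @param alpha level of the generation tests.
#' @param dam_threshold minimum dam mito proportion.
#' @param downsample optional effective-count cap for the generation tests.
#' @return a `parentage_call`.
#' @export
parentage_call <- function(nuclear, mito = NULL, trees = NULL,
                           alpha = 0.001, dam_threshold = 0.99,
                           downsample = NULL) {
  parents <- identify_parents(nuclear)
  dam_info <- if (!is.null(mito)) assign_dam(mito, parents, dam_threshold)
  else list(dam = NA_character_, proportion = NA_real_, reason = "no mito census")
  dam <- dam_info$dam
  sire <- if (!is.na(dam)) setdiff(parents, dam) else NA_character_
  # orient counts: c1 = dam parent when known, else the higher-count parent
  p1 <- if (!is.na(dam)) dam else parents[1]
  p2 <- setdiff(parents, p1)
  gen <- classify_generation(unname(nuclear$counts[p1]), unname(nuclear$counts[p2]),
                             alpha = alpha, downsample = downsample)
  generation <- switch(gen$generation,
                       BC1_toward_1 = sprintf("BC1_toward(%s)", p1),
                       BC1_toward_2 = sprintf("BC1_toward(%s)", p2),
                       gen$generation)
  concordant <- NA
  if (!is.null(trees) && trees$n_singleton > 0) {
    top_tree <- names(sort(trees$counts, decreasing = TRUE))[1:min(2, sum(trees$counts > 0))]
    concordant <- all(top_tree %in% parents)
  }
  structure(list(
    parent_1 = p1, parent_2 = p2, dam = dam, sire = sire,
    dam_proportion = dam_info$proportion, dam_reason = dam_info$reason,
    generation = generation, stats = gen,
    tree_concordant = concordant,
    nuclear = nuclear, mito = mito, trees = trees
  ), class = "parentage_call")
}

#' @export
print.parentage_call <- function(x, ...) {
  cat("parentage_call\n")
  cat(sprintf("  parents   : %s, %s\n", x$parent_1, x$parent_2))
  cat(sprintf("  dam       : %s (mito proportion %s)\n",
              ifelse(is.na(x$dam), "ambiguous", x$dam),
              ifelse(is.na(x$dam_proportion), "-",
                     sprintf("%.4f", x$dam_proportion))))
  cat(sprintf("  generation: %s  (p_hat = %.4f; p[0.5] = %.3g, p[0.75] = %.3g, p[0.25] = %.3g)\n",
              x$generation, x$stats$p_hat, x$stats$p_F1,
              x$stats$p_BC1_1, x$stats$p_BC1_2))
  if (!is.na(x$tree_concordant))
    cat(sprintf("  gene trees: top sister species %sconcordant with parents\n",
                ifelse(x$tree_concordant, "", "NOT ")))
  cat("  note: read counts overstate independent draws; see downsample option\n")
  invisible(x)
}

#' Write a machine-readable parentage report
#'
#' JSON with parents, dam, generation, all counts, proportions and p-values.
#'
#' @param call a `parentage_call`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(call, path) {
  stopifnot(inherits(call, "parentage_call"))
  if (call$nuclear$n_assigned == 0) stop("empty nuclear census; nothing to report")
  report <- list(
    parents = c(call$parent_1, call$parent_2),
    dam = call$dam, sire = call$sire,
    dam_proportion = call$dam_proportion,
    dam_reason = call$dam_reason,
    generation = call$generation,
    statistics = call$stats,
    tree_concordant = call$tree_concordant,
    nuclear_census = list(counts = as.list(call$nuclear$counts),
                          proportions = as.list(call$nuclear$proportions),
                          n_assigned = call$nuclear$n_assigned,
                          n_tie_discarded = call$nuclear$n_tie_discarded,
                          n_no_hit = call$nuclear$n_no_hit),
    mito_census = if (!is.null(call$mito)) list(
      counts = as.list(call$mito$counts),
      proportions = as.list(call$mito$proportions),
      n_assigned = call$mito$n_assigned),
    tree_census = if (!is.null(call$trees)) list(
      counts = as.list(call$trees$counts),
      proportions = as.list(call$trees$proportions),
      n_trees_total = call$trees$n_trees_total,
      n_singleton = call$trees$n_singleton,
      n_multi_sister = call$trees$n_multi_sister,
      n_unrootable = call$trees$n_unrootable)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
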