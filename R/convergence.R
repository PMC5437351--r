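# Randomization test for convergent selective constraint: are the same
# orthologs constrained in multiple independent endosymbiont lineages more
# often than random gene lists of the same sizes would be?

#' Bundle per-lineage gene universes and constrained sublists
#'
#' @param universes Named list of character vectors: the genes analyzed in
#'   each lineage (a shared ortholog-name namespace across lineages).
#' @param constrained Named list of character vectors: the constrained
#'   subset of each lineage's universe (same names/order as `universes`).
#' @return Object of class `lineage_gene_lists`.
#' @export
lineage_gene_lists <- function(universes, constrained) {
  if (length(universes) < 2L) stop("need at least 2 lineages")
  if (length(universes) != length(constrained))
    stop("universes and constrained lists differ in length")
  if (is.null(names(universes)))
    names(universes) <- paste0("lineage", seq_along(universes))
  names(constrained) <- names(universes)
  for (nm in names(universes)) {
    extra <- setdiff(constrained[[nm]], universes[[nm]])
    if (length(extra))
      stop("constrained genes outside the universe of ", nm, ": ",
           paste(utils::head(extra, 5L), collapse = ", "))
  }
  structure(list(universes = lapply(universes, unique),
                 constrained = lapply(constrained, unique)),
            class = "lineage_gene_lists")
}

#' Observed cross-lineage overlap tallies
#'
#' For each gene in the union of the constrained lists, counts the number
#' of lineages `k` in which it is constrained, and tallies genes by `k`
#' (both exactly-k and at-least-k conventions).
#'
#' @param lists A `lineage_gene_lists`.
#' @return List with integer vectors `exact` and `at_least`, each of length
#'   equal to the number of lineages (index = k).
#' @export
observed_overlaps <- function(lists) {
  L <- length(lists$constrained)
  genes <- unlist(lists$constrained, use.names = FALSE)
  if (length(genes) == 0L) {
    z <- stats::setNames(integer(L), seq_len(L))
    return(list(exact = z, at_least = z))
  }
  counts <- table(genes)
  exact <- vapply(seq_len(L), function(k) sum(counts == k), integer(1))
  at_least <- rev(cumsum(rev(exact)))
  names(exact) <- names(at_least) <- seq_len(L)
  list(exact = exact, at_least = at_least)
}

#' Randomization null for cross-lineage overlaps
#'
#' Per replicate, a pseudo-constrained list is drawn for every lineage
#' uniformly without replacement from that lineage's own analyzed-gene
#' universe, with the observed list size; overlap tallies are accumulated.
#' Fully reproducible from `seed`.
#'
#' @param universes Named list of per-lineage gene universes.
#' @param list_sizes Integer vector of constrained-list sizes per lineage.
#' @param n_reps Number of replicates (the reference analysis used 1e5).
#' @param seed Integer seed.
#' @return List with integer matrices `exact` and `at_least`
#'   (`n_reps` x lineages; column k = tally at k).
#' @export
randomization_null <- function(universes, list_sizes, n_reps = 1e5,
                               seed = 1L) {
  L <- length(universes)
  if (length(list_sizes) != L) stop("one list size per lineage required")
  usizes <- lengths(universes)
  if (any(list_sizes > usizes))
    stop("constrained-list size exceeds universe size for lineage ",
         which(list_sizes > usizes)[1L])
  namespace <- unique(unlist(universes, use.names = FALSE))
  N <- length(namespace)
  idx <- lapply(universes, function(u) match(u, namespace))
  n_reps <- as.integer(n_reps)
  exact <- matrix(0L, n_reps, L)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    drawn <- integer(0)
    for (i in seq_len(L))
      drawn <- c(drawn, idx[[i]][sample.int(usizes[i], list_sizes[i])])
    per_gene <- tabulate(drawn, nbins = N)
    exact[r, ] <- tabulate(per_gene, nbins = L)
  }
  at_least <- exact
  for (k in (L - 1L):1L) at_least[, k] <- at_least[, k] + at_least[, k + 1L]
  list(exact = exact, at_least = at_least)
}

#' Empirical upper-tail p-value
#'
#' `p = (1 + #\{replicates >= observed\}) / (1 + n_reps)`; never zero. With
#' `n_reps` replicates the smallest attainable value is `1/(n_reps + 1)`,
#' which is reported as a bound (`p <= 1/(n_reps+1)`) by the printer.
#'
#' @param observed Observed tally.
#' @param null Integer vector of null tallies.
#' @return The empirical p-value.
#' @export
empirical_pvalue <- function(observed, null) {
  if (length(null) == 0L) stop("empty null distribution")
  if (observed == 0) return(1)
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Convergence test across endosymbiont lineages
#'
#' Runs [observed_overlaps()], [randomization_null()] (sizes taken from the
#' observed constrained lists) and [empirical_pvalue()] for every overlap
#' level k, under both the exactly-k and at-least-k conventions.
#'
#' @param lists A `lineage_gene_lists`.
#' @param n_reps Replicates (default 1e5).
#' @param seed Integer seed.
#' @return Object of class `convergence_result`.
#' @export
convergence_test <- function(lists, n_reps = 1e5, seed = 1L) {
  stopifnot(inherits(lists, "lineage_gene_lists"))
  obs <- observed_overlaps(lists)
  null <- randomization_null(lists$universes,
                             lengths(lists$constrained),
                             n_reps = n_reps, seed = seed)
  L <- length(lists$constrained)
  p_exact <- vapply(seq_len(L), function(k)
    empirical_pvalue(obs$exact[k], null$exact[, k]), numeric(1))
  p_at_least <- vapply(seq_len(L), function(k)
    empirical_pvalue(obs$at_least[k], null$at_least[, k]), numeric(1))
  names(p_exact) <- names(p_at_least) <- seq_len(L)
  structure(
    list(observed = obs,
         null_mean = list(exact = colMeans(null$exact),
                          at_least = colMeans(null$at_least)),
         null = null,
         p_values = list(exact = p_exact, at_least = p_at_least),
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         min_p = 1 / (n_reps + 1)),
    class = "convergence_result"
  )
}

#' @export
print.convergence_result <- function(x, ...) {
  L <- length(x$observed$exact)
  cat("Convergent-constraint randomization test (", x$n_reps,
      " replicates, seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  smallest attainable p: %.3g (values at this bound mean p <= it)\n",
              x$min_p))
  for (k in seq_len(L)) {
    cat(sprintf("  k=%d: observed %d (null mean %.2f), p[exact]=%s, p[>=k]=%s\n",
                k, x$observed$exact[k], x$null_mean$exact[k],
                format(x$p_values$exact[k], digits = 3),
                format(x$p_values$at_least[k], digits = 3)))
  }
  invisible(x)
}
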