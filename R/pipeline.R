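# End-to-end orchestration: dN/dS per ortholog pair in every lineage,
# constraint ratios against the free-living reference, per-lineage
# summaries, and (when >= 2 endosymbiont lineages are given) the
# convergence randomization test. Reports are written as TSV + JSON.

#' Run the constraint analysis pipeline
#'
#' @param endo_pairs Named list (one element per endosymbiont lineage) of
#'   lists of `ortholog_pair` objects.
#' @param free_pairs List of `ortholog_pair` objects for the free-living
#'   reference pair (shared gene namespace with the endosymbiont lists).
#' @param out_dir Optional output directory; when given, per-lineage
#'   constraint TSVs, a JSON summary and (if computed) the convergence JSON
#'   are written there.
#' @param constrained_max_R Genes with defined `R` strictly below this
#'   threshold form the constrained list used for the convergence test
#'   (default 2, the "strong or moderately constrained" set; use 1 for the
#'   strictly strong set).
#' @param n_reps,seed Randomization-test replicates and seed.
#' @param saturation_ds Saturation guard passed to [estimate_omega()].
#' @return List with `tables` (per-lineage `constraint_table`s),
#'   `summaries` (per-lineage `constraint_summary`s), and `convergence` (a
#'   `convergence_result` or NULL).
#' @export
run_constraint_pipeline <- function(endo_pairs, free_pairs, out_dir = NULL,
                                    constrained_max_R = 2,
                                    n_reps = 1e5, seed = 1L,
                                    saturation_ds = 2) {
  if (!length(endo_pairs)) stop("no endosymbiont lineages supplied")
  if (!length(free_pairs)) stop("no free-living reference pairs supplied")
  if (is.null(names(endo_pairs)))
    names(endo_pairs) <- paste0("lineage", seq_along(endo_pairs))
  free_est <- lapply(free_pairs, estimate_omega,
                     saturation_ds = saturation_ds)
  tables <- lapply(names(endo_pairs), function(nm) {
    est <- lapply(endo_pairs[[nm]], estimate_omega,
                  saturation_ds = saturation_ds)
    constraint_table(est, free_est, lineage = nm)
  })
  names(tables) <- names(endo_pairs)
  summaries <- lapply(tables, summarize_constraint)
  convergence <- NULL
  if (length(tables) >= 2L) {
    universes <- lapply(tables, function(tb) tb$gene_id[!is.na(tb$R)])
    constrained <- lapply(tables, function(tb)
      tb$gene_id[!is.na(tb$R) & tb$R < constrained_max_R])
    if (all(lengths(constrained) > 0L)) {
      convergence <- convergence_test(
        lineage_gene_lists(universes, constrained),
        n_reps = n_reps, seed = seed)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      utils::write.table(
        as.data.frame(tables[[nm]]),
        file.path(out_dir, paste0("constraint_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(summaries, unclass),
      file.path(out_dir, "constraint_summary.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(convergence)) {
      cv <- convergence
      jsonlite::write_json(
        list(observed = cv$observed, p_values = cv$p_values,
             null_mean = cv$null_mean,
             null_q95 = list(
               exact = apply(cv$null$exact, 2, stats::quantile, 0.95),
               at_least = apply(cv$null$at_least, 2, stats::quantile, 0.95)),
             n_reps = cv$n_reps, seed = cv$seed, min_p = cv$min_p),
        file.path(out_dir, "convergence.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }
  list(tables = tables, summaries = summaries, convergence = convergence)
}

#' Rate of regulatory change per passage
#'
#' @param n_deregulated Number of genes whose expression changed over the
#'   interval.
#' @param n_passages Number of single-colony passages in the interval.
#' @return Genes per passage, rounded to one decimal.
#' @export
deregulation_rate <- function(n_deregulated, n_passages) {
  if (n_passages < 1) stop("need at least one passage")
  if (n_deregulated < 0) stop("negative gene count")
  round(n_deregulated / n_passages, 1)
}
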