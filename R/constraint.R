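# Relative selective constraint: R = omega_e / omega_f compares the
# selective pressure on an endosymbiont gene with that on its ortholog in a
# free-living relative. R < 1 means the gene is under stronger purifying
# selection in the endosymbiont.

#' Relative constraint ratio R
#'
#' @param omega_e Endosymbiont-pair omega (or `NA` when undefined).
#' @param omega_f Free-living-pair omega (or `NA`).
#' @return A list with `R` (numeric or `NA`) and `reason` (`NA` when R is
#'   defined; otherwise `"omega_e_undefined"`, `"omega_f_undefined"` or
#'   `"omega_f_zero"`).
#' @export
compute_R <- function(omega_e, omega_f) {
  if (is.na(omega_e)) return(list(R = NA_real_, reason = "omega_e_undefined"))
  if (is.na(omega_f)) return(list(R = NA_real_, reason = "omega_f_undefined"))
  if (omega_f == 0) return(list(R = NA_real_, reason = "omega_f_zero"))
  list(R = omega_e / omega_f, reason = NA_character_)
}

#' Classify a gene by its relative constraint
#'
#' Boundary convention: `R <= 1` is `strong` (the tabulated convention;
#' genes at exactly R = 1 are counted separately by
#' [summarize_constraint()] so the strict `R < 1` reading can be
#' reconstructed), `1 < R < 2` is `moderate`, `R >= 2` is `relaxed`.
#'
#' @param R Numeric vector of defined constraint ratios.
#' @return Character vector of categories.
#' @export
classify_gene <- function(R) {
  if (anyNA(R)) stop("classify_gene requires defined R; filter exclusions first")
  ifelse(R <= 1, "strong", ifelse(R < 2, "moderate", "relaxed"))
}

#' Build a per-gene constraint table from two omega-estimate sets
#'
#' Joins endosymbiont and free-living estimates on `gene_id`; genes flagged
#' `dS_zero` or `dS_saturated` in either pair (or missing from either set)
#' are categorized `excluded` and never enter summaries or tests.
#'
#' @param endo,free Lists of `omega_estimate` objects (same gene namespace).
#' @param lineage Lineage label attached to the table.
#' @return Data frame of class `constraint_table`: gene_id, omega_e,
#'   omega_f, R, category, exclusion reason.
#' @export
constraint_table <- function(endo, free, lineage = NA_character_) {
  te <- omega_table(endo); tf <- omega_table(free)
  merged <- merge(te[c("gene_id", "omega")], tf[c("gene_id", "omega")],
                  by = "gene_id", suffixes = c("_e", "_f"), all.x = TRUE)
  res <- lapply(seq_len(nrow(merged)), function(i)
    compute_R(merged$omega_e[i], merged$omega_f[i]))
  merged$R <- vapply(res, `[[`, numeric(1), "R")
  merged$reason <- vapply(res, `[[`, character(1), "reason")
  merged$category <- ifelse(is.na(merged$R), "excluded",
                            classify_gene_safe(merged$R))
  attr(merged, "lineage") <- lineage
  class(merged) <- c("constraint_table", "data.frame")
  merged
}

classify_gene_safe <- function(R) {
  out <- rep(NA_character_, length(R))
  ok <- !is.na(R)
  out[ok] <- classify_gene(R[ok])
  out
}

#' Summarize relative constraints for one lineage
#'
#' Counts genes with `R <= 1` (strong constraint) versus `R > 1` (relaxed,
#' in the tabulated two-way sense), percentages to one decimal, and the
#' median R (midpoint convention for even counts). The count at exactly
#' `R = 1` is reported so the strict-inequality convention can be
#' reconstructed.
#'
#' @param x A `constraint_table`, or a numeric vector of defined R values.
#' @param lineage Optional lineage label (taken from the table if present).
#' @return Object of class `constraint_summary`.
#' @export
summarize_constraint <- function(x, lineage = NULL) {
  if (inherits(x, "constraint_table")) {
    if (is.null(lineage)) lineage <- attr(x, "lineage")
    r <- x$R[!is.na(x$R)]
  } else {
    r <- x[!is.na(x)]
  }
  if (length(r) == 0L) stop("no genes with a defined R")
  n_strong <- sum(r <= 1)
  n_relaxed <- sum(r > 1)
  structure(
    list(lineage = if (is.null(lineage)) NA_character_ else lineage,
         n_genes = length(r),
         n_strong = n_strong, n_relaxed = n_relaxed,
         n_at_one = sum(r == 1),
         pct_strong = round(100 * n_strong / length(r), 1),
         pct_relaxed = round(100 * n_relaxed / length(r), 1),
         median_R = stats::median(r)),
    class = "constraint_summary"
  )
}

#' @export
print.constraint_summary <- function(x, ...) {
  cat("Relative selective constraints",
      if (!is.na(x$lineage)) paste0("[", x$lineage, "]"), "\n")
  cat(sprintf("  genes with defined R: %d\n", x$n_genes))
  cat(sprintf("  R <= 1 (strong):   %d (%.1f%%)\n", x$n_strong, x$pct_strong))
  cat(sprintf("  R > 1  (relaxed):  %d (%.1f%%)\n", x$n_relaxed, x$pct_relaxed))
  cat(sprintf("  median R: %.2f\n", x$median_R))
  invisible(x)
}

#' Compare the R distributions of two lineages
#'
#' Mann-Whitney/Wilcoxon rank-sum test on defined R values (see
#' [mann_whitney()] for the exact/approximate switch).
#'
#' @param r_values_a,r_values_b Numeric vectors of defined R values.
#' @return List with `U` and `p_two_sided`.
#' @export
compare_groups <- function(r_values_a, r_values_b) {
  a <- r_values_a[!is.na(r_values_a)]
  b <- r_values_b[!is.na(r_values_b)]
  if (!length(a) || !length(b)) stop("both groups need defined R values")
  mann_whitney(a, b)
}
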