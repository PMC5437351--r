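# Radical vs conservative amino-acid substitutions. A replacement is
# radical when it crosses a class boundary of charge, polarity, or
# polarity-and-volume; the three class tables below are the single source
# of truth for the whole package (the simulator derives its pair pools
# from them).

AA_CHARGE <- c(
  R = "positive", K = "positive", H = "positive",
  D = "negative", E = "negative",
  A = "neutral", C = "neutral", F = "neutral", G = "neutral", I = "neutral",
  L = "neutral", M = "neutral", N = "neutral", P = "neutral", Q = "neutral",
  S = "neutral", T = "neutral", V = "neutral", W = "neutral", Y = "neutral"
)

AA_POLARITY <- c(
  C = "polar", D = "polar", E = "polar", H = "polar", K = "polar",
  N = "polar", Q = "polar", R = "polar", S = "polar", T = "polar",
  W = "polar", Y = "polar",
  A = "nonpolar", F = "nonpolar", G = "nonpolar", I = "nonpolar",
  L = "nonpolar", M = "nonpolar", P = "nonpolar", V = "nonpolar"
)

AA_POLARITY_VOLUME <- c(
  C = "special",
  A = "neutral_small", G = "neutral_small", P = "neutral_small",
  S = "neutral_small", T = "neutral_small",
  N = "polar_small", D = "polar_small", Q = "polar_small", E = "polar_small",
  R = "polar_large", H = "polar_large", K = "polar_large",
  I = "nonpolar_small", L = "nonpolar_small", M = "nonpolar_small",
  V = "nonpolar_small",
  F = "nonpolar_large", W = "nonpolar_large", Y = "nonpolar_large"
)

STANDARD_AA <- sort(names(AA_CHARGE))

#' Classify amino-acid substitutions as radical or conservative
#'
#' A substitution is radical if the two residues differ in charge class,
#' polarity class, or polarity-and-volume class. Class membership, not
#' direction, decides, so the classification is symmetric.
#'
#' @param from_aa,to_aa One-letter amino-acid codes (vectorized; pairwise
#'   distinct, standard residues only).
#' @return Data frame with columns from_aa, to_aa, charge_change,
#'   polarity_change, polarity_volume_change, radical.
#' @export
classify_substitution <- function(from_aa, to_aa) {
  from_aa <- toupper(from_aa); to_aa <- toupper(to_aa)
  bad <- !(from_aa %in% STANDARD_AA) | !(to_aa %in% STANDARD_AA)
  if (any(bad))
    stop("non-standard amino acid in substitution: ",
         from_aa[bad][1L], " -> ", to_aa[bad][1L])
  if (any(from_aa == to_aa))
    stop("identical residues are not a substitution: ",
         from_aa[from_aa == to_aa][1L])
  charge <- AA_CHARGE[from_aa] != AA_CHARGE[to_aa]
  polarity <- AA_POLARITY[from_aa] != AA_POLARITY[to_aa]
  pv <- AA_POLARITY_VOLUME[from_aa] != AA_POLARITY_VOLUME[to_aa]
  data.frame(from_aa = from_aa, to_aa = to_aa,
             charge_change = unname(charge),
             polarity_change = unname(polarity),
             polarity_volume_change = unname(pv),
             radical = unname(charge | polarity | pv),
             stringsAsFactors = FALSE)
}

#' Summarize a substitution spectrum
#'
#' @param subs Data frame with a logical `radical` column (e.g. from
#'   [classify_substitution()] or [read_variant_table()] after filtering to
#'   classifiable rows), or a logical vector of radical flags.
#' @return Object of class `spectrum_summary`: `n_total`, `n_radical`,
#'   `pct_radical` (two decimals).
#' @export
spectrum_summary <- function(subs) {
  radical <- if (is.data.frame(subs)) subs$radical else subs
  if (length(radical) == 0L) stop("empty substitution list")
  if (anyNA(radical)) stop("unclassified substitutions present; filter first")
  n <- length(radical); nr <- sum(radical)
  structure(list(n_total = n, n_radical = nr,
                 pct_radical = round(100 * nr / n, 2)),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Substitution spectrum: %d of %d radical (%.2f%%)\n",
              x$n_radical, x$n_total, x$pct_radical))
  invisible(x)
}

#' Compare two substitution spectra (Fisher's exact test)
#'
#' Builds the 2x2 table (rows = groups, columns = radical / non-radical)
#' and delegates to [fisher_exact()].
#'
#' @param a,b `spectrum_summary` objects.
#' @return A `fisher_result`.
#' @export
compare_spectra <- function(a, b) {
  stopifnot(inherits(a, "spectrum_summary"), inherits(b, "spectrum_summary"))
  if (a$n_total == 0 || b$n_total == 0) stop("degenerate spectrum")
  fisher_exact(a$n_radical, a$n_total - a$n_radical,
               b$n_radical, b$n_total - b$n_radical)
}

#' Read a variant table of amino-acid changes
#'
#' Expects a TSV with header columns `position`, `gene`, `from_aa`,
#' `to_aa`, `frequency` (percent of reads supporting the variant, as in
#' resequencing exports). All rows are retained; a `classifiable` flag
#' marks the rows that enter a radical/conservative spectrum. Synonymous
#' rows (`from_aa == to_aa`), intergenic rows (empty/NA `gene` or residues)
#' and nonsense or stop-loss rows (`*` on either side) are flagged not
#' classifiable; nonsense rows additionally get `nonsense = TRUE`.
#'
#' @param path TSV path.
#' @param fixed_only If TRUE keep only rows at `frequency == 100` (variants
#'   fixed in the population).
#' @return Data frame with the input columns plus `synonymous`, `nonsense`,
#'   `intergenic`, `classifiable`, and the classification flags (NA where
#'   not classifiable).
#' @export
read_variant_table <- function(path, fixed_only = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("position", "gene", "from_aa", "to_aa", "frequency")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  if (fixed_only) df <- df[!is.na(df$frequency) & df$frequency == 100, ]
  if (nrow(df) == 0L) {
    df$synonymous <- df$nonsense <- df$intergenic <-
      df$classifiable <- df$radical <- logical(0)
    return(df)
  }
  df$intergenic <- is.na(df$gene) | is.na(df$from_aa) | is.na(df$to_aa)
  df$nonsense <- !df$intergenic &
    (df$from_aa == "*" | df$to_aa == "*")
  df$synonymous <- !df$intergenic & !df$nonsense &
    df$from_aa == df$to_aa
  df$classifiable <- !df$intergenic & !df$nonsense & !df$synonymous
  df$charge_change <- df$polarity_change <- df$polarity_volume_change <-
    df$radical <- NA
  if (any(df$classifiable)) {
    cl <- classify_substitution(df$from_aa[df$classifiable],
                                df$to_aa[df$classifiable])
    df$charge_change[df$classifiable] <- cl$charge_change
    df$polarity_change[df$classifiable] <- cl$polarity_change
    df$polarity_volume_change[df$classifiable] <- cl$polarity_volume_change
    df$radical[df$classifiable] <- cl$radical
  }
  df
}
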