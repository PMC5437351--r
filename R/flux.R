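# Genome-reduction accounting: insertion/deletion event ledgers stratified
# by coding vs intergenic regions, per-site per-generation nucleotide-loss
# rates, comparisons to reference endosymbiont loss rates, and the exact
# tests for deletion bias.

#' Build a coding/intergenic genome partition
#'
#' Coordinates are 1-based closed intervals (the GFF3 convention); the
#' partition covers `[1, genome_length]` with the complement of the merged
#' coding intervals labeled intergenic.
#'
#' @param coding_starts,coding_ends Integer vectors of coding intervals.
#' @param genome_length Genome size in bp.
#' @return Object of class `genome_annotation`: data frame of intervals
#'   (start, end, kind) plus the genome length.
#' @export
genome_annotation <- function(coding_starts, coding_ends, genome_length) {
  stopifnot(genome_length >= 1,
            length(coding_starts) == length(coding_ends))
  if (length(coding_starts)) {
    if (any(coding_starts < 1) || any(coding_ends > genome_length) ||
        any(coding_ends < coding_starts))
      stop("coding intervals outside [1, genome_length] or reversed")
    cod <- IRanges::reduce(IRanges::IRanges(coding_starts, coding_ends))
  } else {
    cod <- IRanges::IRanges()
  }
  inter <- IRanges::gaps(cod, start = 1L, end = as.integer(genome_length))
  df <- rbind(
    if (length(cod)) data.frame(start = IRanges::start(cod),
                                end = IRanges::end(cod), kind = "coding"),
    if (length(inter)) data.frame(start = IRanges::start(inter),
                                  end = IRanges::end(inter),
                                  kind = "intergenic")
  )
  df <- df[order(df$start), ]
  rownames(df) <- NULL
  structure(list(intervals = df, genome_length = as.integer(genome_length)),
            class = "genome_annotation")
}

#' Read coding intervals from a GFF3 file
#'
#' Imports the annotation with rtracklayer and uses the `CDS` features
#' (falling back to `gene` if no CDS rows exist) as the coding partition.
#'
#' @param path GFF3 path.
#' @param genome_length Genome size in bp; defaults to the maximum feature
#'   end coordinate.
#' @return A `genome_annotation`.
#' @export
read_annotation_gff <- function(path, genome_length = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  sel <- gr[types == "CDS"]
  if (length(sel) == 0L) sel <- gr[types == "gene"]
  if (length(sel) == 0L) stop("no CDS or gene features in ", path)
  if (is.null(genome_length))
    genome_length <- max(GenomicRanges::end(gr))
  genome_annotation(GenomicRanges::start(sel), GenomicRanges::end(sel),
                    genome_length)
}

#' Assign events to coding/intergenic regions
#'
#' Region is decided by the event's start position; an event spanning a
#' region boundary is assigned to its start region with a warning.
#'
#' @param positions Integer vector of 1-based start positions.
#' @param lengths Integer vector of event lengths (for boundary warnings).
#' @param annotation A `genome_annotation`.
#' @return Character vector, `"coding"` or `"intergenic"`.
#' @export
assign_region <- function(positions, lengths, annotation) {
  iv <- annotation$intervals
  if (any(positions < 1 | positions > annotation$genome_length))
    stop("event at position ",
         positions[which(positions < 1 |
                           positions > annotation$genome_length)[1L]],
         " is outside the genome [1, ", annotation$genome_length, "]")
  i <- findInterval(positions, iv$start)
  spans <- positions + pmax(lengths - 1L, 0L) > iv$end[i]
  if (any(spans))
    warning(sum(spans), " event(s) span a region boundary; ",
            "assigned to their start region")
  iv$kind[i]
}

#' Tally insertion/deletion events over a genome partition
#'
#' @param events Data frame with columns `position` (1-based bp), `kind`
#'   (`"insertion"`/`"deletion"`) and `length` (bp, >= 1).
#' @param annotation A `genome_annotation`.
#' @param generations Optional number of generations elapsed; with it the
#'   genome-wide deletion rate (nt per site per generation) is included.
#' @return Object of class `flux_summary` with event counts and nucleotide
#'   totals per kind x region.
#' @export
tally_indels <- function(events, annotation, generations = NULL) {
  stopifnot(all(c("position", "kind", "length") %in% names(events)))
  if (nrow(events)) {
    if (!all(events$kind %in% c("insertion", "deletion")))
      stop("event kind must be 'insertion' or 'deletion'")
    if (any(events$length < 1)) stop("event length must be >= 1")
    region <- assign_region(events$position, events$length, annotation)
  } else {
    region <- character(0)
  }
  kinds <- c("insertion", "deletion")
  regions <- c("coding", "intergenic")
  counts <- matrix(0L, 2, 2, dimnames = list(kinds, regions))
  nt <- matrix(0, 2, 2, dimnames = list(kinds, regions))
  for (k in kinds) for (r in regions) {
    sel <- events$kind == k & region == r
    counts[k, r] <- sum(sel)
    nt[k, r] <- sum(events$length[sel])
  }
  rate <- if (!is.null(generations))
    deletion_rate(sum(nt["deletion", ]), annotation$genome_length,
                  generations) else NA_real_
  structure(list(event_counts = counts, nucleotides = nt,
                 genome_size = annotation$genome_length,
                 generations = if (is.null(generations)) NA_real_
                               else generations,
                 deletion_rate = rate),
            class = "flux_summary")
}

#' @export
print.flux_summary <- function(x, ...) {
  cat("Indel flux over", x$genome_size, "bp genome\n")
  cat("  event counts:\n"); print(x$event_counts)
  cat("  nucleotides:\n"); print(x$nucleotides)
  if (!is.na(x$deletion_rate))
    cat(sprintf("  deletion rate: %.3g nt per site per generation (%g generations)\n",
                x$deletion_rate, x$generations))
  invisible(x)
}

#' Nucleotide-loss rate per site per generation
#'
#' @param deleted_nt Total deleted nucleotides.
#' @param genome_size Genome size in bp.
#' @param generations Generations elapsed.
#' @return `deleted_nt / (genome_size * generations)`.
#' @export
deletion_rate <- function(deleted_nt, genome_size, generations) {
  if (genome_size <= 0 || generations <= 0)
    stop("genome size and generations must be positive")
  if (deleted_nt < 0) stop("negative deleted nucleotide count")
  deleted_nt / (genome_size * generations)
}

#' Convert a per-year rate to per-generation
#'
#' @param rate_per_year Rate per site per year.
#' @param generations_per_year Generations per year (> 0); endosymbiotic
#'   bacteria are typically 15-50.
#' @return Rate per site per generation.
#' @export
per_year_to_per_generation <- function(rate_per_year, generations_per_year) {
  if (any(generations_per_year <= 0)) stop("generations per year must be > 0")
  rate_per_year / generations_per_year
}

#' Fold difference between a rate and a reference rate
#'
#' @param rate Observed rate.
#' @param reference Reference rate (> 0).
#' @return List with `fold` (integer part, matching the convention of
#'   reporting "x times greater") and `ratio` (real-valued).
#' @export
rate_ratio <- function(rate, reference) {
  if (reference <= 0) stop("reference rate must be positive")
  r <- rate / reference
  list(fold = floor(r), ratio = r)
}

#' Two-sided binomial test of insertion/deletion event balance
#'
#' @param n_insert,n_delete Event (or nucleotide) counts.
#' @return Two-sided exact binomial p-value against 0.5.
#' @export
test_event_balance <- function(n_insert, n_delete) {
  n <- n_insert + n_delete
  if (n < 1) stop("need at least one event")
  binom_test_two_sided(n_delete, n, 0.5)
}

#' Fisher test of coding-vs-intergenic deletion/insertion asymmetry
#'
#' Builds the 2x2 nucleotide-count table (rows = coding/intergenic,
#' columns = deleted/inserted) from a flux summary and delegates to
#' [fisher_exact()].
#'
#' @param summary A `flux_summary`.
#' @return A `fisher_result`.
#' @export
coding_vs_intergenic_test <- function(summary) {
  stopifnot(inherits(summary, "flux_summary"))
  nt <- summary$nucleotides
  fisher_exact(nt["deletion", "coding"], nt["insertion", "coding"],
               nt["deletion", "intergenic"], nt["insertion", "intergenic"])
}
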