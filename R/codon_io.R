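#' Read a FASTA file of coding sequences
#'
#' Reads a (possibly aligned) nucleotide FASTA file into a list of codon
#' sequences. Sequences are uppercased and record order is preserved.
#' Characters outside \{A, C, G, T, N, -\} are rejected. Length validation
#' (divisibility by 3) is deliberately deferred to
#' \code{\link{validate_codon_alignment}} so that raw CDS files with
#' trailing bases can still be inspected.
#'
#' @param path Path to a FASTA file.
#' @return A named list of character strings (one per record); names are the
#'   FASTA identifiers (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) return(structure(list(), names = character(0)))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN-]", seqs[i]))
    stop("illegal character '", ch, "' in record ", i,
         " ('", names(set)[i], "') of ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  stats::setNames(as.list(unname(seqs)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named list or character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Construct an ortholog pair of aligned codon sequences
#'
#' @param gene_id Gene identifier (unique within a lineage table).
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @param lineage Lineage tag, e.g. an endosymbiont group name or
#'   `"free_living"`.
#' @return An object of class `ortholog_pair`.
#' @export
ortholog_pair <- function(gene_id, seq_a, seq_b, lineage = NA_character_) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length (", nchar(seq_a),
         " vs ", nchar(seq_b), ") for gene ", gene_id)
  structure(
    list(gene_id = as.character(gene_id), seq_a = seq_a, seq_b = seq_b,
         lineage = as.character(lineage)),
    class = "ortholog_pair"
  )
}

#' @export
print.ortholog_pair <- function(x, ...) {
  cat("Ortholog pair '", x$gene_id, "' (", x$lineage, "), ",
      nchar(x$seq_a), " aligned bp\n", sep = "")
  invisible(x)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not divisible by 3")
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Uses an aligned amino-acid pair to guide the alignment of the two
#' ungapped coding sequences: each amino-acid column maps to one codon
#' column and protein gap columns become `---`. The ungapped CDS must
#' translate exactly to the ungapped protein row under the standard
#' (bacterial) genetic code; a terminal stop codon on either CDS is
#' stripped before checking.
#'
#' @param gene_id Gene identifier for the resulting pair.
#' @param prot_a,prot_b Aligned amino-acid strings (equal length, `-` gaps).
#' @param cds_a,cds_b Ungapped coding sequences.
#' @param lineage Lineage tag.
#' @return An `ortholog_pair` of aligned codons.
#' @export
build_codon_alignment <- function(gene_id, prot_a, prot_b, cds_a, cds_b,
                                  lineage = NA_character_) {
  prot_a <- toupper(prot_a); prot_b <- toupper(prot_b)
  if (nchar(prot_a) != nchar(prot_b))
    stop("protein alignment rows differ in length for gene ", gene_id)
  back <- function(prot, cds, label) {
    cds <- toupper(cds)
    codons <- split_codons(cds)
    # strip a terminal stop codon if present
    if (length(codons) && codon_is_stop(codons[length(codons)]))
      codons <- codons[-length(codons)]
    aas <- strsplit(gsub("-", "", prot), "")[[1L]]
    if (length(codons) != length(aas))
      stop("CDS ", label, " of gene ", gene_id, " has ", length(codons),
           " codons but its protein row has ", length(aas), " residues")
    trans <- translate_codons(codons)
    mism <- which(trans != aas)
    if (length(mism))
      stop("translation mismatch for gene ", gene_id, " (", label,
           ") at protein position ", mism[1L], ": codon ",
           codons[mism[1L]], " encodes ", trans[mism[1L]],
           " but alignment has ", aas[mism[1L]])
    cols <- strsplit(prot, "")[[1L]]
    out <- character(length(cols))
    out[cols == "-"] <- "---"
    out[cols != "-"] <- codons
    paste(out, collapse = "")
  }
  ortholog_pair(gene_id,
                back(prot_a, cds_a, "seq_a"),
                back(prot_b, cds_b, "seq_b"),
                lineage)
}

#' Validate and clean an aligned codon pair
#'
#' Removes codon columns that contain gaps, ambiguity characters, or an
#' internal stop codon in either sequence; a shared terminal stop column is
#' stripped silently. The operation is idempotent and never changes the
#' relative order of retained columns.
#'
#' @param pair An `ortholog_pair`.
#' @return The cleaned `ortholog_pair`, with an attribute `"report"`: a
#'   data frame of removed column indices (1-based codon positions in the
#'   input alignment) and reasons (`"gap"`, `"ambiguous"`, `"stop"`).
#' @export
validate_codon_alignment <- function(pair) {
  stopifnot(inherits(pair, "ortholog_pair"))
  ca <- split_codons(pair$seq_a)
  cb <- split_codons(pair$seq_b)
  n <- length(ca)
  if (n == 0L) stop("no analyzable codons in gene ", pair$gene_id)
  # terminal stop in both sequences: ordinary CDS, strip without reporting
  if (codon_is_stop(ca[n]) && codon_is_stop(cb[n])) {
    ca <- ca[-n]; cb <- cb[-n]; n <- n - 1L
    if (n == 0L) stop("no analyzable codons in gene ", pair$gene_id)
  }
  has_gap <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  has_amb <- (!has_gap) & (grepl("[^ACGT]", ca) | grepl("[^ACGT]", cb))
  is_stop <- (!has_gap) & (!has_amb) &
    (codon_is_stop(ca) | codon_is_stop(cb))
  reason <- rep(NA_character_, n)
  reason[is_stop] <- "stop"
  reason[has_amb] <- "ambiguous"
  reason[has_gap] <- "gap"
  drop <- !is.na(reason)
  report <- data.frame(column = which(drop), reason = reason[drop],
                       stringsAsFactors = FALSE)
  if (all(drop)) stop("no analyzable codons in gene ", pair$gene_id)
  out <- ortholog_pair(pair$gene_id,
                       paste(ca[!drop], collapse = ""),
                       paste(cb[!drop], collapse = ""),
                       pair$lineage)
  attr(out, "report") <- report
  out
}

#' Read a TSV ortholog map
#'
#' @param path TSV with header columns `gene_id`, `seq_id_a`, `seq_id_b`,
#'   `lineage`.
#' @return A data frame.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "seq_id_a", "seq_id_b", "lineage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ortholog map ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(paste(df$lineage, df$gene_id)))
    stop("duplicated gene_id within a lineage in ", path)
  df[need]
}

#' Assemble ortholog pairs from sequence files and a map
#'
#' @param map Data frame as returned by [read_ortholog_map()].
#' @param seqs Named list of sequences (e.g. from [read_fasta()]) containing
#'   every id referenced by the map.
#' @return A list of `ortholog_pair` objects.
#' @export
pairs_from_map <- function(map, seqs) {
  missing_ids <- setdiff(c(map$seq_id_a, map$seq_id_b), names(seqs))
  if (length(missing_ids))
    stop("sequences not found for ids: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  lapply(seq_len(nrow(map)), function(i)
    ortholog_pair(map$gene_id[i],
                  seqs[[map$seq_id_a[i]]],
                  seqs[[map$seq_id_b[i]]],
                  map$lineage[i]))
}
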