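# Genetic-code utilities shared by the dN/dS engine and the simulator.
# The standard code is used throughout; for bacterial CDSs it differs from
# NCBI table 11 only in initiation codons, which never matter here.

.sym <- new.env(parent = emptyenv())

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

genetic_code <- function() {
  if (is.null(.sym$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .sym$gc <- stats::setNames(as.character(gc), names(gc))
  }
  .sym$gc
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 non-stop codons.
#' @export
sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' Translate codons to one-letter amino acids
#'
#' @param codons Character vector of 3-mers over \{A,C,G,T\}.
#' @return Character vector of amino acids (`*` for stop).
#' @export
translate_codons <- function(codons) {
  gc <- genetic_code()
  aa <- unname(gc[codons])
  if (anyNA(aa))
    stop("not a valid codon: ", codons[which(is.na(aa))[1L]])
  aa
}

codon_is_stop <- function(codons) {
  gc <- genetic_code()
  aa <- unname(gc[codons])
  !is.na(aa) & aa == "*"
}

# All nine single-base neighbors of a codon, with the mutated position.
codon_neighbors <- function(codon) {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(codon, "")[[1L]]
  out <- character(0); pos <- integer(0)
  for (p in 1:3) {
    for (b in setdiff(bases, s[p])) {
      t <- s; t[p] <- b
      out <- c(out, paste(t, collapse = ""))
      pos <- c(pos, p)
    }
  }
  data.frame(codon = out, position = pos, stringsAsFactors = FALSE)
}

is_transition <- function(from_base, to_base) {
  purine <- c("A", "G")
  (from_base %in% purine) == (to_base %in% purine)
}
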