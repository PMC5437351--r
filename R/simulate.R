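# Synthetic-data generators: codon pairs diverged under a known omega,
# constrained-gene lists with a tunable convergence effect, substitution
# catalogs with a known radical fraction, and deletion-biased indel
# streams. Every generator is reproducible from its seed and is the stated
# input world for the package's tests.

#' Simulation configuration for a diverged codon pair
#'
#' @param n_codons Number of codons.
#' @param omega Nonsynonymous/synonymous rate ratio of the generating
#'   process.
#' @param kappa Transition/transversion rate ratio (default 1: NG86 is
#'   unbiased without transition bias, which is why recovery tests use it).
#' @param t Expected substitutions per codon summed over both branches
#'   (total divergence).
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_codons = 1000, omega = 0.2, kappa = 1, t = 0.4,
                       seed = 1L) {
  stopifnot(n_codons >= 1, omega >= 0, kappa > 0, t >= 0)
  structure(list(n_codons = as.integer(n_codons), omega = omega,
                 kappa = kappa, t = t, seed = as.integer(seed)),
            class = "sim_config")
}

# Rate bookkeeping for the codon substitution process: single-nucleotide
# changes only, rate kappa for transitions, times omega for nonsynonymous
# changes, rate 0 into stop codons. Rates are rescaled so the mean total
# leaving rate over a uniform distribution of sense codons is 1, making `t`
# an expected substitutions-per-codon branch length.
codon_process <- function(omega, kappa) {
  sc <- sense_codons()
  n <- length(sc)
  aa <- translate_codons(sc)
  nbr_idx <- matrix(0L, n, 9)
  rate <- matrix(0, n, 9)
  deg <- integer(n)
  for (i in seq_len(n)) {
    nb <- codon_neighbors(sc[i])
    keep <- !codon_is_stop(nb$codon)
    nbs <- nb$codon[keep]
    pos <- nb$position[keep]
    j <- match(nbs, sc)
    from_b <- substring(sc[i], pos, pos)
    to_b <- mapply(function(cd, p) substring(cd, p, p), nbs, pos,
                   USE.NAMES = FALSE)
    r <- ifelse(is_transition(from_b, to_b), kappa, 1)
    r <- r * ifelse(aa[j] == aa[i], 1, omega)
    deg[i] <- length(j)
    nbr_idx[i, seq_along(j)] <- j
    rate[i, seq_along(j)] <- r
  }
  tot <- rowSums(rate)
  scale <- mean(tot)
  if (scale == 0) scale <- 1  # omega = 0 with no synonymous exits impossible
  tot <- tot / scale
  prob <- rate / ifelse(rowSums(rate) > 0, rowSums(rate), 1)
  cum <- t(apply(prob, 1, cumsum))
  list(codons = sc, tot = tot, cum = cum, nbr = nbr_idx, deg = deg)
}

# Evolve integer codon states for time tlen under the process (Gillespie,
# vectorized over sites).
evolve_states <- function(state, proc, tlen) {
  if (tlen == 0) return(state)
  n <- length(state)
  t_acc <- stats::rexp(n) / proc$tot[state]
  idx <- which(t_acc < tlen & proc$tot[state] > 0)
  while (length(idx)) {
    u <- stats::runif(length(idx))
    row <- proc$cum[state[idx], , drop = FALSE]
    pick <- rowSums(row < u) + 1L
    pick <- pmin(pick, proc$deg[state[idx]])
    state[idx] <- proc$nbr[cbind(state[idx], pick)]
    t_acc[idx] <- t_acc[idx] + stats::rexp(length(idx)) / proc$tot[state[idx]]
    idx <- idx[t_acc[idx] < tlen]
  }
  state
}

#' Simulate an ortholog pair diverged under a known omega
#'
#' Draws an ancestor of sense codons uniformly and evolves two copies
#' independently for `t/2` each under a continuous-time codon process with
#' single-nucleotide changes (transition rate `kappa`, nonsynonymous rate
#' multiplied by `omega`, zero rate into stop codons). No stop codon is
#' ever emitted.
#'
#' @param config A [sim_config()].
#' @param gene_id Identifier for the returned pair.
#' @param lineage Lineage tag.
#' @return An `ortholog_pair` of equal-length gap-free codon sequences.
#' @export
simulate_codon_pair <- function(config, gene_id = "sim_gene",
                                lineage = "simulated") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  proc <- codon_process(config$omega, config$kappa)
  anc <- sample.int(length(proc$codons), config$n_codons, replace = TRUE)
  a <- evolve_states(anc, proc, config$t / 2)
  b <- evolve_states(anc, proc, config$t / 2)
  ortholog_pair(gene_id,
                paste(proc$codons[a], collapse = ""),
                paste(proc$codons[b], collapse = ""),
                lineage)
}

#' Simulate per-lineage constrained-gene lists with forced convergence
#'
#' Builds a shared gene namespace, draws each lineage's analyzed-gene
#' universe, and fills each constrained list with `n_shared` designated
#' convergent genes (present and constrained in every lineage) plus uniform
#' draws from the rest of that lineage's universe. `n_shared = 0` gives
#' pure null draws for calibration.
#'
#' @param universe_sizes Integer vector of per-lineage analyzed-gene counts
#'   (reference analysis: 483, 462, 514, 448, 348).
#' @param constrained_sizes Integer vector of constrained-list sizes.
#' @param n_shared Number of genes forced into every constrained list.
#' @param seed Integer seed.
#' @param namespace_size Size of the shared ortholog namespace (default:
#'   the largest universe).
#' @return A `lineage_gene_lists`.
#' @export
simulate_constraint_lists <- function(universe_sizes, constrained_sizes,
                                      n_shared = 0, seed = 1L,
                                      namespace_size = max(universe_sizes)) {
  L <- length(universe_sizes)
  if (length(constrained_sizes) != L)
    stop("one constrained size per lineage required")
  if (any(constrained_sizes > universe_sizes))
    stop("constrained size exceeds universe size")
  if (n_shared > min(constrained_sizes))
    stop("n_shared exceeds the smallest constrained list")
  if (namespace_size < max(universe_sizes))
    stop("namespace smaller than the largest universe")
  set.seed(seed)
  namespace <- sprintf("g%05d", seq_len(namespace_size))
  shared <- if (n_shared > 0) namespace[seq_len(n_shared)] else character(0)
  rest <- setdiff(namespace, shared)
  universes <- vector("list", L)
  constrained <- vector("list", L)
  for (i in seq_len(L)) {
    u <- c(shared, sample(rest, universe_sizes[i] - n_shared))
    extra <- sample(setdiff(u, shared), constrained_sizes[i] - n_shared)
    universes[[i]] <- u
    constrained[[i]] <- c(shared, extra)
  }
  names(universes) <- paste0("lineage", seq_len(L))
  lineage_gene_lists(universes, constrained)
}

#' Simulate a substitution catalog with a known radical fraction
#'
#' Draws amino-acid replacements from precomputed pools of radical and
#' non-radical ordered pairs (derived from the package's classification
#' tables) mixed at `p_radical`.
#'
#' @param n Number of substitutions.
#' @param p_radical Probability that a substitution is radical.
#' @param seed Integer seed.
#' @return Data frame as returned by [classify_substitution()].
#' @export
simulate_substitutions <- function(n, p_radical = 0.8, seed = 1L) {
  stopifnot(p_radical >= 0, p_radical <= 1, n >= 0)
  pairs <- expand.grid(from_aa = STANDARD_AA, to_aa = STANDARD_AA,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from_aa != pairs$to_aa, ]
  cl <- classify_substitution(pairs$from_aa, pairs$to_aa)
  rad_pool <- cl[cl$radical, ]
  con_pool <- cl[!cl$radical, ]
  set.seed(seed)
  is_rad <- stats::runif(n) < p_radical
  rows <- integer(n)
  rows[is_rad] <- sample.int(nrow(rad_pool), sum(is_rad), replace = TRUE)
  rows[!is_rad] <- sample.int(nrow(con_pool), sum(!is_rad), replace = TRUE)
  out <- rbind(rad_pool[rows[is_rad], ], con_pool[rows[!is_rad], ])
  out <- out[order(c(which(is_rad), which(!is_rad))), ]
  rownames(out) <- NULL
  out
}

#' Simulate a deletion-biased indel stream over a genome partition
#'
#' Events are placed uniformly on the genome, kinds drawn
#' Bernoulli(`p_deletion`), lengths 1 + Geometric with the requested mean;
#' an optional single large deletion is injected to emulate punctuated
#' losses of whole gene blocks. The coding partition is a single contiguous
#' block of the requested fraction, which is all the region-assignment
#' logic needs.
#'
#' @param genome_length Genome size in bp.
#' @param coding_fraction Fraction of the genome that is coding.
#' @param n_events Number of ordinary indel events.
#' @param p_deletion Probability an event is a deletion.
#' @param mean_length Mean indel length in bp (default 3: most observed
#'   events affect only a few nucleotides).
#' @param big_deletion Optional `c(position, length)` for one injected
#'   large deletion.
#' @param seed Integer seed.
#' @return List with `events` (data frame: position, kind, length) and
#'   `annotation` (a `genome_annotation`).
#' @export
simulate_indels <- function(genome_length = 1e6, coding_fraction = 0.85,
                            n_events = 100, p_deletion = 0.5,
                            mean_length = 3, big_deletion = NULL,
                            seed = 1L) {
  stopifnot(coding_fraction >= 0, coding_fraction <= 1,
            p_deletion >= 0, p_deletion <= 1, mean_length >= 1)
  set.seed(seed)
  coding_end <- round(genome_length * coding_fraction)
  annotation <- if (coding_end >= 1)
    genome_annotation(1L, coding_end, genome_length)
  else
    genome_annotation(integer(0), integer(0), genome_length)
  position <- sample.int(genome_length, n_events, replace = TRUE)
  kind <- ifelse(stats::runif(n_events) < p_deletion,
                 "deletion", "insertion")
  len <- 1L + stats::rgeom(n_events, prob = 1 / mean_length)
  events <- data.frame(position = position, kind = kind, length = len,
                       stringsAsFactors = FALSE)
  if (!is.null(big_deletion)) {
    events <- rbind(events,
                    data.frame(position = big_deletion[1L],
                               kind = "deletion",
                               length = big_deletion[2L]))
  }
  list(events = events, annotation = annotation)
}
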