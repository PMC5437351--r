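# Pairwise dN/dS by the Nei-Gojobori (1986) counting method: per-codon
# synonymous/nonsynonymous site fractions, pathway-averaged difference
# counts between codons, and Jukes-Cantor multiple-hit correction.

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each of the three positions the synonymous fraction is the number of
#' synonymous single-base neighbors divided by the number of non-stop
#' single-base neighbors at that position; stop-codon neighbors are excluded
#' from the denominator, so `S + N = 3` exactly for every sense codon.
#'
#' @param codon A sense codon (3-mer over A/C/G/T).
#' @return Named numeric vector `c(S =, N =)`.
#' @export
count_sites_ng86 <- function(codon) {
  codon <- toupper(codon)
  aa <- translate_codons(codon)
  if (aa == "*") stop("stop codon has no NG86 site counts: ", codon)
  nb <- codon_neighbors(codon)
  nb_aa <- translate_codons(nb$codon)
  S <- 0
  for (p in 1:3) {
    sel <- nb$position == p & nb_aa != "*"
    denom <- sum(sel)
    S <- S + sum(nb_aa[sel] == aa) / denom
  }
  c(S = S, N = 3 - S)
}

#' Pathway-averaged substitution counts between two codons (NG86)
#'
#' When the codons differ at `k` positions, the `k!` orderings of the
#' single-base steps are enumerated; orderings passing through a stop codon
#' are discarded and synonymous/nonsynonymous step counts are averaged over
#' the remaining ones. `sd + nd = k` whenever at least one stop-free
#' pathway exists.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(sd =, nd =)`; both `NA` if every pathway
#'   passes through a stop codon.
#' @export
count_differences_ng86 <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (any(codon_is_stop(c(codon_a, codon_b))))
    stop("stop codon in codon pair: ", codon_a, "/", codon_b)
  a <- strsplit(codon_a, "")[[1L]]
  b <- strsplit(codon_b, "")[[1L]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- list(1L)
  if (k == 2L) perms <- list(c(1L, 2L), c(2L, 1L))
  if (k == 3L) perms <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                             c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
  gc <- genetic_code()
  sd_tot <- 0; nd_tot <- 0; n_valid <- 0L
  for (ord in perms) {
    cur <- a
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in diff_pos[ord]) {
      from_aa <- gc[[paste(cur, collapse = "")]]
      cur[p] <- b[p]
      to_codon <- paste(cur, collapse = "")
      to_aa <- gc[[to_codon]]
      if (to_aa == "*") { ok <- FALSE; break }
      if (to_aa == from_aa) sd <- sd + 1 else nd <- nd + 1
    }
    if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd
              n_valid <- n_valid + 1L }
  }
  if (n_valid == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
}

# Memoized lookup tables over the 61 sense codons.
ng86_tables <- function() {
  if (is.null(.sym$ng86)) {
    sc <- sense_codons()
    n <- length(sc)
    S <- vapply(sc, function(cd) count_sites_ng86(cd)[["S"]], numeric(1))
    SD <- matrix(NA_real_, n, n, dimnames = list(sc, sc))
    ND <- SD
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d <- count_differences_ng86(sc[i], sc[j])
      SD[i, j] <- d[["sd"]]; ND[i, j] <- d[["nd"]]
    }
    .sym$ng86 <- list(codons = sc, S = S, SD = SD, ND = ND)
  }
  .sym$ng86
}

#' Jukes-Cantor correction of a proportion of differing sites
#'
#' @param p Proportion of sites differing, `0 <= p < 3/4`.
#' @return Corrected distance `d = -(3/4) log(1 - 4p/3)`; `NA` with a
#'   warning-free saturation semantics when `p >= 3/4` (callers set the
#'   `dS_saturated` flag).
#' @export
jukes_cantor_correct <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("negative proportion")
  d <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
  d[p == 0] <- 0
  d
}

#' Estimate pairwise dN, dS and omega for an ortholog pair
#'
#' Applies NG86 counting over a validated codon alignment: site counts are
#' averaged over the two sequences, pathway-averaged differences are summed
#' over codon columns, the proportions are Jukes-Cantor corrected, and
#' `omega = dN/dS`. Codon pairs whose every mutational pathway crosses a
#' stop codon are excluded from both site and difference totals.
#'
#' `omega` is reported as 0 when `dN = 0` and `dS > 0`, and is undefined
#' (`NA`) when `dS = 0` (flag `dS_zero`) or when `dS` exceeds
#' `saturation_ds` (flag `dS_saturated`; such genes are excluded from
#' downstream constraint ratios).
#'
#' @param pair An `ortholog_pair`; it is (re-)validated internally, which is
#'   a no-op on already clean alignments.
#' @param saturation_ds Saturation guard on dS (default 2).
#' @param min_codons Below this many analyzable codons the estimate carries
#'   a `too_short` flag (default 30); the estimate is still returned.
#' @return An object of class `omega_estimate`.
#' @export
estimate_omega <- function(pair, saturation_ds = 2, min_codons = 30) {
  clean <- validate_codon_alignment(pair)
  tab <- ng86_tables()
  ia <- match(split_codons(clean$seq_a), tab$codons)
  ib <- match(split_codons(clean$seq_b), tab$codons)
  sd <- tab$SD[cbind(ia, ib)]
  nd <- tab$ND[cbind(ia, ib)]
  blocked <- is.na(sd)
  keep <- !blocked
  n_codons <- sum(keep)
  flags <- character(0)
  if (any(blocked)) flags <- c(flags, "codons_excluded")
  if (n_codons == 0L) stop("no analyzable codons in gene ", pair$gene_id)
  if (n_codons < min_codons) flags <- c(flags, "too_short")
  S_sites <- (sum(tab$S[ia[keep]]) + sum(tab$S[ib[keep]])) / 2
  N_sites <- 3 * n_codons - S_sites
  sd_tot <- sum(sd[keep]); nd_tot <- sum(nd[keep])
  pS <- sd_tot / S_sites
  pN <- nd_tot / N_sites
  dS <- jukes_cantor_correct(pS)
  dN <- jukes_cantor_correct(pN)
  omega <- NA_real_
  if (is.na(dS) || (!is.na(dS) && dS > saturation_ds)) {
    flags <- c(flags, "dS_saturated")
  } else if (dS == 0) {
    flags <- c(flags, "dS_zero")
  } else if (is.na(dN)) {
    flags <- c(flags, "dN_saturated")
  } else {
    omega <- dN / dS
  }
  structure(
    list(gene_id = clean$gene_id, lineage = clean$lineage,
         n_codons = n_codons, n_codons_excluded = sum(blocked),
         S_sites = S_sites, N_sites = N_sites,
         syn_diffs = sd_tot, nonsyn_diffs = nd_tot,
         pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
         flags = flags),
    class = "omega_estimate"
  )
}

#' @export
print.omega_estimate <- function(x, ...) {
  cat("NG86 estimate for gene '", x$gene_id, "' (", x$n_codons,
      " codons)\n", sep = "")
  cat(sprintf("  dN = %.5f  dS = %.5f  omega = %s\n",
              x$dN, x$dS,
              if (is.na(x$omega)) "undefined" else sprintf("%.4f", x$omega)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate omega estimates
#'
#' @param estimates A list of `omega_estimate` objects.
#' @return A data frame with one row per gene, suitable for TSV export
#'   (columns gene_id, S_sites, N_sites, sd, nd, pS, pN, dS, dN, omega,
#'   flags).
#' @export
omega_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(gene_id = e$gene_id, n_codons = e$n_codons,
               S_sites = e$S_sites, N_sites = e$N_sites,
               sd = e$syn_diffs, nd = e$nonsyn_diffs,
               pS = e$pS, pN = e$pN, dS = e$dS, dN = e$dN,
               omega = e$omega,
               flags = paste(e$flags, collapse = ";"),
               stringsAsFactors = FALSE)))
}
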