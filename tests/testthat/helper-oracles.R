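# Independent brute-force oracles. These re-derive expected values from
# first principles and deliberately share no code with the package
# internals they check.

oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(oracle_code) <- names(Biostrings::GENETIC_CODE)

oracle_neighbors <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b != s[p]) { t <- s; t[p] <- b; out <- c(out, paste(t, collapse = "")) }
  }
  out
}

# NG86 over a whole alignment by literal enumeration: per-codon site
# fractions and full pathway enumeration (recursion over orderings).
oracle_ng86 <- function(seq_a, seq_b) {
  codons_a <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  codons_b <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  site_S <- function(codon) {
    aa <- oracle_code[codon]
    s <- 0
    chars <- strsplit(codon, "")[[1]]
    for (p in 1:3) {
      nb <- character(0)
      for (b in setdiff(c("A","C","G","T"), chars[p])) {
        t <- chars; t[p] <- b; nb <- c(nb, paste(t, collapse = ""))
      }
      nb <- nb[oracle_code[nb] != "*"]
      s <- s + sum(oracle_code[nb] == aa) / length(nb)
    }
    s
  }
  paths <- function(a, b) {
    da <- strsplit(a, "")[[1]]; db <- strsplit(b, "")[[1]]
    dp <- which(da != db)
    if (!length(dp)) return(list(list(sd = 0, nd = 0)))
    res <- list()
    for (p in dp) {
      nxt <- da; nxt[p] <- db[p]
      nxtc <- paste(nxt, collapse = "")
      if (oracle_code[nxtc] == "*") next
      step_syn <- oracle_code[nxtc] == oracle_code[a]
      for (sub in paths(nxtc, b)) {
        res[[length(res) + 1]] <- list(sd = sub$sd + as.numeric(step_syn),
                                       nd = sub$nd + as.numeric(!step_syn))
      }
    }
    res
  }
  S_tot <- 0; sd_tot <- 0; nd_tot <- 0; n_used <- 0
  for (i in seq_along(codons_a)) {
    pw <- paths(codons_a[i], codons_b[i])
    if (!length(pw)) next
    n_used <- n_used + 1
    S_tot <- S_tot + (site_S(codons_a[i]) + site_S(codons_b[i])) / 2
    sd_tot <- sd_tot + mean(vapply(pw, `[[`, numeric(1), "sd"))
    nd_tot <- nd_tot + mean(vapply(pw, `[[`, numeric(1), "nd"))
  }
  N_tot <- 3 * n_used - S_tot
  pS <- sd_tot / S_tot; pN <- nd_tot / N_tot
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S_tot, N = N_tot, sd = sd_tot, nd = nd_tot,
       pS = pS, pN = pN, dS = jc(pS), dN = jc(pN))
}

# Two-sided Fisher p by literal enumeration of all tables with the
# observed margins, using dhyper for the conditional density.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  supp <- max(0, k - n2):min(k, m)
  dens <- dhyper(supp, m, n2, k)
  p_obs <- dens[supp == a]
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

oracle_binom_p <- function(k, n, p0) {
  dens <- dbinom(0:n, n, p0)
  min(1, sum(dens[dens <= dens[k + 1] * (1 + 1e-7)]))
}

# Random clean sense-codon sequence pair for property tests.
random_codon_pair <- function(n_codons, n_mut = 5, seed = 1) {
  set.seed(seed)
  sc <- sense_codons()
  a <- sample(sc, n_codons, replace = TRUE)
  b <- a
  for (i in sample(seq_len(n_codons), min(n_mut, n_codons))) {
    repl <- sample(sc, 1)
    b[i] <- repl
  }
  ortholog_pair("rnd", paste(a, collapse = ""), paste(b, collapse = ""))
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

split_codons_for_test <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}
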