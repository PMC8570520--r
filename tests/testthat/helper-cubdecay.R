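# Shared fixtures, all built in code.

BASES4 <- c("A", "C", "G", "T")

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_stochastic_matrix <- function(concentration = 1) {
  m <- matrix(stats::rgamma(16, concentration), 4, 4,
              dimnames = list(BASES4, BASES4))
  m / rowSums(m)
}

# Left eigenvector oracle for the stationary vector, independent of the
# matrix-power route used by the package.
eigen_stationary <- function(p) {
  e <- eigen(t(p))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, BASES4)
}

# A reference set covering every synonymous family with a clear major codon,
# so fitness tables built from it are total.
reference_genes <- function(reps = 6) {
  fams <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  fams[["*"]] <- NULL
  codons <- unlist(lapply(fams, function(f) {
    f <- sort(f)
    c(rep(f[1], 4), f)  # first codon of each family is the major one
  }), use.names = FALSE)
  coding_sequence(strrep(paste(codons, collapse = ""), reps), id = "ref")
}

test_fitness <- function() fitness_table(reference_genes())

# Expected CAI when every codon is drawn uniformly within the set reachable
# from its ancestral codon by single-step synonymous mutations at mutable
# positions (enumeration oracle for the symmetric-kernel equilibrium).
syn_component_oracle <- function(ancestor, table) {
  gc_map <- Biostrings::GENETIC_CODE
  codons <- substring(ancestor$nt, seq(1, ancestor$length, 3),
                      seq(3, ancestor$length, 3))
  n <- length(codons)
  w <- unclass(table)
  scorable <- !is.na(w[codons])
  L0 <- sum(scorable)
  component <- function(codon, allowed_pos) {
    aa <- gc_map[[codon]]
    seen <- codon
    queue <- codon
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      b <- strsplit(cur, "")[[1]]
      for (p in allowed_pos) for (nb in setdiff(BASES4, b[p])) {
        cand <- b; cand[p] <- nb
        cand <- paste(cand, collapse = "")
        if (gc_map[[cand]] == aa && !cand %in% seen) {
          seen <- c(seen, cand); queue <- c(queue, cand)
        }
      }
    }
    seen
  }
  expo <- 1 / L0
  factors <- vapply(seq_len(n), function(i) {
    if (!scorable[i]) return(1)
    allowed <- if (i == 1) 2:3 else if (i == n) 1:2 else 1:3
    comp <- component(codons[i], allowed)
    mean(w[comp]^expo)
  }, numeric(1))
  prod(factors)
}

# Expected CAI for uniform synonymous usage given a protein (full families,
# no single-step restriction).
uniform_family_oracle <- function(protein, table) {
  gc_map <- Biostrings::GENETIC_CODE
  fams <- split(names(gc_map), gc_map)
  fams[["*"]] <- NULL
  w <- unclass(table)
  aa <- strsplit(protein, "")[[1]]
  per_aa <- lapply(fams, function(f) w[f][!is.na(w[f])])
  L0 <- sum(vapply(aa, function(a) length(per_aa[[a]]) > 0, logical(1)))
  expo <- 1 / L0
  prod(vapply(aa, function(a) {
    wf <- per_aa[[a]]
    if (length(wf) == 0) 1 else mean(wf^expo)
  }, numeric(1)))
}
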