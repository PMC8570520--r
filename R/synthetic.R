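## Synthetic inputs for every pipeline stage: noncoding triplets evolved under
## a known context-dependent model, and coding sequences with controlled bias
## toward a fitness table's major codons.  These generators define the test
## bed for parameter-recovery and simulator checks without any external data.

#' Neutrally evolve a nucleotide sequence under a mutation model
#'
#' Applies the same proposal kernel as the decay simulator -- uniform interior
#' site, derived base drawn from the current context's probability row,
#' self-draws discarded -- with no coding constraint, until a target number of
#' substitutions has been applied. By default the target is Poisson with mean
#' `expected_subs_per_site` times the number of interior sites.
#'
#' @param nt Nucleotide string over A, C, G, T.
#' @param model A `"mutation_model"`.
#' @param expected_subs_per_site Expected substitutions per site (small, so
#'   multiple hits stay rare).
#' @param n_target Optional fixed substitution count overriding the Poisson
#'   draw.
#' @return The mutated nucleotide string.
#' @export
evolve_neutral <- function(nt, model, expected_subs_per_site,
                           n_target = NULL) {
  stopifnot(inherits(model, "mutation_model"), expected_subs_per_site >= 0)
  s <- encode_bases(nt)
  if (anyNA(s)) stop("sequence must contain only A, C, G, T")
  if (is.null(n_target))
    n_target <- stats::rpois(1L, expected_subs_per_site * (length(s) - 2L))
  if (n_target == 0L) return(toupper(nt))
  res <- cpp_evolve(s - 1L, model_prob_vector(model), as.integer(n_target),
                    max_proposals = max(1e7, 1e4 * n_target))
  decode_bases(res$seq + 1L)
}

#' Draw a random root sequence from a model's stationary composition
#'
#' Base frequencies are the model's stationary vectors averaged over the ten
#' canonical contexts -- a context-free approximation adequate for seeding
#' neutral evolution.
#'
#' @param n Sequence length (nt).
#' @param model A `"mutation_model"`.
#' @return Nucleotide string of length `n`.
#' @export
random_root <- function(n, model) {
  pi_bar <- colMeans(stationary_vector(model))
  paste(sample(BASES, n, replace = TRUE, prob = pi_bar), collapse = "")
}

#' Generate synthetic noncoding triplet alignments
#'
#' Per region, draws a root from the model's average stationary composition
#' and evolves the outgroup and the two ingroup sequences on independent
#' branches. No indels are introduced, so the evolved sequences are already
#' aligned and every column is comparable.
#'
#' @param n_regions Number of regions.
#' @param region_length Region length in nt.
#' @param model The generating `"mutation_model"`.
#' @param ingroup_subs Expected substitutions/site on each ingroup branch
#'   (default 0.005; low enough that multiple hits are negligible).
#' @param outgroup_subs Expected substitutions/site on the outgroup branch
#'   (default 0.01).
#' @param seed Optional seed.
#' @return List of [triplet_alignment()] objects.
#' @export
generate_triplets <- function(n_regions, region_length, model,
                              ingroup_subs = 0.005, outgroup_subs = 0.01,
                              seed = NULL) {
  stopifnot(ingroup_subs >= 0, outgroup_subs >= 0)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_regions), function(i) {
    root <- random_root(region_length, model)
    triplet_alignment(
      in1 = evolve_neutral(root, model, ingroup_subs),
      in2 = evolve_neutral(root, model, ingroup_subs),
      outg = evolve_neutral(root, model, outgroup_subs),
      region_id = sprintf("synth_%04d", i)
    )
  })
}

#' Generate a coding sequence with controlled codon bias
#'
#' Draws a random protein (first residue Met) and, within each residue's
#' synonymous family, a codon with probability proportional to `w^beta`:
#' `beta = 0` gives uniform synonymous usage, large `beta` concentrates on the
#' family's maximum-fitness codons, so the generated CAI increases with
#' `beta`.
#'
#' @param n_codons Protein length in codons.
#' @param table A [fitness_table()] supplying the w values.
#' @param beta Bias strength (>= 0).
#' @param seed Optional seed.
#' @param id Sequence identifier.
#' @return A [coding_sequence()].
#' @export
generate_coding <- function(n_codons, table, beta, seed = NULL,
                            id = sprintf("synthetic_b%g", beta)) {
  stopifnot(inherits(table, "fitness_table"), beta >= 0, n_codons >= 2)
  if (!is.null(seed)) set.seed(seed)
  aa <- c("M", sample(AA_LETTERS, n_codons - 1L, replace = TRUE))
  fams <- codon_family()
  w <- unclass(table)
  codons <- vapply(aa, function(a) {
    fam <- fams[[a]]
    if (length(fam) == 1L) return(fam)
    wf <- w[fam]
    wf[is.na(wf)] <- 1
    p <- exp(beta * log(wf))
    p <- p / sum(p)
    sample(fam, 1L, prob = p)
  }, character(1))
  coding_sequence(paste(codons, collapse = ""), id = id)
}

#' A fixed heterogeneous context-dependent model for validation and demos
#'
#' Deterministically constructed probability matrices with context-varying
#' transition:transversion ratio (`ts`), overall rate (`s`, off-diagonal row
#' mass, with G/C ancestral bases mutating at 0.8 of the A/T rate) and a bias
#' `g` multiplying rates into G/C targets, so the ten contexts differ in
#' Ts:Tv, substitution rate and stationary G+C -- the qualitative features a
#' context-dependent chloroplast model displays. Useful as a known generating
#' model for parameter-recovery exercises.
#'
#' @return A `"mutation_model"` of kind `"MC"`.
#' @export
example_context_model <- function() {
  params <- data.frame(
    context = canonical_contexts(),
    ts = c(1.0, 2.2, 1.0, 2.0, 4.0, 1.7, 1.1, 3.0, 3.0, 1.4),
    s  = c(0.95, 0.66, 0.96, 0.59, 0.79, 0.98, 0.61, 0.83, 1.00, 0.76),
    g  = c(0.55, 0.75, 0.75, 0.90, 1.05, 1.00, 0.70, 1.35, 1.55, 1.20)
  )
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  mats <- lapply(seq_len(nrow(params)), function(k) {
    p <- params[k, ]
    m <- matrix(0, 4L, 4L, dimnames = list(BASES, BASES))
    for (b in BASES) {
      rate <- vapply(setdiff(BASES, b), function(d) {
        r <- if (d == transition[[b]]) p$ts else 1
        if (d %in% c("C", "G")) r * p$g else r
      }, numeric(1))
      mass <- p$s * if (b %in% c("C", "G")) 0.8 else 1
      m[b, setdiff(BASES, b)] <- mass * rate / sum(rate)
      m[b, b] <- 1 - mass
    }
    m
  })
  mutation_model(stats::setNames(mats, params$context), kind = "MC",
                 normalization_scale = 1)
}
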