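## Base and flanking-context bookkeeping shared across the package.
##
## Bases are indexed A=1, C=2, G=3, T=4 so that the Watson-Crick complement
## is simply 5 - i.  A flanking context "N_N" names the 5' and 3' neighbours
## of a site; its complement is the reverse-complemented pair, so the 16
## contexts collapse to 10 canonical ones for strand-symmetric counting.

BASES <- c("A", "C", "G", "T")

#' The ten canonical flanking-base contexts
#'
#' A site's mutational context is written `N_N` for its immediate 5' and 3'
#' neighbours. Complementary contexts (e.g. `A_A` and `T_T`) describe the same
#' double-stranded neighbourhood read from opposite strands, so substitution
#' counts are pooled into 10 canonical contexts; four of them (`A_T`, `T_A`,
#' `C_G`, `G_C`) are their own complement.
#'
#' @return Character vector of the 10 canonical context labels.
#' @seealso [context_complement()], [merge_complements()]
#' @export
#' @examples
#' canonical_contexts()
canonical_contexts <- function() {
  c("A_A", "A_T", "T_A", "A_C", "A_G", "C_A", "G_A", "C_C", "C_G", "G_C")
}

all_contexts <- function() {
  as.vector(t(outer(BASES, BASES, function(a, b) paste(a, b, sep = "_"))))
}

comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

#' Complement of a flanking context
#'
#' The complement of context `N5_N3` is `comp(N3)_comp(N5)`: reading the same
#' two neighbours on the opposite strand reverses their order and complements
#' each base.
#'
#' @param context Context label such as `"C_T"`.
#' @return The complementary context label (e.g. `"A_G"`).
#' @export
#' @examples
#' context_complement("C_T")  # "A_G"
#' context_complement("A_T")  # self-complementary
context_complement <- function(context) {
  parts <- strsplit(context, "_", fixed = TRUE)
  vapply(parts, function(p) {
    stopifnot(length(p) == 2L, all(p %in% BASES))
    paste(unname(comp_base(p[2L])), unname(comp_base(p[1L])), sep = "_")
  }, character(1))
}

## For every one of the 16 contexts: its canonical representative and whether
## reaching it requires the complement transform.
context_canonical_map <- function() {
  ctx <- all_contexts()
  canon <- canonical_contexts()
  data.frame(
    context = ctx,
    canonical = ifelse(ctx %in% canon, ctx, context_complement(ctx)),
    complemented = !(ctx %in% canon),
    stringsAsFactors = FALSE
  )
}

#' Relabel a 4x4 matrix by base complementation
#'
#' Maps entry (i, j) to (comp(i), comp(j)); used when pooling a count matrix
#' with the matrix of its complementary context, and when serving a
#' non-canonical context from its canonical matrix. The transform is an
#' involution.
#'
#' @param m A 4x4 matrix with rows/columns in A, C, G, T order.
#' @return The relabelled 4x4 matrix.
#' @export
complement_transform <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  out <- m[4:1, 4:1]
  dimnames(out) <- list(BASES, BASES)
  out
}

empty_count_matrix <- function() {
  matrix(0L, 4L, 4L, dimnames = list(BASES, BASES))
}

## Encode a nucleotide character vector to 1..4 (NA for anything else,
## including gaps and IUPAC ambiguity codes).
encode_bases <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) x <- strsplit(x, "")[[1L]]
  match(toupper(x), BASES)
}

decode_bases <- function(i) paste(BASES[i], collapse = "")
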