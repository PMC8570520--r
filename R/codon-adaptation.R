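## Codon fitness tables and the Codon Adaptation Index.
##
## Relative adaptiveness w of a codon is its count in a set of reference
## genes under strong translational selection, relative to the most-used
## synonym in its family.  CAI of a gene is the geometric mean of w over its
## codons.  Single-codon families (Met, Trp) and stop codons carry no
## information about synonymous choice and are excluded throughout.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]
EXCLUDED_CODONS <- c("ATG", "TGG", STOP_CODONS)
AA_LETTERS <- sort(unique(GENETIC_CODE_TABLE[GENETIC_CODE_TABLE != "*"]))

all_codons <- function() names(GENETIC_CODE_TABLE)

codon_family <- function() {
  fam <- split(names(GENETIC_CODE_TABLE), GENETIC_CODE_TABLE)
  fam[["*"]] <- NULL
  fam
}

#' Construct an in-frame coding sequence
#'
#' Validates frame (length divisible by 3) and the absence of internal stop
#' codons; start/stop codons are not required.
#'
#' @param nt Nucleotide string over A, C, G, T.
#' @param id Sequence identifier.
#' @return An object of class `"coding_sequence"`.
#' @export
coding_sequence <- function(nt, id = "seq") {
  nt <- toupper(nt)
  if (nchar(nt) %% 3L != 0L)
    stop("coding sequence length (", nchar(nt), ") is not divisible by 3")
  if (grepl("[^ACGT]", nt))
    stop("coding sequence contains non-ACGT symbols; use resolve_ambiguities()",
         " for IUPAC-ambiguous ancestors")
  aa <- translate_cds(nt)
  internal <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", internal, fixed = TRUE))
    stop("internal stop codon in coding sequence '", id, "'")
  structure(list(id = id, nt = nt, length = nchar(nt)),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("Coding sequence '", x$id, "': ", x$length, " nt (",
      x$length / 3L, " codons)\n", sep = "")
  invisible(x)
}

codons_of <- function(nt) {
  if (inherits(nt, "coding_sequence")) nt <- nt$nt
  n <- nchar(nt)
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate an in-frame nucleotide sequence
#'
#' @param nt Nucleotide string (or `"coding_sequence"`); standard genetic
#'   code, stops rendered as `*`.
#' @return Amino acid string.
#' @export
translate_cds <- function(nt) {
  paste(GENETIC_CODE_TABLE[codons_of(nt)], collapse = "")
}

#' Estimate codon relative adaptiveness from reference genes
#'
#' Pools codon counts over the reference sequences and, within each
#' synonymous family (families defined by amino acid, with the sixfold
#' Leu/Ser/Arg families kept whole), assigns
#' `w(c) = (count(c) + pseudocount) / (max family count + pseudocount)`.
#' The most-used codon of each family keeps `w = 1` exactly, and unobserved
#' codons receive a small positive value instead of zero. Single-codon
#' families, stop codons, and families never observed in the references are
#' omitted.
#'
#' @param refs A `"coding_sequence"`, list of them, or character vector of
#'   in-frame sequences (e.g. highly expressed genes under strong
#'   translational selection).
#' @param pseudocount Pseudocount applied to every codon count (default 0.5).
#' @return An object of class `"fitness_table"`: a named numeric vector of w
#'   values with attributes `excluded` and `pseudocount`.
#' @export
#' @examples
#' ft <- fitness_table(coding_sequence("TTCTTCTTT"))
#' ft[["TTC"]]  # 1
fitness_table <- function(refs, pseudocount = 0.5) {
  if (inherits(refs, "coding_sequence")) refs <- list(refs)
  if (is.character(refs)) refs <- lapply(refs, coding_sequence)
  if (length(refs) == 0L) stop("at least one reference sequence is required")
  stopifnot(all(vapply(refs, inherits, logical(1), "coding_sequence")))
  codons <- unlist(lapply(refs, codons_of))
  counts <- table(factor(codons, levels = all_codons()))
  w <- numeric(0)
  for (fam in codon_family()) {
    fam <- setdiff(fam, EXCLUDED_CODONS)
    if (length(fam) < 2L) next
    cmax <- max(counts[fam])
    if (cmax == 0) next  # family unobserved in the references: unscorable
    w[fam] <- (as.numeric(counts[fam]) + pseudocount) / (cmax + pseudocount)
  }
  if (any(w <= 0))
    stop("non-positive fitness value; use a positive pseudocount when ",
         "reference genes do not use every codon")
  if (length(w)) w <- w[order(names(w))]
  structure(w, class = "fitness_table",
            excluded = EXCLUDED_CODONS, pseudocount = pseudocount)
}

#' @export
print.fitness_table <- function(x, ...) {
  cat("Codon fitness table:", length(x), "codons",
      sprintf("(pseudocount %g)\n", attr(x, "pseudocount")))
  major <- names(x)[unclass(x) == 1]
  cat("  major codons:", paste(major, collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.fitness_table` <- function(x, ...) {
  out <- NextMethod()
  attributes(out) <- attributes(x)[c("names", "excluded", "pseudocount")]
  out
}

#' Codon Adaptation Index
#'
#' Geometric mean of the relative adaptiveness w over the sequence's codons:
#' `CAI = exp(mean(log w))`. Codons absent from the fitness table (Met, Trp,
#' stops) are skipped.
#'
#' @param seq A `"coding_sequence"` or nucleotide string.
#' @param table A [fitness_table()].
#' @return CAI in (0, 1].
#' @export
#' @examples
#' ft <- fitness_table(coding_sequence(strrep("TTCGAA", 10)))
#' cai("TTCTTC", ft)
cai <- function(seq, table) {
  stopifnot(inherits(table, "fitness_table"), length(table) > 0L)
  codons <- codons_of(seq)
  w <- unclass(table)[codons]
  w <- w[!is.na(w)]
  if (length(w) == 0L)
    stop("sequence has no codons scorable by the fitness table")
  exp(mean(log(w)))
}

IUPAC_EXPANSION <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(strsplit(map, ""), function(b) sort(b))
})

#' Resolve IUPAC ambiguities toward extreme codon fitness
#'
#' Reconstructed ancestral sequences may carry IUPAC ambiguity codes. Each
#' ambiguous site is resolved (left to right, other sites held at their
#' current resolution) to the expansion base whose resulting codon has the
#' highest (`mode = "high"`) or lowest (`mode = "low"`) fitness, bracketing
#' the ancestral codon adaptation from above and below. Bases yielding stop
#' codons are disallowed; codons without a table entry (Met, Trp) count as
#' fitness 1, their family maximum; ties go to the alphabetically earlier
#' base.
#'
#' @param seq Nucleotide string over IUPAC codes, length divisible by 3.
#' @param table A [fitness_table()].
#' @param mode `"high"` or `"low"`.
#' @param id Identifier for the returned sequence.
#' @return A `"coding_sequence"`.
#' @export
#' @examples
#' ft <- fitness_table(coding_sequence(strrep("TTC", 9)))
#' resolve_ambiguities("TTY", ft, mode = "high")$nt  # "TTC"
resolve_ambiguities <- function(seq, table, mode = c("high", "low"),
                                id = "resolved") {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "fitness_table"))
  nt <- strsplit(toupper(seq), "")[[1L]]
  if (length(nt) %% 3L != 0L)
    stop("sequence length is not divisible by 3")
  bad <- setdiff(unique(nt), names(IUPAC_EXPANSION))
  if (length(bad)) stop("unknown symbol(s): ", paste(bad, collapse = ", "))
  w_of <- function(codon) {
    aa <- GENETIC_CODE_TABLE[[codon]]
    if (aa == "*") return(NA_real_)
    w <- unclass(table)[codon]
    if (is.na(w)) 1 else unname(w)  # single-codon family: at its maximum
  }
  for (i in seq_along(nt)) {
    cand <- IUPAC_EXPANSION[[nt[i]]]
    if (length(cand) < 2L && nt[i] %in% BASES) next
    ci <- (i - 1L) %/% 3L
    codon_pos <- (i - 1L) %% 3L + 1L
    current <- nt[(ci * 3L + 1L):(ci * 3L + 3L)]
    ws <- vapply(cand, function(b) {
      cod <- current
      cod[codon_pos] <- b
      if (any(!cod %in% BASES)) {
        # other ambiguous positions of the codon not yet resolved: take the
        # best/worst over their expansions so the scan remains well-defined
        grid <- expand.grid(lapply(cod, function(s) IUPAC_EXPANSION[[s]]),
                            stringsAsFactors = FALSE)
        vals <- apply(grid, 1L, function(g) w_of(paste(g, collapse = "")))
        vals <- vals[!is.na(vals)]
        if (length(vals) == 0L) return(NA_real_)
        if (mode == "high") max(vals) else min(vals)
      } else {
        w_of(paste(cod, collapse = ""))
      }
    }, numeric(1))
    ok <- !is.na(ws)
    if (!any(ok))
      stop("all expansions at position ", i, " produce stop codons")
    cand <- cand[ok]; ws <- ws[ok]
    pick <- if (mode == "high") cand[which.max(ws)] else cand[which.min(ws)]
    nt[i] <- pick  # candidates are sorted, so which.* ties break alphabetically
  }
  coding_sequence(paste(nt, collapse = ""), id = id)
}

#' Read coding sequences from FASTA
#'
#' @param file FASTA path.
#' @return Named list of `"coding_sequence"` objects.
#' @export
read_coding_fasta <- function(file) {
  seqs <- Biostrings::readBStringSet(file)
  out <- lapply(seq_along(seqs), function(i)
    coding_sequence(as.character(seqs[[i]]), id = names(seqs)[i]))
  stats::setNames(out, names(seqs))
}

#' Write coding sequences to FASTA
#'
#' @param seqs A `"coding_sequence"` or list of them.
#' @param file Output path.
#' @export
write_coding_fasta <- function(seqs, file) {
  if (inherits(seqs, "coding_sequence")) seqs <- list(seqs)
  ids <- vapply(seqs, function(s) s$id, character(1))
  nts <- vapply(seqs, function(s) s$nt, character(1))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(nts, ids)), file)
  invisible(file)
}

#' Fitness table serialization
#'
#' Two-column TSV (`codon`, `w`) or JSON; both round-trip exactly.
#'
#' @param table A [fitness_table()].
#' @param path Output path.
#' @export
write_fitness_tsv <- function(table, path) {
  stopifnot(inherits(table, "fitness_table"))
  utils::write.table(
    data.frame(codon = names(table), w = format(unclass(table), digits = 17)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fitness_tsv
#' @export
read_fitness_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "w") %in% names(tab)))
  structure(stats::setNames(as.numeric(tab$w), tab$codon),
            class = "fitness_table", excluded = EXCLUDED_CODONS,
            pseudocount = NA_real_)
}

#' @rdname write_fitness_tsv
#' @export
write_fitness_json <- function(table, path) {
  stopifnot(inherits(table, "fitness_table"))
  jsonlite::write_json(as.list(unclass(table)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fitness_tsv
#' @export
read_fitness_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(unlist(obj), class = "fitness_table",
            excluded = EXCLUDED_CODONS, pseudocount = NA_real_)
}
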