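## Scoring noncoding triplet alignments into context-dependent substitution
## count matrices.  A triplet is two closely related ingroup sequences plus an
## outgroup used to polarize observed differences.

#' Construct a triplet alignment
#'
#' Holds three aligned noncoding sequences: an ingroup pair whose differences
#' are the substitutions being counted, and an outgroup used to infer which
#' ingroup base is ancestral. Sequences must be equal-length aligned strings
#' over `A`, `C`, `G`, `T` and `-`; any other IUPAC symbol is tolerated but the
#' affected columns are skipped during scoring.
#'
#' @param in1,in2 Aligned ingroup sequences (single strings).
#' @param outg Aligned outgroup sequence.
#' @param region_id Identifier for the noncoding region.
#' @return An object of class `"triplet_alignment"`.
#' @export
#' @examples
#' triplet_alignment("ACGTA", "ACATA", "ACGTA", region_id = "r1")
triplet_alignment <- function(in1, in2, outg, region_id = "region") {
  seqs <- toupper(c(in1 = unname(in1), in2 = unname(in2), outg = unname(outg)))
  n <- unique(nchar(seqs))
  if (length(n) != 1L)
    stop("malformed alignment: sequences have unequal aligned lengths (",
         paste(nchar(seqs), collapse = ", "), ")")
  structure(
    list(region_id = region_id, in1 = seqs[["in1"]], in2 = seqs[["in2"]],
         outg = seqs[["outg"]], aligned_length = n),
    class = "triplet_alignment"
  )
}

#' @export
print.triplet_alignment <- function(x, ...) {
  cat("Triplet alignment '", x$region_id, "': ", x$aligned_length,
      " aligned columns, ungapped length ", ungapped_length(x), "\n", sep = "")
  invisible(x)
}

## Ungapped length of the shortest member; the basis of the region-length
## filter.
ungapped_length <- function(aln) {
  min(vapply(c(aln$in1, aln$in2, aln$outg),
             function(s) nchar(gsub("-", "", s, fixed = TRUE)), numeric(1)))
}

#' Score a triplet alignment into 16 context count matrices
#'
#' Walks the interior columns of the alignment and tallies each scoreable site
#' into the 4x4 count matrix of its flanking-base context. A column is
#' scoreable only when its two flanking columns are identical across all three
#' sequences and free of gaps/ambiguities (a conserved context) and the focal
#' column itself is a plain base in all three. Conserved ingroup sites add to
#' the diagonal of the ancestral base; ingroup differences are polarized by
#' the outgroup (ancestral = the ingroup base matching the outgroup) and add
#' to the corresponding off-diagonal cell; sites where all three sequences
#' differ are ignored.
#'
#' Regions whose ungapped length is not strictly greater than `min_region_len`
#' contribute nothing: short regions are too alignment-uncertain to score.
#'
#' @param aln A [triplet_alignment()].
#' @param min_region_len Minimum ungapped region length (strict; default 70).
#' @return Named list of 16 integer 4x4 matrices, one per context `N_N`,
#'   rows = ancestral base, columns = derived base.
#' @seealso [merge_complements()] to pool complementary contexts.
#' @export
#' @examples
#' aln <- triplet_alignment("ACGTA", "ACATA", "ACGTA")
#' raw <- score_triplet(aln, min_region_len = 0)
#' raw[["C_T"]]["G", "A"]  # the single polarized substitution
score_triplet <- function(aln, min_region_len = 70) {
  stopifnot(inherits(aln, "triplet_alignment"))
  raw <- stats::setNames(rep(list(empty_count_matrix()), 16L), all_contexts())
  n <- aln$aligned_length
  if (n < 3L || ungapped_length(aln) <= min_region_len) return(raw)

  s1 <- encode_bases(aln$in1)
  s2 <- encode_bases(aln$in2)
  so <- encode_bases(aln$outg)

  ok <- !is.na(s1) & !is.na(s2) & !is.na(so)        # plain A/C/G/T in all three
  cons <- ok & s1 == s2 & s1 == so                  # identical across all three

  i <- 2:(n - 1L)                                   # interior columns only
  ctx_ok <- cons[i - 1L] & cons[i + 1L] & ok[i]
  if (!any(ctx_ok)) return(raw)

  i <- i[ctx_ok]
  f5 <- s1[i - 1L]
  f3 <- s1[i + 1L]
  a1 <- s1[i]; a2 <- s2[i]; ao <- so[i]

  same <- a1 == a2
  anc <- integer(length(i)); der <- integer(length(i)); keep <- logical(length(i))
  # conserved ingroup pair: diagonal, regardless of the outgroup base
  anc[same] <- a1[same]; der[same] <- a1[same]; keep[same] <- TRUE
  # ingroup difference: polarize by the outgroup if it matches one ingroup base
  d <- !same & (ao == a1 | ao == a2)
  anc[d] <- ifelse(ao[d] == a1[d], a1[d], a2[d])
  der[d] <- ifelse(ao[d] == a1[d], a2[d], a1[d])
  keep[d] <- TRUE
  # all three different: ignored

  if (!any(keep)) return(raw)
  idx <- ((f5[keep] - 1L) * 4L + (f3[keep] - 1L)) * 16L +
    (anc[keep] - 1L) * 4L + der[keep]
  tab <- tabulate(idx, nbins = 256L)
  ctx <- all_contexts()
  for (k in seq_len(16L)) {
    block <- tab[((k - 1L) * 16L + 1L):(k * 16L)]
    if (any(block > 0L))
      raw[[ctx[k]]] <- matrix(as.integer(block), 4L, 4L, byrow = TRUE,
                              dimnames = list(BASES, BASES))
  }
  raw
}

#' Score a batch of triplet alignments
#'
#' Applies [score_triplet()] to each alignment and sums the per-region raw
#' matrices elementwise.
#'
#' @param alns List of [triplet_alignment()] objects.
#' @inheritParams score_triplet
#' @return Named list of 16 pooled count matrices.
#' @export
score_triplets <- function(alns, min_region_len = 70) {
  raw <- stats::setNames(rep(list(empty_count_matrix()), 16L), all_contexts())
  for (aln in alns) {
    r <- score_triplet(aln, min_region_len = min_region_len)
    for (ctx in names(raw)) raw[[ctx]] <- raw[[ctx]] + r[[ctx]]
  }
  raw
}

#' Merge complementary context matrices into the 10 canonical matrices
#'
#' Complementary contexts observe the same double-stranded site from opposite
#' strands, so each canonical matrix pools its own counts with the
#' complement-relabelled counts of the complementary context (entry (i, j)
#' mapped to (comp(i), comp(j))). The four self-complementary contexts pass
#' through unchanged. The merge conserves the total count.
#'
#' @param raw Named list of context count matrices (missing contexts are
#'   treated as all-zero).
#' @return An object of class `"substitution_counts"`: the 10 canonical
#'   matrices plus site and substitution totals.
#' @export
merge_complements <- function(raw) {
  stopifnot(is.list(raw))
  bad <- setdiff(names(raw), all_contexts())
  if (length(bad)) stop("unknown context label(s): ", paste(bad, collapse = ", "))
  get <- function(ctx) if (!is.null(raw[[ctx]])) raw[[ctx]] else empty_count_matrix()

  merged <- list()
  for (ctx in canonical_contexts()) {
    cc <- context_complement(ctx)
    m <- get(ctx)
    if (cc != ctx) m <- m + complement_transform(get(cc))
    storage.mode(m) <- "integer"
    dimnames(m) <- list(BASES, BASES)
    merged[[ctx]] <- m
  }
  total <- sum(vapply(merged, sum, numeric(1)))
  subs <- sum(vapply(merged, function(m) sum(m) - sum(diag(m)), numeric(1)))
  structure(
    list(matrices = merged, total_sites = total, total_substitutions = subs),
    class = "substitution_counts"
  )
}

#' @export
print.substitution_counts <- function(x, ...) {
  frac <- if (x$total_sites > 0) x$total_substitutions / x$total_sites else NA_real_
  cat("Context-dependent substitution counts\n")
  cat("  scored sites:        ", format(x$total_sites, big.mark = ","), "\n")
  cat("  observed substitutions:", format(x$total_substitutions, big.mark = ","),
      sprintf(" (fraction %.3g)\n", frac))
  cat("  contexts: ", paste(names(x$matrices), collapse = " "), "\n")
  invisible(x)
}

#' Read a triplet alignment from a multi-FASTA file
#'
#' The file must contain exactly three aligned records; `order` says which
#' record is ingroup 1, ingroup 2 and the outgroup.
#'
#' @param file Path to a FASTA file with three aligned records.
#' @param order Integer vector of length 3 giving the record indices of
#'   (in1, in2, outgroup).
#' @param region_id Region identifier; defaults to the file name.
#' @return A [triplet_alignment()].
#' @export
read_triplet_fasta <- function(file, order = c(1L, 2L, 3L),
                               region_id = basename(file)) {
  seqs <- Biostrings::readBStringSet(file)
  if (length(seqs) != 3L)
    stop("expected exactly 3 records in ", file, ", found ", length(seqs))
  s <- as.character(seqs)
  triplet_alignment(s[order[1L]], s[order[2L]], s[order[3L]],
                    region_id = region_id)
}

#' Read triplet alignments listed in a manifest
#'
#' @param manifest Path to a TSV with columns `region_id` and `file`
#'   (paths resolved relative to the manifest's directory).
#' @inheritParams read_triplet_fasta
#' @return List of [triplet_alignment()] objects.
#' @export
read_triplet_manifest <- function(manifest, order = c(1L, 2L, 3L)) {
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "file") %in% names(tab)))
  base <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(i) {
    f <- tab$file[i]
    if (!file.exists(f)) f <- file.path(base, f)
    read_triplet_fasta(f, order = order, region_id = tab$region_id[i])
  })
}

#' Serialize substitution counts to JSON
#'
#' Integer counts round-trip bit-exactly through [read_counts_json()].
#'
#' @param counts A `"substitution_counts"` object.
#' @param path Output file path.
#' @export
write_counts_json <- function(counts, path) {
  stopifnot(inherits(counts, "substitution_counts"))
  obj <- list(
    total_sites = counts$total_sites,
    total_substitutions = counts$total_substitutions,
    matrices = lapply(counts$matrices, function(m) unclass(m))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_counts_json
#' @export
read_counts_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mats <- lapply(obj$matrices, function(m) {
    m <- matrix(as.integer(m), 4L, 4L, dimnames = list(BASES, BASES))
    m
  })
  out <- merge_complements(mats[canonical_contexts()])
  stopifnot(out$total_sites == obj$total_sites,
            out$total_substitutions == obj$total_substitutions)
  out
}

#' Export substitution counts as a 10-block TSV
#'
#' One block per canonical context: a header line with the context label
#' followed by a 4x4 integer grid (rows = ancestral base A, C, G, T).
#' [read_counts_tsv()] restores the object bit-exactly.
#'
#' @inheritParams write_counts_json
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "substitution_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ctx in names(counts$matrices)) {
    writeLines(paste0("#context\t", ctx), con)
    m <- counts$matrices[[ctx]]
    for (i in 1:4)
      writeLines(paste(m[i, ], collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#context\t", lines)
  mats <- list()
  for (h in hdr) {
    ctx <- sub("^#context\t", "", lines[h])
    rows <- lapply(lines[(h + 1L):(h + 4L)], function(l)
      as.integer(strsplit(l, "\t", fixed = TRUE)[[1L]]))
    mats[[ctx]] <- matrix(unlist(rows), 4L, 4L, byrow = TRUE,
                          dimnames = list(BASES, BASES))
  }
  merge_complements(mats)
}
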