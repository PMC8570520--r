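## Orchestration helpers: extracting intergenic regions from annotated
## genome records and grouping taxa into closely related triplets.
## Coordinates are handled 0-based half-open internally; GenBank's 1-based
## inclusive locations are converted at the parsing boundary.

#' Read a GenBank flat file (minimal parser)
#'
#' Extracts the accession, sequence and a feature table (type and overall
#' span; `join`/`complement` locations are reduced to their enclosing span).
#' Only the fields needed for intergenic-region extraction are parsed.
#'
#' @param file Path to a GenBank-format record.
#' @return An object of class `"genbank_record"`: list with `accession`,
#'   `length`, `features` (data frame with `type`, `start`, `end` in 0-based
#'   half-open coordinates) and `sequence`.
#' @export
read_genbank <- function(file) {
  lines <- readLines(file)
  locus <- grep("^LOCUS", lines, value = TRUE)
  accession <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2]
    else basename(file)
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  feats <- data.frame(type = character(), start = integer(), end = integer())
  if (length(fstart)) {
    fend <- if (length(ostart)) ostart[1] - 1L else length(lines)
    block <- lines[(fstart[1] + 1L):fend]
    key <- grepl("^ {5}\\S", block)
    idx <- which(key)
    rows <- lapply(idx, function(i) {
      parts <- strsplit(trimws(block[i]), "\\s+")[[1]]
      type <- parts[1]
      loc <- paste(parts[-1], collapse = "")
      # locations may continue on following lines
      j <- i + 1L
      while (j <= length(block) && !key[j] && !grepl("^ {21}/", block[j])) {
        loc <- paste0(loc, trimws(block[j]))
        j <- j + 1L
      }
      pos <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(pos) == 0L) return(NULL)
      data.frame(type = type, start = as.integer(min(pos) - 1L),
                 end = as.integer(max(pos)))  # -> 0-based half-open
    })
    feats <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  sequence <- ""
  if (length(ostart)) {
    endrec <- grep("^//", lines)
    endrec <- if (length(endrec)) endrec[1] - 1L else length(lines)
    seqlines <- lines[(ostart[1] + 1L):endrec]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  }
  structure(
    list(accession = accession,
         length = if (nchar(sequence)) nchar(sequence) else
           max(0L, feats$end),
         features = feats, sequence = sequence),
    class = "genbank_record"
  )
}

#' @export
print.genbank_record <- function(x, ...) {
  cat("GenBank record ", x$accession, ": ", x$length, " nt, ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}

#' Extract intergenic regions between annotated features
#'
#' Returns the gaps between consecutive annotated features in genome order:
#' the noncoding regions used to estimate mutation models. Zero-length gaps
#' (abutting features) are omitted and overlapping features produce no region
#' (a warning is logged). Regions are taken on the record's forward strand;
#' the model's complementation machinery keeps downstream counting
#' strand-consistent.
#'
#' @param record A `"genbank_record"`, or a data frame of features with
#'   columns `type`, `start`, `end` in 0-based half-open coordinates.
#' @param sequence Optional genome sequence (taken from the record when
#'   present) used to attach region sequences.
#' @param types Feature types delimiting intergenic space (default gene, CDS,
#'   tRNA, rRNA; set to `NULL` to use all features).
#' @return Data frame with `region_id`, `start`, `end` (0-based half-open),
#'   `length`, and `sequence` when available.
#' @export
#' @examples
#' feats <- data.frame(type = "gene", start = c(0, 150), end = c(100, 300))
#' extract_intergenic(feats)  # one 50 nt region
extract_intergenic <- function(record, sequence = NULL,
                               types = c("gene", "CDS", "tRNA", "rRNA")) {
  if (inherits(record, "genbank_record")) {
    feats <- record$features
    if (is.null(sequence) && nchar(record$sequence)) sequence <- record$sequence
  } else {
    feats <- record
  }
  stopifnot(is.data.frame(feats), all(c("start", "end") %in% names(feats)))
  if (!is.null(types) && "type" %in% names(feats))
    feats <- feats[feats$type %in% types, , drop = FALSE]
  if (nrow(feats) < 2L)
    return(data.frame(region_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      sequence = character()))
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  gap_start <- utils::head(feats$end, -1L)
  gap_end <- utils::tail(feats$start, -1L)
  # a feature nested in or overlapping its neighbour yields a negative gap
  n_overlap <- sum(gap_start > gap_end)
  if (n_overlap > 0)
    warning(n_overlap, " overlapping feature pair(s) produced no region")
  keep <- gap_end > gap_start
  out <- data.frame(
    region_id = sprintf("ig_%04d", seq_len(sum(keep))),
    start = as.integer(gap_start[keep]),
    end = as.integer(gap_end[keep])
  )
  out$length <- out$end - out$start
  out$sequence <- if (!is.null(sequence))
    substring(sequence, out$start + 1L, out$end)
  else rep(NA_character_, nrow(out))
  out
}

#' Group taxa into closely related triplets
#'
#' Implements the family-based sampling protocol: within each family, every
#' genus with at least two genomes contributes one randomly chosen ingroup
#' pair, each paired with an outgroup drawn at random from the family's other
#' genomes; then one additional pair is drawn from the family's remaining
#' (so far unpaired) genomes and the rest are discarded. No accession is used
#' in more than one ingroup pair, preventing duplicate sampling of branches.
#'
#' @param taxa Data frame with columns `accession`, `family`, `genus` (a
#'   `species` column is carried along if present).
#' @param seed Optional seed for reproducible selection.
#' @return Data frame with columns `family`, `in1`, `in2`, `outgroup`.
#' @export
select_triplets <- function(taxa, seed = NULL) {
  stopifnot(is.data.frame(taxa),
            all(c("accession", "family", "genus") %in% names(taxa)))
  if (any(!nzchar(taxa$family)) || any(!nzchar(taxa$genus)))
    stop("taxa records must have non-empty family and genus")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (fam in sort(unique(taxa$family))) {
    members <- taxa[taxa$family == fam, , drop = FALSE]
    if (nrow(members) < 3L) next  # no outgroup possible
    used <- character()
    add_pair <- function(pair) {
      others <- setdiff(members$accession, pair)
      if (length(others) == 0L) return(NULL)
      outg <- if (length(others) == 1L) others else sample(others, 1L)
      data.frame(family = fam, in1 = pair[1L], in2 = pair[2L],
                 outgroup = outg, stringsAsFactors = FALSE)
    }
    for (gen in sort(unique(members$genus))) {
      accs <- setdiff(members$accession[members$genus == gen], used)
      if (length(accs) < 2L) next
      pair <- sample(accs, 2L)
      row <- add_pair(pair)
      if (!is.null(row)) {
        out[[length(out) + 1L]] <- row
        used <- c(used, pair)
      }
    }
    remaining <- setdiff(members$accession, used)
    if (length(remaining) >= 2L) {
      pair <- sample(remaining, 2L)
      row <- add_pair(pair)
      if (!is.null(row)) out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L)
    return(data.frame(family = character(), in1 = character(),
                      in2 = character(), outgroup = character()))
  do.call(rbind, out)
}
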