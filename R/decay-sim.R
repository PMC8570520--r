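## Neutral decay of codon adaptation.  Each round proposes a context-dependent
## mutation (uniform site, derived base drawn from the probability row of the
## site's current context) and accepts it under the synonymous-only or
## dN/dS-gated rule; CAI is recorded at fixed accepted-mutation checkpoints
## over many replicates.

#' Acceptable amino-acid replacements from an alignment
#'
#' Builds, for every alignment column, the set of amino acids observed across
#' the taxa; replacements outside this set are treated as unacceptable by the
#' simulator's selection step.
#'
#' @param aa_alignment Character vector (or list) of equal-length aligned
#'   amino acid strings; gaps (`-`, `.`) are dropped.
#' @return An object of class `"acceptable_replacements"`: a list of
#'   character vectors, one per column.
#' @export
#' @examples
#' acceptable_replacements(c("MA-", "MS-", "MAV"))
acceptable_replacements <- function(aa_alignment) {
  aa_alignment <- unlist(aa_alignment, use.names = FALSE)
  if (length(aa_alignment) == 0L) stop("empty amino-acid alignment")
  n <- unique(nchar(aa_alignment))
  if (length(n) != 1L) stop("aligned amino-acid sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(aa_alignment), ""))
  sets <- lapply(seq_len(ncol(m)), function(j) {
    r <- setdiff(unique(m[, j]), c("-", ".", "X"))
    sort(r)
  })
  structure(sets, class = "acceptable_replacements")
}

#' @export
print.acceptable_replacements <- function(x, ...) {
  sizes <- lengths(x)
  cat("Acceptable replacements over", length(x), "sites;",
      sum(sizes > 1), "sites with observed variation\n")
  invisible(x)
}

## --- internal encodings shared with the C++ kernel ------------------------

## Flatten a model into the 256-vector the kernel indexes by
## (f5 * 4 + f3) * 16 + cur * 4 + der.
model_prob_vector <- function(model) {
  p <- numeric(256L)
  for (f5 in 1:4) for (f3 in 1:4) {
    ctx <- (f5 - 1L) * 4L + (f3 - 1L)
    m <- context_matrix(model, paste(BASES[f5], BASES[f3], sep = "_"))
    p[(ctx * 16L + 1L):(ctx * 16L + 16L)] <- as.vector(t(m))
  }
  p
}

codon_index0 <- function(codon) {
  b <- match(strsplit(codon, "")[[1L]], BASES) - 1L
  b[1L] * 16L + b[2L] * 4L + b[3L]
}

## aa index (0-based into AA_LETTERS) per codon index; stops are -1.
codon_aa_vector <- function() {
  v <- integer(64L)
  for (codon in all_codons()) {
    aa <- GENETIC_CODE_TABLE[[codon]]
    v[codon_index0(codon) + 1L] <-
      if (aa == "*") -1L else match(aa, AA_LETTERS) - 1L
  }
  v
}

codon_logw_vector <- function(table) {
  v <- rep(NA_real_, 64L)
  for (codon in names(table))
    v[codon_index0(codon) + 1L] <- log(unclass(table)[[codon]])
  v
}

acceptable_matrix <- function(acc, ancestor_aa) {
  n <- nchar(ancestor_aa)
  if (length(acc) != n)
    stop("acceptable-replacement list covers ", length(acc),
         " sites but the ancestor has ", n, " codons")
  aa <- strsplit(ancestor_aa, "")[[1L]]
  m <- matrix(0L, n, length(AA_LETTERS))
  for (i in seq_len(n)) {
    if (!aa[i] %in% acc[[i]] && aa[i] != "*")
      stop("site ", i, ": ancestor residue ", aa[i],
           " is missing from its acceptable set")
    m[i, match(acc[[i]], AA_LETTERS)] <- 1L
  }
  m
}

## Counter-based per-replicate seeds below 2^31, so each replicate is
## individually reproducible from the master seed.
replicate_seed <- function(master, i) {
  as.integer((as.double(master) + 1000003 * as.double(i)) %% 2147483629)
}

#' Simulate one replicate of neutral codon-adaptation decay
#'
#' Runs the two-step proposal/acceptance loop until `n_mutations` mutations
#' have been accepted, returning the CAI at every `record_every` accepted
#' mutations together with acceptance statistics. See [simulate_decay()] for
#' the acceptance rules.
#'
#' @inheritParams simulate_decay
#' @param count_proposal_sites Also tally proposals per nucleotide position.
#' @return List with `cai` (checkpoint values, starting at the ancestor),
#'   `final` (`"coding_sequence"`), and acceptance statistics.
#' @export
simulate_replicate <- function(ancestor, table, model,
                               mode = c("syn_only", "with_nonsyn"),
                               acceptable = NULL, dnds = NULL,
                               n_mutations = 500, record_every = 5,
                               max_proposals = 1e7,
                               count_proposal_sites = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(ancestor, "coding_sequence"),
            inherits(table, "fitness_table"),
            inherits(model, "mutation_model"))
  if (n_mutations > 0 && n_mutations %% record_every != 0L)
    stop("record_every must divide n_mutations")
  aa <- translate_cds(ancestor)
  if (mode == "with_nonsyn") {
    if (is.null(dnds) || dnds < 0 || dnds > 1)
      stop("with_nonsyn mode requires dnds in [0, 1]")
    if (is.null(acceptable))
      stop("with_nonsyn mode requires an acceptable-replacements list")
    acc_m <- acceptable_matrix(acceptable, aa)
  } else {
    dnds <- 0
    acc_m <- matrix(0L, 1L, length(AA_LETTERS))
  }
  res <- cpp_decay_replicate(
    encode_bases(ancestor$nt) - 1L, model_prob_vector(model),
    codon_aa_vector(), codon_logw_vector(table), acc_m,
    if (mode == "syn_only") 0L else 1L, dnds,
    as.integer(n_mutations), as.integer(max(record_every, 1L)),
    max_proposals, count_proposal_sites)
  res$final <- coding_sequence(decode_bases(res$final_seq + 1L),
                               id = paste0(ancestor$id, "_sim"))
  res$final_seq <- NULL
  res
}

#' Simulate the neutral decay of codon adaptation
#'
#' From a (typically ancestral) coding sequence, repeatedly: (1) draw a site
#' uniformly over interior positions and a derived base from the probability
#' row of the site's current flanking context -- a draw of the current base is
#' discarded, which is how non-zero diagonals encode rate variation; (2) apply
#' the selection rule. Synonymous changes are always accepted; stop-codon
#' changes never. Nonsynonymous changes are discarded in `syn_only` mode,
#' while in `with_nonsyn` mode they are accepted with probability `dnds`
#' provided the new residue has been observed at that site in the reference
#' alignment (`acceptable`). CAI is recorded at every `record_every` accepted
#' mutations and averaged over replicates.
#'
#' @param ancestor A [coding_sequence()].
#' @param table A [fitness_table()].
#' @param model A `"mutation_model"`.
#' @param mode `"syn_only"` or `"with_nonsyn"`.
#' @param acceptable An [acceptable_replacements()] list (required for
#'   `with_nonsyn`).
#' @param dnds Per-gene dN/dS used as the nonsynonymous acceptance
#'   probability (required for `with_nonsyn`).
#' @param n_mutations Accepted mutations per replicate (default 500).
#' @param record_every Checkpoint spacing in accepted mutations (default 5).
#' @param replicates Number of replicates (default 1000).
#' @param seed Master seed; per-replicate seeds are derived from it by a
#'   counter scheme so runs are bit-reproducible.
#' @param max_proposals Guard against non-terminating runs (per replicate).
#' @param keep_replicates Keep the full replicate x checkpoint CAI matrix.
#' @param keep_sequences Keep each replicate's final sequence.
#' @param label Trajectory label (defaults to the ancestor id).
#' @return An object of class `"cai_trajectory"`: a data frame with columns
#'   `checkpoint` (accepted mutations), `mean_cai` and `sd_cai`, with
#'   acceptance statistics and (optionally) replicate details as attributes.
#' @export
#' @examples
#' ft <- fitness_table(coding_sequence(strrep("TTCGAAAAA", 20)))
#' anc <- generate_coding(40, ft, beta = 50, seed = 1)
#' simulate_decay(anc, ft, k2p_model(), n_mutations = 20, record_every = 5,
#'                replicates = 10, seed = 1)
simulate_decay <- function(ancestor, table, model,
                           mode = c("syn_only", "with_nonsyn"),
                           acceptable = NULL, dnds = NULL,
                           n_mutations = 500, record_every = 5,
                           replicates = 1000, seed = NULL,
                           max_proposals = 1e7,
                           keep_replicates = FALSE, keep_sequences = FALSE,
                           label = ancestor$id) {
  mode <- match.arg(mode)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  n_check <- n_mutations %/% max(record_every, 1L) + 1L
  mat <- matrix(NA_real_, replicates, n_check)
  stats <- c(proposals = 0, self_discards = 0, stop_discards = 0,
             syn_accepted = 0, nonsyn_offered = 0, nonsyn_accepted = 0,
             acceptability_filtered = 0)
  finals <- if (keep_sequences) vector("list", replicates) else NULL
  for (r in seq_len(replicates)) {
    set.seed(replicate_seed(seed, r))
    res <- simulate_replicate(ancestor, table, model, mode = mode,
                              acceptable = acceptable, dnds = dnds,
                              n_mutations = n_mutations,
                              record_every = record_every,
                              max_proposals = max_proposals)
    mat[r, ] <- res$cai
    stats <- stats + unlist(res[names(stats)])
    if (keep_sequences) finals[[r]] <- res$final
  }
  checkpoints <- as.integer(seq(0L, n_mutations, by = max(record_every, 1L)))
  out <- data.frame(
    checkpoint = checkpoints,
    mean_cai = colMeans(mat),
    sd_cai = if (replicates > 1) apply(mat, 2, stats::sd) else rep(0, n_check)
  )
  out$sd_cai[1L] <- 0  # all replicates start at the ancestral CAI
  structure(out,
            class = c("cai_trajectory", "data.frame"),
            label = label, mode = mode, dnds = if (mode == "with_nonsyn") dnds,
            replicates = replicates, seed = seed, stats = stats,
            replicate_cai = if (keep_replicates) mat,
            final_sequences = finals)
}

#' @rdname simulate_decay
#' @param object A `"mutation_model"` (the [stats::simulate()] generic).
#' @param nsim Number of replicates.
#' @param ... Passed on to [simulate_decay()].
#' @export
simulate.mutation_model <- function(object, nsim = 1000, seed = NULL,
                                    ancestor, table, ...) {
  simulate_decay(ancestor, table, object, replicates = nsim, seed = seed, ...)
}

#' @export
print.cai_trajectory <- function(x, ...) {
  st <- attr(x, "stats")
  cat("CAI decay trajectory '", attr(x, "label"), "' (", attr(x, "mode"),
      "): ", attr(x, "replicates"), " replicates x ",
      max(x$checkpoint), " mutations\n", sep = "")
  cat(sprintf("  ancestral CAI %.4f -> terminal mean %.4f (sd %.4f)\n",
              x$mean_cai[1L], x$mean_cai[nrow(x)], x$sd_cai[nrow(x)]))
  if (!is.null(st) && st[["nonsyn_offered"]] > 0)
    cat(sprintf("  realized nonsynonymous acceptance: %.4f\n",
                st[["nonsyn_accepted"]] / st[["nonsyn_offered"]]))
  invisible(x)
}

#' Plot a CAI decay trajectory
#'
#' Mean CAI against accepted mutation count with a +/- 1 SD band.
#'
#' @param x A `"cai_trajectory"`.
#' @param add Add to an existing plot.
#' @param col Line colour.
#' @param ylim Y limits (default spans the band).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cai_trajectory <- function(x, add = FALSE, col = "black", ylim = NULL, ...) {
  lo <- x$mean_cai - x$sd_cai
  hi <- x$mean_cai + x$sd_cai
  if (!add) {
    if (is.null(ylim)) ylim <- range(lo, hi)
    graphics::plot(x$checkpoint, x$mean_cai, type = "n", ylim = ylim,
                   xlab = "Accepted mutations", ylab = "CAI", ...)
  }
  graphics::polygon(c(x$checkpoint, rev(x$checkpoint)), c(lo, rev(hi)),
                    border = NA, col = grDevices::adjustcolor(col, 0.15))
  graphics::lines(x$checkpoint, x$mean_cai, col = col, lwd = 2)
  invisible(x)
}

#' Trajectory serialization as TSV
#'
#' Columns `checkpoint`, `mean_cai`, `sd_cai`; values round-trip exactly.
#'
#' @param trajectory A `"cai_trajectory"`.
#' @param path Output path.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cai_trajectory"))
  df <- data.frame(checkpoint = trajectory$checkpoint,
                   mean_cai = format(trajectory$mean_cai, digits = 17),
                   sd_cai = format(trajectory$sd_cai, digits = 17))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#label\t%s\n#mode\t%s\n#replicates\t%d",
                     attr(trajectory, "label"), attr(trajectory, "mode"),
                     attr(trajectory, "replicates")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("#", key, "\t"), "",
                           meta[startsWith(meta, paste0("#", key, "\t"))])
  tab <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]))
  structure(data.frame(checkpoint = as.integer(tab$checkpoint),
                       mean_cai = as.numeric(tab$mean_cai),
                       sd_cai = as.numeric(tab$sd_cai)),
            class = c("cai_trajectory", "data.frame"),
            label = get("label"), mode = get("mode"),
            replicates = as.integer(get("replicates")),
            stats = NULL, seed = NA_integer_)
}
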