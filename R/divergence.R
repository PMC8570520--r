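## Kimura two-parameter distances between extant genes and reconstructed
## ancestors, converted to inferred mutation counts for placement on the
## simulated decay trajectories.

#' Kimura two-parameter distance and variance for an aligned pair
#'
#' From the proportions of transition (`P`) and transversion (`Q`) differences
#' over compared columns:
#' `k = 1/2 log(1 / (1 - 2P - Q)) + 1/4 log(1 / (1 - 2Q))`, with the usual
#' large-sample variance
#' `(a^2 P + b^2 Q - (a P + b Q)^2) / n` where `a = 1 / (1 - 2P - Q)` and
#' `b = (1 / (1 - 2P - Q) + 1 / (1 - 2Q)) / 2`. Columns containing gaps or
#' ambiguity codes are excluded; `n` counts compared columns. The inferred
#' mutation count is `k * n`, appropriate at the very low divergences this
#' package targets.
#'
#' @param s1,s2 Equal-length aligned nucleotide strings (or
#'   `"coding_sequence"` objects, taken as aligned when equal length).
#' @return An object of class `"k2p_distance"` with fields `p_transition`,
#'   `q_transversion`, `k`, `variance`, `n_sites`, `mutation_count`.
#' @export
#' @examples
#' k2p_distance("ACGT", "ACGT")$k  # 0
k2p_distance <- function(s1, s2) {
  if (inherits(s1, "coding_sequence")) s1 <- s1$nt
  if (inherits(s2, "coding_sequence")) s2 <- s2$nt
  if (nchar(s1) != nchar(s2))
    stop("aligned sequences have unequal lengths (", nchar(s1), " vs ",
         nchar(s2), "); supply a pairwise alignment")
  a1 <- encode_bases(s1)
  a2 <- encode_bases(s2)
  ok <- !is.na(a1) & !is.na(a2)
  n <- sum(ok)
  if (n == 0L) stop("no comparable columns")
  d <- ok & a1 != a2
  ts <- sum(d & abs(a1 - a2) == 2L)
  tv <- sum(d) - ts
  P <- ts / n
  Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("saturated pair: K2P distance undefined (P = ", signif(P, 4),
         ", Q = ", signif(Q, 4), ")")
  a <- 1 / (1 - 2 * P - Q)
  b <- (a + 1 / (1 - 2 * Q)) / 2
  k <- 0.5 * log(a) + 0.25 * log(1 / (1 - 2 * Q))
  v <- (a^2 * P + b^2 * Q - (a * P + b * Q)^2) / n
  structure(
    list(p_transition = P, q_transversion = Q, k = k, variance = v,
         n_sites = n, mutation_count = k * n),
    class = "k2p_distance"
  )
}

#' @export
print.k2p_distance <- function(x, ...) {
  cat(sprintf(
    "K2P distance: k = %.6g (var %.3g) over %d sites; P = %.4g, Q = %.4g\n",
    x$k, x$variance, x$n_sites, x$p_transition, x$q_transversion))
  cat(sprintf("  inferred mutations: %.2f\n", x$mutation_count))
  invisible(x)
}

#' Minimum and maximum inferred mutation counts over a set of ancestors
#'
#' Computes the K2P mutation count between an extant gene and each
#' reconstructed ancestor and returns the extremes, which bracket the gene's
#' position along the simulated trajectories.
#'
#' @param extant A `"coding_sequence"` or aligned string.
#' @param ancestors List of ancestors, each pairwise-aligned to the extant
#'   sequence (equal lengths; supply external alignments when reconstruction
#'   introduced indels).
#' @return List with `min`, `max`, and the per-ancestor `"k2p_distance"`
#'   objects in `estimates`.
#' @export
mutation_range <- function(extant, ancestors) {
  if (inherits(ancestors, "coding_sequence")) ancestors <- list(ancestors)
  stopifnot(length(ancestors) >= 1L)
  est <- lapply(ancestors, function(a) k2p_distance(extant, a))
  counts <- vapply(est, function(e) e$mutation_count, numeric(1))
  list(min = min(counts), max = max(counts), estimates = est)
}

#' Overlay extant genes on simulated decay trajectories
#'
#' Joins simulated trajectories with extant-gene CAI values positioned by
#' their minimum and maximum inferred mutation counts, and classifies each
#' extant point against the envelope spanned by the trajectories'
#' mean +/- 1 SD at the nearest checkpoint: `"above"`, `"within"` or
#' `"below"`; points whose mutation count exceeds the simulated range are
#' flagged `"out_of_range"`.
#'
#' @param trajectories List of `"cai_trajectory"` objects (e.g. one per
#'   reconstructed ancestor).
#' @param extants Data frame with columns `id`, `cai`, `min_mutations`,
#'   `max_mutations` (see [mutation_range()]), or an empty/`NULL` value for a
#'   simulations-only overlay.
#' @return An object of class `"cai_overlay"`: the trajectory list plus a
#'   per-extant table with classifications at the minimum- and maximum-count
#'   positions.
#' @export
build_overlay <- function(trajectories, extants = NULL) {
  if (inherits(trajectories, "cai_trajectory"))
    trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1L,
            all(vapply(trajectories, inherits, logical(1), "cai_trajectory")))
  if (!is.null(extants) && nrow(extants) > 0) {
    stopifnot(all(c("id", "cai", "min_mutations", "max_mutations")
                  %in% names(extants)))
    if (any(extants$min_mutations > extants$max_mutations))
      stop("min_mutations exceeds max_mutations")
    cls_min <- t(vapply(seq_len(nrow(extants)), function(i)
      classify_against_envelope(trajectories, extants$cai[i],
                                extants$min_mutations[i]), character(2)))
    cls_max <- t(vapply(seq_len(nrow(extants)), function(i)
      classify_against_envelope(trajectories, extants$cai[i],
                                extants$max_mutations[i]), character(2)))
    extants$class_min <- cls_min[, 1L]
    extants$class_max <- cls_max[, 1L]
    extants$range_min <- cls_min[, 2L] == "out_of_range"
    extants$range_max <- cls_max[, 2L] == "out_of_range"
  } else {
    extants <- data.frame(id = character(), cai = numeric(),
                          min_mutations = numeric(), max_mutations = numeric(),
                          class_min = character(), class_max = character(),
                          range_min = logical(), range_max = logical())
  }
  structure(list(trajectories = trajectories, extants = extants),
            class = "cai_overlay")
}

## Envelope at the checkpoint nearest to `mutations`: [min(mean - sd),
## max(mean + sd)] over trajectories.
classify_against_envelope <- function(trajectories, cai, mutations) {
  lo <- Inf; hi <- -Inf
  out_of_range <- TRUE
  for (tr in trajectories) {
    if (mutations <= max(tr$checkpoint)) out_of_range <- FALSE
    i <- which.min(abs(tr$checkpoint - mutations))
    lo <- min(lo, tr$mean_cai[i] - tr$sd_cai[i])
    hi <- max(hi, tr$mean_cai[i] + tr$sd_cai[i])
  }
  cls <- if (cai > hi) "above" else if (cai < lo) "below" else "within"
  c(cls, if (out_of_range) "out_of_range" else "in_range")
}

#' @export
print.cai_overlay <- function(x, ...) {
  cat("CAI overlay:", length(x$trajectories), "trajectories,",
      nrow(x$extants), "extant genes\n")
  if (nrow(x$extants) > 0) {
    cat("  classification at minimum mutation count:\n")
    print(table(x$extants$class_min))
    cat("  classification at maximum mutation count:\n")
    print(table(x$extants$class_max))
  }
  invisible(x)
}

#' Plot an overlay of extant genes on decay trajectories
#'
#' Two panels: extant points positioned by their minimum (left) and maximum
#' (right) inferred mutation counts over the simulated trajectories.
#'
#' @param x A `"cai_overlay"`.
#' @param cols Trajectory colours (recycled).
#' @param ... Passed to [plot.cai_trajectory()].
#' @export
plot.cai_overlay <- function(x, cols = c("black", "red", "green3", "blue"), ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ylim <- range(unlist(lapply(x$trajectories, function(tr)
    c(tr$mean_cai - tr$sd_cai, tr$mean_cai + tr$sd_cai))), x$extants$cai)
  for (panel in c("min_mutations", "max_mutations")) {
    first <- TRUE
    for (i in seq_along(x$trajectories)) {
      plot(x$trajectories[[i]], add = !first, ylim = ylim,
           col = cols[(i - 1) %% length(cols) + 1], ...)
      first <- FALSE
    }
    if (nrow(x$extants) > 0)
      graphics::points(x$extants[[panel]], x$extants$cai, pch = 19,
                       col = "blue")
    graphics::title(main = sub("_mutations", " mutation count", panel))
  }
  invisible(x)
}
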