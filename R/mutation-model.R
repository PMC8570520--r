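## Context-dependent mutation models.  Each canonical context carries a 4x4
## row-stochastic probability matrix whose off-diagonal entries are relative
## mutation probabilities and whose non-zero diagonal encodes per-base rate
## variation (a draw of the current base is a discarded "non-mutation").

#' Fit a context-dependent mutation model from substitution counts
#'
#' Converts each 4x4 substitution count matrix into a probability matrix by
#' dividing each row by its total, then applies a single global rescaling so
#' that the fastest row (largest off-diagonal sum) has overall rate
#' `target_max_rate`: every off-diagonal entry is multiplied by the same
#' scalar and each diagonal is reset to keep the row stochastic. The global
#' scalar preserves relative rates both within rows and across matrices, and
#' leaves every matrix's stationary vector unchanged.
#'
#' @param counts A `"substitution_counts"` object (see [merge_complements()]).
#' @param target_max_rate Off-diagonal row sum assigned to the fastest row
#'   (default 1, which minimizes discarded self-mutations in simulation).
#' @return An object of class `"mutation_model"` with elements `matrices`
#'   (10 canonical probability matrices), `kind = "MC2020"`,
#'   `normalization_scale` (the global scalar) and the `counts` used.
#' @export
#' @examples
#' counts <- merge_complements(list())  # all-zero; a real fit needs data
#' @seealso [k2p_model()], [mutation_model()] for externally estimated
#'   matrices, [lookup_row()], [stationary_vector()]
fit_mutation_model <- function(counts, target_max_rate = 1) {
  stopifnot(inherits(counts, "substitution_counts"),
            target_max_rate > 0, target_max_rate <= 1)
  probs <- list()
  for (ctx in names(counts$matrices)) {
    m <- counts$matrices[[ctx]]
    rs <- rowSums(m)
    if (any(rs == 0))
      stop("degenerate data: zero-count row for ancestral base(s) ",
           paste(BASES[rs == 0], collapse = ", "), " in context ", ctx)
    probs[[ctx]] <- m / rs
  }
  model <- rescale_model(probs, target_max_rate)
  structure(
    list(matrices = model$matrices, kind = "MC2020",
         normalization_scale = model$scale, counts = counts),
    class = "mutation_model"
  )
}

## Global rescaling: one scalar c = target / r_max applied to all off-diagonal
## entries; diagonals absorb the remainder.
rescale_model <- function(probs, target_max_rate) {
  offdiag_rate <- function(p) {
    d <- p; diag(d) <- 0; rowSums(d)
  }
  r_max <- max(vapply(probs, function(p) max(offdiag_rate(p)), numeric(1)))
  if (r_max == 0)
    stop("no substitutions observed: cannot rescale a zero-rate model")
  cc <- target_max_rate / r_max
  mats <- lapply(probs, function(p) {
    q <- p * cc
    diag(q) <- 0
    diag(q) <- 1 - rowSums(q)
    dimnames(q) <- list(BASES, BASES)
    q
  })
  list(matrices = mats, scale = cc)
}

#' Construct a mutation model from externally estimated matrices
#'
#' Wraps pre-computed probability matrices (for example a previously published
#' context-dependent chloroplast model) in the same interface as
#' [fit_mutation_model()]. Matrices must be row-stochastic; one matrix per
#' canonical context, or a single matrix applied to every context for
#' context-independent models.
#'
#' @param matrices Named list of 4x4 row-stochastic matrices keyed by
#'   canonical context, or a single 4x4 matrix.
#' @param kind Model label, e.g. `"MC"`.
#' @param normalization_scale Optional scalar recording any prior rescaling.
#' @return A `"mutation_model"`.
#' @export
mutation_model <- function(matrices, kind = "MC", normalization_scale = NA_real_) {
  if (is.matrix(matrices))
    matrices <- stats::setNames(rep(list(matrices), 10L), canonical_contexts())
  stopifnot(is.list(matrices),
            setequal(names(matrices), canonical_contexts()))
  matrices <- lapply(matrices[canonical_contexts()], function(m) {
    stopifnot(all(dim(m) == c(4L, 4L)))
    if (max(abs(rowSums(m) - 1)) > 1e-8)
      stop("matrix rows must sum to 1")
    dimnames(m) <- list(BASES, BASES)
    m
  })
  structure(
    list(matrices = matrices, kind = kind,
         normalization_scale = normalization_scale, counts = NULL),
    class = "mutation_model"
  )
}

#' The Kimura two-parameter comparison model
#'
#' A context-independent probability-matrix model in which every base mutates
#' at the same overall rate with a fixed transition:transversion ratio
#' (default 3:1): within each row's off-diagonal mass, the transition receives
#' `ts_tv / (ts_tv + 2)` and each transversion `1 / (ts_tv + 2)`.
#'
#' @param ts_tv Transition:transversion ratio (default 3).
#' @param target_max_rate Off-diagonal row mass (default 1).
#' @return A `"mutation_model"` of kind `"K2P"`.
#' @export
k2p_model <- function(ts_tv = 3, target_max_rate = 1) {
  s <- target_max_rate
  m <- matrix(0, 4L, 4L, dimnames = list(BASES, BASES))
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  for (b in BASES) {
    for (d in setdiff(BASES, b)) {
      m[b, d] <- if (d == transition[[b]]) s * ts_tv / (ts_tv + 2) else
        s / (ts_tv + 2)
    }
    m[b, b] <- 1 - sum(m[b, ])
  }
  mod <- mutation_model(m, kind = "K2P", normalization_scale = NA_real_)
  mod
}

#' Probability row for a site's context and current base
#'
#' Serves all 16 contexts from the 10 canonical matrices: a non-canonical
#' context is read from the canonical matrix of its complement, taking the row
#' of the complemented current base and relabelling the derived-base entries
#' by complementation. Strand-specific counting thereby stays consistent.
#'
#' @param model A `"mutation_model"`.
#' @param five_prime,three_prime Flanking bases (single characters).
#' @param current Current base at the site.
#' @return Named numeric vector of 4 probabilities in derived-base order
#'   A, C, G, T (sums to 1; the `current` entry is the non-mutation mass).
#' @export
#' @examples
#' m <- k2p_model()
#' lookup_row(m, "G", "T", "C")
lookup_row <- function(model, five_prime, three_prime, current) {
  stopifnot(inherits(model, "mutation_model"),
            five_prime %in% BASES, three_prime %in% BASES, current %in% BASES)
  ctx <- paste(five_prime, three_prime, sep = "_")
  if (ctx %in% canonical_contexts())
    return(model$matrices[[ctx]][current, ])
  cc <- context_complement(ctx)
  row <- model$matrices[[cc]][unname(comp_base(current)), ]
  out <- rev(unname(row))  # relabel derived bases j -> comp(j)
  names(out) <- BASES
  out
}

#' Effective probability matrix for any of the 16 contexts
#'
#' @inheritParams lookup_row
#' @param context Context label (any of the 16).
#' @return A 4x4 row-stochastic matrix.
#' @export
context_matrix <- function(model, context) {
  stopifnot(inherits(model, "mutation_model"))
  if (context %in% canonical_contexts())
    return(model$matrices[[context]])
  complement_transform(model$matrices[[context_complement(context)]])
}

#' Stationary base composition of a probability matrix
#'
#' Computes the stationary vector pi with pi P = pi by repeated squaring of
#' the transition matrix until all rows agree: at convergence each row of
#' P^t equals pi, the equilibrium base composition of a sequence evolving
#' under the matrix.
#'
#' @param p A 4x4 row-stochastic matrix (or a `"mutation_model"`, in which
#'   case a matrix of stationary vectors, one row per canonical context, is
#'   returned).
#' @param tol Maximum allowed row-to-row component difference at convergence.
#' @param max_doublings Maximum number of squarings before giving up.
#' @return Named numeric vector (A, C, G, T) summing to 1, or a 10 x 4 matrix
#'   for a model.
#' @export
#' @examples
#' stationary_vector(k2p_model()$matrices[["A_A"]])
stationary_vector <- function(p, tol = 1e-10, max_doublings = 64L) {
  if (inherits(p, "mutation_model")) {
    out <- t(vapply(p$matrices, stationary_vector, numeric(4),
                    tol = tol, max_doublings = max_doublings))
    colnames(out) <- BASES
    return(out)
  }
  stopifnot(is.matrix(p), all(dim(p) == c(4L, 4L)))
  if (max(abs(rowSums(p) - 1)) > 1e-9) stop("matrix is not row-stochastic")
  q <- p
  for (i in seq_len(max_doublings)) {
    spread <- max(apply(q, 2, function(col) diff(range(col))))
    if (spread < tol) {
      pi <- colMeans(q)
      pi <- pi / sum(pi)
      names(pi) <- BASES
      return(pi)
    }
    q <- q %*% q
  }
  stop("stationary vector did not converge after ", max_doublings,
       " doublings (reducible or periodic matrix?)")
}

equilibrium_stats <- function(pi) {
  gc <- pi[["C"]] + pi[["G"]]
  at <- pi[["A"]] + pi[["T"]]
  c(equil_gc = 100 * gc,
    equil_cg_skew = if (gc > 0) 100 * (pi[["C"]] - pi[["G"]]) / gc else NA_real_,
    equil_ta_skew = if (at > 0) 100 * (pi[["T"]] - pi[["A"]]) / at else NA_real_)
}

is_transition <- function(i, j) abs(i - j) == 2L  # A<->G (1,3), C<->T (2,4)

#' Per-context summary statistics of a fitted mutation model
#'
#' For each canonical context: transition:transversion ratios among
#' substitutions with G/C versus A/T ancestral bases, the substitution rate
#' (off-diagonal count over total count, times 100), the ratio of the
#' per-site substitution rate from ancestral G/C to that from ancestral A/T,
#' and the stationary composition of the probability matrix expressed as
#' percent G+C and the C-G and T-A skews (100 (C - G)/(C + G) and
#' 100 (T - A)/(T + A)). Ratios whose denominator is zero are reported as
#' `NA` rather than raising an error.
#'
#' @param object A `"mutation_model"`; per-context counts are taken from the
#'   fit, or supplied via `counts` for externally loaded models.
#' @param counts Optional `"substitution_counts"` overriding `object$counts`.
#' @param ... Unused.
#' @return A `"summary.mutation_model"` data frame, one row per context.
#' @export
summary.mutation_model <- function(object, counts = object$counts, ...) {
  if (is.null(counts))
    stop("no substitution counts available; supply `counts` to summarize an ",
         "externally loaded model")
  stopifnot(inherits(counts, "substitution_counts"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  rows <- lapply(canonical_contexts(), function(ctx) {
    m <- counts$matrices[[ctx]]
    ts <- matrix(FALSE, 4, 4)
    for (i in 1:4) for (j in 1:4) ts[i, j] <- i != j && is_transition(i, j)
    tv <- matrix(FALSE, 4, 4)
    for (i in 1:4) for (j in 1:4) tv[i, j] <- i != j && !is_transition(i, j)
    gc_rows <- c(2L, 3L); at_rows <- c(1L, 4L)
    ts_tv_gc <- ratio(sum(m[gc_rows, ][ts[gc_rows, ]]),
                      sum(m[gc_rows, ][tv[gc_rows, ]]))
    ts_tv_at <- ratio(sum(m[at_rows, ][ts[at_rows, ]]),
                      sum(m[at_rows, ][tv[at_rows, ]]))
    offdiag <- sum(m) - sum(diag(m))
    sub_rate <- ratio(offdiag, sum(m)) * 100
    rate_gc <- ratio(sum(m[gc_rows, ][ts[gc_rows, ] | tv[gc_rows, ]]),
                     sum(m[gc_rows, ]))
    rate_at <- ratio(sum(m[at_rows, ][ts[at_rows, ] | tv[at_rows, ]]),
                     sum(m[at_rows, ]))
    gc_at <- if (is.na(rate_at) || rate_at == 0) NA_real_ else rate_gc / rate_at
    # a context with no observed substitutions from some bases can be
    # non-ergodic; its equilibrium is then undefined rather than an error
    pi <- tryCatch(stationary_vector(object$matrices[[ctx]]),
                   error = function(e) NULL)
    eq <- if (is.null(pi))
      c(equil_gc = NA_real_, equil_cg_skew = NA_real_, equil_ta_skew = NA_real_)
    else equilibrium_stats(pi)
    data.frame(context = ctx, ts_tv_gc = ts_tv_gc, ts_tv_at = ts_tv_at,
               sub_rate_per100 = sub_rate, gc_at_rate_ratio = gc_at,
               equil_gc = unname(eq["equil_gc"]),
               equil_cg_skew = unname(eq["equil_cg_skew"]),
               equil_ta_skew = unname(eq["equil_ta_skew"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.mutation_model", "data.frame")
  out
}

#' @export
print.summary.mutation_model <- function(x, digits = 3, ...) {
  cat("Context-dependent model summary\n")
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(col) signif(col, digits))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("Context-dependent mutation model (kind: ", x$kind, ")\n", sep = "")
  cat("  ", length(x$matrices), " canonical context matrices",
      if (!is.na(x$normalization_scale))
        sprintf("; global rescale %.4g", x$normalization_scale), "\n", sep = "")
  if (!is.null(x$counts))
    cat("  fitted from ", format(x$counts$total_sites, big.mark = ","),
        " scored sites (", format(x$counts$total_substitutions, big.mark = ","),
        " substitutions)\n", sep = "")
  invisible(x)
}

#' @export
coef.mutation_model <- function(object, ...) object$matrices

#' Serialize a mutation model to JSON
#'
#' Writes kind, normalization scale and the 10 named matrices; the loader
#' accepts the same layout for externally estimated models.
#'
#' @param model A `"mutation_model"`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "mutation_model"))
  obj <- list(kind = model$kind,
              normalization_scale = model$normalization_scale,
              matrices = lapply(model$matrices, unclass))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mats <- lapply(obj$matrices, function(m)
    matrix(as.numeric(m), 4L, 4L, dimnames = list(BASES, BASES)))
  scale <- if (is.null(obj$normalization_scale)) NA_real_ else
    as.numeric(obj$normalization_scale)
  mutation_model(mats, kind = obj$kind, normalization_scale = scale)
}

#' Export each context matrix of a model as TSV
#'
#' @inheritParams write_model_json
#' @export
write_model_tsv <- function(model, path) {
  stopifnot(inherits(model, "mutation_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind\t", model$kind), con)
  for (ctx in names(model$matrices)) {
    writeLines(paste0("#context\t", ctx), con)
    m <- model$matrices[[ctx]]
    for (i in 1:4)
      writeLines(paste(format(m[i, ], digits = 17), collapse = "\t"), con)
  }
  invisible(path)
}
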