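# Fixture: substitution counts concentrated in the self-complementary A_T
# context (which merges as a pass-through), with light uniform counts
# elsewhere so every row is positive.
counts_fixture <- function(at_rows = NULL, background = 100L, offdiag = 1L) {
  raw <- lapply(stats::setNames(nm = cubdecay:::all_contexts()), function(ctx) {
    m <- matrix(offdiag, 4, 4, dimnames = list(BASES4, BASES4))
    diag(m) <- background
    m
  })
  if (!is.null(at_rows)) raw[["A_T"]] <- at_rows
  merge_complements(raw)
}

test_that("probability rows are count rows divided by their totals", {
  at <- matrix(1L, 4, 4, dimnames = list(BASES4, BASES4))
  diag(at) <- 100L
  at["G", ] <- c(10L, 0L, 90L, 0L)  # P(G->A) = 0.1 before rescaling
  counts <- counts_fixture(at_rows = at)
  model <- fit_mutation_model(counts)
  # undo the global rescale on the off-diagonal to recover the raw row
  p_ga <- model$matrices[["A_T"]]["G", "A"] / model$normalization_scale
  expect_equal(p_ga, 0.1)
})

test_that("global rescaling scales all off-diagonal rates by one constant", {
  at <- matrix(0L, 4, 4, dimnames = list(BASES4, BASES4))
  diag(at) <- c(80L, 90L, 100L, 100L)
  at["A", "G"] <- 20L   # off-diagonal row fraction 0.2 (the max)
  at["C", "T"] <- 10L   # 0.1
  counts <- counts_fixture(at_rows = at, offdiag = 0L)
  # zero-count rows elsewhere? background keeps diagonals positive
  model <- fit_mutation_model(counts, target_max_rate = 1)
  offsum <- function(m) { d <- m; diag(d) <- 0; rowSums(d) }
  at_rates <- offsum(model$matrices[["A_T"]])
  expect_equal(unname(at_rates["A"]), 1.0)
  expect_equal(unname(at_rates["C"]), 0.5)
  # every row of every matrix remains stochastic
  for (m in model$matrices)
    expect_equal(rowSums(m), stats::setNames(rep(1, 4), BASES4),
                 tolerance = 1e-12)
})

test_that("rescaling with the identity target leaves the model unchanged", {
  counts <- counts_fixture(background = 50L, offdiag = 5L)
  plain <- lapply(counts$matrices, function(m) m / rowSums(m))
  r_max <- max(vapply(plain, function(p) {
    d <- p; diag(d) <- 0; max(rowSums(d))
  }, numeric(1)))
  model <- fit_mutation_model(counts, target_max_rate = r_max)
  expect_equal(model$matrices[["A_A"]], plain[["A_A"]], tolerance = 1e-12)
  expect_equal(model$normalization_scale, 1)
})

test_that("zero-count rows are a degenerate-data error naming the context", {
  at <- matrix(0L, 4, 4, dimnames = list(BASES4, BASES4))
  counts <- counts_fixture(at_rows = at, offdiag = 0L, background = 0L)
  expect_error(fit_mutation_model(counts), "zero-count row")
})

test_that("K2P rows place 3x the mass on the transition", {
  m <- k2p_model()
  for (ctx in c("A_A", "G_C")) for (b in BASES4) {
    row <- lookup_row(m, substr(ctx, 1, 1), substr(ctx, 3, 3), b)
    expect_equal(unname(row[b]), 0)  # all off-diagonal mass at target rate 1
    transition <- c(A = "G", C = "T", G = "A", T = "C")[[b]]
    expect_equal(unname(row[transition]), 3 / 5)
    for (tv in setdiff(BASES4, c(b, transition)))
      expect_equal(unname(row[tv]), 1 / 5)
  }
})

test_that("non-canonical contexts are served by complement relabelling", {
  # custom A_C matrix with a recognizable P(G->A)
  mats <- k2p_model()$matrices
  ac <- mats[["A_C"]]
  ac["G", ] <- c(0.7, 0.1, 0.1, 0.1)
  mats[["A_C"]] <- ac
  model <- mutation_model(mats, kind = "MC")
  # G_T complements to A_C; current C complements to G; derived T <-> A
  row <- lookup_row(model, "G", "T", "C")
  expect_equal(unname(row["T"]), 0.7)
  expect_equal(unname(row["C"]), 0.1)
  # totality and consistency across all 16 contexts x 4 bases
  for (f5 in BASES4) for (f3 in BASES4) for (b in BASES4) {
    r1 <- lookup_row(model, f5, f3, b)
    cc <- context_complement(paste(f5, f3, sep = "_"))
    r2 <- lookup_row(model, substr(cc, 1, 1), substr(cc, 3, 3),
                     chartr("ACGT", "TGCA", b))
    expect_equal(unname(r1), unname(rev(r2)))
    expect_equal(sum(r1), 1, tolerance = 1e-12)
  }
})

test_that("the K2P stationary vector is uniform", {
  pi <- stationary_vector(k2p_model()$matrices[["A_A"]])
  expect_equal(unname(pi), rep(0.25, 4), tolerance = 1e-12)
})

test_that("a two-state A/G chain has stationary odds b:a", {
  a <- 0.3; b <- 0.1
  p <- matrix(0, 4, 4, dimnames = list(BASES4, BASES4))
  p["A", "A"] <- 1 - a; p["A", "G"] <- a
  p["G", "A"] <- b; p["G", "G"] <- 1 - b
  p["C", "A"] <- 1; p["T", "A"] <- 1  # transient states feeding the chain
  pi <- stationary_vector(p)
  expect_equal(pi[["A"]] / pi[["G"]], b / a, tolerance = 1e-8)
  expect_equal(pi[["C"]], 0, tolerance = 1e-10)
})

test_that("matrix-power stationary agrees with the eigenvector oracle", {
  set.seed(2024)
  for (i in 1:200) {
    p <- random_stochastic_matrix()
    expect_equal(stationary_vector(p), eigen_stationary(p), tolerance = 1e-8)
  }
})

test_that("the stationary vector is invariant under the global rescale", {
  set.seed(7)
  counts <- counts_fixture(background = 200L, offdiag = 3L)
  plain <- lapply(counts$matrices, function(m) m / rowSums(m))
  model <- fit_mutation_model(counts, target_max_rate = 1)
  for (ctx in canonical_contexts()) {
    expect_equal(stationary_vector(plain[[ctx]]),
                 stationary_vector(model$matrices[[ctx]]), tolerance = 1e-8)
  }
})

test_that("non-converging (periodic) matrices raise an error", {
  p <- matrix(0, 4, 4, dimnames = list(BASES4, BASES4))
  p["A", "C"] <- 1; p["C", "A"] <- 1; p["G", "T"] <- 1; p["T", "G"] <- 1
  expect_error(stationary_vector(p), "did not converge")
})

test_that("model summaries compute Ts:Tv, rates and equilibrium skews", {
  # 6 transitions, 2 transversions from ancestral G/C in A_T; 100 sites total
  at <- matrix(0L, 4, 4, dimnames = list(BASES4, BASES4))
  at["G", "A"] <- 4L; at["C", "T"] <- 2L           # transitions from G/C
  at["G", "C"] <- 1L; at["C", "G"] <- 1L           # transversions from G/C
  at["A", "C"] <- 1L; at["T", "A"] <- 1L           # keep A/T rows ergodic
  diag(at) <- c(22L, 23L, 23L, 22L)
  counts <- counts_fixture(at_rows = at, offdiag = 1L, background = 100L)
  model <- fit_mutation_model(counts)
  s <- summary(model)
  row <- s[s$context == "A_T", ]
  expect_equal(row$ts_tv_gc, 3.0)
  expect_equal(row$sub_rate_per100, 100 * 10 / 100)

  # equilibrium block evaluated via a rank-one matrix whose stationary vector
  # is exactly the chosen composition
  pi <- c(A = 0.3, C = 0.25, G = 0.2, T = 0.25)
  rank1 <- matrix(pi, 4, 4, byrow = TRUE, dimnames = list(BASES4, BASES4))
  mats <- stats::setNames(rep(list(rank1), 10), canonical_contexts())
  m2 <- mutation_model(mats, kind = "MC")
  s2 <- summary(m2, counts = counts)
  expect_equal(s2$equil_gc, rep(45, 10))
  expect_equal(s2$equil_cg_skew, rep(100 * 0.05 / 0.45, 10), tolerance = 1e-12)
  expect_equal(s2$equil_ta_skew, rep(100 * -0.05 / 0.55, 10), tolerance = 1e-12)
})

test_that("undefined summary ratios are NA, not errors", {
  at <- matrix(0L, 4, 4, dimnames = list(BASES4, BASES4))
  diag(at) <- 10L
  at["G", "A"] <- 2L  # transitions only, nothing from A/T
  counts <- counts_fixture(at_rows = at, offdiag = 0L)
  model <- fit_mutation_model(counts)
  row <- summary(model)[summary(model)$context == "A_T", ]
  expect_true(is.na(row$ts_tv_gc))  # no transversions from G/C
  expect_true(is.na(row$ts_tv_at))  # no substitutions from A/T at all
})

test_that("model JSON serialization round-trips", {
  counts <- counts_fixture(background = 60L, offdiag = 2L)
  model <- fit_mutation_model(counts)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, f)
  back <- read_model_json(f)
  expect_equal(back$kind, model$kind)
  expect_equal(back$normalization_scale, model$normalization_scale)
  for (ctx in canonical_contexts())
    expect_equal(back$matrices[[ctx]], model$matrices[[ctx]])
})
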