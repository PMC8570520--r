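test_that("acceptable replacement sets collect observed residues per column", {
  acc <- acceptable_replacements(c("MAA", "MSA", "MA-"))
  expect_equal(acc[[1]], "M")
  expect_equal(acc[[2]], c("A", "S"))
  expect_equal(acc[[3]], "A")  # gap dropped
  expect_error(acceptable_replacements(character(0)), "empty")
  expect_error(acceptable_replacements(c("MA", "MAA")), "length")
})

test_that("a zero-mutation run returns the ancestral CAI only", {
  ft <- test_fitness()
  anc <- generate_coding(30, ft, beta = 2, seed = 1)
  tr <- simulate_decay(anc, ft, k2p_model(), n_mutations = 0, replicates = 3,
                       seed = 9)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$mean_cai, cai(anc, ft))
  expect_equal(tr$sd_cai, 0)
})

test_that("checkpoints are exact and start at the ancestral CAI with sd 0", {
  ft <- test_fitness()
  anc <- generate_coding(40, ft, beta = 3, seed = 2)
  tr <- simulate_decay(anc, ft, k2p_model(), n_mutations = 60,
                       record_every = 15, replicates = 8, seed = 4)
  expect_equal(tr$checkpoint, c(0L, 15L, 30L, 45L, 60L))
  expect_equal(tr$mean_cai[1], cai(anc, ft))
  expect_identical(tr$sd_cai[1], 0)
  expect_error(simulate_decay(anc, ft, k2p_model(), n_mutations = 7,
                              record_every = 5, replicates = 2, seed = 1),
               "divide")
})

test_that("synonymous-only runs preserve the protein and the frame", {
  ft <- test_fitness()
  anc <- generate_coding(50, ft, beta = 2, seed = 3)
  tr <- simulate_decay(anc, ft, example_context_model(), n_mutations = 120,
                       record_every = 30, replicates = 40, seed = 11,
                       keep_sequences = TRUE)
  finals <- attr(tr, "final_sequences")
  expect_length(finals, 40)
  for (f in finals) {
    expect_equal(f$length, anc$length)
    expect_equal(translate_cds(f), translate_cds(anc))  # also: no new stops
  }
})

test_that("trajectories are bit-identical under the same seed", {
  ft <- test_fitness()
  anc <- generate_coding(30, ft, beta = 2, seed = 5)
  t1 <- simulate_decay(anc, ft, k2p_model(), n_mutations = 50,
                       record_every = 10, replicates = 10, seed = 77)
  t2 <- simulate_decay(anc, ft, k2p_model(), n_mutations = 50,
                       record_every = 10, replicates = 10, seed = 77)
  t3 <- simulate_decay(anc, ft, k2p_model(), n_mutations = 50,
                       record_every = 10, replicates = 10, seed = 78)
  expect_identical(t1$mean_cai, t2$mean_cai)
  expect_identical(t1$sd_cai, t2$sd_cai)
  expect_false(identical(t1$mean_cai, t3$mean_cai))
})

test_that("an all-restrictive acceptability list reproduces syn-only exactly", {
  ft <- test_fitness()
  anc <- generate_coding(35, ft, beta = 2, seed = 6)
  aa <- translate_cds(anc)
  acc <- acceptable_replacements(aa)  # each site: only the ancestral residue
  syn <- simulate_decay(anc, ft, k2p_model(), mode = "syn_only",
                        n_mutations = 40, record_every = 10, replicates = 10,
                        seed = 21)
  non <- simulate_decay(anc, ft, k2p_model(), mode = "with_nonsyn",
                        acceptable = acc, dnds = 0.5, n_mutations = 40,
                        record_every = 10, replicates = 10, seed = 21)
  expect_identical(syn$mean_cai, non$mean_cai)
  expect_identical(syn$sd_cai, non$sd_cai)
})

test_that("realized nonsynonymous acceptance matches the configured dN/dS", {
  ft <- test_fitness()
  anc <- generate_coding(60, ft, beta = 2, seed = 7)
  # allow every residue everywhere so the dN/dS coin is exercised often
  acc <- structure(rep(list(cubdecay:::AA_LETTERS), 60),
                   class = "acceptable_replacements")
  dnds <- 0.1
  tr <- simulate_decay(anc, ft, example_context_model(), mode = "with_nonsyn",
                       acceptable = acc, dnds = dnds, n_mutations = 200,
                       record_every = 200, replicates = 50, seed = 13)
  st <- attr(tr, "stats")
  offered <- st[["nonsyn_offered"]]
  realized <- st[["nonsyn_accepted"]] / offered
  se <- sqrt(dnds * (1 - dnds) / offered)
  expect_gt(offered, 1000)
  expect_lt(abs(realized - dnds), 3 * se)
})

test_that("proposals are uniform over mutable sites under a context-free model", {
  ft <- test_fitness()
  anc <- generate_coding(40, ft, beta = 1, seed = 8)
  set.seed(99)
  res <- simulate_replicate(anc, ft, k2p_model(), n_mutations = 20000,
                            record_every = 20000, max_proposals = 1e7,
                            count_proposal_sites = TRUE)
  counts <- res$site_proposals[2:(anc$length - 1)]
  expect_equal(sum(res$site_proposals), res$proposals)
  expect_equal(sum(res$site_proposals[c(1, anc$length)]), 0)
  pval <- stats::chisq.test(counts)$p.value
  expect_gt(pval, 0.001)
})

test_that("degenerate ancestors trip the proposal cap instead of hanging", {
  # Met/Trp-only protein: no synonymous move exists anywhere
  ft <- test_fitness()
  anc <- coding_sequence(strrep("ATGTGG", 10), id = "stuck")
  expect_error(
    simulate_replicate(anc, ft, k2p_model(), n_mutations = 5,
                       record_every = 5, max_proposals = 2000),
    "proposal cap")
})

test_that("terminal CAI under K2P approaches the uniform-component oracle", {
  ft <- test_fitness()
  anc <- generate_coding(40, ft, beta = 5, seed = 10)
  tr <- simulate_decay(anc, ft, k2p_model(), n_mutations = 1000,
                       record_every = 250, replicates = 150, seed = 17)
  oracle <- syn_component_oracle(anc, ft)
  mc_se <- tr$sd_cai[nrow(tr)] / sqrt(attr(tr, "replicates"))
  expect_lt(abs(tr$mean_cai[nrow(tr)] - oracle), 3 * mc_se + 1e-6)
})

test_that("a maximal-CAI ancestor starts at 1 and decays in expectation", {
  ft <- test_fitness()
  major <- names(ft)[unclass(ft) == 1]
  anc <- coding_sequence(paste(c("ATG", rep(major, length.out = 45)),
                               collapse = ""), id = "optimal")
  tr <- simulate_decay(anc, ft, k2p_model(), n_mutations = 100,
                       record_every = 25, replicates = 100, seed = 23)
  expect_equal(tr$mean_cai[1], 1.0)
  expect_true(all(diff(tr$mean_cai) <= 0))
})

test_that("the simulate() generic delegates to simulate_decay", {
  ft <- test_fitness()
  anc <- generate_coding(25, ft, beta = 2, seed = 12)
  tr <- simulate(k2p_model(), nsim = 5, seed = 31, ancestor = anc, table = ft,
                 n_mutations = 20, record_every = 5)
  expect_s3_class(tr, "cai_trajectory")
  expect_equal(attr(tr, "replicates"), 5)
})

test_that("trajectory TSV round-trips", {
  ft <- test_fitness()
  anc <- generate_coding(25, ft, beta = 2, seed = 14)
  tr <- simulate_decay(anc, ft, k2p_model(), n_mutations = 20,
                       record_every = 5, replicates = 5, seed = 41)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, f)
  back <- read_trajectory_tsv(f)
  expect_identical(back$checkpoint, tr$checkpoint)
  expect_identical(back$mean_cai, tr$mean_cai)
  expect_identical(back$sd_cai, tr$sd_cai)
  expect_equal(attr(back, "replicates"), attr(tr, "replicates"))
})
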