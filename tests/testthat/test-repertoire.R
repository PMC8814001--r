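test_that("junction frame and stop-codon calls follow the productivity rules", {
  rep <- make_repertoire(
    v_call = c("IGHV3-15", "IGHV3-15", "IGHV1-2", NA),
    d_call = c("IGHD2-2", "IGHD2-2", "IGHD2-2", "IGHD3-10"),
    j_call = "IGHJ4",
    junction = c("TGTGCGAGATGG",   # 12 nt, in frame, no stop
                 "TGTGCGTAGTGG",   # in-frame TAG stop
                 "TGTGCGAGATGGA",  # 13 nt, out of frame
                 "TGTGCGAGATGG"))  # DJ-only record
  out <- callFrameProductivity(rep)
  expect_identical(out$frame_status, c("in", "in", "out", "in"))
  expect_identical(out$has_stop, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(out$productive, c(TRUE, FALSE, FALSE, FALSE))

  bad <- make_repertoire("V", "D", "J", "TGTXUG")
  expect_error(callFrameProductivity(bad), "ACGTN")
})

test_that("stop-codon scan agrees with the regex oracle on random junctions", {
  set.seed(42)
  jn <- vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(3:45, 1), replace = TRUE),
          collapse = ""), character(1))
  rep <- make_repertoire("V", "D", "J", jn)
  out <- callFrameProductivity(rep)
  expect_identical(out$has_stop, oracle_has_stop(jn))
  expect_identical(out$frame_status == "in", nchar(jn) %% 3L == 0L)
})

test_that("locus status distinguishes DJ, VDJ and unresolved records", {
  rep <- make_repertoire(v_call = c(NA, "IGHV3-15", NA),
                         d_call = c("IGHD3-10", NA, NA),
                         j_call = c("IGHJ4", "IGHJ4", "IGHJ6"),
                         junction = "TGTTGG")
  expect_message(status <- classifyLocusStatus(rep), "unresolved")
  expect_identical(as.character(status), c("DJ", "VDJ", "unresolved"))
})

test_that("DJ fraction honors record and template weighting", {
  rep <- make_repertoire(
    v_call = c(rep(NA, 2), rep("IGHV1-2", 8)),
    d_call = "IGHD2-2", j_call = "IGHJ4",
    junction = "TGTTGGTGG",
    duplicate_count = c(15L, 15L, rep(9L, 8L)))  # 30 DJ vs 72 VDJ templates
  expect_equal(djFraction(rep, "records"), 0.2)
  expect_equal(djFraction(rep, "templates"), 30 / 102)
  expect_error(djFraction(rep[0, ]), "empty")

  # dj + vdj fractions over resolvable records sum to 1
  sim <- simulateRepertoire(repertoireSimConfig(seed = 2, n_clones = 400,
                                                n_cells = 4000,
                                                p_dj = 0.3))
  status <- classifyLocusStatus(sim)
  expect_equal(djFraction(sim, "records") +
                 mean(status[status != "unresolved"] == "VDJ"), 1)
})

test_that("nonproductive fraction counts productivity classes", {
  junctions <- c(rep("TGTGCGAGATGG", 6), rep("TGTTAGTGGAAA", 4))
  rep <- make_repertoire("IGHV1-2", "IGHD2-2", "IGHJ4", junctions)
  expect_equal(nonproductiveFraction(rep, "records"), 0.4)
  all_prod <- make_repertoire("IGHV1-2", "IGHD2-2", "IGHJ4",
                              rep("TGTGCGAGATGG", 5))
  expect_equal(nonproductiveFraction(all_prod, "records"), 0)
})

test_that("N-insertion summaries reduce to the configured Poisson means", {
  rep <- make_repertoire("V", "D", "J", "TGTTGG")
  rep <- rep[rep(1, 3), ]
  rep$np1_length <- c(0L, 1L, 2L)
  rep$np2_length <- c(0L, 1L, 1L)
  s <- nInsertionSummary(rep)
  expect_equal(s$mean, (0 + 2 + 3) / 3)
  expect_identical(as.vector(s$histogram), c(1L, 0L, 1L, 1L))

  rep$np1_length <- 0L; rep$np2_length <- 0L
  s0 <- nInsertionSummary(rep)
  expect_equal(s0$mean, 0)
  expect_identical(as.vector(s0$histogram[1]), 3L)

  # two Poisson(lambda) junctions per VDJ record: mean total ~ 2 lambda
  sim <- simulateRepertoire(repertoireSimConfig(
    seed = 23, n_clones = 2000, n_cells = 10000, p_dj = 0,
    tdt_lambda = 3, nonproductive_survival = 1))
  expect_lt(abs(nInsertionSummary(sim)$mean - 6), 0.2)
})

test_that("clone frequencies are template-weighted, normalized and conserved", {
  rep <- make_repertoire(
    v_call = c("IGHV3-15", "IGHV3-15", "IGHV1-2"),
    d_call = "IGHD2-2", j_call = "IGHJ4",
    junction = c("TGTAAATGG", "TGTAAATGG", "TGTCCCTGG"),
    duplicate_count = c(4L, 5L, 9991L))
  cf <- cloneFrequencies(rep)
  expect_identical(nrow(cf), 2L)                # identical keys merge
  expect_equal(sum(cf$frequency), 1, tolerance = 1e-12)
  expect_equal(cf$percent[cf$v_call == "IGHV3-15"], 0.09)
  expect_identical(sum(cf$templates), sum(rep$duplicate_count))

  one <- cloneFrequencies(rep[1, ])
  expect_equal(one$frequency, 1)

  sim <- simulateRepertoire(repertoireSimConfig(seed = 31, n_clones = 300,
                                                n_cells = 3000))
  expect_equal(sum(cloneFrequencies(sim)$frequency), 1, tolerance = 1e-12)
  expect_identical(sum(cloneFrequencies(sim)$templates),
                   sum(sim$duplicate_count))
})

test_that("clone tracking reports per-sample frequencies, zero when absent", {
  base <- make_repertoire("IGHV1-2", "IGHD2-2", "IGHJ4",
                          c("TGTAAATGG", "TGTCCCTGG"),
                          duplicate_count = c(999L, 1L))
  other <- make_repertoire("IGHV1-2", "IGHD2-2", "IGHJ4",
                           c("TGTAAATGG", "TGTCCCTGG"),
                           duplicate_count = c(100L, 900L))
  tr <- trackClone(list(a = base, b = other), "IGHV1-2", "IGHJ4",
                   "TGTCCCTGG")
  expect_equal(tr$frequency, c(0.001, 0.9))
  expect_equal(tr$percent, c(0.1, 90))

  none <- trackClone(list(a = base), "IGHV9-9", "IGHJ4", "TGTTTTTGG")
  expect_equal(none$frequency, 0)

  # record order within files is irrelevant
  shuf <- other[2:1, ]
  tr2 <- trackClone(list(a = base, b = shuf), "IGHV1-2", "IGHJ4",
                    "TGTCCCTGG")
  expect_equal(tr2$frequency, tr$frequency)
})

test_that("clonality spans 0 (uniform) to 1 (monoclonal) and tracks concentration", {
  uni <- make_repertoire(paste0("V", 1:50), "D", "J",
                         paste0("TGT", strrep("A", 3 * (1:50)), "TGG"))
  expect_equal(clonalityIndex(uni), 0, tolerance = 1e-12)

  single <- uni[1, ]
  expect_warning(cl <- clonalityIndex(single), "continuity")
  expect_equal(cl, 1)

  cl_by_conc <- vapply(c(0.05, 0.5, 5), function(cc)
    clonalityIndex(simulateRepertoire(repertoireSimConfig(
      seed = 6, n_clones = 500, n_cells = 20000,
      clone_concentration = cc, nonproductive_survival = 1))),
    numeric(1))
  expect_true(all(diff(cl_by_conc) < 0))
})

test_that("repertoire statistics are invariant under record permutation", {
  sim <- simulateRepertoire(repertoireSimConfig(seed = 44, n_clones = 300,
                                                n_cells = 3000,
                                                p_dj = 0.2))
  set.seed(1)
  shuf <- sim[sample(nrow(sim)), ]
  expect_equal(djFraction(shuf), djFraction(sim))
  expect_equal(nonproductiveFraction(shuf), nonproductiveFraction(sim))
  expect_equal(nInsertionSummary(shuf)$mean, nInsertionSummary(sim)$mean)
  expect_equal(clonalityIndex(shuf), clonalityIndex(sim))
})

test_that("oligoclonality comparison separates known regimes", {
  junctions <- paste0("TGT", strrep("A", 3 * (1:1000)), "TGG")
  poly <- make_repertoire(paste0("V", 1:1000), "D", "J", junctions,
                          duplicate_count = 2L)
  mono <- poly
  mono$duplicate_count <- c(9000L, rep(1L, 999))

  res <- compareOligoclonality(poly, mono, n_boot = 1000, seed = 9)
  expect_lt(res$p_value, 0.01)
  expect_lt(res$delta, 0)

  same <- compareOligoclonality(poly, poly, n_boot = 300, seed = 10)
  expect_gt(same$p_value, 0.05)
  expect_lt(abs(same$delta), 0.05)

  # label swap flips the sign of delta; p stays comparable
  swap <- compareOligoclonality(mono, poly, n_boot = 1000, seed = 9)
  expect_lt(swap$p_value, 0.01)
  expect_gt(swap$delta, 0)

  shallow <- poly[1:10, ]
  expect_error(compareOligoclonality(shallow, poly), "depth")
})

test_that("repertoire summary assembles the headline statistics", {
  sim <- simulateRepertoire(repertoireSimConfig(seed = 55, n_clones = 400,
                                                n_cells = 4000,
                                                p_dj = 0.25))
  s <- repertoireSummary(sim)
  expect_identical(s$n_records, nrow(sim))
  expect_identical(s$n_templates, sum(sim$duplicate_count))
  expect_true(s$dj_fraction >= 0 && s$dj_fraction <= 1)
  expect_true(s$nonproductive_fraction >= 0 &&
                s$nonproductive_fraction <= 1)
  expect_gte(s$n_templates, s$n_records)
  expect_equal(s$top_clone_frequency,
               max(cloneFrequencies(sim)$frequency))
})
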