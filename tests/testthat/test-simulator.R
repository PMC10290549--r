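test_that("binding propensity counts eligible inter-cluster site pairs", {
  # 2 free Nephrin (3 pY each) + 1 free Nck (1 SH2): 6 x 1 pairs for the
  # y1 rule counts only the y1 sites -> per-rule pairs = 2 x 1
  m <- nephrin_nck_nwasp_model("custom", kon = 2, koff = 1,
                               n_nephrin = 2, n_nck = 1, n_nwasp = 0)
  free <- c(parse_complex("Nephrin(y1,y2,y3)", m),
            parse_complex("Nephrin(y1,y2,y3)", m),
            parse_complex("Nck(sh2,sh3a,sh3b,sh3c)", m))
  pr <- propensities(m, free)
  ypr <- pr[grepl("^neph_", pr$rule), ]
  # each of the 3 pY-SH2 rules sees 2 free y-sites x 1 free SH2
  expect_equal(ypr$binding, rep(2 * 2 * 1, 3))
  expect_equal(sum(ypr$binding), 2 * 6)  # 6 pY x 1 SH2 overall
  expect_equal(pr$dissociation, rep(0, nrow(pr)))

  # single cluster containing every molecule: no inter-cluster pairs
  dm <- dimer_model(kon = 3, koff = 0.5, nA = 1, nB = 1)
  dimer <- parse_complex("A(a!1).B(b!1)", dm)
  pr2 <- propensities(dm, dimer)
  expect_equal(pr2$binding, 0)
  expect_equal(pr2$dissociation, 0.5 * 1)

  # intra-cluster pairs are excluded even when free sites remain
  cm <- chain_model(kon = 1, koff = 0)
  aba <- parse_complex("A(a!1).B(b1!1,b2)", cm)       # one free b2 inside
  lone <- parse_complex("A(a)", cm)                   # one free a outside
  pr3 <- propensities(cm, c(aba, lone))
  # one free a (the lone A) x one free b2, and the intra-cluster a is bound
  expect_equal(pr3$binding[pr3$rule == "ab2"], 1)
})

test_that("a rule with kon = 0 leaves the pool monomeric and flat", {
  m <- dimer_model(kon = 0, koff = 0, nA = 6, nB = 4)
  tr <- run_trial(m, seed = 2, audit = TRUE)
  expect_length(tr$final_clusters, 10L)
  expect_true(all(vapply(tr$final_clusters, `[[`, 0L, "size") == 1L))
  expect_true(all(tr$timecourse$A_free == 6))
  expect_true(all(tr$timecourse$B_free == 4))
  expect_true(all(tr$timecourse$clusters == 10))
})

test_that("irreversible dimerization reaches the absorbing all-dimer state", {
  m <- dimer_model(kon = 5, koff = 0, nA = 10, nB = 10, t_end = 100)
  tr <- run_trial(m, seed = 9, audit = TRUE)
  sizes <- vapply(tr$final_clusters, `[[`, 0L, "size")
  expect_length(sizes, 10L)
  expect_true(all(sizes == 2L))
  expect_equal(utils::tail(tr$timecourse$ab_bonds, 1L), 10)
})

test_that("molecule counts are conserved and clusters stay valence-capped trees", {
  m <- nephrin_nck_nwasp_model("custom", kon = 0.05, koff = 0.05,
                               n_nephrin = 12, n_nck = 36, n_nwasp = 18,
                               t_end = 5, n_steps = 10)
  tr <- run_trial(m, seed = 13, audit = TRUE)  # audit re-checks every tally
  counts <- Reduce(`+`, lapply(tr$final_clusters, function(s) {
    out <- c(Nephrin = 0L, Nck = 0L, NWASP = 0L)
    out[names(s$type_counts)] <- s$type_counts
    out
  }))
  expect_identical(counts, c(Nephrin = 12L, Nck = 36L, NWASP = 18L))
  val <- c(Nephrin = 3L, Nck = 4L, NWASP = 6L)
  for (s in tr$final_clusters) {
    expect_equal(s$n_bonds, s$size - 1L)
    expect_true(all(s$degrees <= val[s$node_types]))
  }
  # free_molecule observables never exceed seeds at any output time
  expect_true(all(tr$timecourse$Nephrin_free <= 12))
  expect_true(all(tr$timecourse$Nck_free <= 36))
})

test_that("symmetric self-binding rules use unordered pair counts", {
  m <- selfbind_model(kon = 2, koff = 1, n = 4)
  free <- rep(parse_complex("A(u,v)", m), 4)
  pr <- propensities(m, free)
  expect_equal(pr$binding, 2 * choose(4, 2))
  tr <- run_trial(m, seed = 6, audit = TRUE)  # audit validates sym tallies
  expect_true(all(vapply(tr$final_clusters, `[[`, 0L, "n_bonds") >= 0))
})

test_that("ensembles are reproducible and trials are independent", {
  m <- dimer_model(kon = 1, koff = 1, nA = 8, nB = 8, n_runs = 4)
  e1 <- run_ensemble(m, master_seed = 123)
  e2 <- run_ensemble(m, master_seed = 123)
  expect_equal(e1, e2)
  # single-trial ensemble equals run_trial with the derived seed
  e3 <- run_ensemble(m, n_runs = 1, master_seed = 55)
  expect_equal(e3$trials[[1L]], run_trial(m, seed = trial_seed(55, 1)))
  # the simulate() generic is the same computation
  e4 <- simulate(m, nsim = 4, seed = 123)
  expect_equal(e4$trials, e1$trials)
  # different seeds give different trajectories (overwhelmingly)
  e5 <- run_ensemble(m, master_seed = 124)
  expect_false(identical(e1$trials, e5$trials))
})

test_that("pooled mean bond count of a small ensemble matches the exact law", {
  # 2A+2B at kon=koff: stationary bond distribution pi = (1,4,2)/7,
  # mean 8/7 (birth-death chain, up-rate kon*(2-b)^2, down-rate koff*b)
  m <- dimer_model(kon = 1, koff = 1, nA = 2, nB = 2,
                   t_end = 60, n_steps = 1, n_runs = 50)
  ens <- run_ensemble(m, master_seed = 31)
  bonds <- vapply(ens$trials, function(tr)
    sum(vapply(tr$final_clusters, `[[`, 0L, "n_bonds")), 0L)
  mu <- 8 / 7
  sigma <- sqrt(sum(c(1, 4, 2) / 7 * (0:2 - mu)^2))
  expect_lt(abs(mean(bonds) - mu), 3 * sigma / sqrt(length(bonds)))
})

test_that("written outputs round-trip through the file readers", {
  m <- dimer_model(kon = 2, koff = 0.2, nA = 6, nB = 6, n_runs = 3)
  ens <- run_ensemble(m, master_seed = 17)
  dir <- withr::local_tempdir()
  paths <- write_outputs(ens, dir)
  expect_length(list.files(dir, "\\.gdat$"), 3L)
  expect_length(list.files(dir, "\\.species$"), 3L)
  # gdat round trip
  tc <- read_gdat(file.path(dir, "trial_01.gdat"))
  expect_equal(as.data.frame(tc),
               as.data.frame(ens$trials[[1L]]$timecourse),
               tolerance = 1e-7)
  # species round trip: pooled summary multiset is preserved
  sp <- read_species_file(file.path(dir, "trial_02.species"))
  expect_equal(sum(sp$count), length(ens$trials[[2L]]$final_clusters))
  back <- pool_clusters(sp, m)
  orig <- pool_clusters(ens$trials[[2L]]$final_clusters)
  key <- function(p) sort(vapply(p, function(s)
    paste(s$size, s$n_bonds, paste(sort(names(s$type_counts)),
                                   s$type_counts, collapse = "+")), ""))
  expect_identical(key(back), key(orig))
  # all-monomer trial writes aggregated monomer lines
  m0 <- dimer_model(kon = 0, koff = 0, nA = 100, nB = 0)
  e0 <- run_ensemble(m0, n_runs = 1, master_seed = 1)
  write_outputs(e0, dir, prefix = "mono")
  expect_identical(readLines(file.path(dir, "mono_01.species")), "A(a) 100")
})

test_that("a model with zero copies fast-forwards with flat observables", {
  m <- dimer_model(kon = 1, koff = 1, nA = 0, nB = 0)
  tr <- run_trial(m, seed = 1)
  expect_length(tr$final_clusters, 0L)
  expect_equal(nrow(tr$timecourse), 11L)
  expect_true(all(tr$timecourse$A_free == 0))
})
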