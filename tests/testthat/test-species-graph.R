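test_that("a scaffold-adapter dimer parses to the hand-counted summary", {
  m <- nephrin_nck_nwasp_model()
  cls <- parse_complex("Nephrin(y1!1,y2,y3).Nck(sh2!1,sh3a,sh3b,sh3c)", m)
  expect_length(cls, 1L)
  s <- summarize_cluster(cls[[1L]])
  expect_equal(s$size, 2L)
  expect_equal(s$n_bonds, 1L)
  expect_equal(s$total_sites, 7L)       # 3 pY + 4 Nck domains
  expect_equal(s$bound_sites, 2L)       # one bond engages two sites
  expect_equal(s$bound_fraction, 2 / 7)
  expect_equal(sort(s$degrees), c(1L, 1L))
})

test_that("monomers, dangling labels and over-used labels behave", {
  m <- dimer_model()
  mono <- parse_complex("A(a)", m)
  expect_length(mono, 1L)
  s <- summarize_cluster(mono[[1L]])
  expect_equal(s$size, 1L)
  expect_equal(s$bound_fraction, 0)
  expect_equal(s$degrees, 0L)
  expect_error(parse_complex("A(a!1)", m), "dangling")
  expect_error(parse_complex("A(a!1).B(b!1).A(a!1)", dimer_model()),
               "3 times")
  expect_error(parse_complex("C(c)", m), "undeclared molecule")
  expect_error(parse_complex("A(z)", m), "undeclared site")
  # disconnected input: one cluster per component
  two <- parse_complex("A(a).B(b)", m)
  expect_length(two, 2L)
})

test_that("chain A-B-A summary matches the hand count", {
  s <- summarize_cluster(chain_aba())
  expect_equal(s$size, 3L)
  expect_equal(s$n_bonds, 2L)
  expect_equal(s$total_sites, 4L)
  expect_equal(s$bound_fraction, 1.0)
  expect_equal(sort(s$degrees), c(1L, 1L, 2L))
  expect_true(s$is_tree)
})

test_that("canonical emission is invariant under node permutation", {
  m <- nephrin_nck_nwasp_model()
  set.seed(4)
  clusters <- generate_synthetic_clusters(c("2" = 2, "3" = 2, "4" = 2),
                                          m, seed = 21)
  for (g in clusters) {
    n <- length(g$types)
    ref <- emit_complex(g)
    perms <- gtools_permutations(n)
    for (r in seq_len(nrow(perms)))
      expect_identical(emit_complex(perm_cluster(g, perms[r, ])), ref)
  }
})

test_that("parse_complex(emit_complex(c)) is isomorphic to c", {
  m <- nephrin_nck_nwasp_model()
  clusters <- generate_synthetic_clusters(c("1" = 1, "3" = 2, "5" = 2, "6" = 2),
                                          m, seed = 8)
  for (g in clusters) {
    back <- parse_complex(emit_complex(g), m)
    expect_length(back, 1L)
    expect_true(clusters_isomorphic(g, back[[1L]]))
  }
})

test_that("cyclic complexes parse on the read side and are flagged non-tree", {
  m <- selfbind_model()
  ring <- parse_complex("A(u!1,v!2).A(u!2,v!1)", m)[[1L]]
  s <- summarize_cluster(ring)
  expect_equal(s$size, 2L)
  expect_equal(s$n_bonds, 2L)
  expect_false(s$is_tree)
  expect_error(parse_complex("A(u!1,v!1)", m), "self-bond")
  # emit/parse of a cyclic cluster still round-trips exactly
  expect_equal(summarize_cluster(parse_complex(emit_complex(ring),
                                               m)[[1L]])$n_bonds, 2L)
})

test_that("per-molecule bound fraction is occupied sites over valence", {
  m <- nephrin_nck_nwasp_model()
  dimer <- parse_complex("Nephrin(y1!1,y2,y3).Nck(sh2!1,sh3a,sh3b,sh3c)",
                         m)[[1L]]
  nck <- which(dimer$types == "Nck")
  expect_equal(molecule_bound_fraction(dimer, nck), 1 / 4)
  mono <- parse_complex("NWASP(p1,p2,p3,p4,p5,p6)", m)[[1L]]
  expect_equal(molecule_bound_fraction(mono, 1L), 0)
  full <- chain_aba()
  expect_equal(molecule_bound_fraction(full, 2L), 1)  # both B sites bound
})

test_that("synthetic cluster generation honors sizes, rules, and seeds", {
  m <- nephrin_nck_nwasp_model()
  mono5 <- generate_synthetic_clusters(c("1" = 5), m, seed = 3)
  expect_length(mono5, 5L)
  expect_true(all(vapply(mono5, function(g) length(g$types), 0L) == 1L))

  # valence-1 + valence-1 model cannot reach size 3
  expect_error(generate_synthetic_clusters(c("3" = 1), dimer_model(),
                                           seed = 1, max_tries = 10),
               "unreachable")

  d1 <- generate_synthetic_clusters(c("2" = 10), m, seed = 11)
  d2 <- generate_synthetic_clusters(c("2" = 10), m, seed = 11)
  expect_equal(d1, d2)
  expect_true(all(vapply(d1, function(g) length(g$types), 0L) == 2L))
  # every edge respects a declared rule
  r <- m$rules
  for (g in d1) {
    e <- g$edges
    key <- paste(g$types[e$a], e$site_a, g$types[e$b], e$site_b)
    rkey <- c(paste(r$mol_a, r$site_a, r$mol_b, r$site_b),
              paste(r$mol_b, r$site_b, r$mol_a, r$site_a))
    expect_true(all(key %in% rkey))
  }
})

test_that("handshake lemma and degree caps hold on generated clusters", {
  m <- nephrin_nck_nwasp_model()
  clusters <- generate_synthetic_clusters(
    stats::setNames(rep(1, 8), 1:8), m, seed = 5)
  val <- c(Nephrin = 3L, Nck = 4L, NWASP = 6L)
  tot_bound <- 0
  tot_bonds <- 0
  for (g in clusters) {
    s <- summarize_cluster(g)
    tot_bound <- tot_bound + s$bound_sites
    tot_bonds <- tot_bonds + s$n_bonds
    expect_true(all(s$degrees <= val[s$node_types]))
    expect_equal(s$n_bonds, s$size - 1L)  # trees
  }
  expect_equal(tot_bound, 2 * tot_bonds)
})
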