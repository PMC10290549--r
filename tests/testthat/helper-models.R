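# Shared fixtures: tiny models, hand-built clusters, and independent
# brute-force oracles the statistics are checked against.

dimer_model <- function(kon = 1, koff = 1, nA = 10, nB = 10,
                        t_end = 10, n_steps = 10, n_runs = 1, seed = 1) {
  bngl_model(
    list(A = "a", B = "b"), c(A = nA, B = nB),
    binding_rule("A", "a", "B", "b", kon, koff, name = "ab"),
    observables = data.frame(
      name = c("A_free", "B_free", "ab_bonds", "clusters"),
      kind = c("free_molecule", "free_molecule", "bond_count",
               "total_clusters"),
      target = c("A", "B", "ab", ""), stringsAsFactors = FALSE),
    sim_params = list(t_end = t_end, n_steps = n_steps, n_runs = n_runs,
                      seed = seed))
}

# A has 1 site, B has 2 sites: chains A-B-A possible
chain_model <- function(kon = 1, koff = 1, nA = 10, nB = 5) {
  bngl_model(
    list(A = "a", B = c("b1", "b2")), c(A = nA, B = nB),
    binding_rule("A", "a", "B", c("b1", "b2"), kon, koff,
                 name = c("ab1", "ab2")),
    sim_params = list(t_end = 5, n_steps = 5, n_runs = 1, seed = 1))
}

# single-type symmetric self-binding
selfbind_model <- function(kon = 1, koff = 1, n = 10) {
  bngl_model(
    list(A = c("u", "v")), c(A = n),
    binding_rule("A", "u", "A", "u", kon, koff, name = "uu"),
    sim_params = list(t_end = 5, n_steps = 5, n_runs = 1, seed = 1))
}

# hand-built cluster: chain A-B-A under chain_model types
chain_aba <- function() {
  cluster_graph(
    types = c("A", "B", "A"),
    sites = list("a", c("b1", "b2"), "a"),
    edges = data.frame(a = c(1L, 3L), site_a = c("a", "a"),
                       b = c(2L, 2L), site_b = c("b1", "b2"),
                       rule = c("ab1", "ab2"), stringsAsFactors = FALSE))
}

example_text <- function() {
  c("begin model",
    "begin molecule types",
    "  Nephrin(y1,y2,y3)",
    "  Nck(sh2,sh3a,sh3b,sh3c)",
    "  NWASP(p1,p2,p3,p4,p5,p6)",
    "end molecule types",
    "begin seed species",
    "  Nephrin 8",
    "  Nck 12",
    "  NWASP 6",
    "end seed species",
    "begin reaction rules",
    "  r1: Nephrin(y1) + Nck(sh2) <-> Nephrin(y1!1).Nck(sh2!1) 0.5, 0.1",
    "  r2: Nck(sh3a) + NWASP(p1) <-> Nck(sh3a!1).NWASP(p1!1) 0.5, 0.1",
    "end reaction rules",
    "begin observables",
    "  free_molecule Nck_free Nck",
    "  free_site sh2_free Nck.sh2",
    "  bond_count r1_bonds r1",
    "  total_clusters n_clusters",
    "end observables",
    "end model",
    "simulate t_end=2 n_steps=4 n_runs=2 seed=7")
}

as_tc <- function(df) structure(df, class = c("timecourse", "data.frame"))

pool_sizes_test <- function(pool) vapply(pool, `[[`, 0L, "size")

# ---- independent brute-force oracles (naive enumeration) ----------------

# degrees recomputed by scanning the edge table, not via summarize_cluster
naive_degrees <- function(g) {
  d <- integer(length(g$types))
  for (i in seq_len(nrow(g$edges))) {
    d[g$edges$a[i]] <- d[g$edges$a[i]] + 1L
    d[g$edges$b[i]] <- d[g$edges$b[i]] + 1L
  }
  d
}

naive_occupancy <- function(graphs) {
  sizes <- vapply(graphs, function(g) length(g$types), 0L)
  total <- sum(sizes)
  us <- sort(unique(sizes))
  frac <- vapply(us, function(s) sum(sizes[sizes == s]) / total, 0)
  list(size = us, fraction = frac, aco = sum(sizes^2) / total)
}

naive_binned <- function(graphs, breaks) {
  sizes <- vapply(graphs, function(g) length(g$types), 0L)
  total <- sum(sizes)
  upper <- c(breaks[-1] - 1L, Inf)
  vapply(seq_along(breaks), function(i)
    sum(sizes[sizes >= breaks[i] & sizes <= upper[i]]) / total, 0)
}

naive_bond_hist <- function(graphs, scope = "all") {
  degs <- unlist(lapply(graphs, function(g) {
    d <- naive_degrees(g)
    if (scope == "all") d else d[g$types == scope]
  }))
  list(fraction = as.vector(table(factor(degs, levels = 0:max(degs, 0)))) /
         length(degs),
       mean = mean(degs))
}

naive_bf <- function(g) {
  2 * nrow(g$edges) / sum(lengths(g$sites))
}

naive_bf_matrix <- function(graphs, size_breaks, w) {
  n_bf <- ceiling(1 / w)
  m <- matrix(0, n_bf, length(size_breaks))
  upper <- c(size_breaks[-1] - 1L, Inf)
  for (g in graphs) {
    s <- length(g$types)
    si <- which(s >= size_breaks & s <= upper)
    bi <- min(floor(naive_bf(g) / w) + 1, n_bf)
    m[bi, si] <- m[bi, si] + 1
  }
  for (j in seq_len(ncol(m))) if (sum(m[, j]) > 0) m[, j] <- m[, j] / sum(m[, j])
  m
}

naive_composition <- function(graphs, types) {
  sizes <- vapply(graphs, function(g) length(g$types), 0L)
  us <- sort(unique(sizes))
  m <- matrix(0, length(types), length(us), dimnames = list(types, us))
  for (g in graphs) {
    j <- match(length(g$types), us)
    for (t in g$types) m[t, j] <- m[t, j] + 1
  }
  for (j in seq_along(us)) m[, j] <- m[, j] / sum(m[, j])
  m
}

# ---- brute-force graph isomorphism on small clusters --------------------

perm_cluster <- function(g, perm) {
  inv <- order(perm)  # node i moves to position inv[i]
  e <- g$edges
  e$a <- inv[e$a]
  e$b <- inv[e$b]
  cluster_graph(g$types[perm], g$sites[perm], e)
}

edge_key_set <- function(g) {
  keys <- vapply(seq_len(nrow(g$edges)), function(i) {
    e1 <- paste0(g$edges$a[i], ":", g$edges$site_a[i])
    e2 <- paste0(g$edges$b[i], ":", g$edges$site_b[i])
    paste(sort(c(e1, e2)), collapse = "--")
  }, "")
  sort(keys)
}

clusters_isomorphic <- function(g1, g2) {
  n <- length(g1$types)
  if (n != length(g2$types)) return(FALSE)
  if (n > 7) stop("brute-force isomorphism is for small clusters only")
  perms <- if (n == 1) list(1L) else
    apply(gtools_permutations(n), 1, identity, simplify = FALSE)
  k1 <- edge_key_set(g1)
  for (p in perms) {
    if (!identical(g1$types, g2$types[p])) next
    if (identical(k1, edge_key_set(perm_cluster(g2, p)))) return(TRUE)
  }
  FALSE
}

# all permutations of 1..n (tiny n), base R
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
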