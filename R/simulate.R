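# Network-free stochastic simulation (exact SSA, direct method) of
# reversible multivalent site-site binding over a supply-limited pool.
#
# State bookkeeping keeps every propensity O(1)-updatable per event:
#   - clusters partition the molecule pool; every cluster is a tree because
#     binding acts only between distinct clusters (no ring closure), so a
#     dissociation always splits a cluster in two;
#   - per-cluster free-site tallies per endpoint (clfree) and the per-rule
#     sum over clusters of free_a * free_b (sum_ab) give the number of
#     eligible inter-cluster site pairs without enumerating them:
#       pairs(r) = tot_a * tot_b - sum_ab      (distinct endpoints)
#       pairs(r) = C(tot,2) - sum_c C(free_c,2) (symmetric rule)
#   - binding propensity = kon * pairs(r); dissociation = koff * bonds(r).

# --- model compilation -------------------------------------------------

compile_model <- function(model) {
  tnames <- names(model$molecule_types)
  val <- lengths(model$molecule_types)
  ep_offset <- stats::setNames(cumsum(c(0L, val))[seq_along(val)], tnames)
  n_ep <- sum(val)
  ep_name <- unlist(lapply(tnames, function(t)
    paste(t, model$molecule_types[[t]], sep = ".")), use.names = FALSE)
  r <- model$rules
  n_rules <- nrow(r)
  site_pos <- function(tp, s) match(s, model$molecule_types[[tp]])
  pa <- mapply(site_pos, r$mol_a, r$site_a, USE.NAMES = FALSE)
  pb <- mapply(site_pos, r$mol_b, r$site_b, USE.NAMES = FALSE)
  if (!n_rules) pa <- pb <- integer(0)
  ea <- unname(ep_offset[r$mol_a]) + pa
  eb <- unname(ep_offset[r$mol_b]) + pb
  list(tnames = tnames, val = val, n_ep = n_ep, ep_name = ep_name,
       ep_offset = ep_offset,
       n_rules = n_rules,
       rule_name = r$name,
       rule_ta = match(r$mol_a, tnames), rule_pa = pa, rule_ea = ea,
       rule_tb = match(r$mol_b, tnames), rule_pb = pb, rule_eb = eb,
       rule_sym = ea == eb,
       kon = r$kon, koff = r$koff)
}

compile_observables <- function(model, cm) {
  o <- model$observables
  lapply(seq_len(nrow(o)), function(i) {
    kind <- o$kind[i]
    idx <- switch(kind,
      free_molecule = match(o$target[i], cm$tnames),
      free_site = {
        parts <- strsplit(o$target[i], ".", fixed = TRUE)[[1L]]
        unname(cm$ep_offset[parts[1L]]) +
          match(parts[2L], model$molecule_types[[parts[1L]]])
      },
      bond_count = match(o$target[i], cm$rule_name),
      total_clusters = 0L)
    list(name = o$name[i], kind = kind, idx = idx)
  })
}

# --- mutable simulation state ------------------------------------------

new_state <- function(model, cm) {
  counts <- stats::setNames(rep(0L, length(cm$tnames)), cm$tnames)
  counts[names(model$seeds)] <- model$seeds
  N <- sum(counts)
  mol_type <- rep(seq_along(cm$tnames), counts)
  st <- new.env(parent = emptyenv())
  st$N <- N
  st$mol_type <- mol_type
  st$occ <- lapply(mol_type, function(t) integer(cm$val[t]))
  st$cl_of <- seq_len(N)
  st$cl_members <- as.list(seq_len(N))
  st$cl_size <- rep(1L, N)
  st$cl_free_ids <- integer(0)             # recyclable cluster ids
  st$clfree <- matrix(0, nrow = max(N, 1L), ncol = cm$n_ep)
  for (m in seq_len(N)) {
    t <- mol_type[m]
    st$clfree[m, cm$ep_offset[t] + seq_len(cm$val[t])] <- 1
  }
  st$free_tot <- if (N) colSums(st$clfree[seq_len(N), , drop = FALSE]) else
    numeric(cm$n_ep)
  # per-endpoint lists of molecules with that site free
  st$fl_ids <- vector("list", cm$n_ep)
  st$fl_len <- integer(cm$n_ep)
  st$fl_pos <- matrix(0L, nrow = max(N, 1L), ncol = cm$n_ep)
  for (e in seq_len(cm$n_ep)) st$fl_ids[[e]] <- integer(0)
  for (m in seq_len(N)) {
    t <- mol_type[m]
    for (p in seq_len(cm$val[t])) fl_add(st, cm$ep_offset[t] + p, m)
  }
  # bonds
  cap <- 256L
  st$bn_ma <- integer(cap); st$bn_pa <- integer(cap)
  st$bn_mb <- integer(cap); st$bn_pb <- integer(cap)
  st$bn_rule <- integer(cap)
  st$bn_free <- rev(seq_len(cap))
  st$mol_bonds <- lapply(seq_len(N), function(i) integer(0))
  st$rule_bonds <- lapply(seq_len(max(cm$n_rules, 1L)), function(i) integer(0))
  st$rb_len <- integer(cm$n_rules)
  st$bond_rbpos <- integer(cap)
  st$n_clusters <- N
  st$monomer_by_type <- unname(counts)
  st$sum_ab <- numeric(cm$n_rules)
  for (c in seq_len(N)) sumab_shift(st, cm, c, +1)
  st$visited <- rep(FALSE, max(N, 1L))
  st
}

fl_add <- function(st, e, m) {
  len <- st$fl_len[e] + 1L
  if (len > length(st$fl_ids[[e]]))
    st$fl_ids[[e]] <- c(st$fl_ids[[e]], integer(max(16L, len)))
  st$fl_ids[[e]][len] <- m
  st$fl_pos[m, e] <- len
  st$fl_len[e] <- len
}

fl_rm <- function(st, e, m) {
  p <- st$fl_pos[m, e]
  last <- st$fl_len[e]
  lm <- st$fl_ids[[e]][last]
  st$fl_ids[[e]][p] <- lm
  st$fl_pos[lm, e] <- p
  st$fl_pos[m, e] <- 0L
  st$fl_len[e] <- last - 1L
}

# add (sign=+1) or remove (sign=-1) cluster c's contribution to sum_ab
sumab_shift <- function(st, cm, c, sign) {
  if (!cm$n_rules) return(invisible())
  a <- st$clfree[c, cm$rule_ea]
  b <- st$clfree[c, cm$rule_eb]
  contrib <- ifelse(cm$rule_sym, a * (a - 1) / 2, a * b)
  st$sum_ab <- st$sum_ab + sign * contrib
  invisible()
}

alloc_bond <- function(st) {
  if (!length(st$bn_free)) {
    cap <- length(st$bn_ma)
    grow <- integer(cap)
    st$bn_ma <- c(st$bn_ma, grow); st$bn_pa <- c(st$bn_pa, grow)
    st$bn_mb <- c(st$bn_mb, grow); st$bn_pb <- c(st$bn_pb, grow)
    st$bn_rule <- c(st$bn_rule, grow); st$bond_rbpos <- c(st$bond_rbpos, grow)
    st$bn_free <- rev(cap + seq_len(cap))
  }
  id <- st$bn_free[length(st$bn_free)]
  st$bn_free <- st$bn_free[-length(st$bn_free)]
  id
}

# --- propensities -------------------------------------------------------

state_propensities <- function(st, cm) {
  if (!cm$n_rules) return(list(bind = numeric(0), diss = numeric(0)))
  ta <- st$free_tot[cm$rule_ea]
  tb <- st$free_tot[cm$rule_eb]
  pairs <- ifelse(cm$rule_sym, ta * (ta - 1) / 2, ta * tb) - st$sum_ab
  list(bind = cm$kon * pairs, diss = cm$koff * st$rb_len)
}

#' Event-channel propensities of a cluster configuration
#'
#' Recomputes, from scratch, the binding and dissociation propensities the
#' stochastic engine uses, given a full partition of the molecule pool into
#' clusters. For each rule the binding propensity is `kon` times the number
#' of eligible free site pairs lying in *distinct* clusters (intra-cluster,
#' ring-closing pairs are excluded; clusters stay trees); for a symmetric
#' rule (both endpoints the same site) unordered pairs are counted. The
#' dissociation propensity is `koff` times the current number of bonds the
#' rule has formed. This pure function exists as an oracle and analysis
#' surface; the engine maintains the same quantities incrementally.
#'
#' @param model a [bngl_model()].
#' @param clusters list of [cluster_graph()] covering the molecule pool.
#' @return Data frame with columns `rule`, `binding`, `dissociation`.
#' @export
#' @examples
#' m <- bngl_model(list(A = "a", B = "b"), c(A = 2, B = 1),
#'                 binding_rule("A", "a", "B", "b", 1, 1),
#'                 sim_params = list(t_end = 1, n_steps = 1, n_runs = 1))
#' free <- c(parse_complex("A(a)", m), parse_complex("A(a)", m),
#'           parse_complex("B(b)", m))
#' propensities(m, free)
propensities <- function(model, clusters) {
  cm <- compile_model(model)
  r <- model$rules
  # per-cluster free-site counts per endpoint
  freemat <- t(vapply(clusters, function(g) {
    row <- numeric(cm$n_ep)
    bound <- paste(c(g$edges$a, g$edges$b), c(g$edges$site_a, g$edges$site_b))
    for (v in seq_along(g$types)) {
      t <- match(g$types[v], cm$tnames)
      for (p in seq_along(g$sites[[v]])) {
        if (!paste(v, g$sites[[v]][p]) %in% bound)
          row[cm$ep_offset[t] + p] <- row[cm$ep_offset[t] + p] + 1
      }
    }
    row
  }, numeric(cm$n_ep)))
  tot <- colSums(freemat)
  bind <- diss <- numeric(cm$n_rules)
  for (i in seq_len(cm$n_rules)) {
    a <- freemat[, cm$rule_ea[i]]
    b <- freemat[, cm$rule_eb[i]]
    pairs <- if (cm$rule_sym[i])
      tot[cm$rule_ea[i]] * (tot[cm$rule_ea[i]] - 1) / 2 - sum(a * (a - 1) / 2)
    else
      tot[cm$rule_ea[i]] * tot[cm$rule_eb[i]] - sum(a * b)
    bind[i] <- cm$kon[i] * pairs
    # bonds read from complex strings carry no rule name; attribute them by
    # matching the site pair against the rule pattern (either orientation)
    nb <- sum(vapply(clusters, function(g) {
      e <- g$edges
      named <- !is.na(e$rule) & e$rule == cm$rule_name[i]
      ta <- g$types[e$a]; tb <- g$types[e$b]
      fwd <- ta == r$mol_a[i] & e$site_a == r$site_a[i] &
        tb == r$mol_b[i] & e$site_b == r$site_b[i]
      rev <- ta == r$mol_b[i] & e$site_a == r$site_b[i] &
        tb == r$mol_a[i] & e$site_b == r$site_a[i]
      sum(named | (is.na(e$rule) & (fwd | rev)))
    }, 0))
    diss[i] <- cm$koff[i] * nb
  }
  data.frame(rule = cm$rule_name, binding = bind, dissociation = diss,
             stringsAsFactors = FALSE)
}

# --- events -------------------------------------------------------------

# sample an eligible inter-cluster (molecule_a, molecule_b) pair for rule r;
# uniform over eligible pairs (rejection with exact fallback)
sample_pair <- function(st, cm, r) {
  ea <- cm$rule_ea[r]; eb <- cm$rule_eb[r]
  sym <- cm$rule_sym[r]
  for (k in seq_len(100L)) {
    if (sym) {
      ij <- sample.int(st$fl_len[ea], 2L)
      ma <- st$fl_ids[[ea]][ij[1L]]
      mb <- st$fl_ids[[ea]][ij[2L]]
    } else {
      ma <- st$fl_ids[[ea]][sample.int(st$fl_len[ea], 1L)]
      mb <- st$fl_ids[[eb]][sample.int(st$fl_len[eb], 1L)]
    }
    if (st$cl_of[ma] != st$cl_of[mb]) return(c(ma, mb))
  }
  # exact fallback: weight each a-molecule by its eligible partners
  # (free b-sites outside its own cluster; for a symmetric rule this
  # already excludes the site itself)
  ids_a <- st$fl_ids[[ea]][seq_len(st$fl_len[ea])]
  ca <- st$cl_of[ids_a]
  w <- st$free_tot[eb] - st$clfree[cbind(ca, eb)]
  ma <- ids_a[sample.int(length(ids_a), 1L, prob = w)]
  ids_b <- st$fl_ids[[eb]][seq_len(st$fl_len[eb])]
  ids_b <- ids_b[st$cl_of[ids_b] != st$cl_of[ma]]
  mb <- ids_b[sample.int(length(ids_b), 1L)]
  c(ma, mb)
}

do_bind <- function(st, cm, r, ma, mb) {
  ea <- cm$rule_ea[r]; eb <- cm$rule_eb[r]
  pa <- cm$rule_pa[r]; pb <- cm$rule_pb[r]
  ca <- st$cl_of[ma]; cb <- st$cl_of[mb]
  sumab_shift(st, cm, ca, -1)
  sumab_shift(st, cm, cb, -1)
  id <- alloc_bond(st)
  st$bn_ma[id] <- ma; st$bn_pa[id] <- pa
  st$bn_mb[id] <- mb; st$bn_pb[id] <- pb
  st$bn_rule[id] <- r
  st$occ[[ma]][pa] <- id
  st$occ[[mb]][pb] <- id
  st$mol_bonds[[ma]] <- c(st$mol_bonds[[ma]], id)
  st$mol_bonds[[mb]] <- c(st$mol_bonds[[mb]], id)
  st$rb_len[r] <- st$rb_len[r] + 1L
  if (st$rb_len[r] > length(st$rule_bonds[[r]]))
    st$rule_bonds[[r]] <- c(st$rule_bonds[[r]],
                            integer(max(16L, st$rb_len[r])))
  st$rule_bonds[[r]][st$rb_len[r]] <- id
  st$bond_rbpos[id] <- st$rb_len[r]
  fl_rm(st, ea, ma)
  fl_rm(st, eb, mb)
  st$free_tot[ea] <- st$free_tot[ea] - 1
  st$free_tot[eb] <- st$free_tot[eb] - 1
  # merge clusters: larger one keeps its id
  if (st$cl_size[ca] < st$cl_size[cb]) { tmp <- ca; ca <- cb; cb <- tmp }
  if (st$cl_size[ca] == 1L)
    st$monomer_by_type[st$mol_type[st$cl_members[[ca]][1L]]] <-
      st$monomer_by_type[st$mol_type[st$cl_members[[ca]][1L]]] - 1L
  if (st$cl_size[cb] == 1L)
    st$monomer_by_type[st$mol_type[st$cl_members[[cb]][1L]]] <-
      st$monomer_by_type[st$mol_type[st$cl_members[[cb]][1L]]] - 1L
  st$clfree[ca, ] <- st$clfree[ca, ] + st$clfree[cb, ]
  st$clfree[ca, ea] <- st$clfree[ca, ea] - 1
  st$clfree[ca, eb] <- st$clfree[ca, eb] - 1
  st$clfree[cb, ] <- 0
  st$cl_of[st$cl_members[[cb]]] <- ca
  st$cl_members[[ca]] <- c(st$cl_members[[ca]], st$cl_members[[cb]])
  st$cl_size[ca] <- st$cl_size[ca] + st$cl_size[cb]
  st$cl_members[[cb]] <- integer(0)
  st$cl_size[cb] <- 0L
  st$cl_free_ids <- c(st$cl_free_ids, cb)
  st$n_clusters <- st$n_clusters - 1L
  sumab_shift(st, cm, ca, +1)
  invisible()
}

# component of `start` within cluster `c` after a bond removal (tree split)
component_of <- function(st, start, csize) {
  res <- integer(csize)
  res[1L] <- start
  st$visited[start] <- TRUE
  head <- 1L; cnt <- 1L
  while (head <= cnt) {
    v <- res[head]; head <- head + 1L
    for (bid in st$mol_bonds[[v]]) {
      u <- if (st$bn_ma[bid] == v) st$bn_mb[bid] else st$bn_ma[bid]
      if (!st$visited[u]) {
        cnt <- cnt + 1L
        res[cnt] <- u
        st$visited[u] <- TRUE
      }
    }
  }
  res <- res[seq_len(cnt)]
  st$visited[res] <- FALSE
  res
}

# free-site tally row over endpoints for a set of molecules
free_row <- function(st, cm, members) {
  row <- numeric(cm$n_ep)
  for (m in members) {
    t <- st$mol_type[m]
    free <- which(st$occ[[m]] == 0L)
    if (length(free)) {
      eps <- cm$ep_offset[t] + free
      row[eps] <- row[eps] + 1
    }
  }
  row
}

do_unbind <- function(st, cm, id) {
  r <- st$bn_rule[id]
  ma <- st$bn_ma[id]; pa <- st$bn_pa[id]
  mb <- st$bn_mb[id]; pb <- st$bn_pb[id]
  ea <- cm$rule_ea[r]; eb <- cm$rule_eb[r]
  c0 <- st$cl_of[ma]
  sumab_shift(st, cm, c0, -1)
  # drop the bond everywhere
  st$occ[[ma]][pa] <- 0L
  st$occ[[mb]][pb] <- 0L
  st$mol_bonds[[ma]] <- st$mol_bonds[[ma]][st$mol_bonds[[ma]] != id]
  st$mol_bonds[[mb]] <- st$mol_bonds[[mb]][st$mol_bonds[[mb]] != id]
  p <- st$bond_rbpos[id]
  last <- st$rb_len[r]
  lid <- st$rule_bonds[[r]][last]
  st$rule_bonds[[r]][p] <- lid
  st$bond_rbpos[lid] <- p
  st$rb_len[r] <- last - 1L
  st$bn_free <- c(st$bn_free, id)
  fl_add(st, ea, ma)
  fl_add(st, eb, mb)
  st$free_tot[ea] <- st$free_tot[ea] + 1
  st$free_tot[eb] <- st$free_tot[eb] + 1
  st$clfree[c0, ea] <- st$clfree[c0, ea] + 1
  st$clfree[c0, eb] <- st$clfree[c0, eb] + 1
  # split the tree: find the side of ma, move the smaller side out
  compA <- component_of(st, ma, st$cl_size[c0])
  if (length(compA) * 2L > st$cl_size[c0]) {
    moved <- setdiff(st$cl_members[[c0]], compA)
    kept <- compA
  } else {
    moved <- compA
    kept <- setdiff(st$cl_members[[c0]], compA)
  }
  cn <- if (length(st$cl_free_ids)) {
    x <- st$cl_free_ids[length(st$cl_free_ids)]
    st$cl_free_ids <- st$cl_free_ids[-length(st$cl_free_ids)]
    x
  } else stop("internal: no free cluster id")  # cannot happen: splits <= merges
  rowm <- free_row(st, cm, moved)
  st$clfree[cn, ] <- rowm
  st$clfree[c0, ] <- st$clfree[c0, ] - rowm
  st$cl_of[moved] <- cn
  st$cl_members[[cn]] <- moved
  st$cl_members[[c0]] <- kept
  st$cl_size[cn] <- length(moved)
  st$cl_size[c0] <- length(kept)
  st$n_clusters <- st$n_clusters + 1L
  if (length(moved) == 1L)
    st$monomer_by_type[st$mol_type[moved]] <-
      st$monomer_by_type[st$mol_type[moved]] + 1L
  if (length(kept) == 1L)
    st$monomer_by_type[st$mol_type[kept]] <-
      st$monomer_by_type[st$mol_type[kept]] + 1L
  sumab_shift(st, cm, c0, +1)
  sumab_shift(st, cm, cn, +1)
  invisible()
}

obs_values <- function(st, cobs) {
  vapply(cobs, function(o) as.numeric(switch(o$kind,
    free_molecule = st$monomer_by_type[o$idx],
    free_site = st$free_tot[o$idx],
    bond_count = st$rb_len[o$idx],
    total_clusters = st$n_clusters)), 0)
}

# full-scan audit of the incremental tallies (test hook)
audit_state <- function(st, cm) {
  active <- which(st$cl_size > 0L)
  stopifnot(sum(st$cl_size[active]) == st$N)
  ft <- numeric(cm$n_ep)
  sab <- numeric(cm$n_rules)
  nmono <- integer(length(cm$tnames))
  for (c in active) {
    row <- free_row(st, cm, st$cl_members[[c]])
    if (!isTRUE(all.equal(row, st$clfree[c, ], check.attributes = FALSE)))
      stop("audit: clfree row mismatch for cluster ", c)
    ft <- ft + row
    if (cm$n_rules) {
      a <- row[cm$rule_ea]; b <- row[cm$rule_eb]
      sab <- sab + ifelse(cm$rule_sym, a * (a - 1) / 2, a * b)
    }
    if (st$cl_size[c] == 1L) {
      t <- st$mol_type[st$cl_members[[c]][1L]]
      nmono[t] <- nmono[t] + 1L
    }
    # tree check
    nb <- sum(lengths(st$mol_bonds[st$cl_members[[c]]])) / 2
    if (nb != st$cl_size[c] - 1L) stop("audit: non-tree cluster")
  }
  stopifnot(isTRUE(all.equal(ft, st$free_tot, check.attributes = FALSE)),
            isTRUE(all.equal(sab, st$sum_ab)),
            identical(nmono, as.integer(st$monomer_by_type)),
            st$n_clusters == length(active))
  invisible(TRUE)
}

# materialize the current clusters as cluster_graph objects
state_clusters <- function(st, cm, model) {
  active <- which(st$cl_size > 0L)
  lapply(active, function(c) {
    members <- st$cl_members[[c]]
    local <- stats::setNames(seq_along(members), members)
    bids <- unique(unlist(st$mol_bonds[members], use.names = FALSE))
    tnames <- cm$tnames[st$mol_type[members]]
    sitel <- model$molecule_types[tnames]
    if (length(bids)) {
      edges <- data.frame(
        a = unname(local[as.character(st$bn_ma[bids])]),
        site_a = vapply(bids, function(i)
          model$molecule_types[[cm$tnames[st$mol_type[st$bn_ma[i]]]]][st$bn_pa[i]], ""),
        b = unname(local[as.character(st$bn_mb[bids])]),
        site_b = vapply(bids, function(i)
          model$molecule_types[[cm$tnames[st$mol_type[st$bn_mb[i]]]]][st$bn_pb[i]], ""),
        rule = cm$rule_name[st$bn_rule[bids]],
        stringsAsFactors = FALSE)
    } else edges <- NULL
    cluster_graph(tnames, unname(sitel), edges, check = FALSE)
  })
}

# --- trials and ensembles ----------------------------------------------

#' Run one stochastic trial
#'
#' Exact stochastic simulation (Gillespie direct method) of the model's
#' binding rules: waiting times are exponential in the total propensity and
#' the event channel is chosen proportionally to its propensity. A binding
#' event joins two distinct clusters with a new bond between two uniformly
#' chosen eligible free sites; a dissociation removes a uniformly chosen
#' bond of the rule and splits its (tree) cluster in two. Observables are
#' sampled at `n_steps + 1` evenly spaced times over `[0, t_end]`, each
#' recording the state as of that time. When the total propensity reaches
#' zero the trial fast-forwards to `t_end`.
#'
#' @param model a [bngl_model()].
#' @param seed integer seed for this trial (defaults to the model's).
#' @param keep_graphs keep the full final [cluster_graph()]s (needed to
#'   write species files) in addition to their summaries.
#' @param audit verify the incremental propensity bookkeeping against a full
#'   state scan at every output time (slow; used by the test suite).
#' @return Object of class `nf_trial`: list with `timecourse` (a
#'   `timecourse` data frame), `final_clusters` (list of `cluster_summary`),
#'   `final_graphs` (if kept) and `seed`.
#' @export
run_trial <- function(model, seed = model$sim_params$seed,
                      keep_graphs = TRUE, audit = FALSE) {
  validate_model(model)
  set.seed(as.integer(seed))
  cm <- compile_model(model)
  cobs <- compile_observables(model, cm)
  st <- new_state(model, cm)
  sp <- model$sim_params
  out_times <- seq(0, sp$t_end, length.out = sp$n_steps + 1L)
  obsm <- matrix(0, nrow = length(out_times), ncol = length(cobs))
  k <- 1L
  t <- 0
  repeat {
    pr <- state_propensities(st, cm)
    a0 <- sum(pr$bind) + sum(pr$diss)
    if (a0 <= 0) {
      while (k <= length(out_times)) {
        obsm[k, ] <- obs_values(st, cobs)
        if (audit) audit_state(st, cm)
        k <- k + 1L
      }
      break
    }
    tn <- t + stats::rexp(1L, a0)
    while (k <= length(out_times) && out_times[k] < tn) {
      obsm[k, ] <- obs_values(st, cobs)
      if (audit) audit_state(st, cm)
      k <- k + 1L
    }
    if (tn > sp$t_end) break
    ch <- sample.int(2L * cm$n_rules, 1L, prob = c(pr$bind, pr$diss))
    if (ch <= cm$n_rules) {
      pair <- sample_pair(st, cm, ch)
      do_bind(st, cm, ch, pair[1L], pair[2L])
    } else {
      r <- ch - cm$n_rules
      id <- st$rule_bonds[[r]][sample.int(st$rb_len[r], 1L)]
      do_unbind(st, cm, id)
    }
    t <- tn
  }
  tc <- as.data.frame(obsm)
  names(tc) <- vapply(cobs, `[[`, "", "name")
  tc <- cbind(time = out_times, tc)
  graphs <- state_clusters(st, cm, model)
  structure(list(timecourse = as_timecourse(tc),
                 final_clusters = lapply(graphs, summarize_cluster),
                 final_graphs = if (keep_graphs) graphs,
                 seed = as.integer(seed)),
            class = "nf_trial")
}

#' Derive a trial seed from the master seed
#'
#' Counter-based: the master seed is XORed with a multiplicative hash of the
#' trial index, so trials are independent, reproducible and order-free.
#'
#' @param master_seed integer master seed.
#' @param i trial index (1-based).
#' @return Integer seed below 2^31.
#' @export
trial_seed <- function(master_seed, i) {
  bitwXor(as.integer(master_seed) %% 2147483647L,
          as.integer((i * 1597334677) %% 2147483647))
}

#' Run an ensemble of stochastic trials
#'
#' Executes `n_runs` independent trials of the model, each seeded by
#' [trial_seed()] from the master seed, and collects per-trial observable
#' time courses plus final cluster lists. Bit-reproducible for a fixed
#' master seed.
#'
#' @param model a [bngl_model()].
#' @param n_runs number of trials; defaults to the model's `sim_params`.
#' @param master_seed master seed; defaults to the model's `sim_params`.
#' @param keep_graphs,audit passed to [run_trial()].
#' @param progress log one line per trial to standard error.
#' @return Object of class `nf_ensemble`: list with `trials`, `model`,
#'   `master_seed`.
#' @seealso [pool_clusters()], [write_outputs()]
#' @export
run_ensemble <- function(model, n_runs = model$sim_params$n_runs,
                         master_seed = model$sim_params$seed,
                         keep_graphs = TRUE, audit = FALSE,
                         progress = FALSE) {
  trials <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    t0 <- proc.time()[["elapsed"]]
    trials[[i]] <- run_trial(model, seed = trial_seed(master_seed, i),
                             keep_graphs = keep_graphs, audit = audit)
    if (progress)
      message(sprintf("trial %d/%d done in %.2fs", i, n_runs,
                      proc.time()[["elapsed"]] - t0))
  }
  structure(list(trials = trials, model = model,
                 master_seed = as.integer(master_seed)),
            class = "nf_ensemble")
}

#' @export
#' @rdname run_ensemble
#' @param object,nsim,seed,... [stats::simulate()] interface: `nsim`
#'   overrides `n_runs` and `seed` the master seed.
simulate.bngl_model <- function(object, nsim = object$sim_params$n_runs,
                                seed = object$sim_params$seed, ...) {
  run_ensemble(object, n_runs = nsim, master_seed = seed, ...)
}

#' @export
print.nf_ensemble <- function(x, ...) {
  n <- length(x$trials)
  sizes <- unlist(lapply(x$trials, function(tr)
    vapply(tr$final_clusters, `[[`, 0L, "size")))
  cat(sprintf("<nf_ensemble> %d trial%s of %d molecules (master seed %d)\n",
              n, if (n == 1L) "" else "s", sum(x$model$seeds),
              x$master_seed))
  cat(sprintf("  final clusters pooled: %d (max size %d)\n",
              length(sizes), if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' @export
summary.nf_ensemble <- function(object, ...) {
  pool <- pool_clusters(object)
  occ <- occupancy_distribution(pool)
  bh <- bond_histogram(pool)
  structure(list(n_trials = length(object$trials),
                 n_molecules = sum(object$model$seeds),
                 occupancy = occ,
                 aco = attr(occ, "aco"),
                 mean_bonds = attr(bh, "mean_bonds")),
            class = "summary.nf_ensemble")
}

#' @export
print.summary.nf_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d trials, %d molecules each\n",
              x$n_trials, x$n_molecules))
  cat(sprintf("  average cluster occupancy (ACO): %.3f\n", x$aco))
  cat(sprintf("  mean bonds per molecule:         %.3f\n", x$mean_bonds))
  cat("  occupancy distribution (top sizes):\n")
  o <- x$occupancy[order(-x$occupancy$fraction), ][
    seq_len(min(5L, nrow(x$occupancy))), ]
  for (i in seq_len(nrow(o)))
    cat(sprintf("    size %6d: %6.2f%% of molecules\n",
                o$size[i], 100 * o$fraction[i]))
  invisible(x)
}

#' Write NFsim-style output files for an ensemble
#'
#' Writes, per trial, one gdat observable table and one final-species file
#' (canonical complex string plus count; exact duplicates aggregated), in
#' the dialects [read_gdat()] and [read_species_file()] read back.
#'
#' @param ensemble an `nf_ensemble` from [run_ensemble()] with kept graphs.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; trial `i` yields
#'   `<prefix>_<i>.gdat` and `<prefix>_<i>.species`.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(ensemble, dir, prefix = "trial") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(ensemble$trials)) {
    tr <- ensemble$trials[[i]]
    if (is.null(tr$final_graphs))
      stop("ensemble was run with keep_graphs = FALSE; species files need graphs")
    g <- file.path(dir, sprintf("%s_%02d.gdat", prefix, i))
    write_gdat(tr$timecourse, g)
    strs <- vapply(tr$final_graphs, emit_complex, "")
    agg <- table(strs)
    sp <- file.path(dir, sprintf("%s_%02d.species", prefix, i))
    write_species_file(data.frame(species = names(agg),
                                  count = as.integer(agg),
                                  stringsAsFactors = FALSE), sp)
    paths <- c(paths, g, sp)
  }
  invisible(paths)
}
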