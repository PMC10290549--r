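#' Construct a molecular cluster graph
#'
#' A cluster is a connected molecular network: nodes are individual
#' multivalent molecules, edges are site-site bonds. The degree of a node is
#' the number of bonds made by that molecule and can never exceed its
#' valence (site count).
#'
#' @param types character vector, molecule type name per node.
#' @param sites list of character vectors, declared site names per node
#'   (usually taken from the model's molecule type declarations).
#' @param edges data frame with columns `a`, `site_a`, `b`, `site_b` and
#'   optionally `rule` (node indices into `types`, site names, and the name
#'   of the rule that formed the bond, `NA` when unknown).
#' @param check validate connectivity and site occupancy (default `TRUE`).
#' @return Object of class `cluster_graph`.
#' @export
cluster_graph <- function(types, sites, edges = NULL, check = TRUE) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(a = integer(), site_a = character(),
                        b = integer(), site_b = character(),
                        rule = character(), stringsAsFactors = FALSE)
  }
  if (!"rule" %in% names(edges)) edges$rule <- NA_character_
  g <- structure(list(types = as.character(types), sites = sites,
                      edges = edges), class = "cluster_graph")
  if (check) validate_cluster(g)
  g
}

validate_cluster <- function(g) {
  n <- length(g$types)
  stopifnot(n >= 1L, length(g$sites) == n)
  e <- g$edges
  if (nrow(e)) {
    if (any(e$a < 1L | e$a > n | e$b < 1L | e$b > n))
      stop("edge endpoint out of range")
    if (any(e$a == e$b))
      stop("bond pairs two sites of the same molecule (self-bond)")
    ep <- c(paste(e$a, e$site_a), paste(e$b, e$site_b))
    if (anyDuplicated(ep))
      stop("site engaged by more than one bond: ", ep[duplicated(ep)][1L])
    for (i in seq_len(nrow(e))) {
      if (!e$site_a[i] %in% g$sites[[e$a[i]]])
        stop("edge references unknown site '", e$site_a[i], "'")
      if (!e$site_b[i] %in% g$sites[[e$b[i]]])
        stop("edge references unknown site '", e$site_b[i], "'")
    }
  }
  if (n > 1L) {
    memb <- cluster_components(n, e)
    if (max(memb) != 1L) stop("cluster graph is not connected")
  }
  invisible(g)
}

# connected-component membership for node count n and edge table e
cluster_components <- function(n, e) {
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(e)) ig <- igraph::add_edges(ig, rbind(e$a, e$b))
  igraph::components(ig)$membership
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat(sprintf("<cluster_graph> %d molecules, %d bonds: %s\n",
              length(x$types), nrow(x$edges), emit_complex(x)))
  invisible(x)
}

#' Parse a BNGL complex string into cluster graphs
#'
#' A complex string is a dot-separated list of molecule patterns,
#' `Type(site,site!1,...)`, where `!n` bond labels pair two sites across the
#' complex (each label must occur exactly twice). A well-formed complex is
#' connected and yields one cluster; disconnected input yields one cluster
#' per connected component. Cyclic complexes are accepted on the read side
#' even though the built-in simulator only produces trees.
#'
#' @param string a BNGL complex string.
#' @param model the [bngl_model()] declaring the molecule types and sites.
#' @return List of [cluster_graph()] objects, one per connected component.
#' @export
#' @examples
#' m <- nephrin_nck_nwasp_model()
#' cl <- parse_complex("Nephrin(y1!1,y2,y3).Nck(sh2!1,sh3a,sh3b,sh3c)", m)[[1]]
#' summarize_cluster(cl)
parse_complex <- function(string, model) {
  mols <- strsplit(trimws(string), ".", fixed = TRUE)[[1L]]
  if (!length(mols)) stop("empty complex string")
  n <- length(mols)
  types <- character(n)
  sites <- vector("list", n)
  bonds <- list()  # label -> list of c(node, site)
  for (k in seq_len(n)) {
    m <- regmatches(mols[k], regexec("^([A-Za-z_]\\w*)\\(([^)]*)\\)$",
                                     mols[k]))[[1L]]
    if (!length(m)) stop("malformed molecule pattern: '", mols[k], "'")
    tp <- m[2L]
    if (!tp %in% names(model$molecule_types))
      stop("undeclared molecule type '", tp, "'")
    decl <- model$molecule_types[[tp]]
    types[k] <- tp
    sites[[k]] <- decl
    toks <- trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])
    toks <- toks[nzchar(toks)]
    seen <- character()
    for (tok in toks) {
      sm <- regmatches(tok, regexec("^([A-Za-z_]\\w*)(?:!(\\d+))?$", tok))[[1L]]
      if (!length(sm)) stop("malformed site token '", tok, "' in '", mols[k], "'")
      s <- sm[2L]
      if (!s %in% decl)
        stop("undeclared site '", s, "' on molecule '", tp, "'")
      if (s %in% seen) stop("site '", s, "' listed twice on '", mols[k], "'")
      seen <- c(seen, s)
      if (nzchar(sm[3L])) {
        lab <- sm[3L]
        bonds[[lab]] <- c(bonds[[lab]], list(c(node = k, site = s)))
      }
    }
  }
  ea <- integer(); esa <- character(); eb <- integer(); esb <- character()
  for (lab in names(bonds)) {
    ends <- bonds[[lab]]
    if (length(ends) == 1L)
      stop("dangling bond label '!", lab, "' (occurs once)")
    if (length(ends) > 2L)
      stop("bond label '!", lab, "' occurs ", length(ends), " times")
    ea <- c(ea, as.integer(ends[[1L]]["node"]))
    esa <- c(esa, ends[[1L]]["site"])
    eb <- c(eb, as.integer(ends[[2L]]["node"]))
    esb <- c(esb, ends[[2L]]["site"])
  }
  edges <- data.frame(a = ea, site_a = esa, b = eb, site_b = esb,
                      rule = rep(NA_character_, length(ea)),
                      stringsAsFactors = FALSE, row.names = NULL)
  memb <- cluster_components(n, edges)
  lapply(seq_len(max(memb)), function(cmp) {
    keep <- which(memb == cmp)
    remap <- match(seq_len(n), keep)
    e <- edges[edges$a %in% keep, , drop = FALSE]
    e$a <- remap[e$a]; e$b <- remap[e$b]
    row.names(e) <- NULL
    cluster_graph(types[keep], sites[keep], e)
  })
}

#' Emit the canonical BNGL complex string of a cluster
#'
#' Tree clusters (the only kind the built-in simulator produces) are emitted
#' in a canonical form that is invariant to node relabeling: the tree is
#' rooted at its center (tie broken by a canonical subtree encoding, an
#' AHU-style scheme extended with the site pair carried by each edge), nodes
#' are written in depth-first preorder with children ordered by their
#' encodings, and bond labels are renumbered 1..n in order of first
#' appearance. Two isomorphic trees therefore produce identical strings,
#' which is what deduplication in the species files relies on. Cyclic
#' clusters (read-side only) are emitted deterministically from the stored
#' node order; duplicates are then detected only up to exact string
#' equality.
#'
#' @param cluster a [cluster_graph()].
#' @return A single BNGL complex string.
#' @export
emit_complex <- function(cluster) {
  n <- length(cluster$types)
  e <- cluster$edges
  if (nrow(e) == n - 1L) emit_tree(cluster) else emit_nontree(cluster)
}

emit_tree <- function(g) {
  n <- length(g$types)
  if (n == 1L) return(mol_string(g, 1L, list()))
  # adjacency: for each node, matrix-ish lists of (nbr, my site, their site)
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges$a[i]; b <- g$edges$b[i]
    sa <- g$edges$site_a[i]; sb <- g$edges$site_b[i]
    adj[[a]] <- c(adj[[a]], list(list(nbr = b, my = sa, their = sb)))
    adj[[b]] <- c(adj[[b]], list(list(nbr = a, my = sb, their = sa)))
  }
  # tree centers by iterative leaf pruning
  deg <- vapply(adj, length, 1L)
  alive <- rep(TRUE, n)
  remaining <- n
  while (remaining > 2L) {
    leaves <- which(alive & deg == 1L)
    for (l in leaves) {
      alive[l] <- FALSE
      for (nb in adj[[l]]) if (alive[nb$nbr]) deg[nb$nbr] <- deg[nb$nbr] - 1L
      deg[l] <- 0L
    }
    remaining <- remaining - length(leaves)
  }
  centers <- which(alive)
  enc <- function(v, parent) {
    items <- character()
    for (nb in adj[[v]]) {
      if (nb$nbr == parent) next
      items <- c(items, paste0(nb$my, ">", nb$their, ">", enc(nb$nbr, v)))
    }
    paste0(g$types[v], "{", paste(sort(items), collapse = ";"), "}")
  }
  root <- centers[1L]
  if (length(centers) == 2L &&
      enc(centers[2L], 0L) < enc(centers[1L], 0L)) root <- centers[2L]
  # DFS preorder, children in sorted encoding order; labels by first use
  order_out <- integer(0)
  bond_lab <- list()  # per node: named numeric vector site -> label
  for (k in seq_len(n)) bond_lab[[k]] <- integer(0)
  lab_counter <- 0L
  walk <- function(v, parent) {
    order_out <<- c(order_out, v)
    kids <- Filter(function(nb) nb$nbr != parent, adj[[v]])
    if (length(kids)) {
      keys <- vapply(kids, function(nb)
        paste0(nb$my, ">", nb$their, ">", enc(nb$nbr, v)), "")
      kids <- kids[order(keys)]
      for (nb in kids) {
        lab_counter <<- lab_counter + 1L
        bond_lab[[v]][nb$my] <<- lab_counter
        bond_lab[[nb$nbr]][nb$their] <<- lab_counter
        walk(nb$nbr, v)
      }
    }
  }
  walk(root, 0L)
  paste(vapply(order_out, function(v) mol_string(g, v, bond_lab), ""),
        collapse = ".")
}

emit_nontree <- function(g) {
  n <- length(g$types)
  bond_lab <- vector("list", n)
  for (k in seq_len(n)) bond_lab[[k]] <- integer(0)
  lab <- 0L
  e <- g$edges
  ord <- order(e$a, e$b, e$site_a, e$site_b)
  for (i in ord) {
    lab <- lab + 1L
    bond_lab[[e$a[i]]][e$site_a[i]] <- lab
    bond_lab[[e$b[i]]][e$site_b[i]] <- lab
  }
  paste(vapply(seq_len(n), function(v) mol_string(g, v, bond_lab), ""),
        collapse = ".")
}

mol_string <- function(g, v, bond_lab) {
  labs <- if (length(bond_lab) >= v) bond_lab[[v]] else integer(0)
  toks <- vapply(g$sites[[v]], function(s) {
    if (s %in% names(labs)) paste0(s, "!", labs[[s]]) else s
  }, "")
  paste0(g$types[v], "(", paste(toks, collapse = ","), ")")
}

#' Summarize a molecular cluster
#'
#' Computes the per-cluster record used by all pooled statistics: size
#' (number of molecules), molecule counts per type, bond count, total sites
#' (sum of member valences), bound sites (each bond engages two sites, so
#' `2 * n_bonds`), bound fraction (bound sites / total sites) and the degree
#' of every member molecule.
#'
#' @param cluster a [cluster_graph()].
#' @return Object of class `cluster_summary` with fields `size`,
#'   `type_counts`, `n_bonds`, `total_sites`, `bound_sites`,
#'   `bound_fraction`, `node_types`, `degrees`, `is_tree`, `count`.
#' @export
summarize_cluster <- function(cluster) {
  n <- length(cluster$types)
  e <- cluster$edges
  deg <- tabulate(c(e$a, e$b), nbins = n)
  total_sites <- sum(lengths(cluster$sites))
  n_bonds <- nrow(e)
  val <- lengths(cluster$sites)
  if (any(deg > val)) stop("node degree exceeds valence")
  tc <- table(cluster$types)
  structure(list(size = n,
                 type_counts = stats::setNames(as.integer(tc), names(tc)),
                 n_bonds = n_bonds,
                 total_sites = total_sites,
                 bound_sites = 2L * n_bonds,
                 bound_fraction = 2 * n_bonds / total_sites,
                 node_types = cluster$types,
                 degrees = deg,
                 is_tree = n_bonds == n - 1L,
                 count = 1L),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("<cluster_summary> size %d (%s), %d bonds, BF %.3f\n",
              x$size,
              paste0(names(x$type_counts), ":", x$type_counts, collapse = " "),
              x$n_bonds, x$bound_fraction))
  invisible(x)
}

#' Bound fraction of a single molecule
#'
#' The per-molecule bound fraction is the number of occupied (bonded) sites
#' of the molecule divided by its valence. Contrast with the per-cluster
#' bound fraction reported by [summarize_cluster()], which is the ratio of
#' bound sites to total sites over the whole cluster; the size-resolved
#' saturation matrix ([bf_matrix()]) uses the per-cluster form.
#'
#' @param cluster a [cluster_graph()].
#' @param node index of the molecule within the cluster.
#' @return Numeric in `[0, 1]`.
#' @export
molecule_bound_fraction <- function(cluster, node) {
  e <- cluster$edges
  deg <- sum(e$a == node) + sum(e$b == node)
  deg / length(cluster$sites[[node]])
}

#' Generate synthetic clusters of prescribed sizes
#'
#' Builds random tree clusters obeying a model's binding rules, for testing
#' and for exercising the statistics without running a simulation. Each
#' cluster is grown by repeatedly choosing, uniformly at random, one of the
#' currently feasible attachments (a free site on the cluster plus a rule
#' endpoint matching it) and adding a fresh molecule of the partner type.
#'
#' @param size_spectrum named vector mapping cluster size to the number of
#'   clusters of that size to generate, e.g. `c("1" = 5, "3" = 2)`.
#' @param model a [bngl_model()]; rules constrain which trees are possible.
#' @param seed integer seed; output is reproducible for a fixed seed.
#' @param max_tries attempts per cluster before declaring the size
#'   unreachable under the model's rules.
#' @return List of [cluster_graph()] objects (requested multiplicities, in
#'   increasing size order).
#' @export
generate_synthetic_clusters <- function(size_spectrum, model, seed = 1L,
                                        max_tries = 50L) {
  sizes <- as.integer(names(size_spectrum))
  if (anyNA(sizes) || any(sizes < 1L)) stop("cluster sizes must be >= 1")
  set.seed(seed)
  out <- list()
  for (k in order(sizes)) {
    for (rep in seq_len(size_spectrum[[k]])) {
      out[[length(out) + 1L]] <- grow_tree(sizes[k], model, max_tries)
    }
  }
  out
}

grow_tree <- function(size, model, max_tries) {
  tnames <- names(model$molecule_types)
  r <- model$rules
  if (size > 1L && !nrow(r)) stop("size ", size,
                                  " unreachable: model has no binding rules")
  for (try in seq_len(max_tries)) {
    tp0 <- if (size == 1L) sample(tnames, 1L) else
      sample(unique(c(r$mol_a, r$mol_b)), 1L)
    types <- tp0
    sites <- list(model$molecule_types[[tp0]])
    used <- list(character(0))  # occupied sites per node
    edges <- data.frame(a = integer(), site_a = character(),
                        b = integer(), site_b = character(),
                        rule = character(), stringsAsFactors = FALSE)
    ok <- TRUE
    while (length(types) < size) {
      opts <- list()
      for (v in seq_along(types)) {
        free <- setdiff(sites[[v]], used[[v]])
        for (i in seq_len(nrow(r))) {
          if (r$mol_a[i] == types[v] && r$site_a[i] %in% free)
            opts[[length(opts) + 1L]] <- list(v = v, my = r$site_a[i],
                                              tp = r$mol_b[i],
                                              their = r$site_b[i],
                                              rule = r$name[i])
          if (r$mol_b[i] == types[v] && r$site_b[i] %in% free)
            opts[[length(opts) + 1L]] <- list(v = v, my = r$site_b[i],
                                              tp = r$mol_a[i],
                                              their = r$site_a[i],
                                              rule = r$name[i])
        }
      }
      if (!length(opts)) { ok <- FALSE; break }
      o <- opts[[sample.int(length(opts), 1L)]]
      w <- length(types) + 1L
      types <- c(types, o$tp)
      sites[[w]] <- model$molecule_types[[o$tp]]
      used[[w]] <- o$their
      used[[o$v]] <- c(used[[o$v]], o$my)
      edges <- rbind(edges, data.frame(a = o$v, site_a = o$my, b = w,
                                       site_b = o$their, rule = o$rule,
                                       stringsAsFactors = FALSE))
    }
    if (ok) return(cluster_graph(types, sites, edges))
  }
  stop("cluster size ", size, " unreachable under the model's rules")
}
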