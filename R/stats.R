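# Pooled multi-trial statistics of final molecular clusters. The primary
# mode pools clusters across all trials into one combined dataset (rather
# than averaging per-trial distributions); clusters read from species files
# enter every statistic weighted by their counts (expanded at pooling time).

#' Pool final clusters across trials
#'
#' Builds the combined dataset all cluster statistics operate on: the
#' multiset union of final clusters over trials, each species-file entry
#' expanded by its count.
#'
#' @param x an `nf_ensemble` from [run_ensemble()]; or a character vector of
#'   final-species file paths; or a data frame with `species`/`count`
#'   columns ([read_species_file()] output); or a list of
#'   [cluster_graph()]/`cluster_summary` objects.
#' @param model required [bngl_model()] when `x` holds complex strings.
#' @return Object of class `cluster_pool`: list of `cluster_summary`.
#' @export
pool_clusters <- function(x, model = NULL) {
  summaries <- list()
  if (inherits(x, "nf_ensemble")) {
    if (!length(x$trials)) stop("ensemble has no trials to pool")
    summaries <- unlist(lapply(x$trials, `[[`, "final_clusters"),
                        recursive = FALSE)
  } else if (is.character(x)) {
    if (!length(x)) stop("no species files to pool")
    tabs <- lapply(x, read_species_file)
    summaries <- pool_species_table(do.call(rbind, tabs), model)
  } else if (is.data.frame(x)) {
    summaries <- pool_species_table(x, model)
  } else if (is.list(x)) {
    if (!length(x)) stop("no clusters to pool")
    summaries <- lapply(x, function(c)
      if (inherits(c, "cluster_summary")) c else summarize_cluster(c))
  } else stop("cannot pool object of class ", class(x)[1L])
  # expand count weights into multiset entries
  out <- list()
  for (s in summaries) {
    k <- s$count %||% 1L
    s$count <- 1L
    out <- c(out, rep(list(s), k))
  }
  if (!length(out)) stop("pooled cluster set is empty")
  structure(out, class = "cluster_pool")
}

pool_species_table <- function(tab, model) {
  if (is.null(model)) stop("pooling species strings requires `model`")
  if (!nrow(tab)) stop("no species entries to pool")
  out <- list()
  for (i in seq_len(nrow(tab))) {
    cls <- parse_complex(tab$species[i], model)
    for (g in cls) {
      s <- summarize_cluster(g)
      s$count <- tab$count[i]
      out <- c(out, list(s))
    }
  }
  out
}

#' @export
print.cluster_pool <- function(x, ...) {
  sizes <- vapply(x, `[[`, 0L, "size")
  cat(sprintf("<cluster_pool> %d clusters, %d molecules, sizes %d..%d\n",
              length(x), sum(sizes), min(sizes), max(sizes)))
  invisible(x)
}

pool_sizes <- function(pool) vapply(pool, `[[`, 0L, "size")

#' Molecule-weighted cluster-size (occupancy) distribution and ACO
#'
#' The occupancy distribution gives, for each cluster size, the fraction of
#' all pooled molecules residing in clusters of that size — the probability
#' that a randomly chosen molecule sits in a cluster of a given size. Its
#' mean is the average cluster occupancy (ACO).
#'
#' @param pool a [pool_clusters()] result.
#' @return Data frame (class `occupancy_distribution`) with columns `size`,
#'   `n_clusters`, `fraction`; attributes `aco`, `n_molecules`.
#' @export
#' @examples
#' m <- nephrin_nck_nwasp_model()
#' cl <- generate_synthetic_clusters(c("1" = 2, "2" = 1), m, seed = 1)
#' occupancy_distribution(pool_clusters(cl))   # sizes {1,1,2}: ACO 1.5
occupancy_distribution <- function(pool) {
  sizes <- pool_sizes(pool)
  total <- sum(sizes)
  tab <- table(sizes)
  size <- as.integer(names(tab))
  frac <- size * as.integer(tab) / total
  out <- data.frame(size = size, n_clusters = as.integer(tab),
                    fraction = frac)
  attr(out, "aco") <- sum(size * frac)
  attr(out, "n_molecules") <- total
  class(out) <- c("occupancy_distribution", "data.frame")
  out
}

#' @export
print.occupancy_distribution <- function(x, ...) {
  cat(sprintf("Occupancy distribution over %d molecules (ACO = %.4g)\n",
              attr(x, "n_molecules"), attr(x, "aco")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Default size-bin lower bounds
#'
#' Monomer-resolved bins up to size 10, then roughly logarithmic (1-2-5 per
#' decade) bins, with a final open-ended bin.
#'
#' @param max_size largest cluster size the bins must reach.
#' @return Integer vector of bin lower bounds starting at 1.
#' @export
default_size_breaks <- function(max_size) {
  b <- 1:10
  nxt <- 11
  step <- c(10, 10, 30)  # 11,21,51,101,201,501,...
  i <- 0L
  while (nxt <= max_size) {
    b <- c(b, nxt)
    nxt <- nxt + step[i %% 3L + 1L] * 10^(i %/% 3L)
    i <- i + 1L
  }
  b
}

#' Bin an occupancy distribution into size ranges
#'
#' @param dist an [occupancy_distribution()].
#' @param breaks integer vector of bin lower bounds; must start at 1 and be
#'   strictly increasing (bins are `[b_i, b_{i+1} - 1]`, the last bin
#'   open-ended). Overlapping or non-covering breaks are rejected.
#' @return Data frame (class `binned_distribution`) with columns `label`,
#'   `lower`, `upper`, `fraction`; fractions sum to 1.
#' @export
bin_distribution <- function(dist, breaks) {
  breaks <- as.integer(breaks)
  if (!length(breaks) || breaks[1L] != 1L)
    stop("size bins must cover all sizes: first break must be 1")
  if (any(diff(breaks) <= 0L))
    stop("size bins overlap: breaks must be strictly increasing")
  upper <- c(breaks[-1L] - 1L, NA_integer_)
  idx <- findInterval(dist$size, breaks)
  frac <- vapply(seq_along(breaks), function(i)
    sum(dist$fraction[idx == i]), 0)
  label <- ifelse(is.na(upper), paste0(">=", breaks),
                  ifelse(breaks == upper, as.character(breaks),
                         paste0(breaks, "-", upper)))
  out <- data.frame(label = label, lower = breaks, upper = upper,
                    fraction = frac, stringsAsFactors = FALSE)
  class(out) <- c("binned_distribution", "data.frame")
  out
}

#' Bonds-per-molecule histogram
#'
#' Distribution of node degree (number of bonds made by a molecule) over
#' all pooled molecules or over one molecule type. Support is capped by the
#' scoped type's valence.
#'
#' @param pool a [pool_clusters()] result.
#' @param scope `"all"` or a molecule type name.
#' @param model optional [bngl_model()]; when given, `scope` is validated
#'   against its declared types.
#' @return Data frame (class `bond_histogram`) with columns `bonds`,
#'   `fraction`; attributes `scope`, `mean_bonds`, `n_molecules`.
#' @export
bond_histogram <- function(pool, scope = "all", model = NULL) {
  if (!is.null(model) && scope != "all" &&
      !scope %in% names(model$molecule_types))
    stop("unknown molecule type '", scope, "'")
  degs <- unlist(lapply(pool, function(s) {
    keep <- if (scope == "all") TRUE else s$node_types == scope
    s$degrees[keep]
  }), use.names = FALSE)
  if (!length(degs))
    stop(if (is.null(model) && scope != "all")
      paste0("unknown molecule type '", scope, "' (absent from pool)")
      else paste0("no molecules in scope '", scope, "'"))
  tab <- table(factor(degs, levels = 0:max(degs, 0L)))
  out <- data.frame(bonds = as.integer(names(tab)),
                    fraction = as.integer(tab) / length(degs))
  attr(out, "scope") <- scope
  attr(out, "mean_bonds") <- mean(degs)
  attr(out, "n_molecules") <- length(degs)
  class(out) <- c("bond_histogram", "data.frame")
  out
}

#' Bound-fraction-by-size frequency matrix
#'
#' Histograms the pooled clusters over (size bin, bound-fraction bin) and
#' normalizes within each size bin, giving the conditional distribution of
#' per-cluster bound fraction (bond saturation) given cluster size. Greater
#' spread in small-size columns and convergence to a characteristic value in
#' large ones is the typical signature of supply-limited clustering.
#'
#' @param pool a [pool_clusters()] result.
#' @param size_breaks size-bin lower bounds (default
#'   [default_size_breaks()]).
#' @param bf_width bound-fraction bin width in `(0, 1]` (default 0.05).
#' @return Matrix (class `bf_matrix`) with one row per BF bin and one column
#'   per size bin; each nonempty column sums to 1. Attributes `bf_breaks`,
#'   `size_breaks`, `n_clusters` (per column).
#' @export
bf_matrix <- function(pool, size_breaks = NULL, bf_width = 0.05) {
  if (!(bf_width > 0 && bf_width <= 1))
    stop("bf_width must be in (0, 1]")
  sizes <- pool_sizes(pool)
  bfs <- vapply(pool, `[[`, 0, "bound_fraction")
  if (is.null(size_breaks)) size_breaks <- default_size_breaks(max(sizes))
  n_bf <- ceiling(1 / bf_width)
  bf_idx <- pmin(floor(bfs / bf_width) + 1L, n_bf)  # BF = 1 in top bin
  sz_idx <- findInterval(sizes, size_breaks)
  upper <- c(size_breaks[-1L] - 1L, NA_integer_)
  collab <- ifelse(is.na(upper), paste0(">=", size_breaks),
                   ifelse(size_breaks == upper, as.character(size_breaks),
                          paste0(size_breaks, "-", upper)))
  m <- matrix(0, nrow = n_bf, ncol = length(size_breaks),
              dimnames = list(sprintf("[%.3g,%.3g)", bf_width * (0:(n_bf - 1L)),
                                      pmin(bf_width * (1:n_bf), 1)),
                              collab))
  for (i in seq_along(sizes))
    m[bf_idx[i], sz_idx[i]] <- m[bf_idx[i], sz_idx[i]] + 1
  ncl <- colSums(m)
  nz <- ncl > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2L, ncl[nz], "/")
  attr(m, "bf_breaks") <- bf_width * (0:n_bf)
  attr(m, "size_breaks") <- size_breaks
  attr(m, "n_clusters") <- ncl
  class(m) <- c("bf_matrix", class(m))
  m
}

#' Per-size molecular composition of clusters
#'
#' For each cluster size (or size bin) the fraction of member molecules
#' belonging to each molecule type; fractions sum to 1 within each size.
#' Near-identical compositions across the large sizes indicate
#' stoichiometry-driven clustering.
#'
#' @param pool a [pool_clusters()] result.
#' @param size_breaks optional size-bin lower bounds; default resolves every
#'   observed size exactly.
#' @return Matrix (class `composition_table`), types x sizes, column
#'   fractions summing to 1; attribute `n_molecules` (per column).
#' @export
composition_table <- function(pool, size_breaks = NULL) {
  sizes <- pool_sizes(pool)
  types <- sort(unique(unlist(lapply(pool, function(s) names(s$type_counts)))))
  if (is.null(size_breaks)) {
    keys <- sort(unique(sizes))
    idx <- match(sizes, keys)
    collab <- as.character(keys)
    ncol <- length(keys)
  } else {
    idx <- findInterval(sizes, size_breaks)
    upper <- c(size_breaks[-1L] - 1L, NA_integer_)
    collab <- ifelse(is.na(upper), paste0(">=", size_breaks),
                     ifelse(size_breaks == upper, as.character(size_breaks),
                            paste0(size_breaks, "-", upper)))
    ncol <- length(size_breaks)
  }
  m <- matrix(0, nrow = length(types), ncol = ncol,
              dimnames = list(types, collab))
  for (i in seq_along(pool)) {
    tc <- pool[[i]]$type_counts
    m[names(tc), idx[i]] <- m[names(tc), idx[i]] + tc
  }
  nmol <- colSums(m)
  nz <- nmol > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2L, nmol[nz], "/")
  attr(m, "n_molecules") <- nmol
  class(m) <- c("composition_table", class(m))
  m
}

#' Mean and standard deviation of observable time courses across trials
#'
#' Pointwise mean and sample standard deviation (n - 1 divisor; 0 by
#' convention for a single trial) of each observable over an ensemble's
#' trials — the fluctuation envelope around the mean trajectory.
#'
#' @param x an `nf_ensemble`, or a list of `timecourse` data frames sharing
#'   one time grid.
#' @return Object of class `timecourse_stats`: list with `times`, `mean`
#'   and `sd` (data frames, one column per observable), `n_trials`.
#' @export
timecourse_stats <- function(x) {
  tcs <- if (inherits(x, "nf_ensemble"))
    lapply(x$trials, `[[`, "timecourse") else x
  if (!length(tcs)) stop("need at least one trial")
  times <- tcs[[1L]]$time
  obs <- setdiff(names(tcs[[1L]]), "time")
  for (tc in tcs) {
    if (!identical(names(tc), names(tcs[[1L]])) ||
        !isTRUE(all.equal(tc$time, times)))
      stop("trials have mismatched time grids or observables")
  }
  n <- length(tcs)
  mu <- sdv <- as.data.frame(matrix(0, nrow = length(times),
                                    ncol = length(obs),
                                    dimnames = list(NULL, obs)))
  for (o in obs) {
    vals <- vapply(tcs, function(tc) tc[[o]], numeric(length(times)))
    vals <- matrix(vals, nrow = length(times))
    mu[[o]] <- rowMeans(vals)
    sdv[[o]] <- if (n > 1L) apply(vals, 1L, stats::sd) else 0
  }
  structure(list(times = times, mean = mu, sd = sdv, n_trials = n),
            class = "timecourse_stats")
}

#' @export
print.timecourse_stats <- function(x, ...) {
  cat(sprintf("<timecourse_stats> %d observables, %d time points, %d trials\n",
              ncol(x$mean), length(x$times), x$n_trials))
  invisible(x)
}

#' Export all cluster statistics as tab-separated tables
#'
#' Writes the full analysis of a pooled cluster set (and optionally a
#' time-course envelope) under fixed file names: `occupancy.tsv`,
#' `aco.txt`, `binned_occupancy.tsv`, `bonds_all.tsv`, `bonds_<type>.tsv`
#' for each requested type scope, `bf_matrix.tsv`, `composition.tsv` and
#' `timecourse_stats.tsv`.
#'
#' @param pool a [pool_clusters()] result.
#' @param dir output directory (created if needed).
#' @param tc_stats optional [timecourse_stats()] result.
#' @param size_breaks size-bin lower bounds (default
#'   [default_size_breaks()]).
#' @param bf_width bound-fraction bin width for [bf_matrix()].
#' @param scopes molecule types to write per-type bond histograms for.
#' @return Character vector of written paths, invisibly.
#' @export
write_stat_tables <- function(pool, dir, tc_stats = NULL,
                              size_breaks = NULL, bf_width = 0.05,
                              scopes = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(size_breaks))
    size_breaks <- default_size_breaks(max(pool_sizes(pool)))
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  occ <- occupancy_distribution(pool)
  wtsv(as.data.frame(occ), "occupancy.tsv")
  writeLines(sprintf("aco\t%.10g", attr(occ, "aco")),
             file.path(dir, "aco.txt"))
  paths <- c(paths, file.path(dir, "aco.txt"))
  wtsv(as.data.frame(bin_distribution(occ, size_breaks)),
       "binned_occupancy.tsv")
  wtsv(as.data.frame(bond_histogram(pool, "all")), "bonds_all.tsv")
  present <- unique(unlist(lapply(pool, function(s) names(s$type_counts))))
  for (tp in intersect(scopes, present))
    wtsv(as.data.frame(bond_histogram(pool, tp)),
         paste0("bonds_", tp, ".tsv"))
  bm <- bf_matrix(pool, size_breaks, bf_width)
  bdf <- data.frame(bf_bin = rownames(bm), unclass(bm),
                    check.names = FALSE, stringsAsFactors = FALSE)
  wtsv(bdf, "bf_matrix.tsv")
  cm <- composition_table(pool, size_breaks)
  cdf <- data.frame(type = rownames(cm), unclass(cm),
                    check.names = FALSE, stringsAsFactors = FALSE)
  wtsv(cdf, "composition.tsv")
  if (!is.null(tc_stats)) {
    df <- data.frame(time = tc_stats$times, check.names = FALSE)
    for (o in names(tc_stats$mean)) {
      df[[paste0(o, "_mean")]] <- tc_stats$mean[[o]]
      df[[paste0(o, "_sd")]] <- tc_stats$sd[[o]]
    }
    wtsv(df, "timecourse_stats.tsv")
  }
  invisible(paths)
}
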