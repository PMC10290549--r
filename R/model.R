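#' nfcluster: network-free simulation and statistics of multivalent clusters
#'
#' Multivalent biomolecules (scaffolds and adapters with several binding
#' sites each) interacting through weak, reversible site-site bonds can
#' condense into large supply-limited clusters once concentration and
#' affinity cross a threshold. This package provides a restricted BNGL
#' (BioNetGen language) reader/writer, an exact network-free Gillespie
#' simulator of such systems, graph-level summaries of the molecular
#' clusters each trial produces, and pooled multi-trial statistics:
#' occupancy (molecule-weighted size) distributions, average cluster
#' occupancy, bonds-per-molecule histograms, bound-fraction-by-size
#' matrices, per-size composition tables and time-course envelopes.
#'
#' @section Typical workflow:
#' \preformatted{
#'   model <- read_bngl("model.bngl")
#'   ens   <- run_ensemble(model)
#'   pool  <- pool_clusters(ens)
#'   occupancy_distribution(pool)
#' }
#'
#' @keywords internal
#' @importFrom stats simulate
"_PACKAGE"

#' Construct a rule-based binding model
#'
#' A model consists of multi-site molecule types, seed copy numbers,
#' reversible site-site binding rules, optional observables, and simulation
#' parameters. This is the in-memory form of the restricted BNGL dialect
#' read by [read_bngl()].
#'
#' @param molecule_types named list; one entry per molecule type, each a
#'   character vector of site names (the type's valence is its length).
#' @param seeds named integer vector of initial copy numbers, names matching
#'   `molecule_types`. Types without an entry start at 0 copies.
#' @param rules data frame with columns `name`, `mol_a`, `site_a`, `mol_b`,
#'   `site_b`, `kon`, `koff`. `kon` is the stochastic association rate
#'   constant per eligible free site pair per time unit; `koff` is the
#'   dissociation rate per bond per time unit (0 encodes irreversible
#'   binding). Rates are copy-number based; no molar/volume conversion is
#'   applied.
#' @param observables data frame with columns `name`, `kind`, `target`, or
#'   `NULL` for none. `kind` is one of `"free_molecule"` (fully monomeric
#'   copies of the type named in `target`), `"free_site"` (unbound copies of
#'   `"Type.site"` in `target`), `"bond_count"` (bonds formed by the rule
#'   named in `target`) or `"total_clusters"` (`target` ignored).
#' @param sim_params list with `t_end` (duration), `n_steps` (number of
#'   output points after t = 0), `n_runs` (stochastic trials) and `seed`
#'   (master random seed).
#'
#' @return An object of class `bngl_model`.
#' @seealso [read_bngl()], [write_bngl()], [run_ensemble()]
#' @export
#' @examples
#' m <- bngl_model(
#'   molecule_types = list(A = "a", B = "b"),
#'   seeds = c(A = 10, B = 10),
#'   rules = binding_rule("A", "a", "B", "b", kon = 0.1, koff = 0.1),
#'   sim_params = list(t_end = 10, n_steps = 20, n_runs = 3, seed = 1)
#' )
#' print(m)
bngl_model <- function(molecule_types, seeds, rules,
                       observables = NULL,
                       sim_params = list(t_end = 10, n_steps = 10,
                                         n_runs = 1, seed = 0)) {
  if (is.null(observables)) {
    observables <- data.frame(name = character(), kind = character(),
                              target = character(), stringsAsFactors = FALSE)
  }
  seeds <- stats::setNames(as.integer(seeds), names(seeds))
  sim_params <- utils::modifyList(
    list(t_end = 10, n_steps = 10, n_runs = 1, seed = 0), sim_params)
  m <- structure(list(molecule_types = molecule_types,
                      seeds = seeds,
                      rules = rules,
                      observables = observables,
                      sim_params = sim_params),
                 class = "bngl_model")
  validate_model(m)
  m
}

#' Build a table of reversible binding rules
#'
#' Convenience constructor for the `rules` argument of [bngl_model()]. All
#' vector arguments are recycled to a common length.
#'
#' @param mol_a,site_a molecule type and site name of the first endpoint.
#' @param mol_b,site_b molecule type and site name of the second endpoint.
#' @param kon,koff stochastic on/off rate constants (see [bngl_model()]).
#' @param name optional rule names; defaults to `R1`, `R2`, ...
#' @return data frame of rules.
#' @export
binding_rule <- function(mol_a, site_a, mol_b, site_b, kon, koff,
                         name = NULL) {
  n <- max(length(mol_a), length(site_a), length(mol_b), length(site_b),
           length(kon), length(koff))
  if (is.null(name)) name <- paste0("R", seq_len(n))
  data.frame(name = rep_len(name, n),
             mol_a = rep_len(mol_a, n), site_a = rep_len(site_a, n),
             mol_b = rep_len(mol_b, n), site_b = rep_len(site_b, n),
             kon = rep_len(as.numeric(kon), n),
             koff = rep_len(as.numeric(koff), n),
             stringsAsFactors = FALSE)
}

validate_model <- function(m) {
  mt <- m$molecule_types
  if (length(mt) < 1L) stop("model must declare at least one molecule type")
  nm <- names(mt)
  if (is.null(nm) || any(!nzchar(nm))) stop("molecule type names must be nonempty")
  if (anyDuplicated(nm)) stop("duplicate molecule type name: ",
                              nm[duplicated(nm)][1L])
  for (t in nm) {
    sites <- mt[[t]]
    if (length(sites) < 1L) stop("molecule type '", t, "' must have at least one site")
    if (anyDuplicated(sites)) stop("duplicate site name in '", t, "'")
  }
  if (length(m$seeds) < 1L) stop("model must declare at least one seed species")
  bad <- setdiff(names(m$seeds), nm)
  if (length(bad)) stop("seed species references undeclared molecule type '",
                        bad[1L], "'")
  if (any(m$seeds < 0L)) stop("seed copy numbers must be nonnegative")
  r <- m$rules
  need <- c("name", "mol_a", "site_a", "mol_b", "site_b", "kon", "koff")
  if (!all(need %in% names(r))) stop("rules table lacks required columns")
  if (nrow(r) && anyDuplicated(r$name)) stop("duplicate rule name")
  for (i in seq_len(nrow(r))) {
    for (end in c("a", "b")) {
      mol <- r[[paste0("mol_", end)]][i]
      site <- r[[paste0("site_", end)]][i]
      if (!mol %in% nm)
        stop("rule '", r$name[i], "': undeclared molecule type '", mol, "'")
      if (!site %in% mt[[mol]])
        stop("rule '", r$name[i], "': undeclared site '", site,
             "' on molecule '", mol, "'")
    }
    if (r$kon[i] < 0 || r$koff[i] < 0)
      stop("rule '", r$name[i], "': negative rate constant")
  }
  o <- m$observables
  for (i in seq_len(nrow(o))) {
    kind <- o$kind[i]
    tg <- o$target[i]
    ok <- switch(kind,
      free_molecule = tg %in% nm,
      free_site = {
        parts <- strsplit(tg, ".", fixed = TRUE)[[1L]]
        length(parts) == 2L && parts[1L] %in% nm &&
          parts[2L] %in% mt[[parts[1L]]]
      },
      bond_count = tg %in% r$name,
      total_clusters = TRUE,
      stop("observable '", o$name[i], "': unknown kind '", kind, "'"))
    if (!ok) stop("observable '", o$name[i],
                  "': unresolved target '", tg, "'")
  }
  sp <- m$sim_params
  if (!(sp$t_end > 0)) stop("t_end must be positive")
  if (!(sp$n_steps >= 1)) stop("n_steps must be >= 1")
  if (!(sp$n_runs >= 1)) stop("n_runs must be >= 1")
  invisible(m)
}

#' @export
print.bngl_model <- function(x, ...) {
  cat("Rule-based binding model (restricted BNGL dialect)\n")
  val <- vapply(x$molecule_types, length, 1L)
  cat("  molecule types:",
      paste0(names(val), "(", val, " sites)", collapse = ", "), "\n")
  cat("  seed copies:  ",
      paste0(names(x$seeds), "=", x$seeds, collapse = ", "),
      sprintf(" (total %d molecules)\n", sum(x$seeds)))
  cat("  binding rules:", nrow(x$rules), "\n")
  cat("  observables:  ", nrow(x$observables), "\n")
  sp <- x$sim_params
  cat(sprintf("  simulate:      t_end=%g, n_steps=%d, n_runs=%d, seed=%d\n",
              sp$t_end, sp$n_steps, sp$n_runs, as.integer(sp$seed)))
  invisible(x)
}

# valence (site count) per molecule type, named integer vector
valences <- function(model) {
  vapply(model$molecule_types, length, 1L)
}
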