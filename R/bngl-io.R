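#' Read a model in the restricted BNGL dialect
#'
#' Parses a block-structured model file into a [bngl_model()]. The dialect
#' covers multi-site molecule type declarations, seed species with copy
#' numbers, reversible site-site binding rules with on/off stochastic rate
#' constants, optional observables, and a `simulate` line. Site internal
#' states, compartments, synthesis/degradation and functional rates are
#' outside the dialect and rejected with a line-numbered error.
#'
#' Blocks are `begin molecule types` / `end molecule types`,
#' `begin seed species`, `begin reaction rules`, `begin observables`
#' (optional), plus a top-level line
#' `simulate t_end=<num> n_steps=<int> n_runs=<int> seed=<int>`.
#' `#` starts a comment. Rules are written either reversibly,
#' `R1: A(a) + B(b) <-> A(a!1).B(b!1) kon, koff`, or as a forward line
#' (`->`, one rate, dissociation rate 0) optionally paired with an
#' unbinding line `A(a!1).B(b!1) -> A(a) + B(b) koff` that is merged into
#' the same rule record.
#'
#' @param file path to a model file, or a character vector of lines (a
#'   single string may contain newlines).
#' @return A validated [bngl_model()].
#' @seealso [write_bngl()]
#' @export
read_bngl <- function(file) {
  lines <- as_lines(file)
  raw <- sub("#.*$", "", lines)
  mt <- list()
  seeds <- integer()
  rules <- binding_rule(character(), character(), character(), character(),
                        numeric(), numeric(), name = character())
  unbind <- list()  # deferred reverse lines: list of (mol_a, site_a, mol_b, site_b, koff, lineno)
  obs <- data.frame(name = character(), kind = character(),
                    target = character(), stringsAsFactors = FALSE)
  sim <- NULL
  block <- NULL
  perr <- function(i, ...) stop("line ", i, ": ", ..., call. = FALSE)

  for (i in seq_along(raw)) {
    ln <- trimws(raw[i])
    if (!nzchar(ln)) next
    low <- tolower(gsub("\\s+", " ", ln))
    if (grepl("^begin ", low)) {
      if (!is.null(block)) perr(i, "nested 'begin' inside block '", block, "'")
      block <- sub("^begin ", "", low)
      if (block %in% c("model")) { block <- NULL; next }  # tolerated wrapper
      if (!block %in% c("molecule types", "seed species",
                        "reaction rules", "observables"))
        perr(i, "unknown block '", block, "'")
      next
    }
    if (grepl("^end ", low) || low == "end") {
      endblk <- sub("^end ?", "", low)
      if (endblk %in% c("model", "")) next
      if (is.null(block) || endblk != block)
        perr(i, "'end ", endblk, "' does not match open block")
      block <- NULL
      next
    }
    if (is.null(block)) {
      if (grepl("^simulate\\b", low)) {
        sim <- parse_simulate_line(ln, i, perr)
      } else perr(i, "statement outside any block: '", ln, "'")
      next
    }
    switch(block,
      "molecule types" = {
        m <- regmatches(ln, regexec("^([A-Za-z_]\\w*)\\(([^)]*)\\)$", ln))[[1L]]
        if (!length(m)) perr(i, "malformed molecule type declaration: '", ln, "'")
        if (grepl("~", m[3L])) perr(i, "site internal states (~) are not supported")
        sites <- trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])
        if (!length(sites) || any(!nzchar(sites)))
          perr(i, "molecule type '", m[2L], "' must declare at least one site")
        if (m[2L] %in% names(mt)) perr(i, "duplicate molecule type '", m[2L], "'")
        mt[[m[2L]]] <- sites
      },
      "seed species" = {
        m <- regmatches(ln, regexec(
          "^([A-Za-z_]\\w*)(\\([^)]*\\))?\\s+(\\d+)$", ln))[[1L]]
        if (!length(m)) perr(i, "malformed seed species line: '", ln, "'")
        nm <- m[2L]
        if (nzchar(m[3L])) {
          decl <- trimws(strsplit(gsub("[()]", "", m[3L]), ",")[[1L]])
          if (grepl("!", m[3L]))
            perr(i, "seed species must be fully unbound monomers")
          if (!identical(sort(decl), sort(mt[[nm]] %||% character())))
            perr(i, "seed species sites do not match declaration of '", nm, "'")
        }
        if (nm %in% names(seeds)) perr(i, "duplicate seed species '", nm, "'")
        seeds[nm] <- as.integer(m[4L])
      },
      "reaction rules" = {
        parsed <- parse_rule_line(ln, i, perr)
        if (parsed$kind == "bind") {
          rules <- rbind(rules, parsed$row)
        } else {
          unbind[[length(unbind) + 1L]] <- c(parsed, list(lineno = i))
        }
      },
      "observables" = {
        toks <- strsplit(gsub("\\s+", " ", ln), " ")[[1L]]
        kind <- toks[1L]
        if (!kind %in% c("free_molecule", "free_site", "bond_count",
                         "total_clusters"))
          perr(i, "unknown observable kind '", kind, "'")
        nt <- if (kind == "total_clusters") 2L else 3L
        if (length(toks) != nt) perr(i, "malformed observable line: '", ln, "'")
        obs <- rbind(obs, data.frame(
          name = toks[2L], kind = kind,
          target = if (nt == 3L) toks[3L] else "",
          stringsAsFactors = FALSE))
      })
  }
  if (!is.null(block)) stop("unterminated block '", block, "'", call. = FALSE)
  if (is.null(sim)) stop("missing 'simulate' line", call. = FALSE)

  # fold deferred unbinding lines into their matching binding rule
  for (u in unbind) {
    hit <- which((rules$mol_a == u$mol_a & rules$site_a == u$site_a &
                  rules$mol_b == u$mol_b & rules$site_b == u$site_b) |
                 (rules$mol_a == u$mol_b & rules$site_a == u$site_b &
                  rules$mol_b == u$mol_a & rules$site_b == u$site_a))
    if (!length(hit))
      perr(u$lineno, "unbinding rule has no matching binding rule")
    rules$koff[hit[1L]] <- u$koff
  }
  tryCatch(
    bngl_model(mt, seeds, rules, observables = obs, sim_params = sim),
    error = function(e) stop(conditionMessage(e), call. = FALSE))
}

parse_simulate_line <- function(ln, i, perr) {
  body <- sub("^simulate\\s*", "", ln, ignore.case = TRUE)
  kv <- regmatches(body,
    gregexpr("([A-Za-z_]\\w*)\\s*=\\s*([-+0-9.eE]+)", body))[[1L]]
  if (!length(kv)) perr(i, "simulate line needs key=value pairs")
  keys <- sub("\\s*=.*$", "", kv)
  vals <- as.numeric(sub("^.*=\\s*", "", kv))
  if (anyNA(vals)) perr(i, "non-numeric value on simulate line")
  sp <- as.list(stats::setNames(vals, keys))
  unknown <- setdiff(keys, c("t_end", "n_steps", "n_runs", "seed"))
  if (length(unknown)) perr(i, "unknown simulate key '", unknown[1L], "'")
  if (is.null(sp$t_end) || is.null(sp$n_steps) || is.null(sp$n_runs))
    perr(i, "simulate line must set t_end, n_steps and n_runs")
  list(t_end = sp$t_end, n_steps = as.integer(sp$n_steps),
       n_runs = as.integer(sp$n_runs), seed = as.integer(sp$seed %||% 0))
}

NUMRX <- "[-+0-9.eE]+"
ENDRX <- "([A-Za-z_]\\w*)\\(\\s*([A-Za-z_]\\w*)\\s*\\)"
BNDRX <- "([A-Za-z_]\\w*)\\(\\s*([A-Za-z_]\\w*)!1\\s*\\)"

parse_rule_line <- function(ln, i, perr) {
  name <- NA_character_
  m <- regmatches(ln, regexec("^([A-Za-z_]\\w*)\\s*:\\s*(.*)$", ln))[[1L]]
  if (length(m)) { name <- m[2L]; ln <- m[3L] }
  # reversible or forward binding
  rx <- paste0("^", ENDRX, "\\s*\\+\\s*", ENDRX,
               "\\s*(<->|->)\\s*", BNDRX, "\\.", BNDRX,
               "\\s+(", NUMRX, ")\\s*(?:,\\s*(", NUMRX, "))?$")
  m <- regmatches(ln, regexec(rx, ln))[[1L]]
  if (length(m)) {
    rev <- m[6L] == "<->"
    if (m[2L] != m[7L] || m[3L] != m[8L] || m[4L] != m[9L] || m[5L] != m[10L])
      perr(i, "rule product does not match reactant pattern")
    kon <- as.numeric(m[11L])
    koff <- if (nzchar(m[12L])) as.numeric(m[12L]) else 0
    if (rev && !nzchar(m[12L]))
      perr(i, "reversible rule needs two rate constants 'kon, koff'")
    if (!rev && nzchar(m[12L]))
      perr(i, "forward rule takes a single rate constant")
    if (is.na(kon) || is.na(koff)) perr(i, "non-numeric rate constant")
    if (is.na(name)) name <- paste0(m[2L], "_", m[3L], "__", m[4L], "_", m[5L])
    return(list(kind = "bind", row = binding_rule(
      m[2L], m[3L], m[4L], m[5L], kon, koff, name = name)))
  }
  # unbinding line: A(a!1).B(b!1) -> A(a) + B(b) koff
  rx <- paste0("^", BNDRX, "\\.", BNDRX, "\\s*->\\s*", ENDRX,
               "\\s*\\+\\s*", ENDRX, "\\s+(", NUMRX, ")$")
  m <- regmatches(ln, regexec(rx, ln))[[1L]]
  if (length(m)) {
    if (m[2L] != m[6L] || m[3L] != m[7L] || m[4L] != m[8L] || m[5L] != m[9L])
      perr(i, "unbinding product does not match reactant pattern")
    return(list(kind = "unbind", mol_a = m[2L], site_a = m[3L],
                mol_b = m[4L], site_b = m[5L], koff = as.numeric(m[10L])))
  }
  perr(i, "malformed reaction rule: '", ln, "'")
}

#' Write a model in the restricted BNGL dialect
#'
#' Emits text that [read_bngl()] parses back into a structurally identical
#' model (round-trip identity on the data model).
#'
#' @param model a [bngl_model()].
#' @param file optional path; when `NULL` the text is returned as a
#'   character vector of lines.
#' @return Character vector of lines (invisibly when `file` is given).
#' @export
write_bngl <- function(model, file = NULL) {
  validate_model(model)
  out <- c("begin model", "begin molecule types")
  for (t in names(model$molecule_types))
    out <- c(out, sprintf("  %s(%s)", t,
                          paste(model$molecule_types[[t]], collapse = ",")))
  out <- c(out, "end molecule types", "begin seed species")
  for (t in names(model$seeds))
    out <- c(out, sprintf("  %s(%s) %d", t,
                          paste(model$molecule_types[[t]], collapse = ","),
                          model$seeds[[t]]))
  out <- c(out, "end seed species", "begin reaction rules")
  r <- model$rules
  for (i in seq_len(nrow(r)))
    out <- c(out, sprintf("  %s: %s(%s) + %s(%s) <-> %s(%s!1).%s(%s!1) %s, %s",
                          r$name[i], r$mol_a[i], r$site_a[i],
                          r$mol_b[i], r$site_b[i],
                          r$mol_a[i], r$site_a[i], r$mol_b[i], r$site_b[i],
                          fmt_num(r$kon[i]), fmt_num(r$koff[i])))
  out <- c(out, "end reaction rules", "begin observables")
  o <- model$observables
  for (i in seq_len(nrow(o)))
    out <- c(out, trimws(sprintf("  %s %s %s", o$kind[i], o$name[i],
                                 o$target[i]), which = "right"))
  sp <- model$sim_params
  out <- c(out, "end observables", "end model",
           sprintf("simulate t_end=%s n_steps=%d n_runs=%d seed=%d",
                   fmt_num(sp$t_end), as.integer(sp$n_steps),
                   as.integer(sp$n_runs), as.integer(sp$seed)))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# Accept a path, a multi-line string, or a character vector of lines.
as_lines <- function(file) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    return(readLines(file, warn = FALSE))
  unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shortest decimal representation that round-trips the double
fmt_num <- function(x) {
  s <- sprintf("%.15g", x)
  if (as.numeric(s) != x) s <- sprintf("%.17g", x)
  s
}
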