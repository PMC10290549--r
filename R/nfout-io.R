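#' Read an observable time-course table (gdat dialect)
#'
#' The gdat dialect is the whitespace-delimited table NFsim writes for
#' observables: a header line starting with a comment character naming
#' `time` followed by one name per observable, then numeric rows (scientific
#' notation allowed), one per output time.
#'
#' @param file path or character vector of lines.
#' @return A `timecourse` object: data frame with a `time` column (strictly
#'   increasing) and one numeric column per observable.
#' @export
read_gdat <- function(file) {
  lines <- as_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("gdat input is empty (missing header)")
  hdr <- lines[1L]
  if (!grepl("^\\s*#", hdr)) stop("gdat input lacks a '#'-prefixed header line")
  names <- strsplit(trimws(sub("^\\s*#", "", hdr)), "\\s+")[[1L]]
  if (length(names) < 1L || tolower(names[1L]) != "time")
    stop("gdat header must name 'time' first")
  body <- lines[-1L]
  body <- body[!grepl("^\\s*#", body)]
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(f) != length(names))
      stop("gdat row ", i, " has ", length(f), " fields; header names ",
           length(names))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("gdat row ", i, ": non-numeric cell")
    v
  })
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), 0L, length(names))
  df <- as.data.frame(m)
  names(df) <- names
  names(df)[1L] <- "time"
  if (nrow(df) > 1L && any(diff(df$time) <= 0))
    stop("gdat time column must be strictly increasing")
  as_timecourse(df)
}

as_timecourse <- function(df) {
  stopifnot(is.data.frame(df), names(df)[1L] == "time")
  class(df) <- c("timecourse", "data.frame")
  df
}

#' Write an observable time-course table (gdat dialect)
#'
#' @param tc a `timecourse` data frame (see [read_gdat()]).
#' @param file path to write to.
#' @return The path, invisibly.
#' @export
write_gdat <- function(tc, file) {
  hdr <- paste0("# ", paste(names(tc), collapse = "  "))
  rows <- apply(as.matrix(tc), 1L, function(r)
    paste(sprintf("%.8e", r), collapse = "  "))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' Read a final-species file
#'
#' Each nonempty, non-comment line holds one BNGL complex string and a
#' positive integer count, whitespace-separated: the set of molecular
#' complexes present at the end of one simulation run.
#'
#' @param file path or character vector of lines.
#' @return Data frame with columns `species` (complex string) and `count`,
#'   in file order.
#' @export
read_species_file <- function(file) {
  lines <- as_lines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  out <- data.frame(species = character(length(lines)),
                    count = integer(length(lines)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i],
                    regexec("^(\\S+)\\s+(\\d+)$", lines[i]))[[1L]]
    if (!length(m)) stop("species file line ", i, ": malformed: '",
                         lines[i], "'")
    cnt <- as.integer(m[3L])
    if (cnt < 1L) stop("species file line ", i, ": count must be >= 1")
    out$species[i] <- m[2L]
    out$count[i] <- cnt
  }
  out
}

#' Write a final-species file
#'
#' @param species data frame with columns `species` and `count`.
#' @param file path to write to.
#' @return The path, invisibly.
#' @export
write_species_file <- function(species, file) {
  writeLines(sprintf("%s %d", species$species, species$count), file)
  invisible(file)
}
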