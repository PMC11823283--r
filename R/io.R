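#' Read a long-format count panel from CSV
#'
#' Expects columns `unit_id` (0-based integers), `time`, `outcome`,
#' `count`, `censored` (0/1 or logical) and `population`.  The panel must
#' be complete: every (unit, time, outcome) combination exactly once.
#' Time points are ordered by sorted unique value (the first is the
#' baseline); outcomes keep their order of first appearance in the file.
#' A censored row carrying a count outside \[1, 5\] raises a warning and
#' the value is ignored.
#'
#' @param path CSV file path.
#' @return A [count_panel].
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "time", "outcome", "count", "censored", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  units <- sort(unique(df$unit_id))
  if (!identical(as.integer(units), seq_along(units) - 1L))
    stop("unit_id values must cover 0..(n_units-1)")
  times <- sort(unique(df$time))
  outcomes <- unique(df$outcome)
  I <- length(units); J <- length(times); K <- length(outcomes)
  ui <- match(df$unit_id, units)
  ji <- match(df$time, times)
  ki <- match(df$outcome, outcomes)
  cell <- ui + I * (ji - 1L) + I * J * (ki - 1L)
  dup <- duplicated(cell) | duplicated(cell, fromLast = TRUE)
  if (any(dup)) {
    lines <- which(dup) + 1L   # header is line 1
    stop("duplicated (unit, time, outcome) cells at file lines: ",
         paste(utils::head(lines, 10), collapse = ", "))
  }
  if (nrow(df) != I * J * K)
    stop(sprintf("incomplete panel: %d rows, expected %d (complete panel required)",
                 nrow(df), I * J * K))
  cens <- as.logical(df$censored)
  if (any(is.na(cens))) stop("`censored` must be 0/1 or logical")
  if (any(!is.na(df$count) & df$count < 0))
    stop("negative counts are not allowed")
  if (any(df$population <= 0 | is.na(df$population)))
    stop("populations must be strictly positive")
  bad <- cens & !is.na(df$count) & (df$count < 1 | df$count > 5)
  if (any(bad)) {
    warning("censored rows carry counts outside [1,5]; values ignored")
    df$count[bad] <- NA_integer_
  }
  df$count[cens] <- NA_integer_
  counts <- array(NA_integer_, c(I, J, K))
  counts[cell] <- as.integer(df$count)
  censored <- array(FALSE, c(I, J, K))
  censored[cell] <- cens
  pops <- matrix(NA_real_, I, J)
  pops[ui + I * (ji - 1L)] <- df$population
  count_panel(counts, censored, pops,
              unit_labels = as.character(units),
              time_labels = as.character(times),
              outcome_labels = as.character(outcomes))
}

#' Write a count panel to long-format CSV
#'
#' Inverse of [read_panel_csv()]; censored cells are written with an empty
#' count.  Unit ids are written 0-based.
#'
#' @param panel a [count_panel].
#' @param path output CSV path.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "count_panel"))
  d <- dim(panel$counts)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  df <- data.frame(
    unit_id = g$i - 1L,
    time = panel$time_labels[g$j],
    outcome = panel$outcome_labels[g$k],
    count = as.integer(panel$counts[cbind(g$i, g$j, g$k)]),
    censored = as.integer(panel$censored[cbind(g$i, g$j, g$k)]),
    population = panel$populations[cbind(g$i, g$j)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an adjacency edge list
#'
#' One undirected edge per line, two 0-based integer unit indices separated
#' by whitespace or a comma; duplicate edges (in either orientation) are
#' collapsed.  The graph must cover units `0..n_units-1`, contain no
#' self-loops, and be connected.
#'
#' @param path edge-list file.
#' @param n_units number of units.
#' @return An [adjacency_graph].
#' @export
read_adjacency <- function(path, n_units) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  parts <- strsplit(txt, "[,[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed edge line(s): ", paste(utils::head(bad, 5), collapse = ", "))
  e <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
  if (any(is.na(e))) stop("non-integer edge entries")
  if (any(e < 0L | e >= n_units))
    stop("edge index out of range 0..n_units-1")
  adjacency_graph(e + 1L, n_units)
}

#' Write an adjacency edge list (0-based, one edge per line)
#' @param graph an [adjacency_graph].
#' @param path output file.
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  writeLines(paste(graph$edges[, 1] - 1L, graph$edges[, 2] - 1L), path)
  invisible(path)
}

#' Read a loadings pattern from a structured text file
#'
#' Format: one line of 0/1 per outcome giving the structural mask
#' (whitespace-separated, one column per factor), then one
#' `anchor <row> <col>` line per factor with 0-based coordinates, and
#' optionally `order <i0> <i1> ...` (0-based outcome order) and
#' `labels <a> <b> ...`.  Lines starting with `#` are comments.
#'
#' @param path pattern file.
#' @return A [loadings_pattern].
#' @export
read_pattern <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- trimws(readLines(path, warn = FALSE))
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  is_anchor <- startsWith(txt, "anchor")
  is_order <- startsWith(txt, "order")
  is_labels <- startsWith(txt, "labels")
  mask_lines <- txt[!is_anchor & !is_order & !is_labels]
  mask <- do.call(rbind, lapply(strsplit(mask_lines, "[[:space:]]+"),
                                as.integer))
  if (any(is.na(mask)) || any(!mask %in% c(0L, 1L)))
    stop("mask lines must contain only 0/1")
  anchors <- do.call(rbind, lapply(strsplit(txt[is_anchor], "[[:space:]]+"),
                                   function(p) as.integer(p[2:3]) + 1L))
  if (is.null(anchors)) stop("no anchor lines found")
  ord <- seq_len(nrow(mask))
  if (any(is_order))
    ord <- as.integer(strsplit(txt[is_order][1], "[[:space:]]+")[[1]][-1]) + 1L
  labels <- NULL
  if (any(is_labels))
    labels <- strsplit(txt[is_labels][1], "[[:space:]]+")[[1]][-1]
  loadings_pattern(mask == 1L, anchors, ord, labels)
}

#' Write a loadings pattern file (inverse of [read_pattern()])
#' @param pattern a [loadings_pattern].
#' @param path output file.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "loadings_pattern"))
  lines <- c(apply(pattern$mask * 1L, 1, paste, collapse = " "),
             paste("anchor", pattern$anchors[, 1] - 1L,
                   pattern$anchors[, 2] - 1L),
             paste("order", paste(pattern$outcome_order - 1L, collapse = " ")),
             paste("labels", paste(pattern$outcome_labels, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read sampler settings from a YAML config file
#'
#' Recognised keys: `iterations`, `burn_in`, `thin`, `seed`, `adapt`, and a
#' `proposal_sd` mapping with entries `loadings`, `factors`, `epsilon`,
#' `eta`.  Missing keys fall back to the defaults of [sampler_config()]
#' or to `defaults`.
#'
#' @param path YAML file (or `NULL` for defaults).
#' @param defaults a [sampler_config] supplying fallback values.
#' @return A [sampler_config].
#' @export
read_run_config <- function(path = NULL, defaults = sampler_config()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  psd <- utils::modifyList(defaults$proposal_sd,
                           cfg$proposal_sd %||% list())
  sampler_config(
    n_iter = cfg$iterations %||% defaults$n_iter,
    burn_in = cfg$burn_in %||% defaults$burn_in,
    thin = cfg$thin %||% defaults$thin,
    proposal_sd = psd,
    adapt = cfg$adapt %||% defaults$adapt,
    seed = cfg$seed %||% defaults$seed,
    prior_only = cfg$prior_only %||% defaults$prior_only)
}

#' Write a run manifest
#'
#' Records input paths, config values, seed, package version, timestamps
#' and per-block acceptance rates, sufficient to re-run a fit
#' bit-identically.
#'
#' @param path output JSON file.
#' @param inputs named list of input file paths.
#' @param config a [sampler_config].
#' @param acceptance optional named numeric vector of acceptance rates.
#' @export
write_manifest <- function(path, inputs, config, acceptance = NULL) {
  man <- list(
    package = "dsfactor",
    version = as.character(utils::packageVersion("dsfactor")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    config = unclass(config),
    acceptance = as.list(acceptance))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
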