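#' Read and write electrode-trace CSV files
#'
#' The trace dialect is a CSV with header `time_s,o2_uM`; `#`-prefixed
#' comment lines (retained as metadata) and blank lines are allowed.  The
#' writer emits 6 significant digits, so a round trip reproduces a trace to
#' that precision.
#'
#' @param path file path.
#' @return `read_trace()` returns an [opf_trace] (comment lines in
#'   `attr(, "meta")$comments`); `write_trace()` returns `path` invisibly.
#' @examples
#' tr <- read_trace(system.file("extdata", "synthetic_dtt_trace.csv",
#'                              package = "opfkin"))
#' max_consumption_rate(tr)
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  comments <- sub("^\\s*#\\s?", "", lines[grepl("^\\s*#", lines)])
  body <- lines[keep]
  if (!length(body))
    stop("parse error: no data lines in ", path, call. = FALSE)
  header <- trimws(strsplit(body[1], ",")[[1]])
  if (!identical(header, c("time_s", "o2_uM")))
    stop(sprintf(
      "parse error in %s line %d: expected header 'time_s,o2_uM', found '%s'",
      path, which(keep)[1], body[1]), call. = FALSE)
  if (length(body) < 2)
    stop("parse error: trace has no data rows", call. = FALSE)
  fields <- strsplit(body[-1], ",")
  lineno <- which(keep)[-1]
  bad <- which(lengths(fields) != 2)
  if (length(bad))
    stop(sprintf("parse error in %s line %d: expected 2 fields", path,
                 lineno[bad[1]]), call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 2, byrow = TRUE)
  nonnum <- which(!stats::complete.cases(m))
  if (length(nonnum))
    stop(sprintf("parse error in %s line %d: non-numeric value", path,
                 lineno[nonnum[1]]), call. = FALSE)
  drop <- which(diff(m[, 1]) <= 0)
  if (length(drop))
    stop(sprintf("parse error in %s line %d: time not strictly increasing",
                 path, lineno[drop[1] + 1]), call. = FALSE)
  opf_trace(m[, 1], m[, 2], meta = list(comments = comments))
}

#' @rdname read_trace
#' @param trace an [opf_trace].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "opf_trace"))
  meta <- attr(trace, "meta")
  lines <- character(0)
  if (!is.null(meta$comments))
    lines <- paste0("# ", meta$comments)
  lines <- c(lines, "time_s,o2_uM",
             sprintf("%s,%s", formatC(trace$time_s, digits = 6,
                                      format = "g"),
                     formatC(trace$o2_uM, digits = 6, format = "g")))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write proteome tables
#'
#' Tab-separated tables with columns `protein_id`, `abundance`, `n_cys` and
#' one of `deg_rate_per_min` / `half_life_min` (half-lives are converted to
#' rates via ln 2 on read).
#'
#' @param path file path.
#' @return `read_proteome()` returns a validated data.frame with a
#'   `deg_rate_per_min` column.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "abundance", "n_cys")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("proteome table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!any(c("deg_rate_per_min", "half_life_min") %in% names(df)))
    stop("proteome table needs `deg_rate_per_min` or `half_life_min`",
         call. = FALSE)
  bad <- which(df$abundance < 0)
  if (length(bad))
    stop(sprintf("row %d: negative abundance", bad[1]), call. = FALSE)
  bad <- which(df$n_cys < 0 | df$n_cys %% 1 != 0)
  if (length(bad))
    stop(sprintf("row %d: cysteine count must be a non-negative integer",
                 bad[1]), call. = FALSE)
  if (!"deg_rate_per_min" %in% names(df))
    df$deg_rate_per_min <- log(2) / df$half_life_min
  bad <- which(df$deg_rate_per_min < 0)
  if (length(bad))
    stop(sprintf("row %d: negative degradation rate", bad[1]),
         call. = FALSE)
  df
}

#' @rdname read_proteome
#' @param proteome a proteome data.frame.
#' @export
write_proteome <- function(proteome, path) {
  utils::write.table(proteome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write and read an experiment set (traces plus YAML manifest)
#'
#' The manifest lists, per trace file, the initial concentrations, the
#' injection events and the series grouping; trace files sit next to it in
#' the trace CSV dialect.  `read_manifest(write_manifest(x, dir))` round
#' trips an experiment set.
#'
#' @param experiments an [opf_experiments] set.
#' @param dir output directory (created if needed).
#' @return `write_manifest()` returns the manifest path invisibly;
#'   `read_manifest()` returns an [opf_experiments] set.
#' @export
write_manifest <- function(experiments, dir) {
  stopifnot(inherits(experiments, "opf_experiments"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(experiments))
  for (i in seq_along(experiments)) {
    ex <- experiments[[i]]
    fn <- sprintf("trace_%02d.csv", i)
    write_trace(ex$trace, file.path(dir, fn))
    cond <- ex$conditions
    entries[[i]] <- list(
      trace = fn,
      initial_uM = as.list(cond$init[cond$init != 0 | is.na(cond$init)]),
      injections = if (nrow(cond$injections))
        lapply(seq_len(nrow(cond$injections)), function(j)
          as.list(cond$injections[j, ])) else list(),
      duration_s = cond$duration,
      interval_s = cond$interval,
      diffusion = cond$diffusion)
  }
  manifest <- list(series = attr(experiments, "series"),
                   experiments = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @param path path to a `manifest.yaml`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  man <- yaml::read_yaml(path)
  dir <- dirname(path)
  pairs <- lapply(man$experiments, function(e) {
    init <- unlist(e$initial_uM)
    init <- init[!is.na(init)]
    inj <- if (length(e$injections))
      do.call(rbind, lapply(e$injections, as.data.frame)) else NULL
    cond <- opf_conditions(state = init, injections = inj,
                           duration = e$duration_s, interval = e$interval_s,
                           diffusion = e$diffusion)
    list(conditions = cond, trace = read_trace(file.path(dir, e$trace)))
  })
  opf_experiments(pairs, series = man$series %||% "series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fit-report TSV
#'
#' @param fit an [opf_fit] ensemble.
#' @param path output path.
#' @export
write_fit_report <- function(fit, path) {
  utils::write.table(fit_report(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname capacity_report
#' @param report an `opf_capacity_report`.
#' @param path output TSV path (a human-readable summary goes to a `.txt`
#'   sidecar).
#' @export
write_capacity_report <- function(report, path) {
  stopifnot(inherits(report, "opf_capacity_report"))
  df <- data.frame(quantity = c("demand_kcys_per_min",
                                "supply_per_min", "supply_rounded",
                                "supply_demand_ratio"),
                   value = c(report$demand, report$supply,
                             report$supply_rounded, report$ratio))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- sub("\\.tsv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  con <- file(txt, "w"); on.exit(close(con))
  sink(con); print(report); sink()
  invisible(path)
}
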