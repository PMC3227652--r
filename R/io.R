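#' Load a run configuration
#'
#' Reads a YAML configuration describing a screen run: sample size and seed,
#' sampling ranges, protein totals, stimulation protocol, classifier
#' thresholds, worker count and output path. Every block is optional except
#' `n` and `seed`; omitted values fall back to the reference defaults
#' (detection threshold 10 pM, constant 200 pM stimulus for 10 h, totals
#' 1/60/100 nM, the reconstructed sampling ranges). Unknown keys anywhere in
#' the file are rejected, as are invalid ranges (the offending parameter is
#' named).
#'
#' @param path Path to a YAML file (or a parsed list).
#' @return A list of class `"tgf_run_config"` with elements `n`, `seed`,
#'   `workers`, `out`, `ranges` (tibble), `totals`, `protocol`,
#'   `classifier`.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as a boolean; map it back
  names(raw)[names(raw) == "FALSE"] <- "n"
  known <- c("n", "seed", "workers", "out", "ranges", "totals", "protocol",
             "classifier")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$n) || is.null(raw$seed))
    stop("config must provide 'n' and 'seed'")

  ranges <- if (is.null(raw$ranges)) {
    default_ranges()
  } else if (is.character(raw$ranges)) {
    read_ranges(raw$ranges)
  } else {
    tibble::tibble(
      parameter = names(raw$ranges),
      lower = unname(purrr::map_dbl(raw$ranges,
                                    function(x) as.numeric(x$lower))),
      upper = unname(purrr::map_dbl(raw$ranges,
                                    function(x) as.numeric(x$upper))),
      provenance = unname(purrr::map_chr(raw$ranges, function(x) {
        if (is.null(x$provenance)) "user" else x$provenance
      }))
    )
  }
  validate_ranges(ranges)

  tot <- raw$totals
  check_keys(tot, c("R_tot", "S_tot", "C_tot"), "totals")
  totals <- do.call(total_concentrations, as.list(tot %||% list()))

  pr <- raw$protocol %||% list()
  check_keys(pr, c("preset", "L_pM", "duration_h", "peak_pM", "rise_h",
                   "fall_h"), "protocol")
  preset <- pr$preset %||% "constant"
  protocol <- if (preset == "constant") {
    protocol_constant(L_pM = pr$L_pM %||% 200,
                      duration_h = pr$duration_h %||% 10)
  } else if (preset == "triangle") {
    protocol_triangle(peak_pM = pr$peak_pM %||% 720,
                      rise_h = pr$rise_h %||% 5, fall_h = pr$fall_h %||% 5)
  } else {
    stop("unknown protocol preset: ", preset)
  }

  cl <- raw$classifier %||% list()
  check_keys(cl, names(formals(classifier_config)), "classifier")
  classifier <- do.call(classifier_config, cl)

  structure(list(n = as.integer(raw$n), seed = as.integer(raw$seed),
                 workers = as.integer(raw$workers %||% 1L),
                 out = raw$out, ranges = ranges, totals = totals,
                 protocol = protocol, classifier = classifier),
            class = "tgf_run_config")
}

check_keys <- function(x, allowed, block) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0)
    stop("unknown key(s) in '", block, "': ",
         paste(unknown, collapse = ", "))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration back to YAML
#'
#' Serializes the fully resolved configuration; `load_config(write_config(x))`
#' reproduces `x`.
#'
#' @param config A `"tgf_run_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "tgf_run_config"))
  pr <- config$protocol
  proto <- if (pr$type == "constant") {
    list(preset = "constant", L_pM = pr$L_nM * 1000,
         duration_h = pr$duration_s / 3600)
  } else {
    list(preset = "triangle", peak_pM = pr$peak_nM * 1000,
         rise_h = pr$rise_s / 3600,
         fall_h = (pr$total_s - pr$rise_s) / 3600)
  }
  cl <- unclass(config$classifier)
  cl <- cl[!purrr::map_lgl(cl, is.null)]
  out <- list(
    n = config$n, seed = config$seed, workers = config$workers,
    out = config$out,
    ranges = stats::setNames(
      purrr::pmap(config$ranges[c("lower", "upper", "provenance")], list),
      config$ranges$parameter),
    totals = as.list(unclass(config$totals)),
    protocol = proto,
    classifier = cl
  )
  out <- out[!purrr::map_lgl(out, is.null)]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read and write result tables as TSV
#'
#' Plain-text tab-separated serialization with a header row, stable column
#' order and full floating-point precision, so that
#' `read_results(write_results(x, f))` reproduces `x` (labels as lowercase
#' tokens of the [response_labels()] vocabulary). An empty table writes a
#' header-only file.
#'
#' @param table Data frame (screen, switch or faithfulness table).
#' @param path File path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a tibble.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(tbl)) tbl$label <- as.character(tbl$label)
  # all-missing numeric columns come back as logical; restore their type
  tbl[] <- lapply(tbl, function(x) {
    if (is.logical(x) && all(is.na(x))) as.numeric(x) else x
  })
  tbl
}

#' Read and write a sampling-range table as TSV
#'
#' @param ranges Range table (columns `parameter`, `lower`, `upper`,
#'   optionally `provenance`).
#' @param path File path.
#' @return The range table (read) or `path` invisibly (write).
#' @export
write_ranges <- function(ranges, path) {
  validate_ranges(ranges)
  readr::write_tsv(ranges, path)
  invisible(path)
}

#' @rdname write_ranges
#' @export
read_ranges <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!("provenance" %in% names(tbl))) tbl$provenance <- "user"
  validate_ranges(tbl)
  tibble::as_tibble(tbl)
}

#' Read a two-column time/value TSV as a response trace
#'
#' Accepts any plain-text TSV whose first two columns are time (s) and
#' output (pM), e.g. exported experimental summaries, so traces from outside
#' the simulator can be classified.
#'
#' @param path File path.
#' @return A `"tgf_trace"`.
#' @export
read_trace_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(ncol(tbl) >= 2)
  new_trace(tbl[[1]], tbl[[2]])
}

#' @rdname read_trace_tsv
#' @param trace A `"tgf_trace"`.
#' @export
write_trace_tsv <- function(trace, path) {
  readr::write_tsv(tibble::tibble(time_s = trace$time_s,
                                  output_pM = trace$output_pM), path)
  invisible(path)
}
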