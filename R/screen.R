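#' Run a Monte-Carlo parameter screen
#'
#' Simulates the two-phase protocol (1 h low-ligand equilibration, then the
#' given stimulus) for every supplied parameter set, classifies each response
#' with [classify_with_extension()] (so slow oscillations are followed beyond
#' the 10 h window), and tabulates one record per set: the parameters, the
#' composite features `F`, `D`, `T` of [derived_features()], the response
#' label and all classifier metrics. Individual solver failures never abort
#' the screen; they are recorded under the label `failed` and remain in the
#' denominator of all fractions.
#'
#' @param paramsets Tibble of parameter sets as returned by
#'   [sample_parameters()] (columns `draw`, `k1` ... `k19`, `h`).
#' @param totals A [total_concentrations()].
#' @param protocol A `"tgf_protocol"`.
#' @param cfg A [classifier_config()].
#' @param workers Number of forked workers (results are identical for any
#'   value because all sampling happens before simulation; keep 1 on
#'   platforms without fork support).
#' @param progress_every Emit a progress message with running label counts
#'   every this many records; `Inf` (default) disables logging.
#' @return A `"tgf_screen"` tibble: one row per parameter set with columns
#'   `draw`, `k1` ... `k19`, `h`, `F`, `D`, `T`, `label`, `Opeak`,
#'   `t_peak90`, `Oend`, `theta_used`, `n_peaks`, `period_s`, `duration_s`.
#' @export
#' @examples
#' ps <- sample_parameters(default_ranges(), n = 5, seed = 7)
#' scr <- run_screen(ps)
#' summarize_fractions(scr)
run_screen <- function(paramsets, totals = total_concentrations(),
                       protocol = protocol_constant(),
                       cfg = classifier_config(), workers = 1L,
                       progress_every = Inf) {
  stopifnot(is.data.frame(paramsets))
  if (nrow(paramsets) == 0) {
    return(new_screen(dplyr::bind_cols(paramsets[0, ],
                                       tidy_class_cols()[0, ])))
  }
  rows <- seq_len(nrow(paramsets))
  one <- function(i) {
    p <- as_parameter_set(paramsets[i, ])
    res <- classify_with_extension(p, totals, protocol, cfg)
    if (is.finite(progress_every) && i %% progress_every == 0) {
      message(sprintf("[screen] %d/%d records", i, nrow(paramsets)))
    }
    tidy(res)
  }
  recs <- if (workers > 1L) {
    dplyr::bind_rows(parallel::mclapply(rows, one, mc.cores = workers))
  } else {
    purrr::map_dfr(rows, one)
  }
  feats <- derived_features(paramsets)
  new_screen(dplyr::bind_cols(paramsets, feats, recs))
}

tidy_class_cols <- function() {
  tibble::tibble(label = character(), Opeak = numeric(),
                 t_peak90 = numeric(), Oend = numeric(),
                 theta_used = numeric(), n_peaks = integer(),
                 period_s = numeric(), duration_s = numeric())
}

new_screen <- function(tbl) {
  class(tbl) <- c("tgf_screen", class(tbl))
  tbl
}

#' Label fractions of a screen
#'
#' Fractions of each of the seven response labels (the six phenotypes plus
#' `failed`) over all records of a screen table. Labels never observed are
#' reported with fraction 0, and the fractions sum to 1 exactly.
#'
#' @param table A `"tgf_screen"` (any data frame with a `label` column).
#' @return Tibble with columns `label`, `n`, `fraction`, in the fixed label
#'   order of [response_labels()].
#' @export
summarize_fractions <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (nrow(table) == 0) stop("empty screen table")
  lv <- factor(table$label, levels = response_labels())
  if (anyNA(lv)) stop("unknown label in table")
  cnt <- table(lv)
  tibble::tibble(label = names(cnt), n = as.integer(cnt),
                 fraction = as.integer(cnt) / nrow(table))
}

#' Screen-level one-line summary
#'
#' @param x A `"tgf_screen"`.
#' @param ... Unused.
#' @return One-row tibble: record count, fraction per label, failure rate.
#' @method glance tgf_screen
#' @export
glance.tgf_screen <- function(x, ...) {
  fr <- summarize_fractions(x)
  wide <- stats::setNames(as.list(fr$fraction), paste0("frac_", fr$label))
  tibble::as_tibble(c(list(n = nrow(x)), wide))
}
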