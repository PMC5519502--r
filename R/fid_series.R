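# FidSeries: an ordered set of per-TR complex FIDs with condition labels and
# provenance flags recording which corrections have been applied.

#' Construct a FID series
#'
#' @param fids Complex matrix, one column per TR (`n_points` x `n_trs`), or a
#'   list of equal-length complex vectors.
#' @param condition_labels Character vector (`"baseline"`/`"stimulation"`),
#'   one per TR.
#' @param params An [acquisition_params()].
#' @param subject_id Identifier carried through tables.
#' @param provenance_flags Character vector of corrections already applied.
#' @return An object of class `fid_series`.
#' @export
fid_series <- function(fids, condition_labels, params, subject_id = "s01",
                       provenance_flags = character()) {
  if (is.list(fids)) {
    lens <- lengths(fids)
    if (length(unique(lens)) != 1) stop("all FIDs must have the same length")
    fids <- matrix(unlist(fids), nrow = lens[1])
  }
  if (!is.matrix(fids)) fids <- matrix(fids, ncol = 1)
  if (ncol(fids) != length(condition_labels))
    stop("condition_labels length must equal the number of FIDs")
  if (!all(condition_labels %in% c("baseline", "stimulation")))
    stop("labels must be 'baseline' or 'stimulation'")
  structure(list(fids = fids,
                 condition_labels = condition_labels,
                 params = params,
                 subject_id = subject_id,
                 provenance_flags = provenance_flags),
            class = "fid_series")
}

#' @export
print.fid_series <- function(x, ...) {
  cat(sprintf("<fid_series> %d TRs x %d points [%s]\n",
              ncol(x$fids), nrow(x$fids),
              if (length(x$provenance_flags))
                paste(x$provenance_flags, collapse = ", ") else "raw"))
  cat(sprintf("  baseline: %d TRs, stimulation: %d TRs\n",
              sum(x$condition_labels == "baseline"),
              sum(x$condition_labels == "stimulation")))
  invisible(x)
}

#' Number of TRs in a FID series
#' @param series A `fid_series`.
#' @return Integer count.
#' @export
n_trs <- function(series) ncol(series$fids)

# guard against double application of a correction
assert_not_applied <- function(series, flag) {
  if (flag %in% series$provenance_flags)
    stop(sprintf("correction '%s' has already been applied to this series",
                 flag))
}

add_flag <- function(series, flag) {
  series$provenance_flags <- c(series$provenance_flags, flag)
  series
}

#' Average FID per condition
#'
#' Averages the (typically reduced) TRs of each condition into one FID per
#' condition. Means rather than sums are used so amplitudes stay on the
#' single-spectrum scale regardless of how many TRs contribute; the
#' contributing counts are returned for bookkeeping.
#'
#' @param series A `fid_series`.
#' @return List with complex FIDs `baseline` and `stimulation` and counts
#'   `n_baseline`, `n_stimulation`.
#' @export
combine_condition <- function(series) {
  bi <- series$condition_labels == "baseline"
  si <- series$condition_labels == "stimulation"
  if (!any(bi) || !any(si)) stop("both conditions must be present")
  list(baseline = rowMeans(series$fids[, bi, drop = FALSE]),
       stimulation = rowMeans(series$fids[, si, drop = FALSE]),
       n_baseline = sum(bi), n_stimulation = sum(si))
}
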