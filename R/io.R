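# Dataset container: a JSON header (acquisition parameters, design, truth,
# labels, seed) next to little-endian complex-double binary blobs for the
# metabolite FIDs and the water reference, plus a TSV for the BOLD series.
# The round trip is bit-exact because values are stored as IEEE doubles.

write_complex_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rbind(Re(x), Im(x))), con, size = 8,
           endian = "little")
}

read_complex_bin <- function(path, n_expected) {
  sz <- file.info(path)$size
  want <- n_expected * 16
  if (is.na(sz) || sz != want)
    stop(sprintf("truncated or oversized binary '%s': %d bytes, expected %d (error at byte offset %d)",
                 basename(path), sz, want, min(sz, want)))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = 2 * n_expected, size = 8,
               endian = "little")
  complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
}

#' Write a subject dataset to a directory
#'
#' Layout: `header.json` (schema, acquisition parameters, design, truth,
#' condition labels, CSF fraction, seed), `fids.bin` and `water.bin`
#' (little-endian complex doubles, column-major TR order), `bold.tsv`, and
#' `manifest.json` (package version, creation time, MD5 of the header).
#'
#' @param ds A `subject_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- list(
    schema = "fmrsglu-dataset-1",
    subject_id = ds$fids$subject_id,
    params = unclass(ds$fids$params),
    design = unclass(ds$design),
    truth = lapply(unclass(ds$truth), function(x)
      if (is.null(names(x))) x else as.list(x)),
    condition_labels = ds$fids$condition_labels,
    provenance_flags = ds$fids$provenance_flags,
    csf_fraction = ds$csf_fraction,
    seed = ds$seed,
    n_points = nrow(ds$fids$fids),
    n_trs = ncol(ds$fids$fids))
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_complex_bin(as.vector(ds$fids$fids), file.path(dir, "fids.bin"))
  write_complex_bin(ds$water_reference, file.path(dir, "water.bin"))
  utils::write.table(data.frame(tr = seq_along(ds$bold), bold = ds$bold),
                     file.path(dir, "bold.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "fmrsglu",
    version = as.character(utils::packageVersion("fmrsglu")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    header_md5 = unname(tools::md5sum(file.path(dir, "header.json"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a subject dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `subject_dataset`.
#' @export
read_dataset <- function(dir) {
  hpath <- file.path(dir, "header.json")
  if (!file.exists(hpath)) stop("header.json not found in ", dir)
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  required <- c("schema", "params", "design", "condition_labels",
                "csf_fraction", "seed", "n_points", "n_trs")
  for (f in required)
    if (is.null(header[[f]]))
      stop(sprintf("dataset header violates the schema: field '%s' missing", f))
  for (f in c("spectrometer_freq", "spectral_width", "n_points", "tr", "te",
              "n_averages", "reference_ppm"))
    if (is.null(header$params[[f]]))
      stop(sprintf("dataset header violates the schema: field 'params.%s' missing", f))
  params <- do.call(acquisition_params, header$params)
  design <- do.call(block_design, header$design)
  truth <- header$truth
  if (!is.null(truth)) {
    truth$baseline_concentrations <- unlist(truth$baseline_concentrations)
    truth <- do.call(ground_truth, truth)
  }
  n <- header$n_points * header$n_trs
  fids <- matrix(read_complex_bin(file.path(dir, "fids.bin"), n),
                 nrow = header$n_points)
  water <- read_complex_bin(file.path(dir, "water.bin"), header$n_points)
  bold <- utils::read.delim(file.path(dir, "bold.tsv"))$bold
  structure(list(
    fids = fid_series(fids, header$condition_labels, params,
                      subject_id = header$subject_id,
                      provenance_flags = as.character(header$provenance_flags)),
    water_reference = water,
    bold = bold,
    design = design,
    csf_fraction = header$csf_fraction,
    truth = truth,
    seed = header$seed), class = "subject_dataset")
}

#' Write an analysis table as TSV with a manifest
#'
#' Writes the data.frame as tab-separated values and a sidecar
#' `<name>.manifest.json` recording the package version and the MD5 of the
#' table, so every output can be traced to the software that produced it.
#'
#' @param stats A data.frame (e.g. `group_stats`, line-width or QC tables).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  manifest <- list(package = "fmrsglu",
                   version = as.character(utils::packageVersion("fmrsglu")),
                   created = format(Sys.time(), tz = "UTC", usetz = TRUE),
                   table_md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
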