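#' Write decoding samples as TSV with a JSON sidecar
#'
#' One row per sample with columns session, run, report, label,
#' f0001 ... fK; processing parameters (smoothing, partition size,
#' preprocessing toggles) go into a JSON sidecar next to the TSV.
#'
#' @param samples a [decoding_samples] object.
#' @param path output TSV path (sidecar written as `<path>.json`).
#' @param params optional named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_samples_tsv <- function(samples, path, params = list()) {
  d <- data.frame(session = if (is.null(samples$session)) NA else
                    samples$session,
                  run = if (is.null(samples$run)) NA else samples$run,
                  report = samples$report, label = samples$label)
  X <- samples$X
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  utils::write.table(cbind(d, X), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- c(list(n_samples = nrow(X), n_features = ncol(X),
                 BS = samples$BS), params)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read decoding samples written by [write_samples_tsv]
#'
#' @param path TSV path.
#' @return A [decoding_samples] object.
#' @export
read_samples_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  meta_cols <- c("session", "run", "report", "label")
  X <- as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE])
  side_path <- paste0(path, ".json")
  BS <- if (file.exists(side_path))
    jsonlite::fromJSON(side_path)$BS else NA_integer_
  decoding_samples(X, d$label, d$report, run = d$run, session = d$session,
                   BS = if (is.null(BS)) NA_integer_ else BS)
}
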