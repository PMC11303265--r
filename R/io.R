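#' Write a recording to the plain-text EEG container
#'
#' A simple self-describing TSV: comment header lines carrying the
#' sampling rate, channel ids and montage positions, then one row per
#' channel of tab-separated samples (full double precision, so a
#' write-read round trip is bit-identical). Segment boundaries, when
#' present, are stored in the header.
#'
#' @param rec an [eeg_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# microstatr-eeg v1",
    sprintf("# fs_hz\t%.17g", rec$fs_hz),
    sprintf("# channels\t%s", paste(rec$montage$channel_ids, collapse = "\t")),
    sprintf("# pos_x\t%s",
            paste(sprintf("%.17g", rec$montage$positions[, 1L]),
                  collapse = "\t")),
    sprintf("# pos_y\t%s",
            paste(sprintf("%.17g", rec$montage$positions[, 2L]),
                  collapse = "\t")),
    if (!is.null(rec$segments))
      sprintf("# segments\t%s",
              paste(rec$segments[, 1L], rec$segments[, 2L],
                    sep = ":", collapse = "\t"))
  ), con)
  utils::write.table(format(rec$data, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an EEG recording
#'
#' Reads the plain-text container written by [write_eeg_tsv]. Other
#' common binary EEG formats are not parsed here; requesting one raises
#' an error naming the supported format. A file whose header lacks
#' montage positions is rejected with the affected channels named.
#'
#' @param path file path.
#' @param format only `"tsv"` is supported.
#' @return an [eeg_recording].
#' @export
read_eeg <- function(path, format = "tsv") {
  if (!identical(tolower(format), "tsv"))
    stop("unsupported format '", format,
         "'; supported formats: tsv (microstatr-eeg container)")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 50L)
  hdr <- lines[startsWith(lines, "# ")]
  if (!any(startsWith(hdr, "# microstatr-eeg")))
    stop("not a microstatr-eeg container: ", path)
  get_field <- function(key) {
    row <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    if (length(row) == 0L) return(NULL)
    strsplit(sub(paste0("^# ", key, "\t"), "", row[1L]), "\t")[[1L]]
  }
  fs <- as.numeric(get_field("fs_hz"))
  ch <- get_field("channels")
  px <- as.numeric(get_field("pos_x"))
  py <- as.numeric(get_field("pos_y"))
  if (is.null(px) || is.null(py) || anyNA(px) || anyNA(py) ||
      length(px) != length(ch))
    stop("montage positions missing for channels: ",
         paste(if (is.null(px)) ch else ch[seq_along(ch) > length(px)],
               collapse = ", "))
  segs <- get_field("segments")
  segments <- NULL
  if (!is.null(segs)) {
    parts <- do.call(rbind, strsplit(segs, ":"))
    segments <- cbind(start = as.integer(parts[, 1L]),
                      end = as.integer(parts[, 2L]))
  }
  data <- as.matrix(utils::read.table(path, sep = "\t",
                                      comment.char = "#"))
  dimnames(data) <- NULL
  eeg_recording(data, fs, montage(ch, cbind(px, py)), segments)
}

#' Write / read cohort tables
#'
#' CSV with a fixed, documented column schema (subject_id, group, the
#' clinical fields, then the microstate feature columns in the canonical
#' order: durations, coverages, occurrences, transitions). A header
#' comment carries the schema version.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_cohort_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# microstatr-cohort v1", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
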