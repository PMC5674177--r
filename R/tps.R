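#' Read landmark data from a TPS file
#'
#' Parses the TPS dialect emitted by the tps-UTIL / tps-DIG family of
#' digitizing tools: each record starts with an `LM=<k>` line followed by
#' exactly `k` whitespace-separated "x y" coordinate lines, optionally
#' followed by `ID=`, `IMAGE=`, and `SCALE=` lines. Only 2-D records are
#' accepted; `LM3=` (3-D) records are rejected, since the wing-shape
#' pipeline is strictly two-dimensional.
#'
#' All records in one file must declare the same landmark count (one
#' landmark scheme per dataset). Records lacking an `ID=` line are given ids
#' `record_1`, `record_2`, ...
#'
#' @param path path to a TPS file.
#' @param labels optional label data.frame or path to a labels CSV (see
#'   [read_labels()]) to attach to the dataset.
#' @param apply_scale logical: multiply coordinates by the record's `SCALE=`
#'   factor, converting them to physical units. Off by default: Procrustes
#'   superimposition discards size, and leaving coordinates untouched keeps
#'   the round trip through [write_tps()] exact. The factor is always stored
#'   on the configuration either way.
#' @param scheme_name passed to [shape_dataset()].
#' @return a [shape_dataset()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".tps")
#' writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=A"), f)
#' read_tps(f)
read_tps <- function(path, labels = NULL, apply_scale = FALSE,
                     scheme_name = "bee-forewing-18") {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  configs <- list()
  i <- 1L
  rec <- 0L
  n_lines <- length(lines)
  while (i <= n_lines) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (grepl("^LM3=", line, ignore.case = TRUE))
      stop("record ", rec + 1L, ": 3-D records (LM3=) are not supported; ",
           "this pipeline analyzes 2-D landmarks only")
    if (!grepl("^LM=", line, ignore.case = TRUE))
      stop("line ", i, ": expected an LM= record header, got '", line, "'")
    rec <- rec + 1L
    k <- suppressWarnings(as.integer(sub("^LM=", "", line, ignore.case = TRUE)))
    if (is.na(k) || k < 0L)
      stop("record ", rec, ": malformed landmark count in '", line, "'")
    coords <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      i <- i + 1L
      if (i > n_lines)
        stop("record ", rec, ": file ends after ", j - 1L,
             " of ", k, " declared coordinate lines")
      parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
      xy <- suppressWarnings(as.numeric(parts))
      if (length(xy) != 2L || anyNA(xy))
        stop("record ", rec, ": expected ", k,
             " coordinate lines after LM=, but line ", i,
             " ('", trimws(lines[i]), "') is not an \"x y\" pair")
      coords[j, ] <- xy
    }
    id <- NULL; scl <- NULL
    repeat {
      if (i + 1L > n_lines) break
      nxt <- trimws(lines[i + 1L])
      if (grepl("^ID=", nxt, ignore.case = TRUE)) {
        id <- sub("^ID=", "", nxt, ignore.case = TRUE)
      } else if (grepl("^SCALE=", nxt, ignore.case = TRUE)) {
        scl <- suppressWarnings(
          as.numeric(sub("^SCALE=", "", nxt, ignore.case = TRUE)))
        if (is.na(scl))
          stop("record ", rec, ": malformed SCALE= line '", nxt, "'")
      } else if (grepl("^IMAGE=", nxt, ignore.case = TRUE) || !nzchar(nxt)) {
        ## IMAGE= is carried by digitizers but unused here; blanks skipped
      } else break
      i <- i + 1L
    }
    if (is.null(id)) id <- paste0("record_", rec)
    if (apply_scale && !is.null(scl)) coords <- coords * scl
    configs[[rec]] <- landmark_config(coords, id, scale = scl)
    i <- i + 1L
  }
  if (is.character(labels) && length(labels) == 1L)
    labels <- read_labels(labels)
  shape_dataset(configs, labels, scheme_name)
}

#' Write landmark data to a TPS file
#'
#' Emits one record per specimen: an `LM=` line, the coordinate lines, a
#' `SCALE=` line when the configuration carries one, and an `ID=` line.
#' Coordinates are formatted with 17 significant digits, so
#' `read_tps(write_tps(d))` reproduces them bit-exactly.
#'
#' @param dataset a [shape_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path) {
  stopifnot(inherits(dataset, "shape_dataset"))
  out <- character(0L)
  for (cfg in dataset$configs) {
    out <- c(out,
             paste0("LM=", nrow(cfg$coords)),
             paste(num17(cfg$coords[, 1L]), num17(cfg$coords[, 2L])),
             if (!is.null(cfg$scale)) paste0("SCALE=", num17(cfg$scale)),
             paste0("ID=", cfg$specimen_id))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

## shortest decimal representation that round-trips a double
num17 <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  s[bad] <- sprintf("%.17g", x[bad])
  s
}

#' Read a specimen label table
#'
#' The label table is a CSV with a `specimen_id` column and one column per
#' taxonomic level (conventionally
#' `specimen_id,family,subfamily,tribe,genus,subgenus,species`); empty cells
#' mark levels at which a specimen is unlabeled.
#'
#' @param path path to the CSV.
#' @return data.frame with character columns; empty strings become `NA`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"specimen_id" %in% names(df))
    stop("labels CSV must have a specimen_id column")
  df[] <- lapply(df, function(col) { col[!nzchar(col)] <- NA; col })
  df
}

#' Write a specimen label table
#' @param labels data.frame as returned by [read_labels()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, na = "")
  invisible(path)
}
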