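#' Event matrix
#'
#' The container for per-sample cytometry data: a numeric matrix with one
#' row per event and one column per channel, carrying its sample id and a
#' transform tag so that pipelines cannot silently mix intensity scales.
#'
#' @param x Numeric matrix (or data.frame) with unique column names.
#' @param sample_id Sample identifier.
#' @param transform Transform tag, e.g. `"raw"` or `"arcsinh(b=150)"`.
#' @return An object of class `nk_events` (a classed numeric matrix with
#'   `sample_id` and `transform` attributes).
#' @export
event_matrix <- function(x, sample_id = "S1", transform = "raw") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop("event matrix needs unique column (channel) names")
  }
  if (nrow(x) > 0 && any(!is.finite(x))) stop("event matrix has non-finite values")
  structure(x, sample_id = sample_id, transform = transform,
            class = c("nk_events", class(x)))
}

#' @export
print.nk_events <- function(x, ...) {
  cat("<nk_events> sample ", attr(x, "sample_id"), ": ",
      nrow(x), " events x ", ncol(x), " channels [",
      paste(colnames(x), collapse = ", "), "], transform = ",
      attr(x, "transform"), "\n", sep = "")
  invisible(x)
}

#' @rdname event_matrix
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' @rdname event_matrix
#' @export
transform_tag <- function(x) attr(x, "transform")

# keep attributes when subsetting rows
#' @export
`[.nk_events` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    out <- structure(out, sample_id = attr(x, "sample_id"),
                     transform = attr(x, "transform"),
                     class = class(x))
  }
  out
}

#' Write events to disk
#'
#' CSV files get `#` metadata header lines (sample id and transform tag)
#' followed by a regular header + data table. FCS files are written as
#' FCS 3.1, list mode, 32-bit little-endian floats.
#'
#' @param x An [event_matrix()].
#' @param path Output path.
#' @param format `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "nk_events"))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# sample_id=", attr(x, "sample_id")),
                 paste0("# transform=", attr(x, "transform"))), con)
    utils::write.csv(as.data.frame(unclass(x)), con, row.names = FALSE)
  } else {
    .write_fcs(x, path)
  }
  invisible(path)
}

#' Read an event file
#'
#' Reads a headered CSV (as written by [write_events()]) or an FCS 3.0/3.1
#' file. Channel names can be remapped, and the presence of required
#' channels is checked.
#'
#' @param path File path.
#' @param format `"auto"` (by extension/magic), `"csv"` or `"fcs"`.
#' @param channel_map Optional named character vector `c(file_name =
#'   pipeline_name)` applied to column names after reading.
#' @param required Channel names that must be present after mapping;
#'   missing ones raise an error naming them.
#' @param sample_id Override for the sample id (defaults to file metadata or
#'   the file name).
#' @return An [event_matrix()].
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs"),
                        channel_map = NULL, required = NULL,
                        sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 3)
    format <- if (identical(rawToChar(magic), "FCS")) "fcs" else "csv"
  }
  if (format == "csv") {
    lines <- readLines(path, n = 10)
    meta <- grep("^#", lines, value = TRUE)
    get_meta <- function(key, default) {
      hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
      if (length(hit)) sub(paste0("^#\\s*", key, "="), "", hit[1]) else default
    }
    sid <- get_meta("sample_id", basename(path))
    tf <- get_meta("transform", "raw")
    df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
    x <- as.matrix(df)
  } else {
    fcs <- .read_fcs(path)
    x <- fcs$data
    sid <- if (!is.null(fcs$keywords[["$SRC"]])) fcs$keywords[["$SRC"]] else basename(path)
    tf <- if (!is.null(fcs$keywords[["TRANSFORM"]])) fcs$keywords[["TRANSFORM"]] else "raw"
  }
  if (!is.null(channel_map)) {
    hit <- colnames(x) %in% names(channel_map)
    colnames(x)[hit] <- channel_map[colnames(x)[hit]]
  }
  if (!is.null(required)) {
    missing <- setdiff(required, colnames(x))
    if (length(missing)) {
      stop("event file ", basename(path), " lacks required channel(s): ",
           paste(missing, collapse = ", "))
    }
  }
  if (!is.null(sample_id)) sid <- sample_id
  event_matrix(x, sample_id = sid, transform = tf)
}

# ---- minimal FCS 3.1 writer / FCS 3.0-3.1 reader --------------------------
# List-mode, single data segment. The writer emits 32-bit little-endian
# floats; the reader additionally accepts doubles, big-endian order and
# 8/16/32-bit integer data, which covers the files this pipeline exchanges.

.write_fcs <- function(x, path) {
  m <- unclass(x)
  n_par <- ncol(m)
  n_tot <- nrow(m)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot),
    "$SRC" = attr(x, "sample_id"), "TRANSFORM" = attr(x, "transform")
  )
  for (i in seq_len(n_par)) {
    kw[sprintf("$P%dN", i)] <- colnames(m)[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- "262144"
  }
  fmt_off <- function(v) formatC(v, width = 10, flag = "0") # fixed width
  build_text <- function(bd, ed) {
    kw2 <- kw
    kw2["$BEGINDATA"] <- fmt_off(bd)
    kw2["$ENDDATA"] <- fmt_off(ed)
    paste0("/", paste0(names(kw2), "/", kw2, "/", collapse = ""))
  }
  # offsets are 0-based byte positions per the FCS standard; the header
  # occupies bytes 0..57
  text0 <- build_text(0, 0)
  text_begin <- 58L
  text_end <- text_begin + nchar(text0, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n_par * n_tot - 1L
  text <- build_text(data_begin, data_end)
  stopifnot(nchar(text, type = "bytes") == nchar(text0, type = "bytes"))
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

.read_fcs <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  version <- rawToChar(raw[1:6])
  if (!startsWith(version, "FCS")) stop("not an FCS file: ", path)
  off <- function(a, b) {
    v <- suppressWarnings(as.integer(trimws(rawToChar(raw[a:b]))))
    if (is.na(v)) 0L else v
  }
  text_begin <- off(11, 18); text_end <- off(19, 26)
  data_begin <- off(27, 34); data_end <- off(35, 42)
  # offsets in the file are 0-based; R indexing is 1-based
  text <- rawToChar(raw[(text_begin + 1L):(text_end + 1L)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(as.list(trimws(vals)), trimws(keys))
  if (data_begin == 0 && !is.null(kw[["$BEGINDATA"]])) {
    data_begin <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  byteord <- kw[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  data_raw <- raw[(data_begin + 1L):(data_end + 1L)]
  vals <- switch(
    dtype,
    "F" = readBin(data_raw, "numeric", n = n_par * n_tot, size = 4,
                  endian = endian),
    "D" = readBin(data_raw, "numeric", n = n_par * n_tot, size = 8,
                  endian = endian),
    "I" = {
      bits <- as.integer(kw[["$P1B"]])
      readBin(data_raw, "integer", n = n_par * n_tot, size = bits / 8,
              endian = endian, signed = bits > 16)
    },
    stop("unsupported FCS $DATATYPE: ", dtype)
  )
  m <- matrix(vals, ncol = n_par, byrow = TRUE)
  colnames(m) <- vapply(seq_len(n_par), function(i) {
    nm <- kw[[sprintf("$P%dN", i)]]
    if (is.null(nm)) sprintf("P%d", i) else nm
  }, character(1))
  list(data = m, keywords = kw, version = version)
}

#' Transform event intensities
#'
#' Applies a monotone per-channel variance-stabilizing transform and updates
#' the transform tag.
#'
#' @param x An [event_matrix()].
#' @param method `"identity"`, `"arcsinh"` (`asinh(x / cofactor)`) or
#'   `"log10"` (`log10(1 + x / cofactor)`, requires `x > -cofactor`).
#' @param cofactor Positive scale cofactor (default 150, a typical value for
#'   conventional fluorescence cytometry).
#' @param channels Channels to transform (default: all).
#' @return The transformed [event_matrix()].
#' @export
transform_events <- function(x, method = c("identity", "arcsinh", "log10"),
                             cofactor = 150, channels = colnames(x)) {
  method <- match.arg(method)
  stopifnot(inherits(x, "nk_events"))
  if (method == "identity") return(x)
  if (!is.finite(cofactor) || cofactor <= 0) {
    stop("cofactor must be a positive number (monotone transform)")
  }
  bad <- setdiff(channels, colnames(x))
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  out <- unclass(x)
  if (method == "arcsinh") {
    out[, channels] <- asinh(out[, channels] / cofactor)
  } else {
    if (any(out[, channels] <= -cofactor)) {
      stop("log10 transform undefined for values <= -cofactor")
    }
    out[, channels] <- log10(1 + out[, channels] / cofactor)
  }
  tag <- paste0(attr(x, "transform"), "+", method, "(b=", cofactor, ")")
  event_matrix(out, sample_id = attr(x, "sample_id"), transform = tag)
}
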