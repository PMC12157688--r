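#' Read event-level data
#'
#' Reads an FCS 3.0/3.1 file or a delimited event table (header row, one
#' event per row, one marker per column) into an [epp_events] object.
#' Intensities are returned raw; apply [transform_events()] and [censor()]
#' before gating.
#'
#' @param path input file.
#' @param format `"fcs"`, `"csv"`, or `"auto"` (sniff the FCS magic bytes).
#' @return raw [epp_events] with all dimensions marked phenotyping.
#' @export
read_events <- function(path, format = c("auto", "fcs", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 6L)
    format <- if (length(magic) >= 3 && rawToChar(magic[1:3]) == "FCS")
      "fcs" else "csv"
  }
  if (format == "fcs") return(read_fcs(path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          check.names = FALSE, encoding = "UTF-8")
  if (anyDuplicated(names(df)))
    stop("duplicate channel names in ", path)
  if (nrow(df) > 0 && !all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric column(s) in event table ", path)
  m <- if (nrow(df) == 0) matrix(numeric(0), 0, ncol(df),
                                 dimnames = list(NULL, names(df)))
       else as.matrix(df)
  epp_events(m, names(df))
}

#' Write an event table as CSV
#'
#' Comma separated, header row, '.' decimal, UTF-8; full double precision so
#' that a write/read round trip is exact for finite values.
#'
#' @param events an [epp_events].
#' @param path output file.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "epp_events"))
  df <- as.data.frame(events$values, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- minimal FCS 3.0/3.1 support -------------------------------------------
# Header: 6-byte version, offsets at bytes 10-17 (TEXT begin), 18-25 (TEXT
# end), 26-33 (DATA begin), 34-41 (DATA end), ASCII space padded. TEXT is a
# delimited keyword/value list; DATA is a packed array in list mode.

read_fcs <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", n = 58L)
  if (length(hdr) < 58) stop("truncated FCS header in ", path)
  ver <- rawToChar(hdr[1:6])
  if (!ver %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", ver, "' in ", path)
  off <- function(i, j) {
    s <- trimws(rawToChar(hdr[i:j]))
    if (s == "") 0 else as.numeric(s)
  }
  tb <- off(11, 18); te <- off(19, 26)
  db <- off(27, 34); de <- off(35, 42)
  if (tb <= 0 || te <= tb) stop("garbled FCS TEXT segment offsets in ", path)
  seek(con, tb)
  text <- readBin(con, "raw", n = te - tb + 1)
  delim <- rawToChar(text[1])
  parts <- strsplit(rawToChar(text[-1]), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(trimws(parts[seq(1, length(parts), 2)])))
  need <- function(k) {
    if (is.na(kw[k])) stop("FCS TEXT segment missing ", k, " in ", path)
    kw[[k]]
  }
  P <- as.integer(need("$PAR")); N <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (db <= 0) db <- as.numeric(need("$BEGINDATA"))
  if (de <= 0) de <- as.numeric(need("$ENDDATA"))
  bits <- as.integer(kw[paste0("$P", seq_len(P), "B")])
  nm_n <- kw[paste0("$P", seq_len(P), "N")]
  nm_s <- kw[paste0("$P", seq_len(P), "S")]
  nm <- ifelse(is.na(nm_s) | nm_s == "", nm_n, nm_s)
  nm[is.na(nm)] <- paste0("P", which(is.na(nm)))
  if (anyDuplicated(nm)) nm <- make.unique(nm, sep = "_")
  seek(con, db)
  nvals <- N * P
  vals <- switch(dtype,
    F = readBin(con, "numeric", n = nvals, size = 4L, endian = endian),
    D = readBin(con, "numeric", n = nvals, size = 8L, endian = endian),
    I = {
      if (length(unique(bits)) != 1)
        stop("mixed $PnB integer widths are not supported in ", path)
      readBin(con, "integer", n = nvals, size = bits[1] / 8L,
              endian = endian, signed = bits[1] > 16)
    },
    stop("unsupported $DATATYPE '", dtype, "' in ", path))
  if (length(vals) < nvals)
    stop("FCS DATA segment shorter than $TOT*$PAR in ", path)
  m <- matrix(as.double(vals), nrow = N, ncol = P, byrow = TRUE,
              dimnames = list(NULL, nm))
  epp_events(m, nm)
}

#' Write events as a minimal FCS 3.1 file
#'
#' Single dataset, list mode, 32-bit float, little endian. Intended for
#' interchange of synthetic fixtures and round-trip testing.
#'
#' @param events an [epp_events].
#' @param path output file.
#' @export
write_fcs <- function(events, path) {
  stopifnot(inherits(events, "epp_events"))
  v <- events$values
  P <- ncol(v); N <- nrow(v)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", P, "$TOT", N, "$NEXTDATA", "0")
  for (i in seq_len(P))
    kw <- c(kw, paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), "262144",
            paste0("$P", i, "N"), events$marker_names[i])
  build_text <- function(db, de) {
    kw2 <- c(kw, "$BEGINDATA", db, "$ENDDATA", de)
    paste0("/", paste(kw2, collapse = "/"), "/")
  }
  # iterate once: offsets depend on TEXT length, which depends on offsets
  tb <- 58L
  txt <- build_text(0, 0)
  for (i in 1:3) {
    db <- tb + nchar(txt)
    de <- db + 4L * N * P - 1L
    txt <- build_text(db, de)
  }
  db <- tb + nchar(txt); de <- db + 4L * N * P - 1L
  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8s%8s", tb, tb + nchar(txt) - 1L,
                 db, de, "0", "0")
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.vector(t(v)), con, size = 4L, endian = "little")
  invisible(path)
}
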