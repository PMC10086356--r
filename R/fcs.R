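# Minimal FCS 3.1 list-mode writer/reader: 32-bit floats, little-endian,
# one parameter per channel. Covers what is needed to hand slides to
# flow-cytometry software, not the full standard.

#' Export a cell table as an FCS 3.1 file
#'
#' Writes one event per cell with parameters `x_um`, `y_um` and one
#' channel per marker intensity column, as single-precision floats
#' (little-endian, `$DATATYPE/F`, `$MODE/L`). Masked markers are omitted.
#'
#' @param cells non-empty cell table with `x_um`, `y_um` and marker
#'   intensity columns.
#' @param path output file path.
#' @param markers marker columns to export; default: every column of
#'   `cells` named in [default_intensity_model()].
#' @param masked_markers markers to omit.
#' @return `path`, invisibly.
#' @export
export_fcs <- function(cells, path,
                       markers = intersect(names(default_intensity_model()),
                                           names(cells)),
                       masked_markers = character()) {
  if (!nrow(cells)) stop("export_fcs: empty cell table")
  markers <- setdiff(markers, masked_markers)
  params <- c("x_um", "y_um", markers)
  miss <- setdiff(params, names(cells))
  if (length(miss)) stop("export_fcs: missing column(s): ",
                         paste(miss, collapse = ", "))
  n_ev <- nrow(cells); n_par <- length(params)
  dat <- as.matrix(cells[, params, drop = FALSE])
  storage.mode(dat) <- "double"
  data_bytes <- 4L * n_ev * n_par

  build_text <- function(begin_data, end_data) {
    kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
            "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
            "$BEGINDATA", sprintf("%d", begin_data),
            "$ENDDATA", sprintf("%d", end_data),
            "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
            "$NEXTDATA", "0",
            "$TOT", sprintf("%d", n_ev), "$PAR", sprintf("%d", n_par))
    for (i in seq_len(n_par)) {
      rng <- max(1, ceiling(max(dat[, i], na.rm = TRUE)))
      kv <- c(kv, sprintf("$P%dN", i), params[i],
              sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
              sprintf("$P%dR", i), sprintf("%d", rng))
    }
    paste0("/", paste(kv, collapse = "/"), "/")
  }
  header_len <- 58L
  # fixed-point iteration for the offsets embedded in TEXT
  begin_data <- header_len + nchar(build_text(0, 0), type = "bytes")
  for (i in 1:5) {
    end_data <- begin_data + data_bytes - 1L
    txt <- build_text(begin_data, end_data)
    bd <- header_len + nchar(txt, type = "bytes")
    if (bd == begin_data) break
    begin_data <- bd
  }
  text_end <- header_len + nchar(txt, type = "bytes") - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    header_len, text_end, begin_data, end_data, 0L, 0L)
  stopifnot(nchar(header) == 58L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(dat)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read back an FCS file written by [export_fcs()]
#'
#' Minimal reader for list-mode float FCS 3.0/3.1 files.
#'
#' @param path file path.
#' @return List with `data` (events x parameters matrix, named columns)
#'   and `keywords` (named character vector of the TEXT segment).
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  header <- rawToChar(raw[1:58])
  if (!startsWith(header, "FCS3"))
    stop("not an FCS 3.x file: ", path)
  off <- as.integer(trimws(substring(header,
                                     10 + 8 * (0:5) + 1, 10 + 8 * (1:6))))
  text <- rawToChar(raw[(off[1] + 1):(off[2] + 1)])
  delim <- substr(text, 1, 1)
  toks <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  keys <- toks[seq(1, length(toks) - 1, by = 2)]
  vals <- toks[seq(2, length(toks), by = 2)]
  kw <- stats::setNames(vals, keys)
  n_ev <- as.integer(kw[["$TOT"]]); n_par <- as.integer(kw[["$PAR"]])
  begin_data <- as.integer(kw[["$BEGINDATA"]])
  if (kw[["$DATATYPE"]] != "F" || kw[["$MODE"]] != "L")
    stop("read_fcs: only list-mode float data supported")
  endian <- if (kw[["$BYTEORD"]] == "1,2,3,4") "little" else "big"
  vals <- readBin(raw[(begin_data + 1):length(raw)], "numeric",
                  n = n_ev * n_par, size = 4L, endian = endian)
  m <- matrix(vals, nrow = n_ev, ncol = n_par, byrow = TRUE)
  colnames(m) <- vapply(seq_len(n_par),
                        function(i) kw[[sprintf("$P%dN", i)]], character(1))
  list(data = m, keywords = kw)
}
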