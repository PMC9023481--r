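#' @name wfdb
#' @title PhysioNet WFDB record and annotation files
#'
#' @description
#' Minimal reader/writer for the PhysioNet WFDB dialect used by the MITDB,
#' QTDB, LTAF and BUT PDB layouts: text headers (`.hea`), binary signal files
#' in formats 16 (little-endian 16-bit) and 212 (packed 12-bit pairs), and
#' MIT-format annotation files. Samples are returned in physical units using
#' the header's gain and baseline; the sampling frequency comes from the
#' header; time is never rescaled (sample `i` means `(i-1)/fs` seconds).
#' WFDB's native 0-based sample numbering is converted to this package's
#' 1-based indices on read and back on write.
NULL

# MIT annotation codes <-> display symbols (the subset this package needs;
# the mapping is configurable where it matters, see `read_annotations`)
.ann_codes <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L, "~" = 14L,
  "|" = 16L, "s" = 18L, "T" = 19L, "*" = 20L, "D" = 21L, "\"" = 22L,
  "=" = 23L, "p" = 24L, "B" = 25L, "^" = 26L, "t" = 27L, "+" = 28L,
  "u" = 29L, "?" = 30L, "!" = 31L, "[" = 32L, "]" = 33L, "e" = 34L,
  "n" = 35L, "@" = 36L, "x" = 37L, "f" = 38L, "(" = 39L, ")" = 40L
)

ann_symbol_to_code <- function(sym) {
  code <- .ann_codes[sym]
  if (anyNA(code)) stop("unknown annotation symbol(s): ",
                        paste(sym[is.na(code)], collapse = ", "))
  unname(code)
}

ann_code_to_symbol <- function(code) {
  sym <- names(.ann_codes)[match(code, .ann_codes)]
  sym[is.na(sym)] <- "?"
  sym
}

parse_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec_name <- sub("/.*$", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- vector("list", nsig)
  for (k in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1 + k]), "\\s+")[[1]]
    fmt <- sub("x.*$|:.*$|\\+.*$", "", f[2])
    gain_spec <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_spec)))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_spec)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
    } else if (length(f) >= 5) as.numeric(f[5]) else 0
    units <- if (grepl("/", gain_spec)) sub("^.*/", "", gain_spec) else "mV"
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else
      paste0("ch", k)
    sig[[k]] <- list(file = f[1], fmt = fmt, gain = gain,
                     baseline = baseline, units = units, desc = desc)
  }
  list(record = rec_name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_16 <- function(path, nsig) {
  raw <- readBin(path, integer(), n = file.info(path)$size / 2,
                 size = 2, endian = "little", signed = TRUE)
  matrix(raw, ncol = nsig, byrow = TRUE)
}

read_dat_212 <- function(path, nsig) {
  bytes <- readBin(path, integer(), n = file.info(path)$size,
                   size = 1, signed = FALSE)
  nb <- length(bytes) - length(bytes) %% 3
  b <- matrix(bytes[seq_len(nb)], nrow = 3)
  s1 <- b[1, ] + bitwAnd(b[2, ], 0x0FL) * 256L
  s2 <- b[3, ] + bitwAnd(bitwShiftR(b[2, ], 4L), 0x0FL) * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  v <- as.vector(rbind(s1, s2))
  matrix(v[seq_len(length(v) - length(v) %% nsig)], ncol = nsig, byrow = TRUE)
}

#' Read one channel of a WFDB record
#'
#' @param path record path without extension (e.g. `"data/100"`); `.hea` and
#'   the signal file(s) it names must exist next to it
#' @param channel channel to extract, 1-based
#' @return an [ecg_record()] in physical units
#' @export
read_wfdb <- function(path, channel = 1L) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea)
  hdr <- parse_header(hea)
  if (channel < 1 || channel > hdr$nsig) {
    stop("channel ", channel, " out of range (record has ", hdr$nsig, ")")
  }
  sig <- hdr$signals[[channel]]
  dat <- file.path(dirname(hea), sig$file)
  if (!file.exists(dat)) stop("signal file not found: ", dat)
  adc <- switch(sig$fmt,
    "16" = read_dat_16(dat, hdr$nsig),
    "212" = read_dat_212(dat, hdr$nsig),
    stop("unsupported WFDB signal format: ", sig$fmt)
  )
  if (!is.na(hdr$nsamp) && nrow(adc) > hdr$nsamp) {
    adc <- adc[seq_len(hdr$nsamp), , drop = FALSE]
  }
  phys <- (adc[, channel] - sig$baseline) / sig$gain
  ecg_record(phys, hdr$fs, lead = sig$desc, record_id = hdr$record)
}

#' Write a WFDB record (format 16)
#'
#' @param samples numeric matrix (columns = channels) or vector, physical units
#' @param fs sampling frequency, Hz
#' @param path record path without extension
#' @param gain ADC gain in adu per physical unit
#' @param leads channel labels
#' @return `path`, invisibly
#' @export
write_wfdb <- function(samples, fs, path, gain = 200, leads = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  nsig <- ncol(samples)
  n <- nrow(samples)
  leads <- leads %||% paste0("ch", seq_len(nsig))
  rec <- basename(path)
  adc <- round(samples * gain)
  adc <- pmax(pmin(adc, 32767), -32768)
  dat_name <- paste0(rec, ".dat")
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  close(con)
  cks <- vapply(seq_len(nsig),
                function(k) as.integer(sum(adc[, k]) %% 65536), integer(1))
  hdr <- c(
    sprintf("%s %d %g %d", rec, nsig, fs, n),
    vapply(seq_len(nsig), function(k) {
      sprintf("%s 16 %g(0)/mV 16 0 %d %d 0 %s",
              dat_name, gain, as.integer(adc[1, k]), cks[k], leads[k])
    }, character(1))
  )
  writeLines(hdr, paste0(path, ".hea"))
  invisible(path)
}

read_mit_ann <- function(path) {
  bytes <- readBin(path, integer(), n = file.info(path)$size,
                   size = 1, signed = FALSE)
  n <- length(bytes) - length(bytes) %% 2
  samp <- integer(0)
  code <- integer(0)
  t_cur <- 0
  i <- 1L
  while (i + 1L <= n) {
    lo <- bytes[i]; hi <- bytes[i + 1L]
    i <- i + 2L
    a <- lo + hi * 256L
    typ <- a %/% 1024L
    cnt <- a %% 1024L
    if (typ == 0L && cnt == 0L) break         # EOF
    if (typ == 59L) {                         # SKIP: 4-byte interval follows
      if (cnt == 0L) {
        hw <- bytes[i] + bytes[i + 1L] * 256L
        lw <- bytes[i + 2L] + bytes[i + 3L] * 256L
        i <- i + 4L
        iv <- hw * 65536 + lw
        if (iv >= 2^31) iv <- iv - 2^32
        t_cur <- t_cur + iv
      }
      next
    }
    if (typ %in% c(60L, 61L, 62L, 63L)) {     # NUM/SUB/CHN/AUX: no time
      if (typ == 63L) i <- i + cnt + cnt %% 2L
      next
    }
    t_cur <- t_cur + cnt
    samp <- c(samp, t_cur)
    code <- c(code, typ)
  }
  data.frame(sample = samp + 1L,              # to 1-based
             symbol = ann_code_to_symbol(code),
             stringsAsFactors = FALSE)
}

write_mit_ann <- function(df, path) {
  stopifnot(all(c("sample", "symbol") %in% names(df)))
  df <- df[order(df$sample), , drop = FALSE]
  code <- ann_symbol_to_code(df$symbol)
  samp0 <- as.integer(df$sample) - 1L         # to WFDB 0-based
  if (any(samp0 < 0)) stop("sample indices must be >= 1")
  out <- integer(0)
  prev <- 0L
  for (k in seq_along(samp0)) {
    delta <- samp0[k] - prev
    prev <- samp0[k]
    if (delta < 0) stop("annotations must be sorted")
    if (delta >= 1024L) {
      out <- c(out, 59L * 1024L,                              # SKIP
               delta %/% 65536L, delta %% 65536L)             # high, low
      delta <- 0L
    }
    out <- c(out, code[k] * 1024L + delta)
  }
  out <- c(out, 0L)                                           # EOF
  con <- file(path, "wb")
  lo <- out %% 256L
  hi <- out %/% 256L
  writeBin(as.integer(rbind(lo, hi)), con, size = 1)
  close(con)
  invisible(path)
}

#' Read wave annotations from a WFDB annotation file
#'
#' Reads an MIT-format annotation file and extracts peak indices by symbol.
#' Which symbol means "P peak" differs between databases, so the mapping is an
#' argument; the default follows the BUT PDB / MIT PDB convention (`"p"` for P
#' peaks, `"t"` for T peaks, `"N"` for beat/R labels).
#'
#' @param path annotation file path
#' @param symbols named character vector mapping the roles `p`, `t`, `r` to
#'   annotation symbols; set a role to `NA` to skip it. Alternatively a plain
#'   character vector of symbols can be passed as `filter` semantics via the
#'   `p` role.
#' @param source label for the returned annotations
#' @return a [wave_annotations()]
#' @export
read_annotations <- function(path, symbols = c(p = "p", t = "t", r = "N"),
                             source = "reference") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read_mit_ann(path)
  pick <- function(role) {
    sym <- symbols[[role]]
    if (is.null(sym) || is.na(sym)) return(integer(0))
    sort(unique(df$sample[df$symbol %in% sym]))
  }
  wave_annotations(p_peaks = pick("p"), t_peaks = pick("t"),
                   r_peaks = pick("r"), source = source)
}

#' Write wave annotations to a WFDB annotation file
#'
#' Inverse of [read_annotations()] with the same default symbol mapping;
#' read-back returns the identical (index, symbol) pairs.
#'
#' @param ann a [wave_annotations()]
#' @param path output file path
#' @param symbols role-to-symbol mapping, as in [read_annotations()]
#' @param sig_len optional signal length; indices beyond it are rejected
#' @return `path`, invisibly
#' @export
write_annotations <- function(ann, path, symbols = c(p = "p", t = "t", r = "N"),
                              sig_len = NULL) {
  stopifnot(inherits(ann, "wave_annotations"))
  if (!is.null(sig_len)) {
    all_idx <- c(ann$p_peaks, ann$t_peaks, ann$r_peaks)
    if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > sig_len)) {
      stop("annotation indices outside [1, sig_len]")
    }
  }
  one <- function(idx, sym) {
    if (!length(idx) || is.null(sym) || is.na(sym)) {
      return(data.frame(sample = integer(0), symbol = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(sample = idx, symbol = rep(sym, length(idx)),
               stringsAsFactors = FALSE)
  }
  df <- rbind(one(ann$p_peaks, symbols[["p"]]),
              one(ann$t_peaks, symbols[["t"]]),
              one(ann$r_peaks, symbols[["r"]]))
  write_mit_ann(df, path)
}

#' Read all raw annotations as a data frame
#'
#' Lower-level access when the symbol mapping is not known in advance.
#'
#' @param path annotation file path
#' @return data frame with `sample` (1-based) and `symbol`
#' @export
read_annotations_raw <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  read_mit_ann(path)
}
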