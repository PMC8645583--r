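# Minimal EDF (European Data Format) reader/writer.
#
# Signals are stored as 16-bit little-endian integers mapped linearly from a
# per-signal physical range.  We always write a symmetric physical range in
# microvolts, so gain = phys_max / 32767 and the quantization step is one
# digital unit.  When the sample count is a whole number of seconds the file
# uses 1-s data records; otherwise the whole signal goes into a single
# record (header fields are plain ASCII, so a fractional record duration is
# representable).

edf_digital_max <- 32767L

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x, call. = FALSE)
  formatC(x, width = -width)
}

# numeric -> ASCII decimal that fits an 8-char EDF field and parses back
edf_num8 <- function(x) {
  for (digits in 7:1) {
    s <- trimws(formatC(signif(x, digits), format = "g", digits = digits))
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format ", x, " into an 8-char EDF field", call. = FALSE)
}

write_edf <- function(data, fs, channels, path, phys_max = NULL) {
  ns <- nrow(data)
  n <- ncol(data)
  data_max <- max(abs(data))
  # the range is symmetric, so the positive bound must format into 7 chars
  # (leaving room for the minus sign of the physical minimum)
  fmt7 <- function(x) {
    for (digits in 6:1) {
      s <- trimws(formatC(signif(x, digits), format = "g", digits = digits))
      if (nchar(s) <= 7) return(s)
    }
    stop("cannot format ", x, " into an EDF range field", call. = FALSE)
  }
  if (is.null(phys_max)) {
    # round the range up so the formatted header value still covers the data
    pm_str <- fmt7(if (data_max == 0) 1 else data_max * (1 + 1e-5))
    while (as.numeric(pm_str) < data_max) {
      pm_str <- fmt7(as.numeric(pm_str) * 1.001)
    }
  } else {
    pm_str <- fmt7(phys_max)
    if (data_max > as.numeric(pm_str)) {
      stop("signal exceeds the representable physical range (",
           format(data_max), " > ", pm_str, " uV)", call. = FALSE)
    }
  }
  pm <- as.numeric(pm_str)

  if (n %% fs == 0 && fs == round(fs)) {
    record_dur <- 1
    spr <- as.integer(fs)
  } else {
    record_dur <- n / fs
    spr <- n
  }
  n_rec <- n %/% spr

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)

  wr("0", 8)                       # version
  wr("local patient", 80)
  wr("local recording", 80)
  wr("01.01.00", 8)                # start date
  wr("00.00.00", 8)                # start time
  wr(256L * (ns + 1L), 8)          # header length in bytes
  wr("", 44)                       # reserved
  wr(n_rec, 8)
  wr(edf_num8(record_dur), 8)
  wr(ns, 4)

  for (lab in channels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)               # transducer
  for (i in seq_len(ns)) wr("uV", 8)              # physical dimension
  for (i in seq_len(ns)) wr(paste0("-", pm_str), 8)  # physical minimum
  for (i in seq_len(ns)) wr(pm_str, 8)               # physical maximum
  for (i in seq_len(ns)) wr(-edf_digital_max, 8)  # digital minimum
  for (i in seq_len(ns)) wr(edf_digital_max, 8)   # digital maximum
  for (i in seq_len(ns)) wr("", 80)               # prefiltering
  for (i in seq_len(ns)) wr(spr, 8)               # samples per record
  for (i in seq_len(ns)) wr("", 32)               # reserved

  gain <- pm / edf_digital_max
  dig <- matrix(as.integer(round(data / gain)), nrow = ns)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))

  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_len <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  channels <- fld(16)
  fld(80)
  fld(8)                                   # physical dimension
  pmin <- as.numeric(fld(8))
  pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  stopifnot(header_len == 256L * (ns + 1L))

  if (length(unique(spr)) != 1) {
    stop("EDF file mixes sampling rates across channels", call. = FALSE)
  }
  spr1 <- spr[1]
  fs <- spr1 / record_dur

  raw <- readBin(con, "integer", n = n_rec * ns * spr1, size = 2L,
                 signed = TRUE, endian = "little")
  # records are stored as [signal1 block, signal2 block, ...] per record
  dim(raw) <- c(spr1, ns, n_rec)
  data <- matrix(aperm(raw, c(2, 1, 3)), nrow = ns)

  gain <- (pmax - pmin) / (dmax - dmin)
  offset <- pmin - gain * dmin
  data <- data * gain + offset
  list(data = data, fs = fs, channels = channels,
       quant_step = gain)
}
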