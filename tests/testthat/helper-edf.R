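# Minimal EDF writer used only to build fixtures at test time.  Follows
# the EDF field layout directly; independent of the package reader.
write_edf_fixture <- function(path, data, fs, labels, record_dur = 1,
                              phys_min = -1000, phys_max = 1000) {
  ns <- ncol(data)
  spr <- as.integer(fs * record_dur)       # samples per record per signal
  n_records <- nrow(data) %/% spr
  stopifnot(n_records >= 1)
  pad <- function(s, w) {
    s <- substr(as.character(s), 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("subjX", 80), pad("recX", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 + ns * 256, 8), pad("", 44),
                pad(n_records, 8), pad(format(record_dur), 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  f <- function(vals, w) writeChar(paste0(sapply(vals, pad, w = w),
                                          collapse = ""), con, eos = NULL)
  f(labels, 16); f(rep("", ns), 80); f(rep("uV", ns), 8)
  f(rep(format(phys_min), ns), 8); f(rep(format(phys_max), ns), 8)
  f(rep("-32768", ns), 8); f(rep("32767", ns), 8)
  f(rep("", ns), 80); f(rep(spr, ns), 8); f(rep("", ns), 32)
  gain <- (phys_max - phys_min) / (32767 - (-32768))
  dig <- round((data - phys_min) / gain + (-32768))
  dig <- pmin(pmax(dig, -32768), 32767)
  for (r in seq_len(n_records)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(ns))
      writeBin(as.integer(dig[rows, j]), con, size = 2L, endian = "little")
  }
  invisible(path)
}
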