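# Minimal baseline-TIFF support: uncompressed grayscale 8/16-bit,
# little-endian, multi-IFD (one IFD per frame), single strip per frame,
# optional ImageDescription on the first frame.  No R TIFF package is
# part of the supported stack, so the package carries this small
# self-contained reader/writer; it covers exactly the baseline subset
# that microwell stacks use and rejects everything else loudly.

raw_u16 <- function(v) {
  v <- as.numeric(v)
  as.raw(c(rbind(v %% 256, v %/% 256)))
}

raw_u32 <- function(v) {
  v <- as.numeric(v)
  as.raw(c(rbind(v %% 256, (v %/% 256) %% 256,
                 (v %/% 65536) %% 256, v %/% 16777216)))
}

rd_u16 <- function(buf, off, n = 1) {
  b <- as.integer(buf[off + seq_len(2 * n)])
  b[seq(1, 2 * n, 2)] + 256 * b[seq(2, 2 * n, 2)]
}

rd_u32 <- function(buf, off, n = 1) {
  b <- as.integer(buf[off + seq_len(4 * n)])
  i <- seq(1, 4 * n, 4)
  b[i] + 256 * b[i + 1] + 65536 * b[i + 2] + 16777216 * b[i + 3]
}

# One IFD as raw bytes.  `data_off` is the absolute strip offset,
# `desc_off`/`desc_len` the description block (0 = none), `next_off` the
# next IFD offset (0 terminates the chain).
tiff_ifd_raw <- function(h, w, bits, data_off, desc_off, desc_len, next_off) {
  entry <- function(tag, type, count, value) {
    val <- if (type == 3) c(raw_u16(value), raw_u16(0)) else raw_u32(value)
    c(raw_u16(tag), raw_u16(type), raw_u32(count), val)
  }
  entries <- list(entry(256, 4, 1, w),            # ImageWidth
                  entry(257, 4, 1, h),            # ImageLength
                  entry(258, 3, 1, bits),         # BitsPerSample
                  entry(259, 3, 1, 1),            # Compression = none
                  entry(262, 3, 1, 1))            # Photometric = BlackIsZero
  if (desc_len > 0)
    entries <- c(entries, list(entry(270, 2, desc_len, desc_off)))
  entries <- c(entries,
               list(entry(273, 4, 1, data_off),   # StripOffsets
                    entry(277, 3, 1, 1),          # SamplesPerPixel
                    entry(278, 4, 1, h),          # RowsPerStrip
                    entry(279, 4, 1, h * w * bits / 8),  # StripByteCounts
                    entry(339, 3, 1, 1)))         # SampleFormat = unsigned
  c(raw_u16(length(entries)), do.call(c, entries), raw_u32(next_off))
}

# Write a list of integer-valued matrices as a multi-frame grayscale TIFF.
tiff_write <- function(frames, path, bits = 16L, description = NULL) {
  check(length(frames) >= 1, "no frames to write")
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  maxval <- 2^bits - 1
  frame_raw <- lapply(frames, function(f) {
    check(nrow(f) == h && ncol(f) == w, "frames differ in size")
    v <- as.vector(t(unclass(f)))                 # TIFF is row-major
    check(all(v >= 0 & v <= maxval), "pixel values exceed bit depth")
    if (bits == 16) raw_u16(v) else as.raw(v)
  })
  nbytes <- h * w * bits / 8
  nfr <- length(frames)
  desc_raw <- raw(0)
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0))
    if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
  }
  data_off <- 8 + nbytes * (seq_len(nfr) - 1)
  desc_off <- 8 + nbytes * nfr
  ifd0_off <- desc_off + length(desc_raw)
  ifd_len <- function(i) {
    n_entries <- 10 + (i == 1 && length(desc_raw) > 0)
    2 + 12 * n_entries + 4
  }
  ifd_off <- ifd0_off + cumsum(c(0, vapply(seq_len(nfr - 1), ifd_len,
                                           numeric(1))))
  ifds <- lapply(seq_len(nfr), function(i) {
    tiff_ifd_raw(h, w, bits, data_off[i],
                 desc_off = if (i == 1 && length(desc_raw) > 0) desc_off else 0,
                 desc_len = if (i == 1) length(desc_raw) else 0,
                 next_off = if (i < nfr) ifd_off[i + 1] else 0)
  })
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), raw_u16(42), raw_u32(ifd0_off)), con)
  for (fr in frame_raw) writeBin(fr, con)
  if (length(desc_raw) > 0) writeBin(desc_raw, con)
  for (ifd in ifds) writeBin(ifd, con)
  invisible(path)
}

# Read a baseline grayscale TIFF.  Returns list(frames = list of matrices,
# description = chr or NULL).
tiff_read <- function(path) {
  buf <- readBin(path, "raw", file.size(path))
  check(length(buf) >= 8, "not a TIFF file (truncated header)")
  byte_order <- rawToChar(buf[1:2])
  check(byte_order != "MM",
        "big-endian TIFF not supported by the minimal reader")
  check(byte_order == "II" && rd_u16(buf, 2) == 42, "not a TIFF file")
  ifd_off <- rd_u32(buf, 4)
  frames <- list()
  description <- NULL
  while (ifd_off != 0) {
    n_entries <- rd_u16(buf, ifd_off)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2 + 12 * (e - 1)
      tag <- rd_u16(buf, base)
      type <- rd_u16(buf, base + 2)
      count <- rd_u32(buf, base + 4)
      val <- if (type == 3 && count <= 2) {
        rd_u16(buf, base + 8, count)
      } else if (type == 4 && count == 1) {
        rd_u32(buf, base + 8)
      } else {
        off <- rd_u32(buf, base + 8)
        if (type == 3) rd_u16(buf, off, count)
        else if (type == 4) rd_u32(buf, off, count)
        else if (type == 2) rawToChar(buf[off + seq_len(count - 1)])
        else off
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    check(!is.null(w) && !is.null(h), "IFD missing image dimensions")
    check(g(277, 1) == 1,
          "multi-sample (RGB) TIFF rejected: pipeline expects grayscale")
    bits <- g(258, 1)
    check(bits %in% c(8, 16), "only 8- and 16-bit grayscale supported")
    check(g(259, 1) == 1, "compressed TIFF not supported")
    offs <- g(273); cnts <- g(279)
    check(!is.null(offs) && !is.null(cnts), "IFD missing strip layout")
    datab <- do.call(c, lapply(seq_along(offs), function(s)
      buf[offs[s] + seq_len(cnts[s])]))
    v <- if (bits == 16) rd_u16(datab, 0, length(datab) / 2)
         else as.integer(datab)
    frames[[length(frames) + 1]] <- matrix(v, nrow = h, byrow = TRUE)
    if (is.null(description) && !is.null(g(270)))
      description <- g(270)
    ifd_off <- rd_u32(buf, ifd_off + 2 + 12 * n_entries)
  }
  list(frames = frames, description = description)
}
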