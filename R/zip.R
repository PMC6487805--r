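# Minimal ZIP (PKZIP) writer producing standard deflate entries.
#
# Each entry's raw deflate stream and CRC-32 are obtained from the gzip
# container written by gzfile(): a gzip member is a fixed 10-byte header
# (zlib writes FLG = 0 and MTIME = 0, so output is deterministic), the raw
# deflate stream, then CRC-32 and size (4 bytes each, little-endian).
# Archives are readable by utils::unzip (internal method) and any standard
# unzip tool.

le_bytes <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

zip_entry_parts <- function(data) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- gzfile(tf, "wb")
  writeBin(data, con)
  close(con)
  gz <- readBin(tf, "raw", n = file.info(tf)$size)
  n <- length(gz)
  stopifnot(n >= 18, gz[1] == as.raw(0x1f), gz[2] == as.raw(0x8b),
            gz[4] == as.raw(0x00))  # FLG = 0: fixed 10-byte header
  list(deflate = gz[11:(n - 8)],
       crc = gz[(n - 7):(n - 4)],
       size = length(data))
}

write_zip_archive <- function(zip_path, dir, root = basename(dir)) {
  files <- list.files(dir, recursive = TRUE)
  if (!length(files)) tm_abort("nothing to archive", "write")
  con <- file(zip_path, "wb")
  on.exit(close(con))
  central <- list()
  offset <- 0L
  for (f in files) {
    data <- readBin(file.path(dir, f), "raw",
                    n = file.info(file.path(dir, f))$size)
    p <- zip_entry_parts(data)
    name <- charToRaw(paste(root, f, sep = "/"))
    # local file header: deflate (method 8), no extra field
    local <- c(le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2),
               le_bytes(8, 2), le_bytes(0, 2), le_bytes(0x21, 2),
               p$crc, le_bytes(length(p$deflate), 4), le_bytes(p$size, 4),
               le_bytes(length(name), 2), le_bytes(0, 2), name)
    writeBin(local, con)
    writeBin(p$deflate, con)
    central[[f]] <- list(
      header = c(le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2),
                 le_bytes(0, 2), le_bytes(8, 2), le_bytes(0, 2),
                 le_bytes(0x21, 2), p$crc, le_bytes(length(p$deflate), 4),
                 le_bytes(p$size, 4), le_bytes(length(name), 2),
                 le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
                 le_bytes(0, 2), le_bytes(0, 4), le_bytes(offset, 4), name))
    offset <- offset + length(local) + length(p$deflate)
  }
  cd <- unlist(lapply(central, `[[`, "header"))
  writeBin(cd, con)
  end <- c(le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
           le_bytes(length(files), 2), le_bytes(length(files), 2),
           le_bytes(length(cd), 4), le_bytes(offset, 4), le_bytes(0, 2))
  writeBin(end, con)
  invisible(zip_path)
}
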