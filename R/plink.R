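# PLINK 1 binary genotype triple (.bed/.bim/.fam), SNP-major layout.
# Two bits per call, samples packed 4 per byte low-bits-first:
#   00 = homozygous A1 (dosage 2), 01 = missing, 10 = het, 11 = homozygous A2.

.plink_prefix <- function(path) sub("\\.(bed|bim|fam)$", "", path)

read_plink <- function(path) {
  prefix <- .plink_prefix(path)
  files <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- files[!file.exists(files)]
  if (length(miss)) .stop_fmt("missing PLINK file(s): %s",
                              paste(miss, collapse = ", "))
  fam <- utils::read.table(files[3L], colClasses = "character")
  bim <- utils::read.table(files[2L], colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  ids <- fam[[2L]]
  variants <- data.frame(id = bim[[2L]], chrom = bim[[1L]],
                         pos = as.integer(bim[[4L]]),
                         a1 = bim[[5L]], a2 = bim[[6L]],
                         stringsAsFactors = FALSE)
  raw <- readBin(files[1L], "raw", n = file.size(files[1L]))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    .stop_fmt("%s: not a PLINK .bed file (bad magic bytes)", files[1L])
  }
  if (raw[3L] != as.raw(0x01)) {
    .stop_fmt("%s: only SNP-major .bed files are supported", files[1L])
  }
  bpv <- ceiling(n / 4)        # bytes per variant
  if (length(raw) - 3L != bpv * m) {
    .stop_fmt(".bed payload (%d bytes) does not match %d samples x %d variants",
              length(raw) - 3L, n, m)
  }
  ints <- as.integer(raw[-(1:3)])
  # unpack the four 2-bit fields of every byte
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, ints %/% 64L)
  codes <- matrix(as.vector(codes), nrow = 4L * bpv)[seq_len(n), , drop = FALSE]
  lut <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  d <- matrix(lut[codes + 1L], n, m, dimnames = list(ids, variants$id))
  geno_matrix(d, variants)
}

write_plink <- function(G, prefix) {
  d <- G$dosages
  n <- nrow(d); m <- ncol(d)
  v <- G$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0L, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(rownames(d), rownames(d), 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  code <- matrix(3L, n, m)            # hom A2
  code[d == 2] <- 0L
  code[d == 1] <- 2L
  code[is.na(d)] <- 1L
  bpv <- ceiling(n / 4)
  pad <- matrix(0L, 4L * bpv - n, m)  # unused trailing fields are zero
  code <- rbind(code, pad)
  q <- array(code, c(4L, bpv, m))
  bytes <- q[1L, , ] + 4L * q[2L, , ] + 16L * q[3L, , ] + 64L * q[4L, , ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
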