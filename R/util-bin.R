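# Little-endian binary helpers shared by the chunk codecs and the native
# HDF5/TIFF readers and writers. Offsets and lengths are carried as doubles
# (exact to 2^53, far past any file size handled here).

u8 <- function(x) as.raw(x)

u16le <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, x %/% 256 %% 256))
}

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256,
               x %/% 16777216 %% 256))
}

u64le <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 4294967296
  hi <- x %/% 4294967296
  c_interleave <- rbind(lo %% 256, lo %/% 256 %% 256, lo %/% 65536 %% 256,
                        lo %/% 16777216 %% 256,
                        hi %% 256, hi %/% 256 %% 256, hi %/% 65536 %% 256,
                        hi %/% 16777216 %% 256)
  as.raw(c_interleave)
}

# HDF5 "undefined address": all-ones
UNDEF64 <- as.raw(rep(255, 8))

rd_uint <- function(raw, offset, nbytes) {
  # offset is 0-based; little-endian unsigned integer as double
  b <- as.numeric(raw[(offset + 1):(offset + nbytes)])
  sum(b * 256^(seq_len(nbytes) - 1))
}

is_undef <- function(raw, offset, nbytes = 8) {
  all(raw[(offset + 1):(offset + nbytes)] == as.raw(255))
}

pad8 <- function(r) {
  n <- length(r)
  if (n %% 8 == 0) r else c(r, raw(8 - n %% 8))
}

# Sample codec: integer vector (values in [0, 2^(8b)-1]) <-> raw, LE.
encode_samples <- function(values, bytes_per_sample) {
  if (bytes_per_sample == 1L) {
    as.raw(values)
  } else {
    v <- as.integer(values)
    v <- ifelse(v > 32767L, v - 65536L, v)  # writeBin wants signed 16-bit
    writeBin(v, raw(), size = 2L, endian = "little")
  }
}

decode_samples <- function(raw, bytes_per_sample) {
  if (bytes_per_sample == 1L) {
    as.integer(raw)
  } else {
    readBin(raw, "integer", n = length(raw) / 2L, size = 2L,
            signed = FALSE, endian = "little")
  }
}

# Dense 5D arrays use R dim (x, y, z, c, t): column-major in R, which
# serializes to C order over (t, c, z, y, x) with x fastest -- the chunk
# byte order of the NGFF layout.
array_dim <- function(sizes_tczyx) unname(rev(as.integer(sizes_tczyx)))

serialize_array <- function(arr, bytes_per_sample) {
  encode_samples(as.vector(arr), bytes_per_sample)
}

deserialize_array <- function(raw, sizes_tczyx, bytes_per_sample) {
  array(decode_samples(raw, bytes_per_sample), dim = array_dim(sizes_tczyx))
}
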