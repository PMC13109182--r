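# Minimal baseline TIFF codec: uncompressed grayscale, 8/16-bit unsigned or
# 32-bit float, one sample per pixel, multi-page. Enough to exchange
# single- or two-channel confocal frames and masks with Fiji/tifffile; not
# a general TIFF implementation (no compression, no tiles, no palettes).

#' Write matrices as a grayscale TIFF
#'
#' @param images A numeric matrix or list of matrices (pages). All pages
#'   share one sample type.
#' @param path Output file.
#' @param bits 8 or 16 for unsigned integers (values are rounded and
#'   clipped to range), or `"float"` for 32-bit IEEE floats.
#' @param pixel_size_nm Optional physical pixel size, stored in the TIFF
#'   resolution tags (pixels per centimetre) and recovered by
#'   [read_tiff()].
#' @return `path`, invisibly.
#' @export
write_tiff <- function(images, path, bits = 16, pixel_size_nm = NULL) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L, all(vapply(images, is.matrix, logical(1))))
  is_float <- identical(bits, "float")
  if (!is_float && !bits %in% c(8, 16)) stop("bits must be 8, 16 or 'float'")
  bps <- if (is_float) 32L else as.integer(bits)
  fmt <- if (is_float) 3L else 1L

  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L) # header; first IFD patched in

  pos <- 8L # running file offset
  ifd_offsets <- integer(length(images))
  n_rat <- if (is.null(pixel_size_nm)) 0L else 2L
  for (p in seq_along(images)) {
    m <- images[[p]]
    nr <- nrow(m); nc <- ncol(m)
    nbytes <- nr * nc * (bps %/% 8L)
    data_off <- pos
    # pixel data, row-major
    v <- as.vector(t(m))
    if (is_float) {
      writeBin(as.double(v), con, size = 4, endian = "little")
    } else if (bps == 8L) {
      writeBin(as.raw(pmin(pmax(round(v), 0), 255)), con)
    } else {
      writeBin(as.integer(pmin(pmax(round(v), 0), 65535)), con,
               size = 2, endian = "little")
    }
    pos <- pos + nbytes
    ifd_offsets[p] <- pos
    tags <- list( # tag, type, count, value (inline scalar or offset)
      c(256L, 4L, 1L, nc), c(257L, 4L, 1L, nr), c(258L, 3L, 1L, bps),
      c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L), c(273L, 4L, 1L, data_off),
      c(277L, 3L, 1L, 1L), c(278L, 4L, 1L, nr), c(279L, 4L, 1L, nbytes))
    n_entries <- length(tags) + n_rat + (if (n_rat) 1L else 0L) + 1L # +296,+339
    ifd_size <- 2L + 12L * n_entries + 4L
    if (n_rat) {
      rat_off <- pos + ifd_size
      tags <- c(tags, list(c(282L, 5L, 1L, rat_off),
                           c(283L, 5L, 1L, rat_off + 8L),
                           c(296L, 3L, 1L, 3L)))
    }
    tags <- c(tags, list(c(339L, 3L, 1L, fmt)))
    tags <- tags[order(vapply(tags, `[`, integer(1), 1L))]
    w2(length(tags))
    for (tg in tags) {
      w2(tg[1]); w2(tg[2]); w4(tg[3])
      if (tg[2] == 3L) { w2(tg[4]); w2(0L) } else w4(tg[4])
    }
    next_ifd <- if (p < length(images)) {
      pos + ifd_size + n_rat * 8L +
        0L # next page's data starts right after this IFD block
    } else 0L
    # next IFD offset is the next page's IFD, which we don't know yet;
    # instead we chain by writing the next page's data immediately after,
    # so record a placeholder and patch at the end.
    w4(0L)
    pos <- pos + ifd_size
    if (n_rat) {
      px_per_cm <- 1e7 / pixel_size_nm
      w4(round(px_per_cm * 1000)); w4(1000L) # X
      w4(round(px_per_cm * 1000)); w4(1000L) # Y
      pos <- pos + 16L
    }
  }
  buf <- rawConnectionValue(con)
  # patch IFD chain: header -> IFD1 -> IFD2 -> ... -> 0
  patch_u32 <- function(buf, off0, value) { # off0: 0-based byte offset
    b <- packBits(intToBits(as.integer(value)), "raw")
    buf[off0 + 1:4] <- b[1:4]
    buf
  }
  buf <- patch_u32(buf, 4L, ifd_offsets[1])
  for (p in seq_along(images)) {
    n_entries <- rd_u16(buf, ifd_offsets[p], TRUE)
    link_off <- ifd_offsets[p] + 2L + 12L * n_entries
    nxt <- if (p < length(images)) ifd_offsets[p + 1] else 0L
    buf <- patch_u32(buf, link_off, nxt)
  }
  writeBin(buf, path)
  invisible(path)
}

# raw-buffer readers; off is 0-based
rd_u16 <- function(buf, off, little) {
  b <- as.integer(buf[off + 1:2])
  if (little) b[1] + 256L * b[2] else b[2] + 256L * b[1]
}
rd_u32 <- function(buf, off, little) {
  b <- as.numeric(buf[off + 1:4])
  if (!little) b <- rev(b)
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

#' Read a grayscale TIFF
#'
#' Reads uncompressed 8/16-bit unsigned or 32-bit float grayscale TIFFs
#' (single strip or multi-strip, little- or big-endian, multi-page).
#'
#' @param path TIFF file.
#' @return List of numeric matrices, one per page, with attribute
#'   `pixel_size_nm` when resolution tags are present.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  buf <- readBin(path, "raw", file.size(path))
  order_tag <- rawToChar(buf[1:2])
  little <- order_tag == "II"
  if (!order_tag %in% c("II", "MM") || rd_u16(buf, 2L, little) != 42L) {
    stop("not a TIFF file")
  }
  endian <- if (little) "little" else "big"
  ifd_off <- rd_u32(buf, 4L, little)
  pages <- list()
  pixel_size_nm <- NULL
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)
  while (ifd_off != 0) {
    n <- rd_u16(buf, ifd_off, little)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd_off + 2L + 12L * (k - 1L)
      tag <- rd_u16(buf, e, little)
      typ <- rd_u16(buf, e + 2L, little)
      cnt <- rd_u32(buf, e + 4L, little)
      sz <- type_size[[as.character(typ)]]
      voff <- if (sz * cnt <= 4) e + 8L else rd_u32(buf, e + 8L, little)
      vals <- if (typ == 3L) {
        vapply(seq_len(cnt), function(i) rd_u16(buf, voff + 2L * (i - 1L),
                                                little), numeric(1))
      } else if (typ %in% c(4L, 5L)) {
        # rationals read as numerator/denominator pairs of LONGs
        cnt2 <- if (typ == 5L) 2L * cnt else cnt
        vapply(seq_len(cnt2), function(i) rd_u32(buf, voff + 4L * (i - 1L),
                                                 little), numeric(1))
      } else {
        as.numeric(buf[voff + seq_len(cnt)])
      }
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop(sprintf("missing TIFF tag %d", tag))
        default
      } else v
    }
    if (need(259, 1)[1] != 1) stop("compressed TIFF not supported")
    if (need(277, 1)[1] != 1) stop("only single-sample TIFF supported")
    nc <- need(256)[1]; nr <- need(257)[1]
    bps <- need(258, 1)[1]
    fmt <- need(339, 1)[1]
    offs <- need(273); cnts <- need(279)
    data <- unlist(lapply(seq_along(offs), function(i) {
      buf[offs[i] + seq_len(cnts[i])]
    }))
    npx <- nr * nc
    v <- if (bps == 8) {
      as.numeric(data[seq_len(npx)])
    } else if (bps == 16) {
      readBin(data, "integer", npx, size = 2, signed = FALSE,
              endian = endian)
    } else if (bps == 32 && fmt == 3) {
      readBin(data, "double", npx, size = 4, endian = endian)
    } else if (bps == 32) {
      x <- readBin(data, "integer", npx, size = 4, endian = endian)
      ifelse(x < 0, x + 4294967296, as.numeric(x))
    } else {
      stop(sprintf("unsupported bit depth %d", bps))
    }
    pages[[length(pages) + 1L]] <- matrix(v, nr, nc, byrow = TRUE)
    if (!is.null(tags[["282"]]) && is.null(pixel_size_nm)) {
      res <- tags[["282"]]
      unit <- need(296, 2)[1]
      per_cm <- if (unit == 3) res[1] / res[2]
                else if (unit == 2) res[1] / res[2] / 2.54 else NA
      if (is.finite(per_cm) && per_cm > 0) pixel_size_nm <- 1e7 / per_cm
    }
    ifd_off <- rd_u32(buf, ifd_off + 2L + 12L * n, little)
  }
  if (!is.null(pixel_size_nm)) attr(pages, "pixel_size_nm") <- pixel_size_nm
  pages
}

#' Read a two-channel acquisition as channel images
#'
#' Accepts either one multi-page TIFF (page 1 = damage, page 2 = DNA by
#' default) or two single-channel TIFFs.
#'
#' @param path_ch1 TIFF with the damage channel (or both channels when
#'   `path_ch2` is `NULL`).
#' @param path_ch2 Optional TIFF with the DNA channel.
#' @param channel_order For a two-page file, which page is which:
#'   `c("damage", "dna")` (default) or `c("dna", "damage")`.
#' @param pixel_size_nm Pixel size override; defaults to the file's
#'   resolution metadata, falling back to 45 nm.
#' @return List with `ch1` (damage) and `ch2` (dna) `channel_image`s.
#' @export
read_channels <- function(path_ch1, path_ch2 = NULL,
                          channel_order = c("damage", "dna"),
                          pixel_size_nm = NULL) {
  stopifnot(all(sort(channel_order) == c("damage", "dna")))
  if (is.null(path_ch2)) {
    pages <- read_tiff(path_ch1)
    if (length(pages) < 2L) stop("expected a two-page TIFF")
    ps <- pixel_size_nm %||% attr(pages, "pixel_size_nm") %||% 45
    imgs <- setNames(pages[1:2], channel_order)
  } else {
    p1 <- read_tiff(path_ch1); p2 <- read_tiff(path_ch2)
    ps <- pixel_size_nm %||% attr(p1, "pixel_size_nm") %||% 45
    imgs <- setNames(list(p1[[1]], p2[[1]]), channel_order)
  }
  list(ch1 = channel_image(imgs[["damage"]], ps, "damage"),
       ch2 = channel_image(imgs[["dna"]], ps, "dna"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
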