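# Minimal RIFF/AVI container, uncompressed 24-bit DIB frames.
#
# No video library ships with this toolchain, so the package carries its own
# reader/writer for the one dialect it needs: 'vids'/'DIB ' streams with
# BI_RGB (compression 0) BITMAPINFOHEADER payloads — bottom-up rows, BGR
# byte order, rows padded to 4-byte boundaries. The format is lossless, so
# phantom round trips are bit-exact and segmentation tests are stable.

write_u32 <- function(con, x) {
  writeBin(as.integer(x), con, size = 4L, endian = "little")
}

write_u16 <- function(con, x) {
  writeBin(as.integer(x), con, size = 2L, endian = "little")
}

write_fourcc <- function(con, s) {
  writeChar(s, con, nchars = 4L, eos = NULL)
}

frame_to_dib <- function(fr) {
  h <- dim(fr)[1]; w <- dim(fr)[2]
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  out <- matrix(as.raw(0L), nrow = stride, ncol = h)
  # bottom-up rows, BGR within each pixel
  bgr <- aperm(fr[h:1, , , drop = FALSE], c(3L, 2L, 1L))[c(3L, 2L, 1L), , , drop = FALSE]
  out[seq_len(3L * w), ] <- as.raw(bgr)
  as.vector(out)
}

dib_to_frame <- function(bytes, w, h) {
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  m <- matrix(as.integer(bytes), nrow = stride)
  bgr <- array(m[seq_len(3L * w), , drop = FALSE], dim = c(3L, w, h))
  fr <- aperm(bgr[c(3L, 2L, 1L), , , drop = FALSE], c(3L, 2L, 1L))
  fr[h:1, , , drop = FALSE]
}

#' Write frames to an uncompressed AVI file
#'
#' Encodes RGB frames as an AVI with raw 24-bit DIB payloads (lossless; what
#' the phantom generator emits by default so that segmentation tests are
#' bit-stable).
#'
#' @param frames a `frame_sequence` or a list of `(h, w, 3)` integer arrays
#' @param path output file path
#' @param fps nominal frame rate written into the header
#' @return `path`, invisibly
#' @export
write_avi <- function(frames, path, fps = 30L) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  if (!is.list(frames) || length(frames) < 1L)
    stop_validation("write_avi() needs at least one frame")
  d <- dim(frames[[1]])
  h <- d[1]; w <- d[2]
  n <- length(frames)
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  fsz <- stride * h

  strl_content <- 4L + (8L + 56L) + (8L + 40L)
  hdrl_content <- 4L + (8L + 56L) + (8L + strl_content)
  movi_content <- 4L + n * (8L + fsz)
  idx_content <- 16L * n
  riff_content <- 4L + (8L + hdrl_content) + (8L + movi_content) +
    (8L + idx_content)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)

  write_fourcc(con, "RIFF"); write_u32(con, riff_content)
  write_fourcc(con, "AVI ")

  write_fourcc(con, "LIST"); write_u32(con, hdrl_content)
  write_fourcc(con, "hdrl")
  write_fourcc(con, "avih"); write_u32(con, 56L)
  write_u32(con, round(1e6 / fps))          # dwMicroSecPerFrame
  write_u32(con, fsz * fps)                 # dwMaxBytesPerSec
  write_u32(con, 0L)                        # dwPaddingGranularity
  write_u32(con, 16L)                       # dwFlags: AVIF_HASINDEX
  write_u32(con, n)                         # dwTotalFrames
  write_u32(con, 0L)                        # dwInitialFrames
  write_u32(con, 1L)                        # dwStreams
  write_u32(con, fsz)                       # dwSuggestedBufferSize
  write_u32(con, w); write_u32(con, h)
  for (i in 1:4) write_u32(con, 0L)         # dwReserved

  write_fourcc(con, "LIST"); write_u32(con, strl_content)
  write_fourcc(con, "strl")
  write_fourcc(con, "strh"); write_u32(con, 56L)
  write_fourcc(con, "vids"); write_fourcc(con, "DIB ")
  write_u32(con, 0L)                        # dwFlags
  write_u32(con, 0L)                        # wPriority + wLanguage
  write_u32(con, 0L)                        # dwInitialFrames
  write_u32(con, 1L)                        # dwScale
  write_u32(con, fps)                       # dwRate
  write_u32(con, 0L)                        # dwStart
  write_u32(con, n)                         # dwLength (frames)
  write_u32(con, fsz)                       # dwSuggestedBufferSize
  write_u32(con, 0L)                        # dwQuality
  write_u32(con, 0L)                        # dwSampleSize
  write_u16(con, 0L); write_u16(con, 0L)    # rcFrame
  write_u16(con, w); write_u16(con, h)

  write_fourcc(con, "strf"); write_u32(con, 40L)
  write_u32(con, 40L)                       # biSize
  write_u32(con, w); write_u32(con, h)
  write_u16(con, 1L); write_u16(con, 24L)   # biPlanes, biBitCount
  write_u32(con, 0L)                        # biCompression = BI_RGB
  write_u32(con, fsz)                       # biSizeImage
  write_u32(con, 2835L); write_u32(con, 2835L)
  write_u32(con, 0L); write_u32(con, 0L)

  write_fourcc(con, "LIST"); write_u32(con, movi_content)
  write_fourcc(con, "movi")
  for (fr in frames) {
    fd <- dim(fr)
    if (fd[1] != h || fd[2] != w)
      stop_validation("all frames must share identical dimensions")
    write_fourcc(con, "00db"); write_u32(con, fsz)
    writeBin(frame_to_dib(fr), con)
  }

  write_fourcc(con, "idx1"); write_u32(con, idx_content)
  for (i in seq_len(n)) {
    write_fourcc(con, "00db")
    write_u32(con, 16L)                     # AVIIF_KEYFRAME
    write_u32(con, 4L + (i - 1L) * (8L + fsz))
    write_u32(con, fsz)
  }
  invisible(path)
}

read_u32 <- function(con) {
  v <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(v) == 0L) NA_integer_ else v
}

#' Extract all frames from an AVI video
#'
#' Decodes every frame of an uncompressed 24-bit DIB AVI (the dialect this
#' package writes) into an in-memory `frame_sequence` in display order, RGB
#' channel order.
#'
#' @param video_path path to the `.avi` file
#' @param vendor_dialect calibration-marker convention carried by the video
#'   (`"philips"` green dots, `"ge"` scale line, or `"explicit"`)
#' @return a [frame_sequence()]
#' @export
extract_frames <- function(video_path,
                           vendor_dialect = c("explicit", "philips", "ge")) {
  vendor_dialect <- match.arg(vendor_dialect)
  if (!file.exists(video_path))
    stop_io(sprintf("video file not found: %s", video_path))
  sz <- file.info(video_path)$size
  con <- file(video_path, "rb")
  on.exit(close(con), add = TRUE)

  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF"))
    stop_io(sprintf("not a RIFF/AVI file: %s", video_path))
  read_u32(con)
  ftype <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(ftype, "AVI "))
    stop_io(sprintf("not an AVI file: %s", video_path))

  width <- height <- bpp <- compression <- NA_integer_
  frames_raw <- list()

  walk <- function(end) {
    while (seek(con, where = NA) < end) {
      id <- readChar(con, 4L, useBytes = TRUE)
      csz <- read_u32(con)
      if (is.na(csz) || nchar(id) < 4L) break
      if (identical(id, "LIST")) {
        readChar(con, 4L, useBytes = TRUE)  # list type
        walk(seek(con, where = NA) + csz - 4L)
      } else if (identical(id, "strf")) {
        pos <- seek(con, where = NA)
        read_u32(con)                        # biSize
        width <<- read_u32(con)
        height <<- read_u32(con)
        readBin(con, "integer", 1L, size = 2L, endian = "little")
        bpp <<- readBin(con, "integer", 1L, size = 2L, endian = "little")
        compression <<- read_u32(con)
        seek(con, where = pos + csz)
      } else if (id %in% c("00db", "00dc") && csz > 0L) {
        frames_raw[[length(frames_raw) + 1L]] <<- readBin(con, "raw", n = csz)
      } else {
        seek(con, where = seek(con, where = NA) + csz)
      }
      if (csz %% 2L == 1L) seek(con, where = seek(con, where = NA) + 1L)
    }
  }
  ok <- tryCatch({ walk(sz); TRUE }, error = function(e) FALSE)
  if (!ok || is.na(width) || is.na(height))
    stop_io(sprintf("failed to parse AVI structure: %s", video_path))
  if (!identical(compression, 0L) || !identical(bpp, 24L))
    stop_io("only uncompressed 24-bit DIB AVI streams are supported")
  if (length(frames_raw) == 0L)
    stop_io(sprintf("no decodable frames in video: %s", video_path),
            subclass = "echoplanim_empty_video_error")

  frames <- lapply(frames_raw, dib_to_frame, w = width, h = height)
  frame_sequence(frames, source_path = video_path,
                 vendor_dialect = vendor_dialect)
}
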