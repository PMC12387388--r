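#' Construct an RGB video frame
#'
#' A frame is stored as an integer array with `dim = c(height, width, 3)` in
#' RGB channel order, channel values in `[0, 255]`. Decoders that are
#' BGR-native must convert at the boundary; everything in this package is RGB
#' in memory.
#'
#' @param pixels numeric or integer array of dim `c(h, w, 3)`
#' @return integer array of class `echo_frame`
#' @export
new_frame <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop_validation("a frame must be an array with dim (height, width, 3)")
  if (d[1] < 1L || d[2] < 1L)
    stop_validation("frame height and width must be >= 1")
  px <- as.integer(round(pixels))
  if (anyNA(px) || any(px < 0L) || any(px > 255L))
    stop_validation("frame channel values must lie in [0, 255]")
  out <- array(px, dim = d)
  class(out) <- c("echo_frame", class(out))
  out
}

#' Construct a frame sequence
#'
#' @param frames list of frames (arrays of identical dimensions)
#' @param source_path text path of the originating video ("" when in-memory)
#' @param vendor_dialect one of `"philips"`, `"ge"`, `"explicit"` — which
#'   calibration marker convention the video carries
#' @return object of class `frame_sequence`
#' @export
frame_sequence <- function(frames, source_path = "",
                           vendor_dialect = c("explicit", "philips", "ge")) {
  vendor_dialect <- match.arg(vendor_dialect)
  if (!is.list(frames) || length(frames) < 1L)
    stop_validation("a frame sequence needs at least one frame")
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_validation("all frames in a sequence must share identical dimensions")
  structure(
    list(frames = frames, source_path = source_path,
         vendor_dialect = vendor_dialect),
    class = "frame_sequence"
  )
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence: %d frame(s), %d x %d px, dialect '%s'>\n",
              length(x$frames), d[1], d[2], x$vendor_dialect))
  invisible(x)
}

#' Nearest-neighbour resize of a frame
#'
#' Used to bring frames to the CNN input resolution; nearest-neighbour keeps
#' integer intensities intact.
#'
#' @param frame integer array `(h, w, 3)`
#' @param height,width target size in pixels
#' @return integer array `(height, width, 3)`
#' @export
resize_frame <- function(frame, height, width) {
  d <- dim(frame)
  ri <- pmin(d[1], pmax(1L, as.integer(ceiling(seq_len(height) * d[1] / height))))
  ci <- pmin(d[2], pmax(1L, as.integer(ceiling(seq_len(width) * d[2] / width))))
  frame[ri, ci, , drop = FALSE]
}
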