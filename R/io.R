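# File interchange. The TIFF support is a deliberately minimal writer and
# reader for uncompressed little-endian 32-bit-float grayscale multi-page
# stacks with a JSON payload in the ImageDescription tag — just enough for
# synthetic dark-field movies to round-trip with their fps / pixel-size
# metadata (no R TIFF package is available in this stack).

.TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
                Compression = 259L, Photometric = 262L,
                ImageDescription = 270L, StripOffsets = 273L,
                RowsPerStrip = 278L, StripByteCounts = 279L,
                SampleFormat = 339L)

#' Write a frame stack as a multi-page TIFF
#'
#' Uncompressed 32-bit float grayscale, little-endian, one IFD per frame;
#' `fps` and `pixel_size` travel as JSON in the first page's
#' ImageDescription tag.
#'
#' @param stack a `frame_stack` (see [render_video()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tiff_stack <- function(stack, file) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack)
  ny <- d[1]; nx <- d[2]; nf <- d[3]
  desc <- jsonlite::toJSON(list(fps = attr(stack, "fps"),
                                pixel_size = attr(stack, "pixel_size")),
                           auto_unbox = TRUE, digits = NA)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))
  con <- file(file, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  strip_bytes <- nx * ny * 4L
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  w4(8L + strip_bytes + length(desc_raw))   # first IFD offset
  # layout per frame: [pixel data][IFD]; first frame also carries the
  # description block right after its pixel data
  off <- 8L
  offsets <- list()
  for (k in seq_len(nf)) {
    data_off <- off
    desc_off <- if (k == 1L) data_off + strip_bytes else offsets$desc
    extra <- if (k == 1L) length(desc_raw) else 0L
    ifd_off <- data_off + strip_bytes + extra
    offsets <- list(data = data_off, desc = desc_off, ifd = ifd_off)
    if (k == 1L) first_desc <- desc_off
    # pixel data, row-major (TIFF scanlines top to bottom)
    writeBin(as.numeric(t(stack[, , k])), con, size = 4, endian = "little")
    if (k == 1L) writeBin(desc_raw, con)
    # IFD
    w2(n_entries)
    entry <- function(tag, type, count, value) {
      w2(.TIFF_TAGS[[tag]]); w2(type); w4(count); w4(value)
    }
    entry("ImageWidth", 3L, 1L, nx)
    entry("ImageLength", 3L, 1L, ny)
    entry("BitsPerSample", 3L, 1L, 32L)
    entry("Compression", 3L, 1L, 1L)
    entry("Photometric", 3L, 1L, 1L)
    entry("ImageDescription", 2L, length(desc_raw), first_desc)
    entry("StripOffsets", 4L, 1L, data_off)
    entry("RowsPerStrip", 3L, 1L, ny)
    entry("StripByteCounts", 4L, 1L, strip_bytes)
    entry("SampleFormat", 3L, 1L, 3L)
    # next frame layout is [data][IFD], so its IFD sits one strip further on
    next_ifd <- if (k < nf) ifd_off + ifd_size + strip_bytes else 0L
    w4(next_ifd)
    off <- ifd_off + ifd_size
  }
  invisible(file)
}

#' Read a multi-page TIFF written by [write_tiff_stack()]
#'
#' Supports the same narrow subset: uncompressed little-endian 32-bit
#' float grayscale with single-strip pages.
#'
#' @param file TIFF path.
#' @return A `frame_stack` with `fps` / `pixel_size` attributes restored.
#' @export
read_tiff_stack <- function(file) {
  raw <- readBin(file, "raw", file.size(file))
  r2 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  r4 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || r2(2) != 42L)
    stop_bad("not a little-endian TIFF")
  ifd <- r4(4)
  frames <- list()
  meta <- NULL
  while (ifd != 0L) {
    n <- r2(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd + 2L + (e - 1L) * 12L
      tag <- r2(base); count <- r4(base + 4L); val <- r4(base + 8L)
      tags[[as.character(tag)]] <- c(count = count, value = val)
    }
    nx <- tags[["256"]][["value"]]; ny <- tags[["257"]][["value"]]
    if (tags[["259"]][["value"]] != 1L || tags[["258"]][["value"]] != 32L)
      stop_bad("unsupported TIFF variant (need uncompressed 32-bit float)")
    if (is.null(meta) && !is.null(tags[["270"]])) {
      dof <- tags[["270"]][["value"]]; dcount <- tags[["270"]][["count"]]
      dr <- raw[dof + seq_len(dcount)]
      txt <- rawToChar(dr[dr != as.raw(0L)])   # strip NUL padding
      meta <- jsonlite::fromJSON(txt)
    }
    doff <- tags[["273"]][["value"]]
    px <- readBin(raw[doff + seq_len(nx * ny * 4L)], "numeric",
                  n = nx * ny, size = 4, endian = "little")
    frames[[length(frames) + 1L]] <- t(matrix(px, nrow = nx, ncol = ny))
    ifd <- r4(ifd + 2L + n * 12L)
  }
  stack <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  structure(stack, fps = meta$fps, pixel_size = meta$pixel_size,
            class = "frame_stack")
}

#' Write and read sweep sets (JSON header + CSV traces)
#'
#' The header JSON carries the protocol, solutions and temperature; the
#' CSV has a `t_ms` column plus one `step_<mV>` column per step level.
#'
#' @param sweeps a `sweep_set`.
#' @param basename path without extension; writes `<basename>.json` and
#'   `<basename>.csv`.
#' @return `read_sweep_set()` returns a `sweep_set`.
#' @export
write_sweep_set <- function(sweeps, basename) {
  stopifnot(inherits(sweeps, "sweep_set"))
  hdr <- list(protocol = unclass(sweeps$protocol),
              step_onset_ms = sweeps$step_onset_ms,
              solutions = sweeps$solutions,
              temperature = sweeps$temperature)
  jsonlite::write_json(hdr, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  tr <- as.data.frame(t(sweeps$traces))
  names(tr) <- paste0("step_", sweeps$protocol$step_levels)
  write.csv(cbind(t_ms = sweeps$t_ms, tr), paste0(basename, ".csv"),
            row.names = FALSE)
  invisible(basename)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(basename) {
  hdr <- jsonlite::read_json(paste0(basename, ".json"),
                             simplifyVector = TRUE)
  d <- read.csv(paste0(basename, ".csv"), check.names = FALSE)
  proto <- do.call(step_protocol, hdr$protocol[c(
    "holding_mV", "step_levels", "step_duration_ms", "sample_rate_khz",
    "pre_ms")])
  traces <- t(as.matrix(d[, -1, drop = FALSE]))
  sols <- lapply(hdr$solutions, function(x) unlist(x))
  structure(list(protocol = proto, t_ms = d$t_ms, traces = unname(traces),
                 step_onset_ms = hdr$step_onset_ms, solutions = sols,
                 temperature = hdr$temperature, model = NULL,
                 v_rev_true = NA_real_),
            class = "sweep_set")
}

#' Write and read IV curves as CSV
#'
#' Columns `v_mV`, `i_pA`, `i_sd`.
#'
#' @param iv an [iv_curve()].
#' @param file CSV path.
#' @return `read_iv()` returns an [iv_curve()].
#' @export
write_iv <- function(iv, file) {
  write.csv(data.frame(v_mV = iv$v, i_pA = iv$i, i_sd = iv$i_sd), file,
            row.names = FALSE)
  invisible(file)
}

#' @rdname write_iv
#' @export
read_iv <- function(file) {
  d <- read.csv(file)
  iv_curve(d$v_mV, d$i_pA, d$i_sd)
}

#' Write and read dose-response tables as CSV
#'
#' Columns `dose`, `replicate`, `response`.
#'
#' @param dr a `dose_response_set` or compatible data frame.
#' @param file CSV path.
#' @return `read_dose_response()` returns a data frame.
#' @export
write_dose_response <- function(dr, file) {
  write.csv(as.data.frame(dr)[, c("dose", "replicate", "response")], file,
            row.names = FALSE)
  invisible(file)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(file) read.csv(file)
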