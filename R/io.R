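#' Read and write the package's plain-text interchange formats
#'
#' Spectra, correlation curves, intensity traces and TCSPC decays travel as
#' small CSV files; two-channel image stacks as multi-page 16-bit TIFF
#' (frame-major, channel pairs interleaved b, r) with a JSON sidecar holding
#' the numeric metadata (saturation value, pixel size, frame count).
#'
#' @param s,curve,trace,d,stack object to write.
#' @param path file path.
#' @name photoblue_io
NULL

#' @rdname photoblue_io
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "emission_spectrum"))
  write.csv(data.frame(wavelength_nm = s$binning$bin_centers,
                       counts = s$counts),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname photoblue_io
#' @export
read_spectrum_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("wavelength_nm", "counts") %in% names(df)))
    stopf("%s: expected columns wavelength_nm, counts", path)
  emission_spectrum(spectral_binning(df$wavelength_nm), df$counts)
}

#' @rdname photoblue_io
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mean_rate_hz: %.17g", attr(curve, "mean_rate")), con)
  write.csv(data.frame(lag_s = curve$lag, G = curve$G,
                       stderr = curve$stderr),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname photoblue_io
#' @export
read_curve_csv <- function(path) {
  first <- readLines(path, n = 1L)
  mean_rate <- NA_real_
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("mean_rate_hz:\\s*([-0-9.eE+]+)", first))[[1L]]
    if (length(m) == 2L) mean_rate <- as.numeric(m[2L])
  }
  df <- read.csv(path, skip = skip)
  if (!all(c("lag_s", "G") %in% names(df)))
    stopf("%s: expected columns lag_s, G", path)
  bad <- which(diff(df$lag_s) <= 0)
  if (length(bad))
    stopf("%s: lags not strictly increasing at data line %d", path,
          bad[1L] + 1L)
  correlation_curve(df$lag_s, df$G,
                    if ("stderr" %in% names(df)) df$stderr else NULL,
                    mean_rate = mean_rate)
}

#' @rdname photoblue_io
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_time_s: %.17g", trace$bin_time), con)
  write.csv(data.frame(counts = trace$counts), con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname photoblue_io
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) stopf("%s: missing '# bin_time_s:' header", path)
  m <- regmatches(first, regexec("bin_time_s:\\s*([-0-9.eE+]+)", first))[[1L]]
  if (length(m) != 2L) stopf("%s: missing '# bin_time_s:' header", path)
  df <- read.csv(path, skip = 1L)
  intensity_trace(df$counts, as.numeric(m[2L]))
}

#' @rdname photoblue_io
#' @export
write_decay_csv <- function(d, path) {
  stopifnot(inherits(d, "decay_histogram"))
  n <- length(d$counts)
  write.csv(data.frame(bin_start_ns = d$bin_edges[seq_len(n)],
                       counts = d$counts),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname photoblue_io
#' @export
read_decay_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("bin_start_ns", "counts") %in% names(df)))
    stopf("%s: expected columns bin_start_ns, counts", path)
  n <- nrow(df)
  width <- df$bin_start_ns[2L] - df$bin_start_ns[1L]
  decay_histogram(df$counts, period = df$bin_start_ns[n] + width, n_bins = n)
}

#' @rdname photoblue_io
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "two_channel_stack"))
  sat <- stack$saturation_value
  nf <- dim(stack$I_b)[3L]
  pages <- vector("list", 2L * nf)
  for (t in seq_len(nf)) {
    pages[[2L * t - 1L]] <- pmin(round(stack$I_b[, , t]), sat) / sat
    pages[[2L * t]] <- pmin(round(stack$I_r[, , t]), sat) / sat
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(saturation_value = sat, pixel_size = stack$pixel_size,
               n_frames = nf, channel_order = c("b_580_630", "r_650_700"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname photoblue_io
#' @export
read_stack_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stopf("%s: missing metadata sidecar %s",
                                     path, meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2L != 0L)
    stopf("%s: odd page count %d, expected interleaved b/r channel pairs",
          path, length(pages))
  nf <- length(pages) %/% 2L
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stopf("%s: mismatched channel shapes: %s", path,
          paste(unique(shapes), collapse = " vs "))
  sat <- meta$saturation_value
  dims <- dim(pages[[1L]])
  I_b <- array(0, c(dims, nf))
  I_r <- array(0, c(dims, nf))
  for (t in seq_len(nf)) {
    I_b[, , t] <- round(pages[[2L * t - 1L]] * sat)
    I_r[, , t] <- round(pages[[2L * t]] * sat)
  }
  structure(list(I_b = I_b, I_r = I_r, saturation_value = sat,
                 pixel_size = meta$pixel_size, gp_true = NULL,
                 mask_true = NULL, trajectory = NULL),
            class = "two_channel_stack")
}

#' Validate interchange files against their format invariants
#'
#' Recognizes the package's CSV formats by their column headers and image
#' stacks by the `.tif`/`.tiff` extension, then checks every format
#' invariant (monotone lags, non-negative counts, matching channel shapes,
#' ...), reporting a per-file pass/fail with the failure reason.
#'
#' @param paths character vector of file paths.
#' @return data.frame with columns `file`, `format`, `ok`, `message`.
#' @export
validate_files <- function(paths) {
  one <- function(path) {
    if (!file.exists(path))
      return(data.frame(file = path, format = "missing", ok = FALSE,
                        message = "file does not exist"))
    res <- tryCatch({
      if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        read_stack_tiff(path)
        c("image_stack", "ok")
      } else {
        head_lines <- readLines(path, n = 2L)
        header <- head_lines[[if (startsWith(head_lines[1L], "#")) 2L else 1L]]
        cols <- strsplit(header, ",")[[1L]]
        if (all(c("wavelength_nm", "counts") %in% cols)) {
          read_spectrum_csv(path); c("spectrum_csv", "ok")
        } else if (all(c("lag_s", "G") %in% cols)) {
          read_curve_csv(path); c("curve_csv", "ok")
        } else if (all(c("bin_start_ns", "counts") %in% cols)) {
          read_decay_csv(path); c("decay_csv", "ok")
        } else if ("counts" %in% cols) {
          read_trace_csv(path); c("trace_csv", "ok")
        } else stopf("unrecognized format (columns: %s)", header)
      }
    }, error = function(e) c("invalid", conditionMessage(e)))
    data.frame(file = path, format = res[1L], ok = res[2L] == "ok",
               message = if (res[2L] == "ok") "" else res[2L])
  }
  out <- do.call(rbind, lapply(paths, one))
  rownames(out) <- NULL
  out
}
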