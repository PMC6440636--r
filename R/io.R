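# On-disk formats: stereo WAV impulse responses under
# <root>/<condition>/<az>_<el>.wav with an index CSV, response-log CSV,
# error-table CSV, transform JSON and YAML/JSON run configuration.

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader supporting PCM (16/24/32 bit) and IEEE float
#' (32/64 bit); samples are returned as floats, PCM scaled to [-1, 1).
#'
#' @param path Input .wav path.
#' @return List: \code{samples} (channels x frames matrix), \code{fs},
#'   \code{n_channels}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path)
  }
  fmt <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (id == "data") {
      data <- readBin(con, "raw", sz)
      if (sz %% 2) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV (missing fmt/data chunk): ", path)
  bytes <- fmt$bits / 8
  n <- length(data) %/% bytes
  x <- if (fmt$audio_format == 3 || (fmt$audio_format == 65534 && fmt$bits >= 32)) {
    readBin(data, "double", n, size = bytes, endian = "little")
  } else if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data, "integer", n, size = 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 24) {
    b <- matrix(as.integer(data), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else if (fmt$audio_format == 1 && fmt$bits == 32) {
    readBin(data, "integer", n, size = 4, endian = "little") / 2147483648
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ", fmt$bits, " bit)")
  }
  list(samples = matrix(x, nrow = fmt$n_channels),
       fs = fmt$fs, n_channels = fmt$n_channels)
}

#' Write a WAV file (IEEE float32)
#'
#' @param samples Numeric vector (mono) or channels x frames matrix.
#' @param fs Sampling rate in Hz.
#' @param path Output .wav path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  nch <- nrow(samples)
  x <- as.numeric(samples)  # interleaved by column = by frame
  nbytes <- length(x) * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(3, nch)), con, size = 2, endian = "little")  # float32
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * nch * 4), con, size = 4, endian = "little")
  writeBin(as.integer(c(nch * 4, 32)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

#' Write a BRIR dataset as WAV directory + index CSV
#'
#' Layout: \code{<root>/<condition>/<azimuth>_<elevation>.wav} (stereo,
#' float32) plus \code{<root>/index.csv} with columns filename,
#' azimuth_deg, elevation_deg, condition.
#'
#' @param pairs Dataset as produced by [simulate_ir_dataset()].
#' @param root Output directory (created if needed).
#' @return \code{root}, invisibly.
#' @export
write_ir_dataset <- function(pairs, root) {
  rows <- list()
  for (p in pairs) {
    for (cond in c("with_hmd", "without_hmd")) {
      ir <- p[[cond]]
      dir.create(file.path(root, cond), recursive = TRUE, showWarnings = FALSE)
      fn <- file.path(cond, sprintf("%g_%g.wav", ir$azimuth, ir$elevation))
      write_wav(rbind(ir$left, ir$right), ir$fs, file.path(root, fn))
      rows[[length(rows) + 1]] <- data.frame(
        filename = fn, azimuth_deg = ir$azimuth, elevation_deg = ir$elevation,
        condition = cond)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(root, "index.csv"),
                   row.names = FALSE)
  invisible(root)
}

#' Read a BRIR dataset (WAV directory + index CSV)
#'
#' Entries are matched into with/without-HMD pairs by source direction.
#' Index rows pointing to missing files, and directions missing one
#' condition, are excluded with a warning.
#'
#' @param root Dataset directory containing \code{index.csv}.
#' @return Named list of pairs (\code{with_hmd}, \code{without_hmd}), as
#'   consumed by [cue_table()].
#' @export
read_ir_dataset <- function(root) {
  idx_path <- file.path(root, "index.csv")
  if (!file.exists(idx_path)) stop("no index.csv under ", root)
  idx <- utils::read.csv(idx_path)
  need <- c("filename", "azimuth_deg", "elevation_deg", "condition")
  miss <- setdiff(need, names(idx))
  if (length(miss)) stop("malformed index.csv: missing column(s) ", paste(miss, collapse = ", "))
  bad <- which(!idx$condition %in% c("with_hmd", "without_hmd") |
                 !is.finite(idx$azimuth_deg) | !is.finite(idx$elevation_deg))
  if (length(bad)) stop("malformed index.csv at row(s) ", paste(bad, collapse = ", "))
  entries <- list()
  for (i in seq_len(nrow(idx))) {
    fp <- file.path(root, idx$filename[i])
    if (!file.exists(fp)) {
      warning("missing IR file ", idx$filename[i], "; direction excluded")
      next
    }
    w <- read_wav(fp)
    if (w$n_channels != 2) {
      warning(idx$filename[i], " is not stereo; excluded")
      next
    }
    key <- sprintf("%g_%g", idx$azimuth_deg[i], idx$elevation_deg[i])
    entries[[key]][[idx$condition[i]]] <- binaural_ir(
      left = w$samples[1, ], right = w$samples[2, ], fs = w$fs,
      condition = idx$condition[i],
      azimuth = idx$azimuth_deg[i], elevation = idx$elevation_deg[i])
  }
  complete <- vapply(entries, function(e) {
    all(c("with_hmd", "without_hmd") %in% names(e))
  }, logical(1))
  if (any(!complete)) {
    warning("unpaired direction(s) excluded: ",
            paste(names(entries)[!complete], collapse = ", "))
  }
  entries[complete]
}

#' Read / write pointing-response logs
#'
#' CSV schema: subject, condition, block, target_azimuth_deg,
#' target_elevation_deg, response_azimuth_deg, response_elevation_deg,
#' repetition, handedness.
#'
#' @param path CSV path.
#' @return data.frame of response records.
#' @export
read_responses <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_records(d)
  d
}

#' @rdname read_responses
#' @param records Response records data.frame.
#' @export
write_responses <- function(records, path) {
  check_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write an error table as CSV
#' @param table An \code{error_table} from [summarize_errors()].
#' @param path Output CSV path.
#' @export
write_error_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' FNV-1a hash of an R object (hex string)
#'
#' Used to stamp outputs with a configuration fingerprint.
#'
#' @param x Any serializable R object.
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  p <- 16777619
  for (v in b) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), v)
    # h * p mod 2^32 in exact double arithmetic
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read a run configuration from YAML or JSON
#'
#' @param path .yaml/.yml or .json file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write a run summary JSON stamped with seed and config hash
#'
#' @param summary Named list of results.
#' @param config The configuration the run used.
#' @param seed The seed the run used.
#' @param path Output .json path.
#' @export
write_run_summary <- function(summary, config, seed, path) {
  jsonlite::write_json(
    c(list(seed = seed, config_hash = config_hash(config)), summary),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
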