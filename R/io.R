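# Delimited-text dialect used throughout: comma-separated, header row,
# '.' decimal, UTF-8; empty fields / NaN mean missing.

sniff_format <- function(path) {
  head <- tryCatch(readLines(path, n = 4L, warn = FALSE),
                   error = function(e) character(0))
  if (length(head) == 0L) return("empty")
  if (any(grepl("ooTextFile", head))) {
    if (any(grepl("TextGrid", head))) "textgrid" else "praat"
  } else "csv"
}

#' Read a formant track
#'
#' Reads either a delimited-text track (columns `time_s, F1_Hz, F2_Hz`;
#' empty or NaN formants mark unvoiced frames) or a Praat `Formant` text
#' file (short or long form).  Praat frames carrying fewer than two
#' formants are marked unvoiced.
#'
#' @param path file path.
#' @param format `"auto"` (default, sniffed from the header), `"csv"` or
#'   `"praat"`.
#' @return A [formant_track()].
#' @export
read_formant_track <- function(path, format = c("auto", "csv", "praat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- sniff_format(path)
    if (format == "empty") stop("empty file: ", path)
    if (format == "textgrid") stop("not a formant file (TextGrid?): ", path)
  }
  if (format == "csv") read_track_csv(path) else read_track_praat(path)
}

read_track_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("parse error: no data rows in ", path)
  header <- tolower(strsplit(lines[1], ",")[[1]])
  ix <- function(names) {
    i <- which(trimws(header) %in% names)
    if (length(i) == 0L) NA_integer_ else i[1]
  }
  it <- ix(c("time_s", "t", "time"))
  i1 <- ix(c("f1_hz", "f1"))
  i2 <- ix(c("f2_hz", "f2"))
  if (anyNA(c(it, i1, i2)))
    stop("parse error: expected columns time_s, F1_Hz, F2_Hz in ", path)
  n <- length(lines) - 1L
  t <- f1 <- f2 <- numeric(n)
  for (r in seq_len(n)) {
    fields <- trimws(strsplit(lines[r + 1L], ",")[[1]])
    # trailing empty fields (unvoiced frames) are dropped by strsplit
    if (length(fields) < length(header) &&
        length(fields) >= it)
      fields <- c(fields, rep("", length(header) - length(fields)))
    if (length(fields) < max(it, i1, i2))
      stop(sprintf("parse error at line %d of %s: too few fields",
                   r + 1L, path))
    num <- function(x) {
      if (!nzchar(x) || toupper(x) %in% c("NA", "NAN")) return(NA_real_)
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v))
        stop(sprintf("parse error at line %d of %s: '%s' is not numeric",
                     r + 1L, path, x))
      v
    }
    t[r] <- num(fields[it])
    f1[r] <- num(fields[i1])
    f2[r] <- num(fields[i2])
  }
  if (anyNA(t)) stop("parse error: missing time values in ", path)
  formant_track(t, f1, f2)
}

# numeric token stream from a Praat text file (works for short and long
# forms: lines are either bare values or 'key = value' pairs)
praat_tokens <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[-seq_len(min(2L, length(lines)))]  # File type / Object class
  vals <- character(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("=", ln, fixed = TRUE))
      ln <- trimws(sub(".*=", "", ln))
    if (grepl("\\[\\s*\\d*\\s*\\]\\s*:?$", ln) || grepl(":$", ln)) next
    vals <- c(vals, ln)
  }
  suppressWarnings(as.numeric(vals))
}

read_track_praat <- function(path) {
  v <- praat_tokens(path)
  v <- v[!is.na(v)]
  if (length(v) < 6L) stop("parse error: truncated Praat Formant file ", path)
  nx <- as.integer(v[3])
  dx <- v[4]
  x1 <- v[5]
  i <- 7L  # v[6] is maxnFormants
  t <- x1 + (seq_len(nx) - 1L) * dx
  f1 <- rep(NA_real_, nx)
  f2 <- rep(NA_real_, nx)
  for (fr in seq_len(nx)) {
    if (i + 1L > length(v)) stop("parse error: truncated frame ", fr,
                                 " in ", path)
    nf <- as.integer(v[i + 1L])  # v[i] is the frame intensity
    i <- i + 2L
    if (nf >= 1L && i + 2L * nf - 1L <= length(v)) {
      freqs <- v[i + 2L * (seq_len(nf) - 1L)]
      if (nf >= 2L) {
        f1[fr] <- freqs[1]
        f2[fr] <- freqs[2]
      }
    }
    i <- i + 2L * max(nf, 0L)
  }
  formant_track(t, f1, f2)
}

#' Write a formant track as delimited text
#'
#' Columns `time_s, F1_Hz, F2_Hz`; unvoiced frames are written with empty
#' formant fields.
#'
#' @param track a [formant_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_formant_track <- function(track, path) {
  stopifnot(inherits(track, "formant_track"))
  df <- data.frame(time_s = track$t,
                   F1_Hz = ifelse(track$voiced, track$f1, NA_real_),
                   F2_Hz = ifelse(track$voiced, track$f2, NA_real_))
  utils::write.csv(format(df, digits = 15, trim = TRUE, nsmall = 0),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a phoneme segmentation
#'
#' Reads labeled intervals from delimited text (columns
#' `label, t_start_s, t_end_s`) or from a Praat TextGrid interval tier
#' (short or long text form; the first interval tier is used unless `tier`
#' names another).  Intervals with empty labels (silences) are dropped;
#' out-of-order intervals are sorted; overlapping intervals are an error.
#'
#' @param path file path.
#' @param format `"auto"`, `"csv"` or `"textgrid"`.
#' @param tier optional tier name (TextGrid only).
#' @return A [phoneme_segmentation()].
#' @export
read_segmentation <- function(path, format = c("auto", "csv", "textgrid"),
                              tier = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- sniff_format(path)
    if (format == "empty") stop("empty file: ", path)
    if (format == "praat") stop("not a segmentation file: ", path)
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    need <- c("label", "t_start_s", "t_end_s")
    alt <- c("label", "t_start", "t_end")
    if (all(need %in% names(df))) {
      seg <- df[need]
    } else if (all(alt %in% names(df))) {
      seg <- df[alt]
    } else stop("parse error: expected columns label, t_start_s, t_end_s")
    phoneme_segmentation(seg[[1]], seg[[2]], seg[[3]])
  } else {
    read_seg_textgrid(path, tier)
  }
}

read_seg_textgrid <- function(path, tier = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[-seq_len(min(2L, length(lines)))]
  toks <- character(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("=", ln, fixed = TRUE)) ln <- trimws(sub("^[^=]*=", "", ln))
    if (grepl("\\[\\s*\\d*\\s*\\]\\s*:?$", ln) || grepl(":$", ln)) next
    toks <- c(toks, ln)
  }
  unq <- function(x) {
    x <- sub('^"', "", x)
    sub('"$', "", x)
  }
  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  p <- 1L
  take <- function() {
    if (p > length(toks)) stop("parse error: truncated TextGrid ", path)
    v <- toks[p]
    p <<- p + 1L
    v
  }
  take()                      # global xmin
  take()                      # global xmax
  if (p <= length(toks) && grepl("exists", toks[p])) take()  # tiers? flag
  ntier <- as.integer(take())
  if (is.na(ntier)) stop("parse error: tier count missing in ", path)
  found <- NULL
  for (k in seq_len(ntier)) {
    cls <- unq(take())
    nm <- unq(take())
    take()                    # tier xmin
    take()                    # tier xmax
    nint <- as.integer(take())
    if (is.na(nint)) stop("parse error: interval count missing in ", path)
    if (cls == "IntervalTier") {
      lab <- character(nint)
      t0 <- t1 <- numeric(nint)
      for (ii in seq_len(nint)) {
        t0[ii] <- as.numeric(take())
        t1[ii] <- as.numeric(take())
        lab[ii] <- unq(take())
      }
      want <- if (is.null(tier)) is.null(found) else identical(nm, tier)
      if (want && is.null(found))
        found <- data.frame(label = lab, t_start = t0, t_end = t1)
    } else {
      # point tier: n points of (time, mark)
      for (ii in seq_len(nint)) { take(); take() }
    }
  }
  if (is.null(found)) stop("no interval tier", if (!is.null(tier))
    paste0(" named '", tier, "'"), " in ", path)
  found <- found[nzchar(trimws(found$label)), , drop = FALSE]
  if (nrow(found) == 0L) stop("interval tier has no labeled intervals")
  phoneme_segmentation(found$label, found$t_start, found$t_end)
}

#' Write a phoneme segmentation
#'
#' @param seg a [phoneme_segmentation()].
#' @param path output path.
#' @param format `"csv"` (columns `label, t_start_s, t_end_s`) or
#'   `"textgrid"` (long-form TextGrid with one interval tier `phonemes`).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path, format = c("csv", "textgrid")) {
  stopifnot(inherits(seg, "phoneme_segmentation"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(data.frame(label = seg$label,
                                t_start_s = seg$t_start,
                                t_end_s = seg$t_end),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    num <- function(x) format(x, digits = 15, trim = TRUE)
    out <- c('File type = "ooTextFile"',
             'Object class = "TextGrid"',
             "",
             paste0("xmin = ", num(min(seg$t_start))),
             paste0("xmax = ", num(max(seg$t_end))),
             "tiers? <exists>",
             "size = 1",
             "item []:",
             "    item [1]:",
             '        class = "IntervalTier"',
             '        name = "phonemes"',
             paste0("        xmin = ", num(min(seg$t_start))),
             paste0("        xmax = ", num(max(seg$t_end))),
             paste0("        intervals: size = ", nrow(seg)))
    for (i in seq_len(nrow(seg))) {
      out <- c(out,
               paste0("        intervals [", i, "]:"),
               paste0("            xmin = ", num(seg$t_start[i])),
               paste0("            xmax = ", num(seg$t_end[i])),
               paste0('            text = "', seg$label[i], '"'))
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Read and write action plans as JSON
#'
#' The serialization is `{vtp0, strokes: [{D, t0, mu, sigma, theta_s,
#' theta_e}, ...]}`.
#'
#' @param plan an [action_plan()].
#' @param path file path.
#' @return `write_action_plan()` returns `path` invisibly;
#'   `read_action_plan()` returns an [action_plan()].
#' @export
write_action_plan <- function(plan, path) {
  stopifnot(inherits(plan, "action_plan"))
  jsonlite::write_json(list(vtp0 = plan$vtp0, strokes = plan$strokes),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_action_plan
#' @export
read_action_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  action_plan(as.data.frame(obj$strokes), vtp0 = as.numeric(obj$vtp0))
}

#' Write a stroke table as delimited text
#'
#' One row per lognormal: the six stroke parameters plus the recomputed
#' peak time, peak speed and 5% support bounds.
#'
#' @param strokes stroke data frame.
#' @param path output path.
#' @param level support level used for the bound columns.
#' @return `path`, invisibly.
#' @export
write_strokes <- function(strokes, path, level = 0.05) {
  strokes <- as_strokes(strokes)
  if (nrow(strokes) > 0L) {
    sup <- strokes_support(strokes, level)
    df <- cbind(strokes, peak_time = stroke_peak_time(strokes),
                peak_speed = stroke_peak_speed(strokes),
                support_begin = sup[, "t_begin"],
                support_end = sup[, "t_end"])
  } else {
    df <- cbind(strokes, peak_time = numeric(0), peak_speed = numeric(0),
                support_begin = numeric(0), support_end = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_strokes
#' @export
read_strokes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_strokes(as_strokes(df))
  as_strokes(df)
}

#' Read and write sampled signals as delimited text
#'
#' Column `t` plus one column per channel.
#'
#' @param x a [sampled_signal()].
#' @param path file path.
#' @return `write_signal()` returns `path` invisibly; `read_signal()`
#'   returns a [sampled_signal()] (the time grid must be uniform).
#' @export
write_signal <- function(x, path) {
  stopifnot(inherits(x, "sampled_signal"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  df <- utils::read.csv(path)
  if (!"t" %in% names(df) || ncol(df) < 2L)
    stop("parse error: expected a 't' column plus channels in ", path)
  t <- df$t
  d <- diff(t)
  if (length(d) == 0L || max(d) - min(d) > 1e-6 * mean(d))
    stop("signal time grid is not uniform in ", path)
  m <- as.matrix(df[setdiff(names(df), "t")])
  sampled_signal(m, dt = mean(d), t_start = t[1])
}
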