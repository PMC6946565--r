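#' Write tracks to a plain-text file
#'
#' Two dialects are supported: `"csv"` (default) with header
#' `track_id,t,x,y[,state]`, and `"xyt"`, the whitespace-delimited
#' headerless `x y t track_id` layout of single-molecule tracker output
#' files. Numbers are written with 6 significant digits in a fixed column
#' order, so identical input yields byte-identical files.
#'
#' @param ts A [trackset()].
#' @param path Output file path.
#' @param dialect `"csv"` or `"xyt"`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path, dialect = c("csv", "xyt")) {
  dialect <- match.arg(dialect)
  d <- as.data.frame(ts)
  fmt <- function(v) sprintf("%.6g", v)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "csv") {
    has_state <- !is.null(d$state)
    writeLines(paste(c("track_id", "t", "x", "y",
                       if (has_state) "state"), collapse = ","), con)
    if (nrow(d)) {
      lines <- paste(d$track_id, fmt(d$t), fmt(d$x), fmt(d$y), sep = ",")
      if (has_state) lines <- paste(lines, d$state, sep = ",")
      writeLines(lines, con)
    }
  } else {
    if (nrow(d))
      writeLines(paste(fmt(d$x), fmt(d$y), fmt(d$t), d$track_id), con)
  }
  invisible(path)
}

#' Read tracks from a plain-text file
#'
#' Parses the `"csv"` (`track_id,t,x,y[,state]`, with header) or `"xyt"`
#' (whitespace-delimited `x y t [track_id]`, no header) dialect written by
#' [write_tracks()] or produced by single-molecule tracking software. An
#' `xyt` file without an id column is read as one track. Malformed lines
#' are reported with their line numbers; times must be strictly increasing
#' within each track.
#'
#' @param path Input file path.
#' @param dialect `"auto"` (sniff the first line), `"csv"` or `"xyt"`.
#' @return A [trackset()].
#' @export
read_tracks <- function(path, dialect = c("auto", "csv", "xyt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (dialect == "auto")
    dialect <- if (length(lines) && grepl("^track_id,", lines[1]))
      "csv" else "xyt"
  if (dialect == "csv") {
    if (!length(lines) || !grepl("^track_id,", lines[1]))
      stop("missing 'track_id,t,x,y' header in ", path, call. = FALSE)
    header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    if (!all(c("track_id", "t", "x", "y") %in% header))
      stop("missing required column(s) in ", path, ": expected track_id,t,x,y",
           call. = FALSE)
    has_state <- "state" %in% header
    body <- lines[-1]
    parts <- strsplit(body, ",", fixed = TRUE)
    nf <- lengths(parts)
    id_col <- match("track_id", header); t_col <- match("t", header)
    x_col <- match("x", header); y_col <- match("y", header)
    s_col <- match("state", header)
    get <- function(col) vapply(parts, function(p)
      if (length(p) >= col) p[col] else NA_character_, character(1))
    tv <- suppressWarnings(as.numeric(get(t_col)))
    xv <- suppressWarnings(as.numeric(get(x_col)))
    yv <- suppressWarnings(as.numeric(get(y_col)))
    bad <- which(nf < length(header) | is.na(tv) | is.na(xv) | is.na(yv))
    if (length(bad))
      stop("malformed line(s) ", paste(utils::head(bad + 1L, 5),
                                       collapse = ", "),
           " in ", path, call. = FALSE)
    d <- data.frame(track_id = get(id_col), t = tv, x = xv, y = yv,
                    stringsAsFactors = FALSE)
    if (has_state) d$state <- get(s_col)
  } else {
    body <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    nf <- lengths(parts)
    if (length(nf) && any(nf < 3L))
      stop("malformed line(s) ",
           paste(utils::head(which(nf < 3L), 5), collapse = ", "),
           " in ", path, call. = FALSE)
    xv <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1)))
    yv <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
    tv <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
    idv <- vapply(parts, function(p)
      if (length(p) >= 4L) p[4] else "1", character(1))
    bad <- which(is.na(xv) | is.na(yv) | is.na(tv))
    if (length(bad))
      stop("malformed line(s) ", paste(utils::head(bad, 5), collapse = ", "),
           " in ", path, call. = FALSE)
    d <- data.frame(track_id = idv, t = tv, x = xv, y = yv,
                    stringsAsFactors = FALSE)
  }
  ids <- unique(d$track_id)
  tracks <- lapply(ids, function(id) {
    di <- d[d$track_id == id, , drop = FALSE]
    if (any(diff(di$t) <= 0))
      stop("non-monotone time in track '", id, "' of ", path, call. = FALSE)
    gc_track(id = id, t = di$t, x = di$x, y = di$y, state = di$state)
  })
  trackset(tracks, metadata = list(source = path, dialect = dialect))
}
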