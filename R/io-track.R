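#' Conservation tracks
#'
#' A `conservation_track` is a per-chromosome sparse map from 0-based base
#' position to a score in [0,1] (phastCons-style posterior probabilities).
#' Internally each chromosome holds two parallel vectors (`pos`, `score`)
#' sorted by position.
#'
#' @param chrom_maps named list; each element a list with integer `pos` and
#'   numeric `score` vectors of equal length.
#' @return a `conservation_track`.
#' @export
conservation_track <- function(chrom_maps) {
  for (chrom in names(chrom_maps)) {
    m <- chrom_maps[[chrom]]
    stopifnot(length(m$pos) == length(m$score))
    if (any(m$pos < 0L)) stop("negative track position")
    if (any(m$score < 0 | m$score > 1))
      stop("conservation score outside [0,1]")
    if (anyDuplicated(m$pos))
      stop(sprintf("overlapping track records on %s", chrom))
    ord <- order(m$pos)
    chrom_maps[[chrom]] <- list(pos = as.integer(m$pos[ord]),
                                score = as.numeric(m$score[ord]))
  }
  structure(chrom_maps, class = "conservation_track")
}

#' Read a conservation track
#'
#' Accepts bedGraph (`chrom start end value`, 0-based half-open) or
#' fixedStep WIG (`fixedStep chrom=... start=... step=...` headers with
#' 1-based starts). Every covered base is mapped to its score; overlapping
#' records and scores outside [0,1] are errors.
#'
#' @param path file path.
#' @return a [conservation_track].
#' @export
read_conservation_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  pos_by <- list(); score_by <- list()
  push <- function(chrom, pos, score) {
    pos_by[[chrom]] <<- c(pos_by[[chrom]], pos)
    score_by[[chrom]] <<- c(score_by[[chrom]], score)
  }
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[[i]]
    if (startsWith(line, "fixedStep")) {
      kv <- parse_wig_header(line)
      j <- i + 1L
      vals <- c()
      while (j <= length(lines) && !startsWith(lines[[j]], "fixedStep")) {
        vals <- c(vals, as.numeric(lines[[j]])); j <- j + 1L
      }
      if (any(is.na(vals))) stop("non-numeric WIG value")
      # fixedStep starts are 1-based
      pos <- kv$start - 1L + kv$step * (seq_along(vals) - 1L)
      push(kv$chrom, pos, vals)
      i <- j
    } else {
      fields <- strsplit(line, "[ \t]+")[[1L]]
      if (length(fields) != 4L)
        stop(sprintf("bedGraph line with %d fields: '%s'",
                     length(fields), line))
      start <- as.integer(fields[2L]); end <- as.integer(fields[3L])
      value <- as.numeric(fields[4L])
      if (is.na(start) || is.na(end) || is.na(value) || end <= start)
        stop(sprintf("malformed bedGraph line: '%s'", line))
      push(fields[1L], seq.int(start, end - 1L), rep(value, end - start))
      i <- i + 1L
    }
  }
  conservation_track(lapply(stats::setNames(nm = names(pos_by)), function(ch)
    list(pos = pos_by[[ch]], score = score_by[[ch]])))
}

parse_wig_header <- function(line) {
  get <- function(key) {
    m <- regmatches(line, regexec(paste0(key, "=(\\S+)"), line))[[1L]]
    if (length(m) != 2L) stop(sprintf("fixedStep header missing %s", key))
    m[2L]
  }
  list(chrom = get("chrom"), start = as.integer(get("start")),
       step = as.integer(get("step")))
}

#' Write a conservation track as bedGraph
#'
#' Runs of consecutive bases with identical score are merged into single
#' bedGraph records.
#'
#' @param track a [conservation_track].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conservation_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    m <- track[[chrom]]
    if (length(m$pos) == 0L) next
    # break into runs of consecutive positions with equal score
    brk <- c(TRUE, diff(m$pos) != 1L | diff(m$score) != 0)
    run <- cumsum(brk)
    starts <- tapply(m$pos, run, function(p) p[1L])
    ends <- tapply(m$pos, run, function(p) p[length(p)] + 1L)
    vals <- tapply(m$score, run, function(s) s[1L])
    writeLines(paste(chrom, starts, ends,
                     format_score(vals), sep = "\t"), con)
  }
  invisible(path)
}

format_score <- function(x) formatC(x, format = "g", digits = 15)

#' Look up per-base scores over an interval
#' @param track a [conservation_track].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return numeric vector of scores at covered bases (uncovered bases are
#'   dropped, not returned as NA).
#' @export
track_scores <- function(track, chrom, start, end) {
  m <- track[[chrom]]
  if (is.null(m)) return(numeric(0))
  sel <- m$pos >= start & m$pos < end
  m$score[sel]
}
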