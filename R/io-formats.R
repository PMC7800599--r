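# File formats: BED peak tables, WIG signal tracks. Readers validate and
# report offending line numbers; writers round-trip exactly. BED files are
# 0-based half-open and WIG files 1-based on disk; both are converted to the
# internal 1-based closed GRanges / Rle representation on read.

#' Read peak records from BED
#'
#' Accepts BED3 and wider. Column 4 is the peak name, column 5 a numeric
#' score; with `summit_col = TRUE` column 7 is interpreted as the summit
#' offset in bp from the peak start (the narrowPeak-style dialect some peak
#' callers emit). `track`, `browser` and `#` comment lines are permitted.
#' A `.` in the name or score column reads as missing.
#'
#' @param path Path to a BED file.
#' @param summit_col Interpret column 7 as a summit offset.
#' @return A `GRanges` (1-based closed) with metadata columns `name`, `score`
#'   and `summit` (0-based offset from peak start, `NA` when absent), in file
#'   order.
#' @export
read_bed <- function(path, summit_col = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(name = character(), score = numeric(), summit = integer())
    return(gr)
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stopf("BED line %d: fewer than 3 columns", lineno[which(nf < 3)[1]])
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get_col(1)
  start0 <- suppressWarnings(as.numeric(get_col(2)))
  end0 <- suppressWarnings(as.numeric(get_col(3)))
  bad <- is.na(start0) | is.na(end0) | start0 != floor(start0) | end0 != floor(end0)
  if (any(bad)) stopf("BED line %d: non-integer coordinate field", lineno[which(bad)[1]])
  bad <- start0 < 0
  if (any(bad)) stopf("BED line %d: negative coordinate", lineno[which(bad)[1]])
  bad <- start0 >= end0
  if (any(bad)) stopf("BED line %d: start >= end", lineno[which(bad)[1]])

  name <- get_col(4)
  name[!is.na(name) & name == "."] <- NA_character_
  score_raw <- get_col(5)
  score <- suppressWarnings(as.numeric(ifelse(is.na(score_raw) | score_raw == ".", NA, score_raw)))
  bad <- !is.na(score_raw) & score_raw != "." & is.na(score)
  if (any(bad)) stopf("BED line %d: non-numeric score", lineno[which(bad)[1]])
  summit <- rep(NA_integer_, length(lines))
  if (summit_col) {
    s_raw <- get_col(7)
    s <- suppressWarnings(as.numeric(ifelse(is.na(s_raw) | s_raw %in% c(".", "-1"), NA, s_raw)))
    bad <- !is.na(s) & (s < 0 | s >= end0 - start0 | s != floor(s))
    if (any(bad)) stopf("BED line %d: summit offset outside the peak", lineno[which(bad)[1]])
    summit <- as.integer(s)
  }
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  mcols(gr) <- DataFrame(name = name, score = score, summit = summit)
  gr
}

#' Write peak records as BED
#'
#' Inverse of [read_bed()]: coordinates are written 0-based half-open; records
#' keep their input order. A record with no score is written as a 4-column
#' line (or 3 columns if it also has no name); records with a summit carry it
#' in column 7 with `.` placeholders in columns 5-6 as needed.
#'
#' @param peaks `GRanges` with optional `name`, `score`, `summit` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  n <- length(peaks)
  name <- if (!is.null(peaks$name)) peaks$name else rep(NA_character_, n)
  score <- if (!is.null(peaks$score)) peaks$score else rep(NA_real_, n)
  summit <- if (!is.null(peaks$summit)) peaks$summit else rep(NA_integer_, n)
  # number of columns each record needs
  ncols <- ifelse(!is.na(summit), 7L, ifelse(!is.na(score), 5L, ifelse(!is.na(name), 4L, 3L)))
  cols <- cbind(as.character(seqnames(peaks)),
                sprintf("%d", start(peaks) - 1L),
                sprintf("%d", end(peaks)),
                ifelse(is.na(name), ".", name),
                ifelse(is.na(score), ".", format_num(score)),
                ".",
                ifelse(is.na(summit), ".", sprintf("%d", summit)))
  out <- vapply(seq_len(n), function(i) paste(cols[i, seq_len(ncols[i])], collapse = "\t"), "")
  writeLines(out, path)
  invisible(path)
}

#' Construct a signal track
#'
#' A signal track stores one numeric value (or `NA` for "no data") per base of
#' each chromosome, as run-length-encoded vectors.
#'
#' @param values Named list of `S4Vectors::Rle` vectors (one per chromosome)
#'   or plain numeric vectors. Chromosomes in `sizes` that are absent from
#'   `values` are filled with `NA`.
#' @param sizes Named chromosome lengths.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, sizes) {
  sizes <- chrom_sizes(sizes)
  unknown <- setdiff(names(values), names(sizes))
  if (length(unknown)) stopf("track chromosome(s) not in chrom sizes: %s", paste(unknown, collapse = ", "))
  vals <- lapply(names(sizes), function(ch) {
    v <- values[[ch]]
    if (is.null(v)) return(Rle(NA_real_, sizes[[ch]]))
    v <- as(v, "Rle")
    if (length(v) != sizes[[ch]])
      stopf("track for %s has length %d, chromosome length is %d", ch, length(v), sizes[[ch]])
    v
  })
  names(vals) <- names(sizes)
  structure(list(values = vals, sizes = sizes), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  def <- vapply(x$values, function(v) sum(runLength(v)[!is.na(runValue(v))]), 0)
  cat(sprintf("signal_track: %d chromosome(s), %.0f/%0.f bp with data\n",
              length(x$values), sum(def), sum(x$sizes)))
  invisible(x)
}

#' Per-base values of a signal track over an interval
#'
#' @param track A `signal_track`.
#' @param chrom Chromosome name.
#' @param start,end 1-based closed interval bounds.
#' @return Numeric vector of length `end - start + 1` (`NA` where no data).
#' @export
track_values <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stopf("chromosome %s not in track", chrom)
  as.numeric(v[start:end])
}

.parse_kv <- function(line) {
  parts <- strsplit(trimws(line), "[ \t]+")[[1]][-1]
  kv <- strsplit(parts, "=")
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

#' Read a WIG signal track
#'
#' Parses fixedStep and variableStep blocks (UCSC WIG dialect, 1-based
#' coordinates, `span`/`step` defaults of 1) into a [signal_track()]. Bases
#' not covered by any block carry the "no data" state (`NA`).
#'
#' @param path Path to a WIG file.
#' @param sizes Named chromosome lengths; declarations on unknown chromosomes
#'   or spans running past a chromosome end are rejected with the declaration
#'   line number.
#' @return A `signal_track`.
#' @export
read_wig <- function(path, sizes) {
  sizes <- chrom_sizes(sizes)
  lines <- readLines(path)
  is_decl <- grepl("^(fixedStep|variableStep)", lines)
  is_skip <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
  runs <- list()  # per block: data.frame(chrom, start1, end1, value)
  block_starts <- which(is_decl)
  first_data <- which(!is_skip & !is_decl)[1]
  if (!is.na(first_data) &&
      (length(block_starts) == 0 || first_data < block_starts[1]))
    stopf("WIG line %d: data before any fixedStep/variableStep declaration", first_data)
  block_ends <- c(block_starts[-1] - 1L, length(lines))
  for (b in seq_along(block_starts)) {
    decl_line <- block_starts[b]
    kv <- .parse_kv(lines[decl_line])
    chrom <- kv[["chrom"]]
    if (is.na(chrom) || !(chrom %in% names(sizes)))
      stopf("WIG line %d: unknown chromosome '%s'", decl_line, chrom)
    span <- as.integer(kv["span"] %na% "1")
    body_idx <- setdiff(seq(decl_line + 1L, length.out = max(block_ends[b] - decl_line, 0)),
                        which(is_skip))
    body <- lines[body_idx]
    if (grepl("^fixedStep", lines[decl_line])) {
      start1 <- as.integer(kv[["start"]])
      step <- as.integer(kv["step"] %na% "1")
      vals <- suppressWarnings(as.numeric(body))
      if (anyNA(vals) && length(body))
        stopf("WIG line %d: non-numeric value in fixedStep block", body_idx[which(is.na(vals))[1]])
      if (length(vals)) {
        starts <- start1 + (seq_along(vals) - 1L) * step
        if (starts[length(starts)] + span - 1L > sizes[[chrom]] || start1 < 1)
          stopf("WIG line %d: block extends beyond chromosome %s", decl_line, chrom)
        runs[[length(runs) + 1]] <- data.frame(chrom = chrom, start = starts,
                                               end = starts + span - 1L, value = vals)
      }
    } else {
      if (length(body)) {
        mat <- strsplit(body, "[ \t]+")
        pos <- suppressWarnings(as.integer(vapply(mat, `[`, "", 1)))
        vals <- suppressWarnings(as.numeric(vapply(mat, `[`, "", 2)))
        if (anyNA(pos) || anyNA(vals))
          stopf("WIG line %d: malformed variableStep data line",
                body_idx[which(is.na(pos) | is.na(vals))[1]])
        if (any(pos < 1) || any(pos + span - 1L > sizes[[chrom]]))
          stopf("WIG line %d: block extends beyond chromosome %s", decl_line, chrom)
        runs[[length(runs) + 1]] <- data.frame(chrom = chrom, start = pos,
                                               end = pos + span - 1L, value = vals)
      }
    }
  }
  allruns <- if (length(runs)) do.call(rbind, runs) else
    data.frame(chrom = character(), start = integer(), end = integer(), value = numeric())
  vals <- lapply(names(sizes), function(ch) {
    r <- allruns[allruns$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0) return(Rle(NA_real_, sizes[[ch]]))
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
      stopf("WIG: overlapping spans on chromosome %s", ch)
    gap_before <- r$start - c(0L, r$end[-nrow(r)]) - 1L
    tail_gap <- sizes[[ch]] - r$end[nrow(r)]
    lens <- as.vector(rbind(gap_before, r$end - r$start + 1L))
    vv <- as.vector(rbind(NA_real_, r$value))
    if (tail_gap > 0) { lens <- c(lens, tail_gap); vv <- c(vv, NA_real_) }
    keep <- lens > 0
    Rle(vv[keep], lens[keep])
  })
  names(vals) <- names(sizes)
  signal_track(vals, sizes)
}

`%na%` <- function(a, b) if (is.na(a)) b else a

#' Write a signal track as WIG
#'
#' Inverse of [read_wig()]. Runs of constant value become spans; consecutive
#' equal-width contiguous spans are emitted as one fixedStep block
#' (`step = span = width`), isolated spans as variableStep blocks. Bases with
#' no data are simply not covered, so gaps survive a round trip.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    rl <- runLength(v); rv <- runValue(v)
    ends <- cumsum(rl)
    starts <- ends - rl + 1L
    keep <- !is.na(rv)
    if (!any(keep)) next
    starts <- starts[keep]; ends <- ends[keep]; vals <- rv[keep]; w <- ends - starts + 1L
    n <- length(starts)
    # new block when not contiguous with previous run or width changes
    newblk <- c(TRUE, starts[-1] != ends[-n] + 1L | w[-1] != w[-n])
    blk <- cumsum(newblk)
    for (bi in unique(blk)) {
      i <- which(blk == bi)
      if (length(i) >= 2) {
        writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                           ch, starts[i[1]], w[i[1]], w[i[1]]), con)
        writeLines(format_num(vals[i]), con)
      } else {
        writeLines(sprintf("variableStep chrom=%s span=%d", ch, w[i]), con)
        writeLines(sprintf("%d %s", starts[i], format_num(vals[i])), con)
      }
    }
  }
  invisible(path)
}
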