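#' Read a per-base depth track from bedGraph
#'
#' @param path bedGraph file (0-based half-open intervals with a depth
#'   value). Intervals must be non-overlapping; rows are sorted on read.
#' @return data frame with columns `chrom`, `start`, `end`, `depth`
#'   (run-length representation; positions absent from the track have
#'   depth 0).
#' @export
read_depth_track <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop("failed to parse bedGraph '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  track <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      depth = as.numeric(S4Vectors::mcols(gr)$score),
                      stringsAsFactors = FALSE)
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  rownames(track) <- NULL
  validate_track(track)
  track
}

validate_track <- function(track) {
  stopifnot_cols(track, c("chrom", "start", "end", "depth"), "depth track")
  if (any(track$depth < 0)) stop("negative depth in track", call. = FALSE)
  if (any(track$start >= track$end)) {
    stop("empty interval in depth track", call. = FALSE)
  }
  for (ch in unique(track$chrom)) {
    sel <- track[track$chrom == ch, ]
    if (nrow(sel) > 1 && any(sel$start[-1] < sel$end[-nrow(sel)])) {
      stop("overlapping intervals in depth track on ", ch, call. = FALSE)
    }
  }
  invisible(track)
}

#' @rdname read_depth_track
#' @param track depth track data frame.
#' @export
write_depth_track <- function(track, path) {
  validate_track(track[order(track$chrom, track$start), , drop = FALSE])
  lines <- paste(track$chrom, track$start, track$end,
                 format(track$depth, trim = TRUE, scientific = FALSE),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Depth lookup at positions
#'
#' @param track depth track from [read_depth_track()].
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return numeric vector of depths; 0 where the track has no interval.
#' @export
depth_at <- function(track, chrom, pos) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(tr) == 0) next
    idx <- findInterval(pos[sel], tr$start)
    hit <- idx >= 1 & idx <= nrow(tr)
    hit[hit] <- pos[sel][hit] < tr$end[idx[hit]]
    out[sel[hit]] <- tr$depth[idx[hit]]
  }
  out
}

# Run-length encode per-position depths (positions 0-based, need not be
# contiguous; zero depths are dropped).
track_from_depths <- function(chrom, pos, depth) {
  keep <- depth > 0
  pos <- pos[keep]; depth <- depth[keep]; chrom <- chrom[keep]
  if (length(pos) == 0) {
    return(empty_df(list(chrom = character(), start = integer(),
                         end = integer(), depth = numeric())))
  }
  ord <- order(chrom, pos)
  pos <- pos[ord]; depth <- depth[ord]; chrom <- chrom[ord]
  new_run <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                 pos[-1] != pos[-length(pos)] + 1L |
                 depth[-1] != depth[-length(depth)])
  run_id <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, length(pos))
  data.frame(chrom = chrom[first], start = pos[first],
             end = pos[last] + 1L, depth = depth[first],
             stringsAsFactors = FALSE)
}

# Per-position depths of a track inside [start, end); returns positions with
# a track interval only (uncovered positions are implicit zeros).
track_positions <- function(track, chrom, start, end) {
  tr <- track[track$chrom == chrom & track$end > start & track$start < end, ,
              drop = FALSE]
  if (nrow(tr) == 0) {
    return(data.frame(pos = integer(0), depth = numeric(0)))
  }
  pos <- unlist(lapply(seq_len(nrow(tr)), function(i) {
    seq.int(max(tr$start[i], start), min(tr$end[i], end) - 1L)
  }))
  depth <- rep(tr$depth, pmin(tr$end, end) - pmax(tr$start, start))
  data.frame(pos = pos, depth = depth)
}
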