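#' Construct a methylome object
#'
#' A methylome is the canonical in-memory container for per-CpG counts from a
#' single WGBS sample: a data.frame with columns \code{chrom}, \code{pos}
#' (0-based position of the C on the plus strand), \code{meth} and
#' \code{unmeth} (read counts), carrying \code{sample_id}, \code{tissue} and
#' \code{condition} as attributes. Sites are kept strictly sorted by
#' \code{(chrom, pos)}; duplicate positions within a chromosome are an error.
#'
#' All internal coordinates in this package are 0-based half-open; conversion
#' to/from 1-based conventions happens only at file boundaries.
#'
#' @param sites data.frame with columns chrom, pos, meth, unmeth.
#' @param sample_id sample identifier.
#' @param tissue tissue label.
#' @param condition one of "normal", "cancer", "metastasis".
#' @return An object of class \code{methylome}.
#' @export
methylome <- function(sites, sample_id = "sample", tissue = "unknown",
                      condition = c("normal", "cancer", "metastasis")) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "meth", "unmeth") %in% names(sites)))
  sites <- as.data.frame(sites)[, c("chrom", "pos", "meth", "unmeth")]
  sites$chrom <- as.character(sites$chrom)
  if (nrow(sites) > 0) {
    if (any(sites$meth < 0) || any(sites$unmeth < 0))
      stop("negative read counts are not allowed")
    if (any(sites$pos < 0)) stop("negative positions are not allowed")
    o <- order(sites$chrom, sites$pos)
    if (is.unsorted(o, strictly = TRUE) || any(o != seq_len(nrow(sites)))) {
      warning("sites were not sorted by (chrom, pos); sorting on load")
      sites <- sites[o, , drop = FALSE]
      rownames(sites) <- NULL
    }
    dup <- duplicated(sites[, c("chrom", "pos")])
    if (any(dup)) stop("duplicate CpG positions within a chromosome")
  }
  structure(sites, class = c("methylome", "data.frame"),
            sample_id = sample_id, tissue = tissue, condition = condition)
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("methylome '%s' (%s, %s): %d CpG sites on %d chromosome(s)\n",
              attr(x, "sample_id"), attr(x, "tissue"), attr(x, "condition"),
              nrow(x), length(unique(x$chrom))))
  invisible(x)
}

#' Per-site raw methylation level
#'
#' \code{meth / (meth + unmeth)}; \code{NA} (undefined) at zero coverage.
#' Vectorized over sites.
#'
#' @param meth methylated counts (or a methylome, in which case unmeth is
#'   taken from it).
#' @param unmeth unmethylated counts.
#' @return numeric vector in \[0, 1\], NA where coverage is zero.
#' @export
methylation_level <- function(meth, unmeth) {
  if (inherits(meth, "methylome")) {
    unmeth <- meth$unmeth
    meth <- meth$meth
  }
  cov <- meth + unmeth
  ifelse(cov > 0, meth / cov, NA_real_)
}

#' Read a Bismark-style coverage file
#'
#' Six tab-separated columns: chrom, start (1-based), end (1-based), percent
#' methylation, methylated count, unmethylated count. The percent column is
#' ignored and recomputed from counts; positions are shifted to 0-based.
#'
#' @param path file path.
#' @inheritParams methylome
#' @return a \code{methylome}.
#' @export
read_bismark_coverage <- function(path, sample_id = basename(path),
                                  tissue = "unknown", condition = "normal") {
  if (file.size(path) == 0)
    return(methylome(data.frame(chrom = character(), pos = integer(),
                                meth = integer(), unmeth = integer()),
                     sample_id, tissue, condition))
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0)
    return(methylome(data.frame(chrom = character(), pos = integer(),
                                meth = integer(), unmeth = integer()),
                     sample_id, tissue, condition))
  if (ncol(dt) < 6)
    stop("coverage file must have 6 tab-separated columns, found ", ncol(dt))
  num <- lapply(dt[, 2:6], function(col) suppressWarnings(as.numeric(col)))
  bad <- Reduce(`|`, lapply(num, is.na))
  if (any(bad))
    stop("parse error in coverage file at line ", which(bad)[1])
  if (any(num[[4]] < 0) || any(num[[5]] < 0))
    stop("negative read count in coverage file at line ",
         which(num[[4]] < 0 | num[[5]] < 0)[1])
  sites <- data.frame(chrom = dt[[1]], pos = as.integer(num[[1]] - 1L),
                      meth = as.integer(num[[4]]),
                      unmeth = as.integer(num[[5]]))
  methylome(sites, sample_id, tissue, condition)
}

#' Write a methylome as a Bismark-style coverage file
#'
#' Inverse of \code{\link{read_bismark_coverage}} (1-based output, percent
#' recomputed; 0 at zero coverage).
#'
#' @param m a methylome.
#' @param path output path.
#' @param header emit a header line (default FALSE).
#' @export
write_bismark_coverage <- function(m, path, header = FALSE) {
  lev <- methylation_level(m)
  out <- data.table::data.table(
    chrom = m$chrom, start = m$pos + 1L, end = m$pos + 1L,
    pct = round(100 * ifelse(is.na(lev), 0, lev), 6),
    meth = m$meth, unmeth = m$unmeth)
  data.table::fwrite(out, path, sep = "\t", col.names = header)
  invisible(path)
}

#' Pool symmetric-CpG strand counts
#'
#' Records at adjacent positions (p, p+1) on the same chromosome are taken to
#' be the two strands of one CpG and pooled into a single site at p (the
#' plus-strand coordinate) with summed counts. Pairing is greedy
#' left-to-right: in a run of consecutive positions, (p, p+1) pool first, then
#' scanning continues after p+1. Unpaired sites pass through. Total counts are
#' conserved.
#'
#' @param m a methylome.
#' @return a methylome with pooled counts.
#' @export
merge_strand_counts <- function(m) {
  if (nrow(m) < 2) return(m)
  chrom <- m$chrom; pos <- m$pos
  n <- nrow(m)
  adj <- c(chrom[-n] == chrom[-1] & pos[-1] == pos[-n] + 1L, FALSE)
  pair_first <- logical(n)
  i <- 1L
  while (i < n) {
    if (adj[i]) {
      pair_first[i] <- TRUE
      i <- i + 2L
    } else i <- i + 1L
  }
  second <- c(FALSE, pair_first[-n])
  meth <- m$meth; unmeth <- m$unmeth
  meth[pair_first] <- meth[pair_first] + meth[which(pair_first) + 1L]
  unmeth[pair_first] <- unmeth[pair_first] + unmeth[which(pair_first) + 1L]
  keep <- !second
  methylome(data.frame(chrom = chrom[keep], pos = pos[keep],
                       meth = meth[keep], unmeth = unmeth[keep]),
            attr(m, "sample_id"), attr(m, "tissue"), attr(m, "condition"))
}

#' Read genomic intervals from a BED3/BED4 file
#'
#' Coordinates are 0-based half-open. A fourth column, if present, is kept as
#' \code{name}.
#'
#' @param path file path.
#' @return data.frame with columns chrom, start, end and optionally name.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  out <- data.frame(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]))
  if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
  if (any(out$start >= out$end))
    stop("invalid interval (start >= end) at line ",
         which(out$start >= out$end)[1])
  out
}

#' Write genomic intervals as BED
#'
#' @param intervals data.frame with chrom, start, end and optional further
#'   columns (written in order after the first three).
#' @param path output path.
#' @param header emit a header line (default FALSE).
#' @export
write_bed <- function(intervals, path, header = FALSE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0 && any(intervals$start >= intervals$end))
    stop("invalid interval (start >= end)")
  cols <- c("chrom", "start", "end",
            setdiff(names(intervals), c("chrom", "start", "end")))
  data.table::fwrite(intervals[, cols, drop = FALSE], path, sep = "\t",
                     col.names = header)
  invisible(path)
}

#' Write a bedGraph track (4 columns, value per interval)
#'
#' Used for smoothed methylation levels (one 1-bp interval per CpG) and for
#' simulated histone signal.
#'
#' @param chrom,start,end,value parallel vectors, or a data.frame in `chrom`.
#' @param path output path.
#' @export
write_bedgraph <- function(chrom, start = NULL, end = NULL, value = NULL,
                           path) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  } else {
    df <- data.frame(chrom = chrom, start = start, end = end, value = value)
  }
  data.table::fwrite(df[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#' @param path file path.
#' @return data.frame with chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
             end = as.integer(dt[[3]]), value = as.numeric(dt[[4]]))
}
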