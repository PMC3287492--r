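#' Copy-number matrix container
#'
#' Bundles an n x T matrix of per-segment mean copy numbers (linear scale,
#' ~2 for diploid) with the segment grid the columns refer to. This is the
#' observation object consumed by every downstream stage: each row is one
#' sample's piecewise-constant copy-number profile on a genome-wide grid of
#' T segments shared by all samples.
#'
#' @param values numeric matrix, samples x segments; all entries must be
#'   positive and finite.
#' @param sample_ids character vector of sample identifiers, one per row.
#' @param grid data frame with columns `chromosome`, `start`, `end`
#'   describing the segment of each column, sorted by chromosome then start.
#' @return An object of class `cn_matrix`: a list with elements `values`
#'   (the matrix, with row and column names set), `sample_ids`, and `grid`.
#' @examples
#' g <- data.frame(chromosome = "1", start = c(1, 501), end = c(500, 1000))
#' m <- cn_matrix(matrix(2, 2, 2), c("S1", "S2"), g)
#' dim(m$values)
#' @export
cn_matrix <- function(values, sample_ids, grid) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (length(sample_ids) != nrow(values))
    stop("length of 'sample_ids' must equal nrow(values)")
  grid <- validate_grid(grid)
  if (nrow(grid) != ncol(values))
    stop("grid has ", nrow(grid), " segments but matrix has ",
         ncol(values), " columns")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all copy-number values must be positive and finite")
  rownames(values) <- sample_ids
  colnames(values) <- segment_names(grid)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 grid = grid),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat("Copy-number matrix: ", length(x$sample_ids), " samples x ",
      nrow(x$grid), " segments on ",
      length(unique(x$grid$chromosome)), " chromosome(s)\n", sep = "")
  cat("Value range: [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.cn_matrix <- function(x) dim(x$values)

segment_names <- function(grid) {
  paste0(grid$chromosome, ":", grid$start, "-", grid$end)
}

validate_grid <- function(grid) {
  need <- c("chromosome", "start", "end")
  if (!all(need %in% names(grid)))
    stop("grid must have columns chromosome, start, end")
  grid <- as.data.frame(grid)[need]
  grid$chromosome <- as.character(grid$chromosome)
  if (any(grid$start > grid$end)) stop("grid has start > end")
  grid
}

# Chromosome run-length encoding of grid columns, in column order.
# Used by the HMM to reset the chain at chromosome boundaries.
chromosome_runs <- function(grid) {
  rle(as.character(grid$chromosome))
}

#' Read a SEG-like table of per-sample copy-number segments
#'
#' Parses a tab-delimited segmentation table (one row per sample-segment,
#' as produced by CBS-style segmentation) with header columns
#' `sample`, `chromosome`, `start`, `end`, `mean`. Values are converted to
#' linear copy number internally: a `log2` dialect value v becomes
#' 2 * 2^v, so a log2-ratio of 0 is diploid (copy number 2). Rows on sex
#' chromosomes (X, Y, chrX, chrY, 23, 24) are dropped, with a message, to
#' avoid gender-driven artefacts in downstream clustering; rows with
#' non-positive linear copy number are rejected with a warning.
#'
#' @param path path to the tab-delimited file.
#' @param dialect either `"linear"` (mean column is linear copy number) or
#'   `"log2"` (mean column is a log2 ratio relative to diploid).
#' @return data frame of segment records with columns `sample_id`,
#'   `chromosome`, `start`, `end`, `mean_cn` (always linear copy number).
#' @seealso [build_union_grid()], [summarize_to_matrix()]
#' @export
read_seg_table <- function(path, dialect = c("linear", "log2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- trimws(tolower(names(df)))
  need <- c("sample", "chromosome", "start", "end", "mean")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("segment table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  rec <- data.frame(
    sample_id  = as.character(df$sample),
    chromosome = sub("^chr", "", as.character(df$chromosome)),
    start      = as.integer(df$start),
    end        = as.integer(df$end),
    mean_cn    = as.numeric(df$mean),
    stringsAsFactors = FALSE
  )
  sex <- rec$chromosome %in% c("X", "Y", "23", "24")
  if (any(sex)) {
    message("Dropped ", sum(sex), " sex-chromosome segment(s)")
    rec <- rec[!sex, , drop = FALSE]
  }
  if (dialect == "log2") rec$mean_cn <- 2 * 2^rec$mean_cn
  bad <- !is.finite(rec$mean_cn) | rec$mean_cn <= 0
  if (any(bad)) {
    warning("Rejected ", sum(bad),
            " segment record(s) with non-positive copy number")
    rec <- rec[!bad, , drop = FALSE]
  }
  if (any(rec$start > rec$end)) stop("segment with start > end in ", path)
  rec
}

#' Build the union segment grid across samples
#'
#' Collects, per chromosome, every distinct segment boundary observed in any
#' sample and tiles the intervals between consecutive union breakpoints.
#' This converts per-sample segmentations (with sample-specific breakpoints)
#' into a common grid on which all samples can be compared; T is the total
#' number of union intervals. Coordinates are 1-based and inclusive, so a
#' breakpoint between adjacent segments [a,b] and [b+1,c] splits the union
#' grid at b|b+1.
#'
#' @param records data frame of segment records as from [read_seg_table()].
#' @return data frame (grid) with columns `chromosome`, `start`, `end`,
#'   sorted by chromosome then start.
#' @export
build_union_grid <- function(records) {
  if (nrow(records) == 0) stop("no segment records")
  chroms <- unique(records$chromosome)
  # order autosome labels numerically when possible
  num <- suppressWarnings(as.numeric(chroms))
  chroms <- chroms[order(is.na(num), num, chroms)]
  out <- lapply(chroms, function(ch) {
    r <- records[records$chromosome == ch, , drop = FALSE]
    # breakpoints: interval left edges (start) and right edges (end).
    # In 1-based inclusive coordinates, cut points are starts-1 and ends.
    cuts <- sort(unique(c(r$start - 1L, r$end)))
    data.frame(chromosome = ch,
               start = cuts[-length(cuts)] + 1L,
               end   = cuts[-1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize segment records onto a common grid
#'
#' Computes the sample x segment matrix of mean copy numbers: cell (j, t) is
#' the length-weighted mean of sample j's source-segment means over grid
#' interval t. When source segments tile the grid exactly (the usual case
#' after [build_union_grid()]) this is an exact copy of the source means.
#' Every sample must cover every grid interval.
#'
#' @param records data frame of segment records.
#' @param grid segment grid as from [build_union_grid()].
#' @return A [cn_matrix()].
#' @export
summarize_to_matrix <- function(records, grid) {
  grid <- validate_grid(grid)
  samples <- unique(records$sample_id)
  t_n <- nrow(grid)
  vals <- matrix(NA_real_, length(samples), t_n)
  for (j in seq_along(samples)) {
    r <- records[records$sample_id == samples[j], , drop = FALSE]
    for (t in seq_len(t_n)) {
      rr <- r[r$chromosome == grid$chromosome[t] &
                r$start <= grid$end[t] & r$end >= grid$start[t], ,
              drop = FALSE]
      if (nrow(rr) == 0)
        stop("sample ", samples[j], " does not cover grid interval ",
             segment_names(grid[t, , drop = FALSE]))
      w <- pmin(rr$end, grid$end[t]) - pmax(rr$start, grid$start[t]) + 1
      covered <- sum(w)
      if (covered < grid$end[t] - grid$start[t] + 1)
        stop("sample ", samples[j], " only partially covers grid interval ",
             segment_names(grid[t, , drop = FALSE]))
      vals[j, t] <- sum(w * rr$mean_cn) / covered
    }
  }
  cn_matrix(vals, samples, grid)
}

#' Write / read a copy-number matrix as TSV
#'
#' The on-disk format is a tab-delimited table whose header row carries the
#' segment coordinates as `chrom:start-end`, whose first column is
#' `sample_id`, and whose cells are linear mean copy numbers. A write/read
#' round trip reproduces the matrix to at least 6 significant digits.
#'
#' @param m a [cn_matrix()].
#' @param path output (or input) file path.
#' @return `read_cn_matrix` returns a [cn_matrix()]; `write_cn_matrix`
#'   returns `path` invisibly.
#' @export
write_cn_matrix <- function(m, path) {
  stopifnot(inherits(m, "cn_matrix"))
  df <- data.frame(sample_id = m$sample_ids,
                   signif(m$values, 8),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cn_matrix
#' @export
read_cn_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty matrix file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "sample_id")
    stop("matrix file must have a sample_id column followed by segments")
  seg_names <- names(df)[-1]
  parsed <- regmatches(seg_names,
                       regexec("^(.+):([0-9]+)-([0-9]+)$", seg_names))
  if (any(lengths(parsed) != 4))
    stop("malformed segment header; expected chrom:start-end")
  grid <- data.frame(
    chromosome = vapply(parsed, `[`, "", 2),
    start = as.integer(vapply(parsed, `[`, "", 3)),
    end = as.integer(vapply(parsed, `[`, "", 4)),
    stringsAsFactors = FALSE
  )
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric values in matrix file")
  cn_matrix(vals, df$sample_id, grid)
}
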