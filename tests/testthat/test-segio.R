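write_seg_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".seg",
                                .local_envir = parent.frame())
  writeLines(c("sample\tchromosome\tstart\tend\tmean", lines), path)
  path
}

test_that("read_seg_table parses linear and log2 dialects", {
  p <- write_seg_file("S1\t1\t1\t1000\t2.0")
  rec <- read_seg_table(p, dialect = "linear")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mean_cn, 2.0)
  expect_equal(rec$start, 1L)

  p2 <- write_seg_file("S1\t1\t1\t1000\t0.0")
  rec2 <- read_seg_table(p2, dialect = "log2")
  expect_equal(rec2$mean_cn, 2.0)   # log2 ratio 0 is diploid
  p3 <- write_seg_file("S1\t1\t1\t1000\t1.0")
  expect_equal(read_seg_table(p3, dialect = "log2")$mean_cn, 4.0)
})

test_that("sex chromosomes are dropped and bad records rejected", {
  p <- write_seg_file(c("S1\t1\t1\t1000\t2.0",
                        "S1\tX\t1\t1000\t2.0",
                        "S1\tchrY\t1\t1000\t2.0"))
  expect_message(rec <- read_seg_table(p, "linear"), "sex-chromosome")
  expect_equal(rec$chromosome, "1")

  p2 <- write_seg_file(c("S1\t1\t1\t1000\t2.0",
                         "S1\t2\t1\t1000\t-0.5"))
  expect_warning(rec2 <- read_seg_table(p2, "linear"), "non-positive")
  expect_equal(nrow(rec2), 1)
})

test_that("missing columns give a format error naming the column", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchromosome\tstart\tmean", "S1\t1\t1\t2.0"), path)
  expect_error(read_seg_table(path, "linear"), "end")
})

test_that("build_union_grid unions breakpoints across samples", {
  rec <- data.frame(
    sample_id = c("A", "A", "B"),
    chromosome = "1",
    start = c(1L, 51L, 1L),
    end = c(50L, 100L, 100L),
    mean_cn = c(2, 3, 2.5))
  g <- build_union_grid(rec)
  expect_equal(nrow(g), 2)
  expect_equal(g$start, c(1L, 51L))
  expect_equal(g$end, c(50L, 100L))

  # single segment -> single interval
  g1 <- build_union_grid(rec[1, ])
  expect_equal(nrow(g1), 1)

  # two chromosomes ordered numerically
  rec2 <- data.frame(sample_id = "A", chromosome = c("2", "1"),
                     start = 1L, end = 100L, mean_cn = 2)
  g2 <- build_union_grid(rec2)
  expect_equal(g2$chromosome, c("1", "2"))
})

test_that("build_union_grid is idempotent on already-gridded records", {
  rec <- data.frame(sample_id = rep(c("A", "B"), each = 3),
                    chromosome = "1",
                    start = rep(c(1L, 101L, 301L), 2),
                    end = rep(c(100L, 300L, 400L), 2),
                    mean_cn = 2)
  g <- build_union_grid(rec)
  rec_regrid <- data.frame(sample_id = "A", chromosome = g$chromosome,
                           start = g$start, end = g$end, mean_cn = 2)
  expect_equal(build_union_grid(rec_regrid), g)
})

test_that("summarize_to_matrix computes length-weighted means", {
  # grid interval [1,100] covered half by mean 2 and half by mean 4
  rec <- data.frame(sample_id = "A", chromosome = "1",
                    start = c(1L, 51L), end = c(50L, 100L),
                    mean_cn = c(2, 4))
  grid <- data.frame(chromosome = "1", start = 1L, end = 100L)
  m <- summarize_to_matrix(rec, grid)
  expect_equal(unname(m$values[1, 1]), 3.0)

  # exact tiling is an identity copy
  g2 <- build_union_grid(rec)
  m2 <- summarize_to_matrix(rec, g2)
  expect_equal(unname(m2$values[1, ]), c(2, 4))

  # uncovered interval errors with the sample named
  grid3 <- data.frame(chromosome = "1", start = c(1L, 101L),
                      end = c(100L, 200L))
  expect_error(summarize_to_matrix(rec, grid3), "A")
})

test_that("summarization conserves the per-sample length-weighted mean", {
  set.seed(4)
  starts <- c(1L, 201L, 501L, 901L)
  ends <- c(200L, 500L, 900L, 1200L)
  rec <- do.call(rbind, lapply(c("A", "B"), function(sid)
    data.frame(sample_id = sid, chromosome = "1", start = starts,
               end = ends, mean_cn = runif(4, 1, 4))))
  # a finer grid splitting each source segment in two
  cuts <- sort(unique(c(starts - 1L, ends, (starts + ends) %/% 2L)))
  grid <- data.frame(chromosome = "1", start = cuts[-length(cuts)] + 1L,
                     end = cuts[-1L])
  m <- summarize_to_matrix(rec, grid)
  w <- grid$end - grid$start + 1
  for (sid in c("A", "B")) {
    r <- rec[rec$sample_id == sid, ]
    expect_equal(sum(m$values[sid, ] * w) / sum(w),
                 sum(r$mean_cn * (r$end - r$start + 1)) /
                   sum(r$end - r$start + 1))
  }
})

test_that("matrix TSV round-trips and rejects malformed input", {
  set.seed(1)
  m <- toy_matrix(matrix(runif(6, 1, 4), 2, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cn_matrix(m, path)
  m2 <- read_cn_matrix(path)
  expect_equal(m2$values, m$values, tolerance = 1e-6)
  expect_equal(m2$sample_ids, m$sample_ids)
  expect_equal(m2$grid, m$grid)

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(read_cn_matrix(empty), "empty")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tnot-a-coord", "S1\t2.0"), bad)
  expect_error(read_cn_matrix(bad), "chrom:start-end")
})

test_that("a cohort-scale matrix round-trips", {
  set.seed(2)
  n <- 79; T_n <- 500   # synthetic values; exercises shape handling only
  g <- data.frame(chromosome = rep(as.character(1:5), each = 100),
                  start = rep(seq_len(100) * 1000L - 999L, 5),
                  end = rep(seq_len(100) * 1000L, 5))
  m <- cn_matrix(matrix(exp(rnorm(n * T_n, log(2), 0.3)), n, T_n),
                 sprintf("GB%02d", 1:n), g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cn_matrix(m, path)
  m2 <- read_cn_matrix(path)
  expect_equal(dim(m2$values), c(n, T_n))
  expect_equal(m2$values, m$values, tolerance = 1e-6)
})
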