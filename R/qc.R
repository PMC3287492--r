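#' Count copy-number alteration regions per sample
#'
#' A segment counts as altered when its mean copy number falls below `lo`
#' (loss) or above `hi` (gain). Tumour samples with extensive genomic
#' instability show many altered segments; normal-contaminated samples are
#' pulled toward the flat diploid profile and show few.
#'
#' @param m a [cn_matrix()].
#' @param lo loss threshold (default 1.5); must be < 2.
#' @param hi gain threshold (default 2.5); must be > 2.
#' @return named integer vector of per-sample alteration counts.
#' @export
count_alteration_regions <- function(m, lo = 1.5, hi = 2.5) {
  stopifnot(inherits(m, "cn_matrix"))
  if (!(lo < 2 && 2 < hi)) stop("need lo < 2 < hi")
  counts <- rowSums(m$values < lo | m$values > hi)
  stats::setNames(as.integer(counts), m$sample_ids)
}

#' Random-forest contamination filter
#'
#' Flags tumour samples whose copy-number profiles resemble normal tissue
#' (normal-cell contamination of the specimen). A random forest is trained
#' on two groups: the `top_fraction` of tumour samples with the highest
#' alteration counts (labelled tumour) and all supplied normal samples
#' (labelled normal). Every tumour sample is then scored with the forest's
#' normal-class probability as its contamination probability; samples
#' exceeding 0.5 are flagged for exclusion. Features are the raw segment
#' mean copy numbers, so tumours and normals must share the same grid.
#'
#' @param m tumour [cn_matrix()].
#' @param normals normal-sample [cn_matrix()] on the same segment grid.
#' @param top_fraction fraction of tumours (by alteration count) used as
#'   the tumour training class, in (0, 0.5\] (default 0.25).
#' @param lo,hi alteration thresholds passed to
#'   [count_alteration_regions()].
#' @param seed integer seed for forest training.
#' @param ntree number of trees (default 500).
#' @return data frame of class `qc_report` with columns `sample_id`,
#'   `contamination_prob`, `excluded`; the forest's out-of-bag error rate
#'   is attached as attribute `"oob_error"`.
#' @export
qc_filter <- function(m, normals, top_fraction = 0.25, lo = 1.5, hi = 2.5,
                      seed = 1, ntree = 500) {
  stopifnot(inherits(m, "cn_matrix"), inherits(normals, "cn_matrix"))
  if (top_fraction <= 0 || top_fraction > 0.5)
    stop("top_fraction must be in (0, 0.5]")
  if (ncol(normals$values) != ncol(m$values))
    stop("tumours and normals must share the same segment grid")
  counts <- count_alteration_regions(m, lo, hi)
  n_top <- max(2L, ceiling(top_fraction * nrow(m$values)))
  top_idx <- order(counts, decreasing = TRUE)[seq_len(n_top)]
  if (nrow(normals$values) < 2)
    stop("need at least 2 normal samples to train the classifier")
  x_train <- rbind(m$values[top_idx, , drop = FALSE], normals$values)
  y_train <- factor(c(rep("tumour", n_top),
                      rep("normal", nrow(normals$values))),
                    levels = c("tumour", "normal"))
  colnames(x_train) <- paste0("seg", seq_len(ncol(x_train)))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x_train, y = y_train,
                                   ntree = ntree)
  oob <- as.numeric(rf$err.rate[nrow(rf$err.rate), "OOB"])
  x_all <- m$values
  colnames(x_all) <- colnames(x_train)
  prob <- stats::predict(rf, newdata = x_all, type = "prob")[, "normal"]
  report <- data.frame(sample_id = m$sample_ids,
                       contamination_prob = as.numeric(prob),
                       excluded = as.numeric(prob) > 0.5,
                       stringsAsFactors = FALSE)
  attr(report, "oob_error") <- oob
  class(report) <- c("qc_report", "data.frame")
  report
}
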