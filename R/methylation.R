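#' Per-CpG methylation level (beta value)
#'
#' `beta = m / (m + u)` for CpGs with coverage at or above `min_coverage`;
#' lower-coverage CpGs keep their counts but get `NA` beta.
#'
#' @param records data.frame with `chrom`, `pos`, `condition`, `m_count`,
#'   `u_count`.
#' @param min_coverage minimum total reads for a beta value.
#' @return The input with a `beta` column appended.
#' @examples
#' computeBetas(data.frame(chrom = "chr1", pos = 1, condition = "a",
#'                         m_count = 6, u_count = 2))$beta  # 0.75
#' @export
computeBetas <- function(records, min_coverage = 1) {
  need <- c("chrom", "pos", "condition", "m_count", "u_count")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lacks column(s): ", paste(miss, collapse = ", "))
  if (any(records$m_count < 0 | records$u_count < 0))
    stop("counts must be >= 0")
  cov <- records$m_count + records$u_count
  records$beta <- ifelse(cov >= max(1, min_coverage),
                         records$m_count / cov, NA_real_)
  records
}

#' Compare per-CpG methylation between two conditions
#'
#' Computes per-CpG differences `beta_A - beta_B` over CpGs with a beta value
#' in both conditions and tests them with a paired two-sided Student t-test
#' (default), a Wilcoxon signed-rank test, or an unpaired t-test. CpGs
#' present (or covered) in only one condition are dropped from the paired
#' test and reported separately. If every paired difference is exactly 0 the
#' comparison returns mean difference 0 with p = 1; a nonzero constant
#' difference leaves the paired t statistic undefined and is an error.
#'
#' @param records data.frame as in [computeBetas()] with exactly two
#'   conditions (beta computed internally).
#' @param condition_a,condition_b condition labels; defaults are the sorted
#'   unique conditions. The reported difference is A - B.
#' @param min_coverage minimum coverage for a CpG to contribute.
#' @param paired paired-by-CpG comparison (default) or unpaired.
#' @param test `"t"` (default) or `"wilcoxon"` (signed-rank, paired only).
#' @return list: `per_cpg` (chrom, pos, beta_a, beta_b, diff), `mean_diff`,
#'   `conf_int` (95%), `statistic`, `p_value`, `n_shared`, `unshared`
#'   (CpGs usable in only one condition).
#' @export
compareMethylation <- function(records, condition_a = NULL,
                               condition_b = NULL, min_coverage = 1,
                               paired = TRUE, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  records <- computeBetas(records, min_coverage)
  conds <- sort(unique(records$condition))
  if (is.null(condition_a)) condition_a <- conds[1]
  if (is.null(condition_b)) condition_b <- setdiff(conds, condition_a)[1]
  if (!all(c(condition_a, condition_b) %in% conds))
    stop("conditions not found in records")
  a <- records[records$condition == condition_a & !is.na(records$beta), ]
  b <- records[records$condition == condition_b & !is.na(records$beta), ]
  key_a <- paste(a$chrom, a$pos)
  key_b <- paste(b$chrom, b$pos)
  shared <- intersect(key_a, key_b)
  if (length(shared) < 2L)
    stop("need >= 2 CpGs with beta values shared between conditions")
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  per_cpg <- data.frame(chrom = a$chrom[ia], pos = a$pos[ia],
                        beta_a = a$beta[ia], beta_b = b$beta[ib],
                        stringsAsFactors = FALSE)
  per_cpg$diff <- per_cpg$beta_a - per_cpg$beta_b
  unshared <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))

  if (paired) {
    d <- per_cpg$diff
    constant <- all(abs(d - d[1]) < 1e-12)
    if (constant && abs(d[1]) < 1e-12) {
      res <- list(mean_diff = 0, conf_int = c(0, 0), statistic = 0,
                  p_value = 1)
    } else if (constant) {
      stop("degenerate comparison: all paired differences equal")
    } else if (test == "wilcoxon") {
      ht <- suppressWarnings(wilcox.test(d, alternative = "two.sided"))
      res <- list(mean_diff = mean(d), conf_int = c(NA_real_, NA_real_),
                  statistic = unname(ht$statistic), p_value = ht$p.value)
    } else {
      ht <- t.test(d)
      res <- list(mean_diff = mean(d), conf_int = as.numeric(ht$conf.int),
                  statistic = unname(ht$statistic), p_value = ht$p.value)
    }
  } else {
    if (test == "wilcoxon")
      stop("wilcoxon mode is implemented for the paired comparison")
    ht <- t.test(per_cpg$beta_a, per_cpg$beta_b)
    res <- list(mean_diff = mean(per_cpg$beta_a) - mean(per_cpg$beta_b),
                conf_int = as.numeric(ht$conf.int),
                statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  c(list(per_cpg = per_cpg, condition_a = condition_a,
         condition_b = condition_b, n_shared = nrow(per_cpg),
         unshared = unshared, paired = paired, test = test), res)
}
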