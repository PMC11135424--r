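#' Percent-spliced-in from junction counts
#'
#' PSI with effective-length normalization:
#' `psi = (inc/len_inc) / (inc/len_inc + skp/len_skp)`. Replicates with zero
#' informative reads get `NA` and are excluded from pooled estimates with a
#' warning. Pooled per-group PSI uses summed counts.
#'
#' @param counts data.frame with columns `event_id`, `group`, `replicate`,
#'   `inc_reads`, `skp_reads`, `len_inc`, `len_skp`.
#' @return list with `replicate` (per event/replicate PSI) and `group`
#'   (pooled PSI per event and group).
#' @examples
#' counts <- data.frame(event_id = "e1", group = "control", replicate = 1,
#'                      inc_reads = 30, skp_reads = 10, len_inc = 2,
#'                      len_skp = 1)
#' computePsi(counts)$replicate$psi  # 0.6
#' @export
computePsi <- function(counts) {
  need <- c("event_id", "group", "replicate", "inc_reads", "skp_reads",
            "len_inc", "len_skp")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("counts lacks column(s): ", paste(miss, collapse = ", "))
  if (any(counts$inc_reads < 0 | counts$skp_reads < 0))
    stop("read counts must be >= 0")
  if (any(counts$len_inc < 1 | counts$len_skp < 1))
    stop("effective lengths must be >= 1")
  ninc <- counts$inc_reads / counts$len_inc
  nskp <- counts$skp_reads / counts$len_skp
  tot <- ninc + nskp
  psi <- ifelse(tot > 0, ninc / tot, NA_real_)
  if (anyNA(psi))
    warning(sum(is.na(psi)),
            " replicate(s) with zero informative reads excluded (PSI undefined)")
  rep_df <- data.frame(event_id = counts$event_id, group = counts$group,
                       replicate = counts$replicate, psi = psi,
                       stringsAsFactors = FALSE)

  key <- paste(counts$event_id, counts$group, sep = "\r")
  inc_sum <- tapply(counts$inc_reads / counts$len_inc, key, sum)
  skp_sum <- tapply(counts$skp_reads / counts$len_skp, key, sum)
  tot_sum <- inc_sum + skp_sum
  psi_pool <- ifelse(tot_sum > 0, inc_sum / tot_sum, NA_real_)
  parts <- do.call(rbind, strsplit(names(inc_sum), "\r", fixed = TRUE))
  grp_df <- data.frame(event_id = parts[, 1], group = parts[, 2],
                       psi = as.numeric(psi_pool), stringsAsFactors = FALSE)
  rownames(grp_df) <- NULL
  list(replicate = rep_df, group = grp_df)
}

binomLogLik <- function(inc, skp, p) {
  ll <- 0
  if (inc > 0) ll <- ll + inc * log(p)
  if (skp > 0) ll <- ll + skp * log(1 - p)
  ll
}

#' Binomial likelihood-ratio test for one splicing event
#'
#' Pooled inclusion reads per group are modelled as
#' `inc ~ Binomial(inc + skp, theta_group)`; the null shares one theta. The
#' statistic `2 * (l(theta1, theta2) - l(theta, theta))` is referred to
#' chi-square(1). Effective lengths affect PSI point estimates, not this
#' count-level test.
#'
#' @param inc_control,skp_control,inc_mutant,skp_mutant per-replicate read
#'   counts (vectors are pooled by summation).
#' @return list with `statistic` and `p_value` (`NA` when a group has no
#'   informative reads).
#' @examples
#' testEvent(50, 50, 90, 10)  # p from 2 * (l(0.5, 0.9) - l(0.7, 0.7))
#' @export
testEvent <- function(inc_control, skp_control, inc_mutant, skp_mutant) {
  i1 <- sum(inc_control); s1 <- sum(skp_control)
  i2 <- sum(inc_mutant); s2 <- sum(skp_mutant)
  if (i1 + s1 == 0 || i2 + s2 == 0)
    return(list(statistic = NA_real_, p_value = NA_real_))
  p1 <- i1 / (i1 + s1)
  p2 <- i2 / (i2 + s2)
  p0 <- (i1 + i2) / (i1 + s1 + i2 + s2)
  stat <- 2 * (binomLogLik(i1, s1, p1) + binomLogLik(i2, s2, p2) -
                 binomLogLik(i1, s1, p0) - binomLogLik(i2, s2, p0))
  stat <- max(stat, 0)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Differential splicing across all events
#'
#' Computes pooled per-group PSI and the per-event likelihood-ratio test,
#' joining gene expression for downstream filtering.
#'
#' @param counts long count table as in [computePsi()], plus `gene_id` and
#'   optionally exon coordinates (`chrom`, `start`, `end`, `strand`,
#'   `event_type`) which are carried through.
#' @param expression data.frame with `gene_id`, `tpm`.
#' @return data.frame, one row per event: PSI per group, `delta_psi`
#'   (mutant - control), `p_value`, `gene_tpm`.
#' @seealso [callEvents()]
#' @export
testSplicing <- function(counts, expression = NULL) {
  if (!all(c("control", "mutant") %in% counts$group))
    stop("counts must contain groups 'control' and 'mutant'")
  ids <- unique(counts$event_id)
  ctrl <- counts$group == "control"
  key_all <- paste(counts$event_id, counts$group, sep = "\r")
  i_sum <- tapply(counts$inc_reads, key_all, sum)
  s_sum <- tapply(counts$skp_reads, key_all, sum)
  kc <- paste(ids, "control", sep = "\r")
  km <- paste(ids, "mutant", sep = "\r")
  i1 <- i_sum[kc]; s1 <- s_sum[kc]; i2 <- i_sum[km]; s2 <- s_sum[km]
  i1[is.na(i1)] <- 0; s1[is.na(s1)] <- 0
  i2[is.na(i2)] <- 0; s2[is.na(s2)] <- 0

  res <- mapply(testEvent, i1, s1, i2, s2, SIMPLIFY = FALSE)
  p <- vapply(res, `[[`, numeric(1), "p_value")
  stat <- vapply(res, `[[`, numeric(1), "statistic")

  li <- counts$len_inc[match(ids, counts$event_id)]
  ls <- counts$len_skp[match(ids, counts$event_id)]
  psi_of <- function(i, s) {
    ni <- i / li; ns <- s / ls
    ifelse(ni + ns > 0, ni / (ni + ns), NA_real_)
  }
  psi_c <- psi_of(i1, s1)
  psi_m <- psi_of(i2, s2)

  first <- match(ids, counts$event_id)
  out <- data.frame(event_id = ids,
                    gene_id = counts$gene_id[first],
                    stringsAsFactors = FALSE)
  for (col in c("chrom", "start", "end", "strand", "event_type"))
    if (col %in% names(counts)) out[[col]] <- counts[[col]][first]
  out$psi_control <- as.numeric(psi_c)
  out$psi_mutant <- as.numeric(psi_m)
  out$delta_psi <- out$psi_mutant - out$psi_control
  out$statistic <- as.numeric(stat)
  out$p_value <- as.numeric(p)
  out$gene_tpm <- if (!is.null(expression))
    expression$tpm[match(out$gene_id, expression$gene_id)] else NA_real_
  rownames(out) <- NULL
  out
}

#' Call significant splicing events
#'
#' Benjamini-Hochberg correction is applied jointly across all tested events;
#' an event is called when `fdr < fdr_threshold`, `|delta_psi| >
#' dpsi_threshold` and `gene_tpm > tpm_threshold`. Direction is
#' `included-in-mutant` for positive delta PSI, `excluded-in-mutant` for
#' negative, and `ns` when any filter fails.
#'
#' @param events data.frame from [testSplicing()] (needs `p_value`,
#'   `delta_psi`, `gene_tpm`).
#' @param fdr_threshold,dpsi_threshold,tpm_threshold filter cutoffs.
#' @return The input with `fdr`, `direction` and logical `called` columns.
#' @export
callEvents <- function(events, fdr_threshold = 0.05, dpsi_threshold = 0.1,
                       tpm_threshold = 1) {
  if (nrow(events) == 0L) {
    events$fdr <- numeric(0)
    events$direction <- character(0)
    events$called <- logical(0)
    return(events)
  }
  events$fdr <- p.adjust(events$p_value, method = "BH")
  called <- !is.na(events$fdr) & events$fdr < fdr_threshold &
    !is.na(events$delta_psi) & abs(events$delta_psi) > dpsi_threshold &
    !is.na(events$gene_tpm) & events$gene_tpm > tpm_threshold
  events$direction <- ifelse(!called, "ns",
                             ifelse(events$delta_psi > 0,
                                    "included-in-mutant",
                                    "excluded-in-mutant"))
  events$called <- called
  events
}

#' Summarize direction and type of called events
#'
#' @param events output of [callEvents()]; only rows with `called = TRUE`
#'   contribute.
#' @return list with `n_called`, `frac_included`, `frac_excluded` (`NA` when
#'   nothing is called) and a per-`event_type` count table.
#' @export
summarizeDirection <- function(events) {
  called <- events[!is.null(events$called) & events$called, , drop = FALSE]
  n <- nrow(called)
  if (n == 0L)
    return(list(n_called = 0L, frac_included = NA_real_,
                frac_excluded = NA_real_, by_type = table(character(0))))
  inc <- sum(called$direction == "included-in-mutant")
  by_type <- if ("event_type" %in% names(called))
    table(called$event_type) else table(rep("SE", n))
  list(n_called = n, frac_included = inc / n, frac_excluded = 1 - inc / n,
       by_type = by_type)
}

#' Overlap of differentially expressed and alternatively spliced genes
#'
#' 2x2 Fisher's exact test of membership in the two gene sets over a common
#' expressed-gene universe.
#'
#' @param as_genes,de_genes character vectors of gene identifiers, subsets of
#'   `universe`.
#' @param universe all eligible genes.
#' @return list with `overlap` (size and identity), the 2x2 `table`,
#'   `odds_ratio` and two-sided `p_value`.
#' @export
overlapDeAs <- function(as_genes, de_genes, universe) {
  as_genes <- unique(as_genes)
  de_genes <- unique(de_genes)
  universe <- unique(universe)
  if (!all(as_genes %in% universe) || !all(de_genes %in% universe))
    stop("both gene sets must be subsets of the universe")
  both <- intersect(as_genes, de_genes)
  tab <- matrix(c(length(both),
                  length(setdiff(as_genes, de_genes)),
                  length(setdiff(de_genes, as_genes)),
                  length(universe) - length(union(as_genes, de_genes))),
                nrow = 2,
                dimnames = list(AS = c("yes", "no"), DE = c("yes", "no")))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(overlap = length(both), genes = both, table = tab,
       odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
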