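#' Chi-squared test of two paired counts against equal expectation
#'
#' Goodness-of-fit of a count pair (a, b) against the equal split
#' `e = (a + b) / 2`: `chisq = (a - e)^2 / e + (b - e)^2 / e`, 1 degree of
#' freedom, no continuity correction; p from the upper tail of the
#' chi-squared distribution.
#'
#' @param a,b non-negative counts with `a + b > 0`.
#' @return List: `statistic`, `df` (1), `p`.
#' @examples
#' chisq_two_counts(18382, 13754)$statistic  # 666.5
#' @export
chisq_two_counts <- function(a, b) {
  stopifnot(a >= 0, b >= 0)
  if (a + b == 0) stop("a + b must be > 0")
  e <- (a + b) / 2
  stat <- (a - e)^2 / e + (b - e)^2 / e
  list(statistic = stat, df = 1L, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by summing, over all tables with the observed
#' margins, the hypergeometric point probabilities not exceeding that of
#' the observed table (the standard two-sided convention). Implemented
#' directly from [stats::dhyper()] point probabilities.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List: `odds_ratio` (sample odds ratio, ad/bc), `p` (two-sided),
#'   `degenerate` (TRUE when a margin is zero, in which case p = 1 by
#'   convention).
#' @examples
#' fisher_exact_2x2(matrix(c(7, 29, 7, 3), 2))$p  # ~0.0045
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  n <- r1 + r2
  odds <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("degenerate 2x2 table (zero margin); p = 1 by convention")
    return(list(odds_ratio = odds, p = 1, degenerate = TRUE))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  pk <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  p <- min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
  if (1 - p < 1e-12) p <- 1
  list(odds_ratio = odds, p = p, degenerate = FALSE)
}

#' Classify an insertion frequency
#'
#' `low` for f <= 0.2, `fixed` for f >= 0.9 (a threshold allowing for some
#' estimation error), `intermediate` otherwise; boundaries inclusive.
#' Missing frequencies (overlapping insertions, where the population
#' frequency cannot be estimated) are unclassified (NA).
#'
#' @param f frequency vector in \[0, 1\] (NAs allowed).
#' @param low,fixed class thresholds.
#' @return Factor with levels low, intermediate, fixed.
#' @export
classify_frequency <- function(f, low = 0.2, fixed = 0.9) {
  if (any(f < 0 | f > 1, na.rm = TRUE)) stop("frequencies must be in [0, 1]")
  cls <- ifelse(is.na(f), NA_character_,
                ifelse(f <= low, "low",
                       ifelse(f >= fixed, "fixed", "intermediate")))
  factor(cls, levels = c("low", "intermediate", "fixed"))
}

#' Site-frequency spectrum of TE insertions
#'
#' Bins the non-missing frequencies over (0, 1\] and reports counts,
#' proportions, the proportion of low-frequency insertions (f <= 0.2) and
#' the mean frequency.
#'
#' @param records data.frame with a `frequency` column, or a numeric
#'   vector of frequencies.
#' @param bin_width bin width over (0, 1\], default 0.1.
#' @return List: `bins` (data.frame: lo, hi, count, proportion),
#'   `prop_low`, `mean_frequency`, `n`.
#' @export
frequency_spectrum <- function(records, bin_width = 0.1) {
  f <- if (is.data.frame(records)) records$frequency else records
  f <- f[!is.na(f)]
  if (length(f) == 0) stop("no records with non-missing frequency")
  if (any(f < 0 | f > 1)) stop("frequencies must be in [0, 1]")
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  idx <- cut(f, breaks = breaks, include.lowest = FALSE)
  # f == 0 would fall outside (0, 1]; treat exact zeros as first bin
  idx[f == 0] <- levels(idx)[1]
  counts <- as.integer(table(idx))
  bins <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                     count = counts, proportion = counts / length(f))
  list(bins = bins, prop_low = mean(f <= 0.2), mean_frequency = mean(f),
       n = length(f))
}

#' Per-family summaries for two species and shared-insertion flags
#'
#' For each TE family and species: total insertions, low-frequency
#' (f <= 0.2) and fixed (f >= 0.9) counts, and the mean frequency over
#' records with non-missing f. Records with missing frequency count
#' toward `n_total` only. A family is flagged `shared_high` when the
#' supplied cross-species insertion pairs contain at least one pair with
#' both frequencies >= 0.8 (the operational criterion for vertical
#' transmission). Families with 10 or fewer insertions in both species
#' combined carry `shown = FALSE`.
#'
#' @param records1,records2 insertion tables (columns `family`,
#'   optionally `order`, `frequency`) for species 1 and 2.
#' @param shared_pairs optional data.frame of cross-species pairs with
#'   columns `family`, `f1`, `f2`.
#' @param min_total families must exceed this combined total to be
#'   `shown` (default 10).
#' @param high_threshold both-species frequency threshold for a shared
#'   pair to qualify (default 0.8).
#' @return data.frame: family, order, n_total_1, n_low_1, n_fixed_1,
#'   mean_f_1, n_total_2, n_low_2, n_fixed_2, mean_f_2, total_both,
#'   shared_high, shown.
#' @export
family_summaries <- function(records1, records2, shared_pairs = NULL,
                             min_total = 10, high_threshold = 0.8) {
  one <- function(records) {
    if (is.null(records) || nrow(records) == 0)
      return(data.frame(family = character(0), order = character(0),
                        n_total = integer(0), n_low = integer(0),
                        n_fixed = integer(0), mean_f = numeric(0)))
    sp <- split(records, records$family)
    do.call(rbind, lapply(sp, function(d) {
      cls <- classify_frequency(d$frequency)
      data.frame(family = d$family[1],
                 order = if ("order" %in% names(d)) d$order[1] else NA,
                 n_total = nrow(d),
                 n_low = sum(cls == "low", na.rm = TRUE),
                 n_fixed = sum(cls == "fixed", na.rm = TRUE),
                 mean_f = if (all(is.na(d$frequency))) NA_real_
                          else mean(d$frequency, na.rm = TRUE))
    }))
  }
  s1 <- one(records1); s2 <- one(records2)
  fam <- union(s1$family, s2$family)
  m <- merge(merge(data.frame(family = fam), s1, all.x = TRUE),
             s2, by = "family", all.x = TRUE,
             suffixes = c("_1", "_2"))
  for (col in c("n_total_1", "n_low_1", "n_fixed_1",
                "n_total_2", "n_low_2", "n_fixed_2"))
    m[[col]][is.na(m[[col]])] <- 0L
  m$order <- ifelse(is.na(m$order_1), m$order_2, m$order_1)
  m$order_1 <- m$order_2 <- NULL
  m$total_both <- m$n_total_1 + m$n_total_2
  sh <- rep(FALSE, nrow(m))
  if (!is.null(shared_pairs) && nrow(shared_pairs) > 0) {
    q <- shared_pairs[!is.na(shared_pairs$f1) & !is.na(shared_pairs$f2) &
                        shared_pairs$f1 >= high_threshold &
                        shared_pairs$f2 >= high_threshold, , drop = FALSE]
    sh <- m$family %in% q$family
  }
  m$shared_high <- sh
  m$shown <- m$total_both > min_total
  rownames(m) <- NULL
  m
}

#' Number of families with many low-frequency insertions
#'
#' Counts families with more than `threshold` low-frequency insertions in
#' the given species column of a [family_summaries()] table — the
#' operational definition of a recently active family.
#'
#' @param summaries output of [family_summaries()].
#' @param species 1 or 2.
#' @param threshold count threshold, default 10.
#' @return Integer count of active families.
#' @export
count_active_families <- function(summaries, species = 1, threshold = 10) {
  col <- paste0("n_low_", species)
  sum(summaries[[col]] > threshold)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; p-value via the t approximation
#' (`stats::cor.test(..., method = "spearman", exact = FALSE)`).
#'
#' @param x,y equal-length numeric vectors, n >= 3, neither constant.
#' @return List: `rho`, `p`, `n`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector")
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Read an insertion table from TSV
#'
#' Columns: `chromosome`, `position` (1-based bp), `family`, `order`,
#' `frequency` (in \[0, 1\] or empty/NA for overlapping insertions whose
#' frequency could not be estimated).
#'
#' @param path TSV file path.
#' @return data.frame of insertion records.
#' @export
read_insertions <- function(path) {
  d <- as.data.frame(data.table::fread(path, na.strings = c("NA", "")))
  req <- c("chromosome", "position", "family", "frequency")
  if (!all(req %in% names(d)))
    stop("insertion TSV must have columns: ", paste(req, collapse = ", "))
  if (any(d$frequency < 0 | d$frequency > 1, na.rm = TRUE))
    stop("frequency outside [0, 1] in ", path)
  d
}
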