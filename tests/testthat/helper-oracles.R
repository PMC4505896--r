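# Independent reference implementations used as oracles.  These stay
# deliberately naive (enumeration / closed forms), separate from the code
# paths they check.

# Tiny genome maps used throughout.
tiny_map <- function(total_sites = 1e4, morgans = 0.5) {
  toy_genome_map(total_sites, n_arms = 4, morgans_per_arm = morgans)
}

# A map with zero genetic length (no recombination).
norecomb_map <- function(total_sites = 1e4, n_arms = 2) {
  len <- total_sites / n_arms
  rt <- data.frame(arm = paste0("a", seq_len(n_arms)),
                   start = 1, end = len, rate = 0)
  build_genome_map(rt, min_rate = 0)
}

# Fisher 2x2 two-sided p by full enumeration of tables with the observed
# margins, using choose() only.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  pk <- vapply(support, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1), numeric(1))
  p_obs <- pk[support == tab[1, 1]]
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# Exhaustive same-family chain-partition oracle: enumerate every subset of
# the k-1 gaps to link; partition score is the sum over linked gaps of
# match * min(adjacent fragment lengths) - penalty * gap; ties prefer
# fewer links.  Returns the chained spans (start, end) sorted.
oracle_chain <- function(starts, ends, match = 1, penalty = 0.5) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  k <- length(starts)
  if (k == 1) return(data.frame(start = starts, end = ends))
  len <- ends - starts
  gaps <- starts[-1] - ends[-k]
  benefit <- match * pmin(len[-k], len[-1]) - penalty * gaps
  best <- NULL; best_score <- -Inf; best_links <- Inf
  for (mask in 0:(2^(k - 1) - 1)) {
    link <- as.logical(bitwAnd(mask, 2^(0:(k - 2))))
    score <- sum(benefit[link])
    nl <- sum(link)
    if (score > best_score || (score == best_score && nl < best_links)) {
      best_score <- score; best_links <- nl; best <- link
    }
  }
  chain <- cumsum(c(1, as.integer(!best)))
  do.call(rbind, lapply(split(seq_len(k), chain), function(ix)
    data.frame(start = starts[ix[1]], end = ends[ix[length(ix)]])))
}

# Brute-force ML window scan, independent of find_ml_window's bookkeeping.
oracle_ml_scan <- function(windows, c_m, c_s, label_m, label_s) {
  wm <- windows[windows$pop_label == label_m, ]
  ws <- windows[windows$pop_label == label_s, ]
  wm <- wm[order(wm$v_lo), ]; ws <- ws[order(ws$v_lo), ]
  best <- NULL; best_p <- -Inf
  for (i in seq_len(nrow(wm))) {
    if (!wm$usable[i] || !ws$usable[i]) next
    pm <- 2 * pnorm(abs(c_m - wm$mu[i]) / wm$sigma[i], lower.tail = FALSE)
    ps <- 2 * pnorm(abs(c_s - ws$mu[i]) / ws$sigma[i], lower.tail = FALSE)
    if (pm * ps > best_p) {  # strict: first (lowest-v) max wins
      best_p <- pm * ps
      best <- wm$window_id[i]
    }
  }
  list(window_id = best, p_joint = best_p)
}

# Hand-built window tables for inference tests (no simulation needed).
fake_windows <- function(n = 30, label = "N500", mu = NULL, sigma = 5,
                         step = 1e-5, size = 1e-4) {
  v_lo <- (seq_len(n) - 1) * step
  if (is.null(mu)) mu <- 10 + 5 * seq_len(n)
  d <- data.frame(window_id = seq_len(n), v_lo = v_lo, v_hi = v_lo + size,
                  pop_label = label, n = 50, mu = mu, sigma = sigma,
                  usable = TRUE)
  class(d) <- c("te_windows", "data.frame")
  d
}

# Minimal valid ensemble records.
fake_ensemble <- function(v, c, pop_label = "N500", N = 500,
                          extinct = FALSE) {
  d <- data.frame(run_id = seq_along(v), pop_label = pop_label, N = N,
                  v = v, c = c, extinct = extinct)
  class(d) <- c("te_ensemble", "data.frame")
  d
}
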