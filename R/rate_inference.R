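#' Run an ensemble of forward simulations over a transposition-rate range
#'
#' For each run a transposition rate is drawn uniformly from `v_range` and
#' a full forward simulation is executed; the final pool-sampled copy
#' number `c` is recorded. With two population sizes supplied, the whole
#' campaign is repeated per size, and each record carries its population
#' label. Run seeds are derived as `base_seed + run_index`, so the
#' ensemble is reproducible and individual runs can be re-executed.
#'
#' @param params a `sim_params` template; its `N` is overridden by
#'   `pop_sizes` when supplied.
#' @param n_sims number of simulations per population size.
#' @param v_range transposition-rate range, default `c(0, 0.003)`.
#' @param pop_sizes named integer vector of population sizes, e.g.
#'   `c(small = 6583, large = 10000)`; NULL (default) uses `params$N`
#'   with label `"N<value>"`.
#' @param base_seed integer base seed; run i of population-size slot j
#'   uses seed `base_seed + (j-1)*n_sims + (i-1)`.
#' @param track_sites passed to [run_simulation()]; default FALSE (site
#'   tracking is not needed for ensemble fitting and costs memory/time).
#' @return data.frame of class `te_ensemble`: run_id, pop_label, N, v, c,
#'   extinct. Extinct runs have `c = NA` and are excluded from window
#'   fitting downstream.
#' @export
run_ensemble <- function(params, n_sims, v_range = c(0, 0.003),
                         pop_sizes = NULL, base_seed = 1L,
                         track_sites = FALSE) {
  stopifnot(inherits(params, "sim_params"), n_sims >= 1,
            length(v_range) == 2, v_range[1] >= 0, v_range[2] > v_range[1])
  if (is.null(pop_sizes)) {
    pop_sizes <- structure(params$N, names = paste0("N", params$N))
  }
  if (is.null(names(pop_sizes)))
    names(pop_sizes) <- paste0("N", pop_sizes)
  out <- vector("list", length(pop_sizes) * n_sims)
  k <- 0L
  for (j in seq_along(pop_sizes)) {
    for (i in seq_len(n_sims)) {
      k <- k + 1L
      seed <- as.integer(base_seed) + (j - 1L) * as.integer(n_sims) +
        (i - 1L)
      set.seed(seed)
      v <- runif(1, v_range[1], v_range[2])
      p <- params
      p$N <- as.integer(pop_sizes[j])
      p$v <- v
      if (p$sample_haplotypes > 2 * p$N)
        stop("sample_haplotypes exceeds 2N for population size ",
             pop_sizes[j])
      tr <- run_simulation(p, track_sites = track_sites,
                           keep_population = FALSE)
      out[[k]] <- data.frame(run_id = k, pop_label = names(pop_sizes)[j],
                             N = p$N, v = v,
                             c = if (tr$extinct) NA_integer_ else tr$sample$c,
                             extinct = tr$extinct)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("te_ensemble", "data.frame")
  res
}

#' Group an ensemble into overlapping transposition-rate windows
#'
#' Windows start at `v_range[1]` and advance by `step` while
#' `start + window_size <= v_range[2]` (windows that would protrude past
#' the upper bound are dropped); membership is half-open
#' `v_lo <= v < v_hi`. Within each window and population label a normal
#' distribution is fitted to the sampled copy numbers by the sample mean
#' and unbiased standard deviation. Windows with fewer than `min_points`
#' records are marked unusable; the fitted standard deviation is floored
#' at `sigma_floor` to avoid zero-variance degeneracy. Extinct runs are
#' excluded.
#'
#' With the defaults over (0, 0.003) this yields 291 windows per label.
#'
#' @param ensemble a `te_ensemble` (or data.frame with pop_label, v, c,
#'   extinct).
#' @param window_size window width on the rate axis, default 1e-4.
#' @param step window step, default 1e-5.
#' @param v_range rate range covered, default `c(0, 0.003)`.
#' @param min_points minimum records for a usable window, default 10.
#' @param sigma_floor lower bound for the fitted standard deviation in
#'   copies, default 0.5.
#' @return data.frame of class `te_windows`: window_id, v_lo, v_hi,
#'   pop_label, n, mu, sigma, usable.
#' @export
build_windows <- function(ensemble, window_size = 1e-4, step = 1e-5,
                          v_range = c(0, 0.003), min_points = 10,
                          sigma_floor = 0.5) {
  stopifnot(nrow(ensemble) > 0, window_size > 0, step > 0)
  e <- ensemble[!ensemble$extinct & !is.na(ensemble$c), , drop = FALSE]
  if (nrow(e) == 0) stop("no usable (non-extinct) ensemble records")
  if (any(e$v < v_range[1] | e$v > v_range[2]))
    stop("ensemble records with v outside v_range")
  n_win <- floor((v_range[2] - v_range[1] - window_size) / step + 1e-9) + 1
  if (n_win < 1) stop("v_range too narrow for a single window")
  labels <- unique(e$pop_label)
  rows <- vector("list", n_win * length(labels))
  k <- 0L
  for (w in seq_len(n_win)) {
    v_lo <- v_range[1] + (w - 1) * step
    v_hi <- v_lo + window_size
    inw <- e$v >= v_lo & e$v < v_hi
    for (lab in labels) {
      k <- k + 1L
      cc <- e$c[inw & e$pop_label == lab]
      n <- length(cc)
      mu <- if (n > 0) mean(cc) else NA_real_
      sg <- if (n > 1) sd(cc) else NA_real_
      sg <- max(sg, sigma_floor, na.rm = TRUE)
      rows[[k]] <- data.frame(window_id = w, v_lo = v_lo, v_hi = v_hi,
                              pop_label = lab, n = n, mu = mu, sigma = sg,
                              usable = n >= min_points)
    }
  }
  res <- do.call(rbind, rows)
  if (!any(res$usable)) stop("no usable windows (all below min_points)")
  class(res) <- c("te_windows", "data.frame")
  res
}

#' Two-tailed window probability of an observed copy number
#'
#' `P(c | W) = 1 - P(mu - |mu - c| < X < mu + |mu - c|)` for
#' `X ~ Normal(mu, sigma)`, i.e. the two-tailed area outside the symmetric
#' interval about the window mean: `2 * (1 - pnorm(|c - mu| / sigma))`.
#' Equals 1 at `c = mu` and decreases strictly in `|c - mu|`.
#'
#' @param mu fitted window mean.
#' @param sigma fitted window standard deviation, > 0.
#' @param c observed copy number.
#' @return Probability in (0, 1\]. Vectorized over all arguments.
#' @export
tail_prob <- function(mu, sigma, c) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  2 * pnorm(-abs(c - mu) / sigma)
}

#' Find the maximum-likelihood transposition-rate window for a family
#'
#' Scans every usable window and returns the one maximizing
#' `P(c_m | W) * P(c_s | W)`. In `equal_N` mode a single fit per window is
#' used for both species; in `unequal_N` mode the fit of the
#' smaller-population label is used for species 1 (`c_m`) and the
#' larger-population label for species 2 (`c_s`). Ties are broken toward
#' the lowest rate; the result is invariant to the row order of
#' `windows`.
#'
#' @param windows a `te_windows` table.
#' @param c_m,c_s observed copy numbers of species 1 and species 2.
#' @param mode `"equal_N"` (default when one label present) or
#'   `"unequal_N"`.
#' @param label_m,label_s population labels backing `c_m` and `c_s`;
#'   defaults: the single label in `equal_N` mode, `"small"`/`"large"` in
#'   `unequal_N` mode.
#' @return List: `window` (the winning row, fields of both labels),
#'   `v_ml` (window midpoint rate), `p_m`, `p_s`.
#' @export
find_ml_window <- function(windows, c_m, c_s,
                           mode = c("equal_N", "unequal_N"),
                           label_m = NULL, label_s = NULL) {
  mode <- match.arg(mode)
  labs <- unique(windows$pop_label)
  if (mode == "equal_N") {
    if (is.null(label_m)) {
      if (length(labs) != 1)
        stop("equal_N mode with several labels: specify label_m/label_s")
      label_m <- labs
    }
    if (is.null(label_s)) label_s <- label_m
  } else {
    if (is.null(label_m)) label_m <- "small"
    if (is.null(label_s)) label_s <- "large"
  }
  if (!all(c(label_m, label_s) %in% labs))
    stop("labels not present in windows: ", label_m, ", ", label_s)
  wm <- windows[windows$pop_label == label_m, , drop = FALSE]
  ws <- windows[windows$pop_label == label_s, , drop = FALSE]
  wm <- wm[order(wm$v_lo), , drop = FALSE]
  ws <- ws[order(ws$v_lo), , drop = FALSE]
  if (!identical(wm$window_id, ws$window_id))
    stop("window tables of the two labels do not align")
  ok <- wm$usable & ws$usable
  if (!any(ok)) stop("no usable windows for the requested labels")
  p_m <- rep(NA_real_, nrow(wm))
  p_s <- p_m
  p_m[ok] <- tail_prob(wm$mu[ok], wm$sigma[ok], c_m)
  p_s[ok] <- tail_prob(ws$mu[ok], ws$sigma[ok], c_s)
  prod <- p_m * p_s
  prod[!ok] <- -Inf
  best <- which.max(prod)  # first maximum = lowest v on ties
  list(window = cbind(wm[best, c("window_id", "v_lo", "v_hi")],
                      data.frame(mu_m = wm$mu[best], sigma_m = wm$sigma[best],
                                 n_m = wm$n[best], mu_s = ws$mu[best],
                                 sigma_s = ws$sigma[best], n_s = ws$n[best])),
       v_ml = wm$v_lo[best] + (wm$v_hi[best] - wm$v_lo[best]) / 2,
       p_m = p_m[best], p_s = p_s[best])
}

#' Test a TE family for transposition-rate heterogeneity
#'
#' Runs [find_ml_window()] for the family's observed copy-number pair and
#' combines the two per-species tail probabilities at the
#' maximum-likelihood window into `p_joint = p_m * p_s`, Bonferroni
#' corrects over the number of families tested
#' (`p_adj = min(1, p_joint * n_families)`) and assigns the significance
#' code `**` (< 0.001), `*` (< 0.01), `+` (< 0.05) or `""`.
#'
#' @param windows a `te_windows` table.
#' @param obs either a data.frame with columns `family`, `c_m`, `c_s`
#'   (and optionally `order`), or a single observation given via `c_m`,
#'   `c_s`.
#' @param n_families Bonferroni multiplier; defaults to `nrow(obs)` for a
#'   data.frame and 1 for a single observation.
#' @param mode,label_m,label_s see [find_ml_window()].
#' @param c_m,c_s single-family observation (used when `obs` is missing).
#' @param family family name for a single observation.
#' @return data.frame of class `te_test`: family, order (if supplied),
#'   c_m, c_s, v_ml, p_m, p_s, p_joint, p_adj, signif_code.
#' @export
family_test <- function(windows, obs = NULL, n_families = NULL,
                        mode = c("equal_N", "unequal_N"),
                        label_m = NULL, label_s = NULL,
                        c_m = NULL, c_s = NULL, family = "family1") {
  mode <- match.arg(mode)
  if (is.null(obs)) {
    stopifnot(!is.null(c_m), !is.null(c_s))
    obs <- data.frame(family = family, c_m = c_m, c_s = c_s)
  }
  if (is.null(n_families)) n_families <- nrow(obs)
  stopifnot(n_families >= 1)
  rows <- lapply(seq_len(nrow(obs)), function(i) {
    ml <- find_ml_window(windows, obs$c_m[i], obs$c_s[i], mode = mode,
                         label_m = label_m, label_s = label_s)
    p_joint <- ml$p_m * ml$p_s
    p_adj <- min(1, p_joint * n_families)
    data.frame(family = obs$family[i],
               order = if ("order" %in% names(obs)) obs$order[i] else NA,
               c_m = obs$c_m[i], c_s = obs$c_s[i], v_ml = ml$v_ml,
               p_m = ml$p_m, p_s = ml$p_s, p_joint = p_joint,
               p_adj = p_adj, signif_code = signif_code(p_adj))
  })
  res <- do.call(rbind, rows)
  class(res) <- c("te_test", "data.frame")
  res
}

#' Significance coding of Bonferroni-adjusted p-values
#'
#' `**` below 0.001, `*` below 0.01, `+` below 0.05, otherwise `""`.
#'
#' @param p_adj adjusted p-value(s).
#' @return Character vector of codes.
#' @export
signif_code <- function(p_adj) {
  vapply(p_adj, function(p) {
    if (p < 0.001) "**" else if (p < 0.01) "*" else if (p < 0.05) "+" else ""
  }, character(1))
}

#' Population sizes from an effective-size ratio
#'
#' Given the large population size and the ratio of effective population
#' sizes (estimated as the ratio of nucleotide diversities of the two
#' species), returns the pair used for the unequal-N simulations; the
#' small size is `round(N_large / ratio)`.
#'
#' @param N_large large population size (default 10000).
#' @param ratio effective-size ratio > 0 (default 1.519).
#' @return Named integer vector `c(small = ..., large = ...)`.
#' @examples
#' ne_pop_sizes()  # small = 6583, large = 10000
#' @export
ne_pop_sizes <- function(N_large = 10000, ratio = 1.519) {
  stopifnot(ratio > 0)
  c(small = as.integer(round(N_large / ratio)),
    large = as.integer(N_large))
}

#' Read / write ensemble tables
#'
#' TSV with columns run_id, pop_label, N, v, c, extinct.
#' @param path file path.
#' @param ensemble a `te_ensemble`.
#' @return `read_ensemble` returns a `te_ensemble` data.frame.
#' @export
read_ensemble <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  req <- c("run_id", "pop_label", "N", "v", "c", "extinct")
  if (!all(req %in% names(d)))
    stop("ensemble TSV must have columns: ", paste(req, collapse = ", "))
  d$extinct <- as.logical(d$extinct)
  class(d) <- c("te_ensemble", "data.frame")
  d
}

#' @rdname read_ensemble
#' @export
write_ensemble <- function(ensemble, path) {
  data.table::fwrite(as.data.frame(ensemble), path, sep = "\t")
  invisible(path)
}
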