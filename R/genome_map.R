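#' Build an insertion-site genome map from a recombination-rate table
#'
#' Constructs the simulated insertion-site space: a set of chromosome-arm
#' segments in which every base pair is a potential TE insertion site, plus
#' a per-window recombination map. Windows with a rate below `min_rate`
#' (low-recombination regions) are excluded from the map before
#' construction, and the retained windows define the segments, so the total
#' site count `T` equals the summed segment lengths in bp.
#'
#' Coordinates in `recomb_table` and `arm_ranges` are 1-based inclusive
#' base-pair positions (the convention of recombination-rate calculators and
#' GFF); internally the map uses 0-based half-open coordinates, and site
#' indices form one contiguous 0-based range of length `T` across arms.
#' Each arm is an independent linkage group (free recombination between
#' arms).
#'
#' @param recomb_table data.frame with columns `arm`, `start`, `end`
#'   (1-based inclusive bp) and `rate` (cM/Mbp). Windows must tile each arm
#'   range without gaps or overlaps.
#' @param min_rate minimum recombination rate (cM/Mbp) for a window to be
#'   retained; default 1.
#' @param arm_ranges data.frame with columns `arm`, `start`, `end` (1-based
#'   inclusive bp) delimiting each arm. Defaults to the bounding range of
#'   `recomb_table` per arm.
#' @return An object of class `genome_map` with elements `segments`
#'   (data.frame: arm, start, end; 0-based half-open), `windows`
#'   (data.frame: arm, start, end, rate; 0-based half-open), `T` (total
#'   site count) and `arm_morgans` (genetic length per arm, Morgans).
#' @examples
#' rt <- data.frame(arm = "2L", start = 1, end = 1000, rate = 2)
#' gm <- build_genome_map(rt)
#' gm$T  # 1000
#' @export
build_genome_map <- function(recomb_table, min_rate = 1, arm_ranges = NULL) {
  req <- c("arm", "start", "end", "rate")
  if (!all(req %in% names(recomb_table)))
    stop("recomb_table needs columns: ", paste(req, collapse = ", "))
  rt <- as.data.frame(recomb_table)
  rt$arm <- as.character(rt$arm)
  # to 0-based half-open
  rt$start0 <- as.numeric(rt$start) - 1
  rt$end0 <- as.numeric(rt$end)
  if (any(rt$end0 <= rt$start0)) stop("recomb window with end <= start")
  if (min_rate < 0) stop("min_rate must be >= 0")

  if (is.null(arm_ranges)) {
    arm_ranges <- do.call(rbind, lapply(split(rt, rt$arm), function(d)
      data.frame(arm = d$arm[1], start = min(d$start), end = max(d$end))))
  }
  ar <- as.data.frame(arm_ranges)
  ar$arm <- as.character(ar$arm)
  ar$start0 <- as.numeric(ar$start) - 1
  ar$end0 <- as.numeric(ar$end)

  win <- list(); seg <- list(); arm_M <- numeric(0)
  for (i in seq_len(nrow(ar))) {
    a <- ar$arm[i]
    d <- rt[rt$arm == a, , drop = FALSE]
    if (nrow(d) == 0) stop("arm range '", a, "' not covered by any window")
    d <- d[order(d$start0), , drop = FALSE]
    d$start0 <- pmax(d$start0, ar$start0[i])
    d$end0 <- pmin(d$end0, ar$end0[i])
    d <- d[d$end0 > d$start0, , drop = FALSE]
    if (nrow(d) == 0) stop("arm range '", a, "' not covered by any window")
    if (any(d$start0[-1] < d$end0[-nrow(d)]))
      stop("overlapping recombination windows on arm '", a, "'")
    tiles <- all(d$start0[1] == ar$start0[i], d$end0[nrow(d)] == ar$end0[i],
                 nrow(d) == 1 || all(d$start0[-1] == d$end0[-nrow(d)]))
    if (!tiles)
      stop("recombination windows do not tile arm range '", a, "'")
    keep <- d[d$rate >= min_rate, , drop = FALSE]
    if (nrow(keep) == 0) next
    win[[a]] <- data.frame(arm = a, start = keep$start0, end = keep$end0,
                           rate = keep$rate)
    # coalesce adjacent retained windows into segments
    brk <- cumsum(c(TRUE, keep$start0[-1] != keep$end0[-nrow(keep)]))
    sg <- do.call(rbind, lapply(split(keep, brk), function(k)
      data.frame(arm = a, start = min(k$start0), end = max(k$end0))))
    seg[[a]] <- sg
  }
  if (length(win) == 0) stop("no windows retained: all below min_rate")
  windows <- do.call(rbind, win); rownames(windows) <- NULL
  segments <- do.call(rbind, seg); rownames(segments) <- NULL
  total_T <- sum(segments$end - segments$start)
  # genetic length per arm: cM/Mbp * bp / 1e6 / 100 = Morgans
  arm_morgans <- vapply(split(windows, windows$arm), function(d)
    sum(d$rate * (d$end - d$start)) / 1e8, numeric(1))
  structure(list(segments = segments, windows = windows, T = total_T,
                 arm_morgans = arm_morgans),
            class = "genome_map")
}

#' The Drosophila melanogaster arm ranges used for full-scale simulation
#'
#' The four high-recombination autosome-arm ranges (the X, chromosome 4 and
#' regions below 1 cM/Mbp are excluded); their summed length is the
#' full-scale insertion-site count T = 68,700,000.
#'
#' @return data.frame with columns `arm`, `start`, `end` (1-based inclusive).
#' @export
dmel_arm_ranges <- function() {
  data.frame(arm = c("2L", "2R", "3L", "3R"),
             start = c(300000, 3900000, 900000, 6600000) + 1,
             end = c(16600000, 20700000, 17400000, 25700000))
}

#' Full-scale D. melanogaster genome map with a uniform surrogate rate
#'
#' Builds the genome map over [dmel_arm_ranges()]. The published 1000-kb
#' recombination-rate profile is not bundled; a uniform surrogate rate
#' (default 2 cM/Mbp, a typical value for high-recombination arm regions)
#' is used instead, so this map is synthetic with respect to the fine-scale
#' recombination landscape while reproducing T = 68,700,000 exactly.
#'
#' @param rate uniform recombination rate in cM/Mbp.
#' @return A `genome_map`.
#' @export
dmel_genome_map <- function(rate = 2) {
  ar <- dmel_arm_ranges()
  rt <- data.frame(arm = ar$arm, start = ar$start, end = ar$end, rate = rate)
  build_genome_map(rt, min_rate = 1, arm_ranges = ar)
}

#' Scaled toy genome map for desk-scale simulation
#'
#' Equal-length arms, one recombination window each. The per-arm genetic
#' length (Morgans) is set directly, so a scaled map preserves the genetic
#' length of a Drosophila arm (about 0.5 Morgans) rather than its physical
#' rate density.
#'
#' @param total_sites total insertion-site count T.
#' @param n_arms number of arms (independent linkage groups).
#' @param morgans_per_arm genetic length of each arm.
#' @return A `genome_map`.
#' @export
toy_genome_map <- function(total_sites = 1e5, n_arms = 4,
                           morgans_per_arm = 0.5) {
  len <- floor(total_sites / n_arms)
  lens <- rep(len, n_arms)
  lens[n_arms] <- total_sites - len * (n_arms - 1)
  rate <- morgans_per_arm * 1e8 / lens  # cM/Mbp giving the target Morgans
  starts <- c(0, cumsum(lens))[seq_len(n_arms)]
  rt <- data.frame(arm = paste0("arm", seq_len(n_arms)),
                   start = 1, end = lens, rate = pmax(rate, 1))
  build_genome_map(rt, min_rate = 0)
}

#' Read a recombination map from TSV
#'
#' Expects columns `arm`, `start`, `end` (1-based inclusive bp) and
#' `rate` (cM/Mbp).
#'
#' @param path TSV file path.
#' @return data.frame suitable for [build_genome_map()].
#' @export
read_recomb_map <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  req <- c("arm", "start", "end", "rate")
  if (!all(req %in% names(d)))
    stop("recombination map must have columns: ", paste(req, collapse = ", "))
  d
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", nrow(x$segments), "segments over",
      length(unique(x$segments$arm)), "arms; T =",
      format(x$T, big.mark = ","), "sites\n")
  cat("genetic length (Morgans):",
      paste(sprintf("%s=%.3g", names(x$arm_morgans), x$arm_morgans),
            collapse = ", "), "\n")
  invisible(x)
}

# Internal: flatten a genome_map into the list consumed by the C++ engine.
# Site indices are remapped to one contiguous 0-based range of length T.
as_cpp_map <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  seg <- map$segments
  win <- map$windows
  arms <- unique(seg$arm)
  arm_start <- integer(0); arm_len <- integer(0); arm_M <- numeric(0)
  win_start <- integer(0); win_len <- integer(0); win_M <- numeric(0)
  arm_wb <- integer(0); arm_we <- integer(0)
  offset <- 0L
  for (a in arms) {
    sa <- seg[seg$arm == a, , drop = FALSE]
    wa <- win[win$arm == a, , drop = FALSE]
    wa <- wa[order(wa$start), , drop = FALSE]
    alen <- as.integer(sum(sa$end - sa$start))
    arm_start <- c(arm_start, offset)
    arm_len <- c(arm_len, alen)
    arm_wb <- c(arm_wb, length(win_start))
    # remap window bp spans onto the contiguous site range of this arm
    woff <- offset
    for (j in seq_len(nrow(wa))) {
      wl <- as.integer(wa$end[j] - wa$start[j])
      win_start <- c(win_start, woff)
      win_len <- c(win_len, wl)
      win_M <- c(win_M, wa$rate[j] * wl / 1e8)
      woff <- woff + wl
    }
    arm_we <- c(arm_we, length(win_start))
    arm_M <- c(arm_M, sum(wa$rate * (wa$end - wa$start)) / 1e8)
    offset <- offset + alen
  }
  list(T = as.integer(map$T), arm_start = arm_start, arm_len = arm_len,
       arm_M = arm_M, win_start = win_start, win_len = win_len,
       win_M = win_M, arm_win_begin = arm_wb, arm_win_end = arm_we)
}
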