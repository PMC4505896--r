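#' Configuration for the synthetic-data generators
#'
#' Bundles the scale and ground-truth parameters of the synthetic inputs.
#' Defaults are desk-scale: 20 families, N = 500 diploids, T = 1e5 sites,
#' 2000 generations, pool sampling of 145 haplotypes with minimum count 3
#' (the sampling design of the study the generators emulate).
#'
#' @param seed RNG seed; every generator is deterministic given the seed.
#' @param n_families number of TE families.
#' @param N diploid population size for per-family simulations.
#' @param total_sites insertion-site count T of the toy genome.
#' @param generations generations per simulation.
#' @param v_range transposition-rate range families are drawn from.
#' @param het_fraction fraction of families with truly heterogeneous
#'   rates between the two species (v drawn independently per species).
#' @param x,t,m0 fitness and initialization parameters
#'   (see [sim_params()]).
#' @param pool,min_count pool-sampling parameters.
#' @param missing_rate fraction of insertion records emitted with missing
#'   frequency (emulating overlapping insertions), default 0.1.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 42L, n_families = 20, N = 500,
                         total_sites = 1e5, generations = 2000,
                         v_range = c(0, 0.003), het_fraction = 0.5,
                         x = 4e-4, t = 1.3, m0 = 10,
                         pool = 145, min_count = 3, missing_rate = 0.1) {
  stopifnot(seed == round(seed), n_families >= 1, het_fraction >= 0,
            het_fraction <= 1)
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 N = as.integer(N), total_sites = total_sites,
                 generations = as.integer(generations), v_range = v_range,
                 het_fraction = het_fraction, x = x, t = t,
                 m0 = as.integer(m0), pool = as.integer(pool),
                 min_count = as.integer(min_count),
                 missing_rate = missing_rate),
            class = "synth_config")
}

#' Synthetic per-family copy-number observations for two species
#'
#' Assigns each family a transposition rate per species (a `het_fraction`
#' of families get independent rates, the rest share one rate), then
#' generates the observed copy numbers either by running the forward
#' simulator twice per family (`method = "simulate"`) or by drawing from
#' window-level normal fits of a supplied ensemble
#' (`method = "normal"`, fast; requires `windows`). The manifest records
#' the true rates and which families are heterogeneous.
#'
#' @param config a `synth_config`.
#' @param method `"simulate"` or `"normal"`.
#' @param windows a `te_windows` table (required for `method = "normal"`).
#' @param genome optional `genome_map`; defaults to
#'   `toy_genome_map(config$total_sites)`.
#' @return List: `observations` (data.frame: family, order, c_m, c_s) and
#'   `manifest` (data.frame: family, v_m, v_s, heterogeneous).
#' @export
synth_family_observations <- function(config,
                                      method = c("simulate", "normal"),
                                      windows = NULL, genome = NULL) {
  stopifnot(inherits(config, "synth_config"))
  method <- match.arg(method)
  set.seed(config$seed)
  nf <- config$n_families
  fam <- sprintf("FAM%02d", seq_len(nf))
  orders <- sample(c("LTR", "non-LTR", "TIR"), nf, replace = TRUE)
  v_m <- runif(nf, config$v_range[1], config$v_range[2])
  het <- seq_len(nf) <= round(config$het_fraction * nf)
  v_s <- ifelse(het, runif(nf, config$v_range[1], config$v_range[2]), v_m)

  draw_c <- function(v, fam_seed) {
    if (method == "simulate") {
      if (is.null(genome)) genome <- toy_genome_map(config$total_sites)
      set.seed(fam_seed)
      p <- sim_params(genome, N = config$N, v = v, x = config$x,
                      t = config$t, generations = config$generations,
                      m0 = config$m0,
                      sample_haplotypes = config$pool,
                      min_count = config$min_count)
      tr <- run_simulation(p, track_sites = FALSE, keep_population = FALSE)
      if (tr$extinct) NA_integer_ else tr$sample$c
    } else {
      if (is.null(windows)) stop("method = 'normal' requires windows")
      u <- windows[windows$usable, , drop = FALSE]
      i <- which.min(abs((u$v_lo + u$v_hi) / 2 - v))
      set.seed(fam_seed)
      max(0L, as.integer(round(rnorm(1, u$mu[i], u$sigma[i]))))
    }
  }
  c_m <- integer(nf); c_s <- integer(nf)
  for (i in seq_len(nf)) {
    c_m[i] <- draw_c(v_m[i], config$seed + 1000L + i)
    c_s[i] <- draw_c(v_s[i], config$seed + 2000L + i)
  }
  list(observations = data.frame(family = fam, order = orders,
                                 c_m = c_m, c_s = c_s),
       manifest = data.frame(family = fam, v_m = v_m, v_s = v_s,
                             heterogeneous = het))
}

#' Synthetic per-insertion frequency tables for two species
#'
#' For each species and family a small forward simulation is run and the
#' final generation pool-sampled, giving per-site sample frequencies in
#' \[min_count/pool, 1\]. A subset of families receives a planted shared
#' high-frequency insertion pair (both species f >= 0.8) and one planted
#' non-qualifying pair (one side < 0.8); a `missing_rate` fraction of
#' records per species is emitted with missing frequency, emulating
#' overlapping insertions. The manifest records every planted pair and
#' each family's expected shared-high status.
#'
#' @param config a `synth_config`; family simulations are scaled down
#'   internally (N, T, generations divided) to keep the generator fast.
#' @param n_shared number of families given a qualifying shared
#'   high-frequency pair (default 5); the next `n_near` families get a
#'   non-qualifying pair.
#' @param n_near number of families with a non-qualifying pair
#'   (default 3).
#' @return List: `records1`, `records2` (insertion tables: chromosome,
#'   position, family, order, frequency), `shared_pairs` (family, pos1,
#'   pos2, f1, f2), `manifest` (family, shared_high_expected).
#' @export
synth_insertion_table <- function(config, n_shared = 5, n_near = 3) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nf <- config$n_families
  fam <- sprintf("FAM%02d", seq_len(nf))
  orders <- sample(c("LTR", "non-LTR", "TIR"), nf, replace = TRUE)
  # deliberately tiny per-family scale: the generator's job is structure,
  # not equilibrium accuracy
  Ns <- max(100L, config$N %/% 5L)
  Ts <- max(1e4, config$total_sites / 10)
  gens <- max(300L, config$generations %/% 5L)
  pool <- min(config$pool, 2L * Ns)
  genome <- toy_genome_map(Ts)
  v_fam <- runif(nf, pmax(config$v_range[1], 5e-4), config$v_range[2])

  seg <- genome$segments
  site_to_pos <- function(site) {
    offs <- cumsum(c(0, seg$end - seg$start))
    i <- findInterval(site, offs, rightmost.closed = FALSE)
    data.frame(chromosome = seg$arm[i],
               position = seg$start[i] + (site - offs[i]) + 1L)
  }
  one_species <- function(sp) {
    recs <- vector("list", nf)
    for (i in seq_len(nf)) {
      set.seed(config$seed + sp * 10000L + i)
      p <- sim_params(genome, N = Ns, v = v_fam[i], x = config$x,
                      t = config$t, generations = gens, m0 = config$m0,
                      sample_haplotypes = pool,
                      min_count = config$min_count)
      tr <- run_simulation(p, track_sites = FALSE, keep_population = FALSE)
      if (tr$extinct || tr$sample$c == 0) {
        recs[[i]] <- NULL
        next
      }
      s <- tr$sample$sites
      pos <- site_to_pos(s$site)
      recs[[i]] <- data.frame(chromosome = pos$chromosome,
                              position = pos$position, family = fam[i],
                              order = orders[i], frequency = s$freq)
    }
    do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  }
  r1 <- one_species(1); r2 <- one_species(2)

  # planted shared pairs
  shared_fams <- fam[seq_len(min(n_shared, nf))]
  near_fams <- fam[seq_len(min(n_shared + n_near, nf))][-seq_len(min(n_shared, nf))]
  set.seed(config$seed + 777L)
  plant <- function(fams, f1r, f2r) {
    if (length(fams) == 0)
      return(data.frame(family = character(0), pos1 = integer(0),
                        pos2 = integer(0), f1 = numeric(0), f2 = numeric(0)))
    data.frame(family = fams,
               pos1 = sample.int(1e6, length(fams)),
               pos2 = sample.int(1e6, length(fams)),
               f1 = runif(length(fams), f1r[1], f1r[2]),
               f2 = runif(length(fams), f2r[1], f2r[2]))
  }
  sp_good <- plant(shared_fams, c(0.8, 1), c(0.8, 1))
  sp_near <- plant(near_fams, c(0.8, 1), c(0.3, 0.79))
  shared_pairs <- rbind(sp_good, sp_near)
  add_pair_records <- function(r, pairs, which_f, which_pos) {
    if (nrow(pairs) == 0) return(r)
    ord <- orders[match(pairs$family, fam)]
    rbind(r, data.frame(chromosome = "armS", position = pairs[[which_pos]],
                        family = pairs$family, order = ord,
                        frequency = pairs[[which_f]]))
  }
  r1 <- add_pair_records(r1, shared_pairs, "f1", "pos1")
  r2 <- add_pair_records(r2, shared_pairs, "f2", "pos2")

  # overlapping insertions: missing frequency
  miss <- function(r, k) {
    n_miss <- round(config$missing_rate * nrow(r))
    if (n_miss == 0) return(r)
    set.seed(config$seed + 888L + k)
    extra <- r[sample.int(nrow(r), n_miss), , drop = FALSE]
    extra$frequency <- NA_real_
    extra$position <- extra$position + 7L
    rbind(r, extra)
  }
  r1 <- miss(r1, 1); r2 <- miss(r2, 2)
  rownames(r1) <- rownames(r2) <- NULL
  list(records1 = r1, records2 = r2, shared_pairs = shared_pairs,
       manifest = data.frame(family = fam,
                             shared_high_expected = fam %in% shared_fams))
}

#' Synthetic annotation fixture with planted boundary cases
#'
#' Builds a toy TE annotation, microsatellite annotation and
#' orthologous-block table that exercise every refinement rule at its
#' boundary, together with expected outputs computed by construction from
#' the planted cases (an oracle independent of the refinement code):
#'
#' * microsatellite overlaps of 29, 30 and 31 bases on 100-bp TEs
#'   (kept / removed / removed at the 30% threshold);
#' * same-family fragment pairs with gaps on both sides of the linking
#'   threshold, including the exact-equality boundary (not linked);
#' * an overlapping same-family pair (merged) and a nested cross-family
#'   pair (shorter dropped) and a partial cross-family overlap
#'   (shorter truncated);
#' * features of 99 and 100 bp at the minimum-length filter;
#' * block gaps of 19,999 / 20,000 / 20,001 bp at the 20-kb linking
#'   threshold.
#'
#' @param config a `synth_config` (only the seed is used).
#' @param dir optional directory; when given, writes `te_raw.gff3`,
#'   `microsats.gff3`, `expected_refined.gff3`, `blocks.tsv`,
#'   `expected_linked.tsv` and returns the paths in the result.
#' @return List: `tes`, `microsats`, `expected_refined`, `blocks`,
#'   `expected_linked`, `manifest` (planted case -> expected
#'   disposition), and `paths` when `dir` is given.
#' @export
synth_annotation_fixture <- function(config = synth_config(), dir = NULL) {
  f <- function(chrom, start, end, family, order = "LTR")
    feature_table(chrom, start, end, family, order = order)
  manifest <- list()
  tes <- list(); ms <- list(); exp_out <- list()
  note <- function(case, disposition)
    manifest[[length(manifest) + 1]] <<- data.frame(case = case,
                                                    disposition = disposition)

  # -- chrM: microsatellite overlap boundaries (100-bp TEs) --------------
  tes$m1 <- f("chrM", 1000, 1100, "famA")   # overlap 29 -> kept
  ms$m1 <- f("chrM", 1071, 1200, "ms")
  exp_out$m1 <- feature_table("chrM", 1000, 1100, "famA", order = "LTR",
                              score = 100)
  note("microsat_29_of_100", "kept")
  tes$m2 <- f("chrM", 3000, 3100, "famA")   # overlap 30 -> removed
  ms$m2 <- f("chrM", 3070, 3200, "ms")
  note("microsat_30_of_100", "removed")
  tes$m3 <- f("chrM", 5000, 5100, "famA")   # overlap 31 -> removed
  ms$m3 <- f("chrM", 5069, 5200, "ms")
  note("microsat_31_of_100", "removed")

  # -- chrL: same-family linking ----------------------------------------
  # lengths 150/120, gap 20: 0.5*20 = 10 < 120 -> linked
  tes$l1a <- f("chrL", 1000, 1150, "famB")
  tes$l1b <- f("chrL", 1170, 1290, "famB")
  exp_out$l1 <- feature_table("chrL", 1000, 1290, "famB", order = "LTR",
                              score = 150 + 120 - 0.5 * 20)
  note("link_gap20", "linked")
  # lengths 150/120, gap 300: 0.5*300 = 150 > 120 -> not linked
  tes$l2a <- f("chrL", 9000, 9150, "famB")
  tes$l2b <- f("chrL", 9450, 9570, "famB")
  exp_out$l2a <- feature_table("chrL", 9000, 9150, "famB", order = "LTR",
                               score = 150)
  exp_out$l2b <- feature_table("chrL", 9450, 9570, "famB", order = "LTR",
                               score = 120)
  note("link_gap300", "not_linked")
  # lengths 150/120, gap 240: 0.5*240 = 120 == min -> not linked (strict)
  tes$l3a <- f("chrL", 20000, 20150, "famB")
  tes$l3b <- f("chrL", 20390, 20510, "famB")
  exp_out$l3a <- feature_table("chrL", 20000, 20150, "famB", order = "LTR",
                               score = 150)
  exp_out$l3b <- feature_table("chrL", 20390, 20510, "famB", order = "LTR",
                               score = 120)
  note("link_gap_equality", "not_linked")
  # overlapping same family -> merged
  tes$l4a <- f("chrL", 30000, 30200, "famB")
  tes$l4b <- f("chrL", 30150, 30400, "famB")
  exp_out$l4 <- feature_table("chrL", 30000, 30400, "famB", order = "LTR",
                              score = 400)
  note("overlap_merge", "merged")

  # -- chrX2: cross-family overlap resolution ---------------------------
  # B nested in longer A -> B dropped
  tes$x1a <- f("chrX2", 1000, 2000, "famC", order = "TIR")
  tes$x1b <- f("chrX2", 1300, 1700, "famD", order = "TIR")
  exp_out$x1 <- feature_table("chrX2", 1000, 2000, "famC", order = "TIR",
                              score = 1000)
  note("nested_cross_family", "shorter_dropped")
  # partial overlap: B [5500,6400) truncated to [6000,6400) by A [5000,6000)
  tes$x2a <- f("chrX2", 5000, 6000, "famC", order = "TIR")
  tes$x2b <- f("chrX2", 5500, 6400, "famD", order = "TIR")
  exp_out$x2a <- feature_table("chrX2", 5000, 6000, "famC", order = "TIR",
                               score = 1000)
  exp_out$x2b <- feature_table("chrX2", 6000, 6400, "famD", order = "TIR",
                               score = 900)
  note("partial_cross_family", "shorter_truncated")

  # -- chrS: minimum-length filter --------------------------------------
  tes$s1 <- f("chrS", 1000, 1099, "famE", order = "non-LTR")  # 99 -> dropped
  tes$s2 <- f("chrS", 2000, 2100, "famE", order = "non-LTR")  # 100 -> kept
  exp_out$s2 <- feature_table("chrS", 2000, 2100, "famE", order = "non-LTR",
                              score = 100)
  note("length_99", "dropped")
  note("length_100", "kept")

  te_raw <- do.call(rbind, tes)
  microsats <- do.call(rbind, ms)
  expected <- do.call(rbind, unname(exp_out))
  expected <- expected[order(expected$chrom, expected$start), , drop = FALSE]
  rownames(te_raw) <- rownames(microsats) <- rownames(expected) <- NULL
  class(te_raw) <- class(microsats) <- class(expected) <-
    c("te_features", "data.frame")

  # -- orthologous blocks: 20-kb gap boundary ---------------------------
  blocks <- data.frame(
    chromA = "2L", chromB = "chr2L",
    startA = c(0,     25000, 60000,  100100, 200000, 240001),
    endA =   c(5000,  40000, 100000, 150000, 220000, 260000),
    startB = c(0,     23000, 61000,  101000, 200000, 240100),
    endB =   c(5000,  41000, 101000, 151000, 219000, 259000))
  # gaps (A, B): (20000, 18000) -> merged; (20000, 20000) -> merged;
  # (100, 0) -> merged; (50000, 49000) -> new; (20001, 21100) -> new
  expected_linked <- data.frame(
    chromA = "2L", chromB = "chr2L",
    startA = c(0, 200000, 240001), endA = c(150000, 220000, 260000),
    startB = c(0, 200000, 240100), endB = c(151000, 219000, 259000))
  note("block_gaps_le_20000", "merged")
  note("block_gap_20001", "not_merged")

  manifest <- do.call(rbind, manifest)
  out <- list(tes = te_raw, microsats = microsats,
              expected_refined = expected, blocks = blocks,
              expected_linked = expected_linked, manifest = manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      te_raw = file.path(dir, "te_raw.gff3"),
      microsats = file.path(dir, "microsats.gff3"),
      expected_refined = file.path(dir, "expected_refined.gff3"),
      blocks = file.path(dir, "blocks.tsv"),
      expected_linked = file.path(dir, "expected_linked.tsv"),
      manifest = file.path(dir, "manifest.tsv"))
    write_te_gff(te_raw, paths$te_raw)
    write_te_gff(microsats, paths$microsats)
    write_te_gff(expected, paths$expected_refined)
    write_blocks(blocks, paths$blocks)
    write_blocks(expected_linked, paths$expected_linked)
    data.table::fwrite(manifest, paths$manifest, sep = "\t")
    out$paths <- paths
  }
  out
}
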