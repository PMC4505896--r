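#' Simulation parameters for the equilibrium TE model
#'
#' Bundles and validates the parameters of the forward-in-time simulation.
#' The fitness function is `w = 1 - x * g^t` (clamped at 0), where `g` is
#' the diploid TE copy number; `x` scales the selective impact of an
#' insertion and `t` is the synergism exponent, which must exceed 1 for a
#' stable transposition-selection equilibrium. Excision is not modelled
#' (u = 0).
#'
#' @param genome a `genome_map` (see [build_genome_map()]).
#' @param N diploid population size (>= 2).
#' @param v per-copy per-generation transposition probability.
#' @param x selective impact scale (default 4e-4).
#' @param t synergism exponent (default 1.3; warns if <= 1).
#' @param generations number of generations to simulate.
#' @param m0 initial insertions per haploid genome, placed uniformly at
#'   random (default 10); the model needs a burn-in of several thousand
#'   generations to forget this choice.
#' @param sample_haplotypes haploid genomes drawn (without replacement)
#'   from the final generation, default 145.
#' @param min_count minimum count among sampled haplotypes for an
#'   insertion to be identified, default 3.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(genome, N = 1000, v = 0.002, x = 4e-4, t = 1.3,
                       generations = 4000, m0 = 10,
                       sample_haplotypes = 145, min_count = 3) {
  stopifnot(inherits(genome, "genome_map"))
  if (N < 2) stop("N must be >= 2")
  if (v < 0 || v > 1) stop("v must be in [0, 1]")
  if (x < 0) stop("x must be >= 0")
  if (t <= 0) stop("t must be > 0")
  if (t <= 1 && x > 0)
    warning("stable transposition-selection equilibria require t > 1")
  if (generations < 0) stop("generations must be >= 0")
  if (sample_haplotypes > 2 * N)
    stop("sample_haplotypes must be <= 2N")
  structure(list(genome = genome, N = as.integer(N), v = v, x = x, t = t,
                 generations = as.integer(generations), m0 = as.integer(m0),
                 sample_haplotypes = as.integer(sample_haplotypes),
                 min_count = as.integer(min_count)),
            class = "sim_params")
}

#' Fitness of an individual carrying g TE insertions
#'
#' `w = max(0, 1 - x * g^t)`; `g = 0` gives exactly 1. Negative values of
#' the raw expression are clamped to 0 (inviable) because the polynomial
#' form is a truncated approximation of an exponentially decreasing
#' fitness.
#'
#' @param g diploid copy number(s), >= 0.
#' @param x selective impact scale, >= 0.
#' @param t synergism exponent, > 0.
#' @return Fitness value(s) in \[0, 1\].
#' @examples
#' fitness(100, 0.0004, 1.3)  # ~0.8408
#' @export
fitness <- function(g, x = 4e-4, t = 1.3) {
  stopifnot(all(g >= 0), x >= 0, t > 0)
  pmax(0, 1 - x * g^t)
}

#' Mating probabilities under fecundity selection
#'
#' Probability of being drawn as a parent scales linearly with fitness:
#' `p_i = w_i / sum(w)` (equivalently `w_i / (N * wbar)`).
#'
#' @param w vector of fitness values, all >= 0; at least two must be
#'   positive, otherwise the population cannot form a mating pair and the
#'   extinction condition is signalled as an error of class
#'   `te_extinction`.
#' @return Probability vector summing to 1.
#' @export
mating_probabilities <- function(w) {
  if (any(w < 0)) stop("fitness values must be >= 0")
  if (sum(w > 0) < 2)
    stop(structure(class = c("te_extinction", "error", "condition"),
                   list(message = "population extinct: fewer than two individuals with positive fitness",
                        call = sys.call(-1))))
  w / sum(w)
}

#' Draw one recombinant gamete from a parent
#'
#' Per linkage group (arm), the crossover count is Poisson with mean equal
#' to the arm's genetic length in Morgans; breakpoint positions have
#' density proportional to the per-window recombination rate; parental
#' phase alternates between breakpoints with no interference; arms assort
#' independently.
#'
#' @param parent list of two haplotypes (sorted integer vectors of 0-based
#'   site indices) or a single individual from a population object.
#' @param genome a `genome_map`.
#' @return Integer vector: one recombinant haplotype.
#' @export
make_gamete <- function(parent, genome) {
  stopifnot(inherits(genome, "genome_map"), length(parent) == 2)
  cpp_make_gamete(as.integer(parent[[1]]), as.integer(parent[[2]]),
                  as_cpp_map(genome))
}

#' Apply one round of transposition to a haplotype pair
#'
#' The number of attempted transpositions is Binomial(g, v) with g the
#' diploid copy count; each new insertion is placed uniformly at random
#' over all T sites on a uniformly chosen haplotype of the pair; attempts
#' landing on an occupied site of that haplotype are discarded. Excisions
#' never occur.
#'
#' @param pair list of two haplotypes (sorted 0-based site indices).
#' @param v transposition probability in \[0, 1\].
#' @param genome a `genome_map`.
#' @return List of the two updated haplotypes.
#' @export
transpose <- function(pair, v, genome) {
  stopifnot(v >= 0, v <= 1, inherits(genome, "genome_map"))
  res <- cpp_transpose(as.integer(pair[[1]]), as.integer(pair[[2]]), v,
                       as.integer(genome$T))
  list(res$h1, res$h2)
}

#' Advance a population by one generation
#'
#' N offspring are produced; for each, two distinct parents are sampled
#' with probability proportional to their stored fitness (the second
#' parent is redrawn until it differs from the first), each contributes
#' one recombinant gamete, offspring fitness is evaluated on the
#' pre-transposition genome and stored for the next round of mating, and
#' transpositions are then applied (new insertions affect fitness only in
#' the next generation).
#'
#' @param pop a `te_population`: list with `haplotypes` (list of 2N sorted
#'   integer vectors), `fitness` (length-N vector) and `N`.
#' @param params a `sim_params`.
#' @return Updated `te_population`; errors with class `te_extinction` if
#'   fewer than two individuals have positive fitness.
#' @export
step_generation <- function(pop, params) {
  stopifnot(inherits(params, "sim_params"))
  res <- cpp_step_generation(pop$haplotypes, pop$fitness,
                             as_cpp_map(params$genome),
                             params$v, params$x, params$t)
  if (isTRUE(res$extinct))
    stop(structure(class = c("te_extinction", "error", "condition"),
                   list(message = "population extinct", call = sys.call())))
  te_population(res$haplotypes, fitness = res$fitness)
}

#' Construct a population object
#'
#' @param haplotypes list of 2N sorted integer vectors (0-based site
#'   indices); haplotypes 2i-1 and 2i belong to individual i.
#' @param fitness optional length-N fitness vector; computed from `x`, `t`
#'   if missing.
#' @param x,t fitness parameters used when `fitness` is missing.
#' @return An object of class `te_population`.
#' @export
te_population <- function(haplotypes, fitness = NULL, x = 4e-4, t = 1.3) {
  if (length(haplotypes) %% 2 != 0)
    stop("haplotypes must come in pairs (2N entries)")
  N <- length(haplotypes) / 2
  if (is.null(fitness)) {
    g <- vapply(seq_len(N), function(i)
      length(haplotypes[[2 * i - 1]]) + length(haplotypes[[2 * i]]),
      numeric(1))
    fitness <- fitness(g, x, t)
  }
  structure(list(haplotypes = haplotypes, fitness = fitness,
                 N = as.integer(N)),
            class = "te_population")
}

#' Diploid copy numbers of a population
#' @param pop a `te_population`.
#' @return Integer vector of length N.
#' @export
copy_numbers <- function(pop) {
  vapply(seq_len(pop$N), function(i)
    length(pop$haplotypes[[2 * i - 1]]) + length(pop$haplotypes[[2 * i]]),
    integer(1))
}

#' Run a forward simulation
#'
#' Initializes each haploid genome with `m0` insertions placed uniformly at
#' random, iterates [step_generation()] for `params$generations`
#' generations and records a trajectory (per-generation mean diploid copy
#' number and, if `track_sites`, fixed and segregating site counts).
#' Finally the pool-style sample of the last generation is taken with
#' [sample_pool()]. Identical seed and parameters give identical results.
#'
#' @param params a `sim_params`.
#' @param track_sites record fixed/segregating site counts per generation
#'   (needs working memory of order T; default TRUE).
#' @param keep_population return the final population (default TRUE).
#' @return An object of class `te_trajectory`: `mean_copy` (length
#'   generations+1), `n_fixed`, `n_seg`, `extinct`, `extinct_generation`,
#'   `population` (a `te_population` or NULL), and `sample` (result of
#'   [sample_pool()], NULL if extinct) with final sampled copy number
#'   `sample$c`.
#' @export
run_simulation <- function(params, track_sites = TRUE,
                           keep_population = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  res <- cpp_run_simulation(as_cpp_map(params$genome), params$N, params$v,
                            params$x, params$t, params$generations,
                            params$m0, isTRUE(track_sites))
  pop <- NULL
  smp <- NULL
  if (!res$extinct) {
    hl <- res$hap_len
    haps <- split(res$hap_sites, rep.int(seq_along(hl), hl))
    haps <- unname(lapply(haps, as.integer))
    # haplotypes with zero copies drop out of split(); reinsert them
    full <- rep(list(integer(0)), length(hl))
    full[hl > 0] <- haps
    pop <- te_population(full, x = params$x, t = params$t)
    smp <- sample_pool(pop, params$sample_haplotypes, params$min_count)
  }
  structure(list(params = params, mean_copy = res$mean_copy,
                 n_fixed = res$n_fixed, n_seg = res$n_seg,
                 extinct = res$extinct,
                 extinct_generation = if (res$extinct) res$extinct_generation else NA_integer_,
                 population = if (keep_population) pop else NULL,
                 sample = smp),
            class = "te_trajectory")
}

#' @export
print.te_trajectory <- function(x, ...) {
  g <- length(x$mean_copy) - 1
  if (x$extinct) {
    cat("te_trajectory: EXTINCT at generation", x$extinct_generation, "\n")
  } else {
    cat("te_trajectory:", g, "generations; final mean copy number",
        sprintf("%.2f", x$mean_copy[g + 1]), "\n")
    if (!is.null(x$sample))
      cat("sampled copy number c =", x$sample$c, "(",
          x$sample$n_haplotypes, "haplotypes, min count",
          x$sample$min_count, ")\n")
  }
  invisible(x)
}

#' Pool-style sampling of a population
#'
#' Draws `n_haplotypes` haploid genomes without replacement from the 2N of
#' the population and identifies a TE insertion at a site when its count
#' among the sampled haplotypes is at least `min_count`. This emulates
#' Pool-Seq insertion calling at a given physical coverage.
#'
#' @param pop a `te_population` (or plain list of haplotypes).
#' @param n_haplotypes haploid sample size (default 145); must be <= 2N.
#' @param min_count minimum count to identify an insertion (default 3).
#' @return List with `c` (number of identified insertions), `sites`
#'   (data.frame: site, count, freq = count / n_haplotypes for identified
#'   sites), `n_haplotypes`, `min_count`.
#' @export
sample_pool <- function(pop, n_haplotypes = 145, min_count = 3) {
  haps <- if (inherits(pop, "te_population")) pop$haplotypes else pop
  if (n_haplotypes > length(haps))
    stop("n_haplotypes exceeds the 2N available haplotypes")
  idx <- sample.int(length(haps), n_haplotypes)
  s <- sort(unlist(haps[idx], use.names = FALSE))
  if (length(s) == 0) {
    sites <- data.frame(site = integer(0), count = integer(0),
                        freq = numeric(0))
  } else {
    r <- rle(s)
    keep <- r$lengths >= min_count
    sites <- data.frame(site = r$values[keep], count = r$lengths[keep],
                        freq = r$lengths[keep] / n_haplotypes)
  }
  list(c = nrow(sites), sites = sites,
       n_haplotypes = as.integer(n_haplotypes),
       min_count = as.integer(min_count))
}

#' Closed-form equilibrium copy number approximation
#'
#' Transposition-selection balance `v = x * t * g^(t-1)` gives
#' `g = (v / (x t))^(1 / (t - 1))`. This neglects the mean-fitness
#' normalization of the selection differential and is accurate only while
#' `x * g^t << 1` (small fitness load), i.e. at the low end of the
#' transposition-rate range; see [equilibrium_recursion()] for the
#' numerical mean-field prediction without that assumption.
#'
#' @param v transposition rate.
#' @param x,t fitness parameters.
#' @return Approximate equilibrium mean diploid copy number.
#' @export
equilibrium_copy_number <- function(v, x = 4e-4, t = 1.3) {
  (v / (x * t))^(1 / (t - 1))
}

#' Deterministic mean-field recursion for the equilibrium copy number
#'
#' Iterates `g' = (1 + v) * E[g w] / E[w]` with g Poisson-distributed
#' around the current mean (the infinite-population, linkage-equilibrium
#' approximation of the simulator). Serves as an independent oracle for
#' the stochastic simulation.
#'
#' @param v transposition rate.
#' @param x,t fitness parameters.
#' @param g0 starting mean copy number.
#' @param generations iterations (default 20000, enough for convergence
#'   throughout the default rate range).
#' @return Mean copy number after iteration (the fixed point for large
#'   `generations`).
#' @export
equilibrium_recursion <- function(v, x = 4e-4, t = 1.3, g0 = 20,
                                  generations = 20000) {
  gbar <- g0
  for (i in seq_len(generations)) {
    gmax <- max(50, ceiling(gbar + 10 * sqrt(gbar) + 20))
    g <- 0:gmax
    p <- stats::dpois(g, gbar)
    w <- pmax(0, 1 - x * g^t)
    denom <- sum(p * w)
    if (denom <= 0) return(0)
    gbar <- (1 + v) * sum(g * p * w) / denom
  }
  gbar
}
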