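#' Configuration for the forward Wright-Fisher simulation
#'
#' The default demography mirrors a bottlenecked wild sexual population: an
#' ancestral population of `N` diploids burns in for `burn_in` generations,
#' contracts to `bottleneck_frac * N` at `bottleneck_start` generations
#' before present, and at `split_time` generations before present splits
#' into subpopulations of `split_frac * N` that either self (selfing rate 1)
#' or outcross (rate 0); a standard-neutral-model (SNM) arm keeps constant
#' `N`, random mating and neutral mutations throughout. Mutations arise at
#' `mu` per bp per generation; under the `"deleterious"` scenario, new
#' exonic mutations are deleterious with probability `p_deleterious`, with
#' `|s|` drawn from a gamma distribution of fitness effects and dominance
#' `h` (0 = fully recessive); under `"neutral"` every mutation has `s = 0`.
#'
#' @param N ancestral diploid population size.
#' @param burn_in burn-in generations (default `10 * N`).
#' @param bottleneck_frac,split_frac population-size fractions of the
#'   bottleneck and post-split subpopulations.
#' @param bottleneck_start,split_time epoch boundaries in generations before
#'   present (strictly decreasing).
#' @param L simulated sequence length in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param r per-bp per-generation recombination rate.
#' @param scenario `"deleterious"` or `"neutral"`.
#' @param p_deleterious probability a new exonic mutation is deleterious
#'   under the deleterious scenario.
#' @param dfe_shape,dfe_mean gamma DFE shape and mean `|s|`.
#' @param h dominance coefficient of deleterious mutations.
#' @param exon_frac,exon_mean_bp synthetic exon-mask coverage and mean exon
#'   length (the mask is regenerated deterministically from the run seed).
#' @param n_sample diploids sampled at the end of each replicate.
#' @param replicates replicate count.
#' @return a `sim_config` list.
#' @export
sim_config <- function(N = 1000, burn_in = 10 * N, bottleneck_frac = 0.25,
                       split_frac = 0.1, bottleneck_start = 10000,
                       split_time = 2000, L = 1e6, mu = 2.2e-8, r = 1.0e-7,
                       scenario = c("deleterious", "neutral"),
                       p_deleterious = 1.0, dfe_shape = 0.186,
                       dfe_mean = 0.01, h = 0, exon_frac = 0.25,
                       exon_mean_bp = 300, n_sample = 20, replicates = 100) {
  scenario <- match.arg(scenario)
  stopifnot(N >= 2, mu >= 0, r >= 0, h >= 0, h <= 1,
            bottleneck_start > split_time, split_time > 0,
            bottleneck_frac > 0, split_frac > 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

make_exon_mask <- function(L, exon_frac, mean_len) {
  if (exon_frac <= 0) return(list(start = numeric(0), end = numeric(0)))
  gap_mean <- mean_len * (1 - exon_frac) / exon_frac
  starts <- ends <- numeric(0)
  at <- stats::rexp(1, 1 / gap_mean)
  while (at < L) {
    len <- stats::rexp(1, 1 / mean_len)
    starts <- c(starts, at); ends <- c(ends, min(at + len, L))
    at <- at + len + stats::rexp(1, 1 / gap_mean)
  }
  list(start = starts, end = ends)
}

arm_schedule <- function(cfg, arm) {
  if (arm == "snm") {
    total <- cfg$burn_in + cfg$bottleneck_start
    return(list(gens = total, N = cfg$N, selfing = 0))
  }
  selfing <- if (arm == "selfing") 1 else 0
  list(gens = c(cfg$burn_in, cfg$bottleneck_start - cfg$split_time,
                cfg$split_time),
       N = c(cfg$N, max(2, round(cfg$bottleneck_frac * cfg$N)),
             max(2, round(cfg$split_frac * cfg$N))),
       selfing = c(0, 0, selfing))
}

run_arm_once <- function(cfg, arm, mask) {
  sched <- arm_schedule(cfg, arm)
  deleterious <- cfg$scenario == "deleterious" && arm != "snm"
  wf_simulate(as.integer(sched$gens), as.integer(sched$N),
              as.numeric(sched$selfing), cfg$L, cfg$mu, cfg$r,
              mask$start, mask$end, deleterious, cfg$p_deleterious,
              cfg$dfe_shape, cfg$dfe_mean, cfg$h,
              as.integer(cfg$n_sample), 100000L)
}

#' Run the forward simulation over all arms and replicates
#'
#' Simulates the `selfing`, `outcrossing` and `snm` arms for
#' `cfg$replicates` replicates each and summarizes the final-generation
#' sample of each replicate (per-bp diversity, heterozygosity, deleterious
#' site counts). Deterministic under `(cfg, seed)`; a replicate whose
#' population collapses (all fitness zero) is rerun with a fresh derived
#' seed up to `retry_cap` times.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; per-replicate, per-arm seeds are derived from
#'   it deterministically.
#' @param arms arms to run.
#' @param retry_cap replicate retries after a fitness collapse.
#' @return object of class `sim_result`: data frame `results` (`replicate`,
#'   `arm`, `pi`, `het`, `n_het_del`, `n_hom_del`, `n_segregating`) with the
#'   config and seed attached.
#' @export
run_sim <- function(cfg = sim_config(), seed = 1,
                    arms = c("selfing", "outcrossing", "snm"),
                    retry_cap = 5) {
  set.seed(seed)
  mask <- make_exon_mask(cfg$L, cfg$exon_frac, cfg$exon_mean_bp)
  rows <- list()
  for (arm in arms) {
    ai <- match(arm, c("selfing", "outcrossing", "snm"))
    for (rep in seq_len(cfg$replicates)) {
      for (try in 0:retry_cap) {
        s <- (abs(seed) * 7L + ai * 1009L + rep * 9973L + try * 7919L) %%
          2147483647L
        set.seed(s)
        res <- run_arm_once(cfg, arm, mask)
        if (!isTRUE(res$failed)) break
      }
      if (isTRUE(res$failed))
        stop("replicate ", rep, " (", arm, ") collapsed after ", retry_cap,
             " retries")
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep, arm = arm, pi = res$pi, het = res$het,
        n_het_del = res$n_het_del, n_hom_del = res$n_hom_del,
        n_segregating = res$n_segregating, stringsAsFactors = FALSE)
    }
  }
  out <- list(results = do.call(rbind, rows), config = cfg, seed = seed)
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  agg <- stats::aggregate(cbind(pi, het, n_het_del, n_hom_del) ~ arm,
                          x$results, mean)
  cat("sim_result:", max(x$results$replicate), "replicates, scenario",
      x$config$scenario, "\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Compare genetic diversity between simulation arms
#'
#' Pairs replicates by index and reports per-arm mean diversity, the mean
#' paired differences, and Wilcoxon signed-rank p-values for selfing vs
#' outcrossing and outcrossing vs SNM.
#'
#' @param res a `sim_result` from [run_sim()].
#' @return list with `means` (per-arm mean pi) and `tests` (data frame of
#'   comparisons with mean differences and p-values).
#' @export
compare_arms <- function(res) {
  r <- res$results
  arms <- unique(r$arm)
  if (min(table(r$arm)) < 5) stop("need at least 5 replicates per arm")
  get <- function(a) r$pi[r$arm == a][order(r$replicate[r$arm == a])]
  means <- vapply(arms, function(a) mean(get(a)), 0)
  pairs <- list(c("selfing", "outcrossing"), c("outcrossing", "snm"))
  pairs <- Filter(function(p) all(p %in% arms), pairs)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    a <- get(p[1]); b <- get(p[2])
    pv <- if (all(a == b)) 1 else
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
    data.frame(comparison = paste(p[1], "vs", p[2]),
               mean_diff = mean(a - b), p_value = pv,
               stringsAsFactors = FALSE)
  }))
  list(means = means, tests = tests)
}

#' Write simulation results as TSV plus a JSON config echo
#' @param res a `sim_result`.
#' @param dir output directory.
#' @export
write_sim_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$results, file.path(dir, "sim_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- res$config
  class(meta) <- NULL
  meta$seed <- res$seed
  jsonlite::write_json(meta, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
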