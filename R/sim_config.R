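#' Simulation configuration for a TE invasion
#'
#' Builds and validates the parameter set of the forward simulator. Defaults
#' correspond to the standard single-population setup: five 1-Mb chromosomes,
#' a 100-kb piRNA cluster at the distal end of each chromosome, recombination
#' at 4 cM/Mb, transposition rate `u = 0.1` per copy and generation, neutral
#' insertions (`x = 0`), `N = 1000` diploids and equal per-copy mobilization of
#' full-length (FL) and internally deleted (ID) copies (`fl_id = 0.5`).
#'
#' @param chrom_len Integer vector of chromosome lengths in bp.
#' @param rr Recombination rate per chromosome in cM/Mb (recycled to the
#'   number of chromosomes).
#' @param cluster_len piRNA cluster length per chromosome in bp (one terminal
#'   cluster per chromosome, occupying the last `cluster_len` bp; recycled).
#' @param u Transposition rate per TE copy and generation (`u >= 0`).
#' @param conversion Conversion rate `c`: probability that a transposing FL
#'   element produces a fresh ID copy with two random breakpoints.
#' @param x Per-copy fitness cost; fitness of an individual with `n` copies is
#'   `max(0, 1 - x * n)`.
#' @param N Diploid population size (constant over time).
#' @param fl_id Per-copy mobilization weight of FL copies; ID copies carry
#'   weight `1 - fl_id`. At 0.5 every copy is an equally likely template.
#' @param consensus_len Length of the TE consensus sequence in bp (ID
#'   breakpoints are drawn on `1..consensus_len`).
#' @param n_fl Number of FL insertions seeding the invasion, each placed at a
#'   distinct random site on one haplotype of one individual (frequency
#'   `1/2N`).
#' @param n_pops Number of populations in the 1D stepping-stone chain.
#' @param migration_m Number of migrants copied at each migration event.
#' @param migration_interval Generations between migration events; every
#'   `migration_interval` generations migrants move from the most recently
#'   invaded population to the next naive one.
#' @param generations Total number of generations to simulate.
#' @param record_every Cadence (in generations) of the scalar time series.
#' @param sample_generations Generations at which full ID fingerprints are
#'   recorded; defaults to the final generation.
#' @param seed Optional integer seed; replicate `r` of a multi-replicate run
#'   uses `seed + r - 1`.
#'
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(conversion = 0.005, generations = 100, N = 100, n_fl = 30)
#' cfg$u
#' @export
sim_config <- function(chrom_len = rep(1000000L, 5),
                       rr = 4,
                       cluster_len = 100000L,
                       u = 0.1,
                       conversion = 0,
                       x = 0,
                       N = 1000L,
                       fl_id = 0.5,
                       consensus_len = 2907L,
                       n_fl = 300L,
                       n_pops = 1L,
                       migration_m = 0L,
                       migration_interval = 0L,
                       generations = 500L,
                       record_every = 1L,
                       sample_generations = NULL,
                       seed = NULL) {
  chrom_len <- as.integer(chrom_len)
  nchr <- length(chrom_len)
  rr <- rep_len(as.double(rr), nchr)
  cluster_len <- rep_len(as.integer(cluster_len), nchr)
  if (is.null(sample_generations)) sample_generations <- generations
  cfg <- list(
    chrom_len = chrom_len, rr = rr, cluster_len = cluster_len,
    u = as.double(u), conversion = as.double(conversion), x = as.double(x),
    N = as.integer(N), fl_id = as.double(fl_id),
    consensus_len = as.integer(consensus_len), n_fl = as.integer(n_fl),
    n_pops = as.integer(n_pops), migration_m = as.integer(migration_m),
    migration_interval = as.integer(migration_interval),
    generations = as.integer(generations),
    record_every = as.integer(record_every),
    sample_generations = as.integer(sample_generations),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$chrom_len) >= 1, all(cfg$chrom_len >= 1))
  if (any(cfg$cluster_len > cfg$chrom_len)) {
    abort("cluster length must not exceed chromosome length")
  }
  if (any(cfg$cluster_len < 0) || any(cfg$rr < 0)) {
    abort("cluster lengths and recombination rates must be nonnegative")
  }
  if (cfg$u < 0) abort("transposition rate u must be >= 0")
  for (nm in c("conversion", "fl_id")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(sprintf("%s must be in [0, 1]", nm))
    }
  }
  if (cfg$x < 0) abort("selection coefficient x must be >= 0")
  if (cfg$N < 2) abort("population size N must be >= 2")
  if (cfg$consensus_len < 2) abort("consensus length must be >= 2")
  if (cfg$n_fl < 0) abort("initial FL count must be >= 0")
  if (cfg$n_pops < 1) abort("need at least one population")
  if (cfg$migration_m > cfg$N) abort("migrant count exceeds population size")
  if (cfg$n_pops > 1 && cfg$migration_interval > 0 &&
      cfg$migration_interval * (cfg$n_pops - 1) > cfg$generations) {
    abort("migration schedule incompatible with total generations: the last naive population is never reached")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) of %s bp, clusters %s bp, rr %s cM/Mb\n",
              length(x$chrom_len), paste(unique(x$chrom_len), collapse = "/"),
              paste(unique(x$cluster_len), collapse = "/"),
              paste(unique(x$rr), collapse = "/")))
  cat(sprintf("  u = %g, c = %g, x = %g, N = %d, fl_id = %g, consensus %d bp\n",
              x$u, x$conversion, x$x, x$N, x$fl_id, x$consensus_len))
  cat(sprintf("  %d population(s), %d initial FL, %d generations",
              x$n_pops, x$n_fl, x$generations))
  if (x$n_pops > 1) {
    cat(sprintf(", %d migrants every %d generations",
                x$migration_m, x$migration_interval))
  }
  cat("\n")
  invisible(x)
}

# list passed to the C++ engine
cfg_for_engine <- function(cfg) {
  list(chrom_len = cfg$chrom_len, cluster_len = cfg$cluster_len, rr = cfg$rr,
       u = cfg$u, c = cfg$conversion, x = cfg$x, N = cfg$N, fl_id = cfg$fl_id,
       consensus_len = cfg$consensus_len)
}

#' Read or write a simulation configuration
#'
#' Configurations are stored as YAML (or JSON) using the simulator's CLI
#' vocabulary: `genome` (bp), `rr` (cM/Mb), `cluster` (bp), `u`, `c`, `x`,
#' `N`, `fl_id`, `n_fl`, `consensus`, `populations`, `migration` (`m`,
#' `interval`), `generations`, `record_every`, `sample_generations`, `seed`.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `read_config()` returns a [sim_config()]; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  mig <- raw$migration %||% list()
  sim_config(
    chrom_len = raw$genome %||% rep(1000000L, 5),
    rr = raw$rr %||% 4,
    cluster_len = raw$cluster %||% 100000L,
    u = raw$u %||% 0.1,
    conversion = raw$c %||% 0,
    x = raw$x %||% 0,
    N = raw$N %||% 1000L,
    fl_id = raw$fl_id %||% 0.5,
    consensus_len = raw$consensus %||% 2907L,
    n_fl = raw$n_fl %||% 300L,
    n_pops = raw$populations %||% 1L,
    migration_m = mig$m %||% 0L,
    migration_interval = mig$interval %||% 0L,
    generations = raw$generations %||% 500L,
    record_every = raw$record_every %||% 1L,
    sample_generations = raw$sample_generations,
    seed = raw$seed
  )
}

#' @rdname read_config
#' @param cfg A [sim_config()] object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- list(
    genome = cfg$chrom_len, rr = cfg$rr, cluster = cfg$cluster_len,
    u = cfg$u, c = cfg$conversion, x = cfg$x, N = cfg$N, fl_id = cfg$fl_id,
    consensus = cfg$consensus_len, n_fl = cfg$n_fl, populations = cfg$n_pops,
    migration = list(m = cfg$migration_m, interval = cfg$migration_interval),
    generations = cfg$generations, record_every = cfg$record_every,
    sample_generations = cfg$sample_generations
  )
  if (!is.null(cfg$seed)) out$seed <- cfg$seed
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
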